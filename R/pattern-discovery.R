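#' Euclidean distances between cell types for one gene
#'
#' For a single gene, each cell type is represented by the vector of its
#' replicate (per-embryo) phi values; the distance between two cell types is
#' the Euclidean distance between these replicate vectors. Replicate order
#' (embryo order) must be identical across cell types so coordinates align.
#'
#' @param profile Numeric matrix, cell types in rows, embryos (replicates)
#'   in columns; no missing values.
#' @return Symmetric matrix of pairwise distances with zero diagonal.
#' @export
celltype_distances <- function(profile) {
  if (!is.matrix(profile)) stop("profile must be a cell-types x embryos matrix")
  if (anyNA(profile)) {
    stop("profile has missing entries; replicate sets must be identical across cell types")
  }
  as.matrix(stats::dist(profile, method = "euclidean"))
}

#' Two-cluster cut by single-linkage hierarchical clustering
#'
#' Agglomerates items bottom-up under single linkage (cluster distance =
#' minimum pairwise distance) and stops before the final merge, returning
#' the two top-level clusters. Equivalently: the two components left after
#' deleting the single largest edge of a minimum spanning tree of the
#' distance matrix. When two candidate merges are at exactly equal distance,
#' the pair whose smallest member index is lowest (then lowest second index)
#' is merged, making the cut deterministic on degenerate inputs.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal,
#'   at least 2 items.
#' @return List with `cluster_a` and `cluster_b` (integer index vectors;
#'   `cluster_a` contains item 1), and `merge_height`, the linkage distance
#'   of the skipped final merge.
#' @export
single_linkage_two_cut <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 items to cut")
  if (ncol(d) != n || any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")

  clusters <- as.list(seq_len(n))
  # single-linkage distance between current clusters
  cd <- d
  diag(cd) <- Inf
  while (length(clusters) > 2) {
    m <- length(clusters)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    best_key <- c(Inf, Inf)
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        dd <- cd[a, b]
        key <- c(min(clusters[[a]][1], clusters[[b]][1]),
                 max(clusters[[a]][1], clusters[[b]][1]))
        if (dd < best_d ||
            (dd == best_d && (key[1] < best_key[1] ||
                              (key[1] == best_key[1] && key[2] < best_key[2])))) {
          best <- c(a, b)
          best_d <- dd
          best_key <- key
        }
      }
    }
    a <- best[1]; b <- best[2]
    merged <- sort(c(clusters[[a]], clusters[[b]]))
    keep <- setdiff(seq_len(m), c(a, b))
    new_cd <- matrix(Inf, m - 1, m - 1)
    if (length(keep)) {
      new_cd[seq_along(keep), seq_along(keep)] <- cd[keep, keep, drop = FALSE]
      new_cd[m - 1, seq_along(keep)] <- pmin(cd[a, keep], cd[b, keep])
      new_cd[seq_along(keep), m - 1] <- new_cd[m - 1, seq_along(keep)]
    }
    clusters <- c(clusters[keep], list(merged))
    cd <- new_cd
  }
  height <- cd[1, 2]
  ca <- clusters[[1]]; cb <- clusters[[2]]
  if (1L %in% cb) { tmp <- ca; ca <- cb; cb <- tmp }
  list(cluster_a = ca, cluster_b = cb, merge_height = height)
}

#' Type-5 ("hydrologist") sample quantile
#'
#' Hyndman-Fan type 5: with sorted values x_1..x_n and h = n*p + 0.5, the
#' quantile is x_1 for h <= 1, x_n for h >= n, and otherwise the linear
#' interpolation x_floor(h) + (h - floor(h)) * (x_floor(h)+1 - x_floor(h)).
#' This is the interpolation used for the TQR's quartiles.
#'
#' @param values Non-empty numeric vector.
#' @param p Probability (or vector of probabilities) in \[0, 1\].
#' @return Quantile value(s).
#' @export
#' @examples
#' quantile_type5(c(1, 2, 3, 4), 0.25)  # 1.5
quantile_type5 <- function(values, p) {
  if (!length(values)) stop("values must be non-empty")
  if (anyNA(values)) stop("values must not contain NA")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  x <- sort(values)
  n <- length(x)
  vapply(p, function(pp) {
    h <- n * pp + 0.5
    if (h <= 1) return(x[1])
    if (h >= n) return(x[n])
    lo <- floor(h)
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }, numeric(1))
}

#' Transquartile Range (TQR) of an ON/OFF split
#'
#' The reliability score of a two-cluster call: the first quartile of the
#' ON cluster's pooled values minus the third quartile of the OFF cluster's
#' pooled values, both computed with the type-5 quantile. The TQR grows
#' with the separation of the cluster means and shrinks as within-cluster
#' spread grows at fixed separation; it is negative when the clusters'
#' central halves overlap. No parametric estimate of variance or dispersion
#' is involved.
#'
#' @param on_values,off_values Non-empty numeric vectors of pooled replicate
#'   phi values for the ON and OFF cell types.
#' @return The TQR score (phi units).
#' @export
#' @examples
#' tqr_score(c(0.8, 0.9, 1.0, 1.1), c(0.0, 0.1, 0.2, 0.3))  # 0.60
tqr_score <- function(on_values, off_values) {
  quantile_type5(on_values, 0.25) - quantile_type5(off_values, 0.75)
}

#' Call the ON/OFF expression pattern of one gene
#'
#' Runs the per-gene procedure: Euclidean distances between cell-type
#' replicate vectors, single-linkage two-cluster cut, ON/OFF labelling
#' (the cluster with the larger pooled mean is ON; an exact tie goes to the
#' cluster containing the earlier cell type in canonical order), and TQR
#' scoring over the pooled replicate values of each side.
#'
#' @param profile Cell-types x embryos matrix of phi values, rownames the
#'   cell types in canonical order.
#' @param gene_id Optional gene identifier carried into the result.
#' @param pooled If `TRUE` (default) quartiles are computed over the pooled
#'   replicate values of a cluster's cells; if `FALSE`, over per-cell-type
#'   means.
#' @return List of class `pattern_call`: `gene_id`, `pattern` (named 0/1
#'   integer vector over cell types), `on_cells`, `tqr`, `on_values`,
#'   `off_values`, `merge_height`.
#' @export
call_pattern <- function(profile, gene_id = NA_character_, pooled = TRUE) {
  cell_types <- rownames(profile)
  if (is.null(cell_types)) stop("profile must have cell-type rownames")
  d <- celltype_distances(profile)
  cut <- single_linkage_two_cut(d)
  pool <- function(idx) as.vector(profile[idx, , drop = FALSE])
  va <- pool(cut$cluster_a); vb <- pool(cut$cluster_b)
  ma <- mean(va); mb <- mean(vb)
  if (ma > mb) {
    on_idx <- cut$cluster_a
  } else if (mb > ma) {
    on_idx <- cut$cluster_b
  } else {
    # tie: the cluster containing the earlier canonical cell type is ON
    on_idx <- if (min(cut$cluster_a) < min(cut$cluster_b)) cut$cluster_a else cut$cluster_b
  }
  off_idx <- setdiff(seq_len(nrow(profile)), on_idx)
  on_values <- pool(on_idx); off_values <- pool(off_idx)
  tqr <- if (pooled) {
    tqr_score(on_values, off_values)
  } else {
    tqr_score(rowMeans(profile[on_idx, , drop = FALSE]),
              rowMeans(profile[off_idx, , drop = FALSE]))
  }
  pattern <- stats::setNames(integer(length(cell_types)), cell_types)
  pattern[on_idx] <- 1L
  structure(
    list(gene_id = gene_id, pattern = pattern,
         on_cells = cell_types[sort(on_idx)], tqr = tqr,
         on_values = on_values, off_values = off_values,
         merge_height = cut$merge_height),
    class = "pattern_call")
}

# Build the cell-types x embryos profile array from a phi matrix + sheet.
# Returns list(values = 3d array [gene, cell_type, embryo], embryos used).
# Embryos that do not cover every cell type are dropped entirely so
# replicate vectors stay aligned; embryo order is sorted label order.
profile_array <- function(phi, sheet) {
  v <- if (inherits(phi, "phi_matrix")) phi$values else phi
  cell_types <- attr(sheet, "cell_types")
  sheet <- sheet[match(colnames(v), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) {
    missing <- setdiff(colnames(v), sheet$sample_id)
    stop("sample sheet does not cover sample(s): ",
         paste(missing, collapse = ", "))
  }
  embryos <- sort(unique(sheet$embryo))
  cover <- vapply(embryos, function(e) {
    all(cell_types %in% sheet$cell_type[sheet$embryo == e])
  }, logical(1))
  embryos <- embryos[cover]
  if (!length(embryos)) stop("no embryo covers all cell types")
  arr <- array(NA_real_, dim = c(nrow(v), length(cell_types), length(embryos)),
               dimnames = list(rownames(v), cell_types, embryos))
  for (e in embryos) {
    for (ct in cell_types) {
      j <- which(sheet$embryo == e & sheet$cell_type == ct)
      if (length(j) > 1) {
        stop(sprintf("multiple samples for embryo '%s', cell type '%s'; filter by platform first",
                     e, ct))
      }
      arr[, ct, e] <- v[, j]
    }
  }
  list(values = arr, embryos = embryos, cell_types = cell_types)
}

#' Discover and rank expression patterns for all genes
#'
#' Applies [call_pattern()] to every gene of a phi matrix and ranks the
#' calls by TQR, descending; ties are broken by gene id, ascending. Genes
#' with all-zero (or constant) values get TQR 0 and therefore sort after
#' every positive-TQR gene. The result is invariant to the column order of
#' the input: replicates are aligned by embryo label, not file order.
#'
#' @param phi A `phi_matrix` (or plain genes x samples matrix of phi
#'   values).
#' @param sheet A `sample_sheet` covering the matrix's samples. If it has a
#'   `platform` column with more than one value, filter first (see
#'   `platform`).
#' @param platform Optional platform label to filter the sheet (and the
#'   matrix columns) to before discovery.
#' @param pooled Passed to [call_pattern()].
#' @return Data frame of class `pattern_calls` with columns `gene_id`, one
#'   0/1 column per cell type in canonical order, `tqr`, and `rank`
#'   (1-based, in sorted order). Per-gene pooled ON/OFF values are kept in
#'   the `on_values`/`off_values` attributes (lists indexed by gene id).
#' @export
discover_and_rank <- function(phi, sheet, platform = NULL, pooled = TRUE) {
  v <- if (inherits(phi, "phi_matrix")) phi$values else phi
  if (!is.null(platform)) {
    if (!"platform" %in% names(sheet)) stop("sheet has no platform column")
    keep <- sheet$sample_id[sheet$platform == platform]
    if (!length(keep)) stop("no samples for platform: ", platform)
    sheet <- sample_sheet(as.data.frame(sheet)[sheet$platform == platform, ,
                                               drop = FALSE],
                          cell_types = attr(sheet, "cell_types"))
    v <- v[, colnames(v) %in% keep, drop = FALSE]
  }
  pa <- profile_array(v, sheet)
  genes <- rownames(v)
  calls <- lapply(seq_along(genes), function(i) {
    prof <- matrix(pa$values[i, , ], nrow = length(pa$cell_types),
                   dimnames = list(pa$cell_types, pa$embryos))
    call_pattern(prof, gene_id = genes[i], pooled = pooled)
  })
  bits <- do.call(rbind, lapply(calls, function(cl) cl$pattern))
  tqr <- vapply(calls, function(cl) cl$tqr, numeric(1))
  ord <- order(-tqr, genes)
  out <- data.frame(gene_id = genes[ord], bits[ord, , drop = FALSE],
                    tqr = tqr[ord], rank = seq_along(genes),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cell_types") <- pa$cell_types
  attr(out, "on_values") <- stats::setNames(
    lapply(calls[ord], function(cl) cl$on_values), out$gene_id)
  attr(out, "off_values") <- stats::setNames(
    lapply(calls[ord], function(cl) cl$off_values), out$gene_id)
  class(out) <- c("pattern_calls", "data.frame")
  out
}

#' Run the full discovery pipeline on counts
#'
#' Convenience wrapper: proportions (spikes excluded by default) -> phi
#' transform -> per-gene two-cut and TQR ranking. Also assembles a run
#' manifest (configuration, input hashes, package version) for
#' reproducibility.
#'
#' @param counts A [count_matrix()].
#' @param sheet A `sample_sheet`.
#' @param exclude_spikes Exclude spike-in rows from totals and output.
#' @param clustering_space `"phi"` (default) or `"proportion"`; the latter
#'   clusters raw proportions, for sensitivity analysis only.
#' @param platform,pooled Passed to [discover_and_rank()].
#' @return A `pattern_calls` data frame with a `manifest` attribute.
#' @export
discover_patterns <- function(counts, sheet, exclude_spikes = TRUE,
                              clustering_space = c("phi", "proportion"),
                              platform = NULL, pooled = TRUE) {
  clustering_space <- match.arg(clustering_space)
  props <- to_proportions(counts, exclude_spikes = exclude_spikes)
  mat <- if (clustering_space == "phi") phi_transform(props) else props$values
  calls <- discover_and_rank(mat, sheet, platform = platform, pooled = pooled)
  attr(calls, "manifest") <- list(
    tool = "tqrpatterns",
    version = as.character(utils::packageVersion("tqrpatterns")),
    config = list(exclude_spikes = exclude_spikes,
                  clustering_space = clustering_space,
                  platform = platform, pooled = pooled),
    n_genes = length(counts$gene_ids),
    n_spikes = sum(counts$is_spike),
    n_samples = length(counts$sample_ids))
  calls
}

#' Write a run manifest as JSON
#'
#' Serialises the manifest attached by [discover_patterns()], adding input
#' file hashes and a timestamp.
#'
#' @param calls A `pattern_calls` object from [discover_patterns()].
#' @param path Output JSON path.
#' @param inputs Named character vector of input file paths to hash (MD5).
#' @export
write_run_manifest <- function(calls, path, inputs = character()) {
  manifest <- attr(calls, "manifest")
  if (is.null(manifest)) stop("calls carry no manifest; use discover_patterns()")
  if (length(inputs)) {
    md5 <- tools::md5sum(inputs)
    manifest$input_md5 <- as.list(stats::setNames(unname(md5),
                                                  basename(inputs)))
  }
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
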