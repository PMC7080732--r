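#' Convert counts to within-sample proportions
#'
#' Depth normalisation only: each count is divided by its sample's total.
#' There is deliberately no across-gene normalisation (GC content,
#' transcript length); a gene's expression measure is the proportion it
#' contributes to its sample's reads, assumed independent of sequencing
#' depth. When `exclude_spikes` is set (the default for all downstream
#' analysis), spike-in rows are removed and the per-sample totals are
#' computed over endogenous genes only.
#'
#' @param x A [count_matrix()].
#' @param exclude_spikes Drop spike-in rows and exclude them from the
#'   per-sample totals (default `TRUE`).
#' @return An object of class `proportion_matrix`: list with `values`
#'   (genes x samples matrix of proportions in \[0, 1\]), `gene_ids`,
#'   `sample_ids`, and `totals` (the per-sample denominators actually used).
#' @export
to_proportions <- function(x, exclude_spikes = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  if (exclude_spikes && any(x$is_spike)) m <- m[!x$is_spike, , drop = FALSE]
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop("sample(s) with zero total counts over included genes: ",
         paste(colnames(m)[totals <= 0], collapse = ", "))
  }
  p <- sweep(m, 2, totals, "/")
  structure(
    list(values = p, gene_ids = rownames(m), sample_ids = colnames(m),
         totals = totals),
    class = "proportion_matrix")
}

#' The phi (arcsine-square-root) transformation of proportions
#'
#' Variance-stabilising transform phi(p) = 2 * asin(sqrt(p)), mapping
#' \[0, 1\] monotonically onto \[0, pi\]. The difference of two phi values is
#' Cohen's h, an effect-size index for proportions, so distances in phi
#' space are effect sizes. At low proportions phi(p) is approximately
#' 2 * sqrt(p).
#'
#' @param p Proportion(s) in \[0, 1\], or a `proportion_matrix`.
#' @return For numeric input, phi values of the same shape. For a
#'   `proportion_matrix`, an object of class `phi_matrix` (list with
#'   `values`, `gene_ids`, `sample_ids`, `totals`).
#' @export
#' @examples
#' phi_transform(c(0, 0.25, 1))  # 0, pi/3, pi
phi_transform <- function(p) {
  if (inherits(p, "proportion_matrix")) {
    v <- phi_transform(p$values)
    return(structure(
      list(values = v, gene_ids = p$gene_ids, sample_ids = p$sample_ids,
           totals = p$totals),
      class = "phi_matrix"))
  }
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE)) {
    stop("proportions must lie in [0, 1]")
  }
  p <- pmin(pmax(p, 0), 1)  # clamp floating-point dust at the boundaries
  2 * asin(sqrt(p))
}

#' Cohen's h effect size for two proportions
#'
#' h = phi(p1) - phi(p2); antisymmetric in its arguments. Ranges over
#' \[-pi, pi\], with |h| = pi only for the maximal contrast 1 vs 0.
#'
#' @param p1,p2 Proportions in \[0, 1\] (vectorised).
#' @return Effect size(s) in phi units.
#' @export
#' @examples
#' cohens_h(0.25, 0)  # pi/3
cohens_h <- function(p1, p2) {
  phi_transform(p1) - phi_transform(p2)
}

#' Per-cell-type mean of phi values, with optional display clipping
#'
#' Averages the phi-transformed values across each cell type's replicate
#' samples. `clip_at` caps values for display (heat maps saturate above a
#' threshold, e.g. 0.05, so low cell-specific signals remain visible); the
#' clipped matrix is never used for clustering or TQR scoring.
#'
#' @param phi A `phi_matrix` (or plain genes x samples matrix).
#' @param sheet A `sample_sheet` covering the matrix's samples.
#' @param clip_at Optional ceiling; values above it are set to it.
#' @return Genes x cell-types matrix of mean phi values, cell types in
#'   canonical order.
#' @export
celltype_mean_matrix <- function(phi, sheet, clip_at = NULL) {
  v <- if (inherits(phi, "phi_matrix")) phi$values else phi
  cell_types <- attr(sheet, "cell_types")
  sheet <- sheet[match(colnames(v), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("sample sheet does not cover all samples")
  out <- matrix(NA_real_, nrow(v), length(cell_types),
                dimnames = list(rownames(v), cell_types))
  for (ct in cell_types) {
    idx <- which(sheet$cell_type == ct)
    if (!length(idx)) stop("cell type with no samples in sheet: ", ct)
    out[, ct] <- rowMeans(v[, idx, drop = FALSE])
  }
  if (!is.null(clip_at)) out <- pmin(out, clip_at)
  out
}

#' Write a phi matrix to TSV
#'
#' Same layout as the count table (gene ids in the first column, sample ids
#' in the header), values at 9 significant digits.
#'
#' @param phi A `phi_matrix`.
#' @param path Output path.
#' @export
write_phi_matrix <- function(phi, path) {
  stopifnot(inherits(phi, "phi_matrix"))
  m <- signif(phi$values, 9)
  df <- data.frame(gene_id = phi$gene_ids, m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
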