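#' Configuration for the synthetic-embryo count simulator
#'
#' Defines the generative model for a synthetic 16-cell-stage dataset:
#' per-gene baseline proportions are log-normal; a chosen subset of genes
#' gets a planted ON/OFF pattern with a target Cohen's h between ON and OFF
#' proportions; every gene x embryo combination receives a multiplicative
#' log-normal batch effect shared by all cells of that embryo (this is what
#' makes same-embryo cells more alike than same-cell-type cells across
#' embryos); expected proportions are renormalised per sample; library
#' sizes are log-normal; and counts are negative-binomial. ERCC-style
#' spike-in rows have fixed expected proportions (no embryo effect) with
#' the same count noise; silent genes are all-zero.
#'
#' @param n_genes Number of endogenous genes (default 1000).
#' @param n_embryos Number of embryos/batches (default 4).
#' @param cell_types Cell types per embryo (default the canonical 8).
#' @param n_patterned Number of genes with a planted pattern (default 40).
#' @param pattern_set List of 0/1 bit vectors to plant, cycled through in
#'   order (default the nine named reference patterns).
#' @param effect_size_h Target Cohen's h between ON and OFF expected
#'   proportions, in (0, pi] (default 0.08).
#' @param baseline_logmean,baseline_logsd Log-normal parameters of the
#'   baseline expected proportion; `baseline_logmean = NULL` (default)
#'   centres the distribution at 1/n_genes. Default `baseline_logsd` 1.5,
#'   a realistic several-orders-of-magnitude expression spread.
#' @param batch_logsd SD of the log-normal gene x embryo batch effect
#'   (default 0.4).
#' @param dispersion Negative-binomial overdispersion (`size = 1/dispersion`;
#'   0 = Poisson). The default 0.1 puts within-embryo replicate correlation
#'   of phi values near 0.9 at the other defaults.
#' @param library_size_mean,library_size_logsd Log-normal library sizes
#'   (defaults 2e5 and 0.3; scaled down from the tens of millions of reads
#'   per cell of a real run so simulations are fast — depth is a knob, not
#'   a structural feature).
#' @param n_silent Genes with zero expected expression (default 50).
#' @param n_spikes Spike-in rows (default 30), occupying `spike_fraction`
#'   (default 0.05) of each library in expectation.
#' @param spike_fraction Expected fraction of counts from spike-ins.
#' @param intermediate_fraction Fraction of patterned genes given two
#'   designated pattern cells at an intermediate level (default 0) —
#'   emulates genes like Lefty whose weakly expressing pattern cells get
#'   clustered OFF.
#' @param intermediate_placement `"geomean"` (default): intermediate cells
#'   at the geometric mean of the ON/OFF proportions, which lies below the
#'   phi midpoint; `"phi_mid"`: exactly midway in phi space.
#' @param seed Optional integer seed; generation is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_embryos = 4,
                       cell_types = ciona_cell_types(),
                       n_patterned = 40,
                       pattern_set = reference_patterns(cell_types),
                       effect_size_h = 0.08,
                       baseline_logmean = NULL, baseline_logsd = 1.5,
                       batch_logsd = 0.4, dispersion = 0.1,
                       library_size_mean = 2e5, library_size_logsd = 0.3,
                       n_silent = 50, n_spikes = 30, spike_fraction = 0.05,
                       intermediate_fraction = 0,
                       intermediate_placement = c("geomean", "phi_mid"),
                       seed = NULL) {
  cfg <- list(n_genes = n_genes, n_embryos = n_embryos,
              cell_types = cell_types, n_patterned = n_patterned,
              pattern_set = pattern_set, effect_size_h = effect_size_h,
              baseline_logmean = if (is.null(baseline_logmean))
                log(1 / n_genes) else baseline_logmean,
              baseline_logsd = baseline_logsd, batch_logsd = batch_logsd,
              dispersion = dispersion,
              library_size_mean = library_size_mean,
              library_size_logsd = library_size_logsd,
              n_silent = n_silent, n_spikes = n_spikes,
              spike_fraction = spike_fraction,
              intermediate_fraction = intermediate_fraction,
              intermediate_placement = match.arg(intermediate_placement),
              seed = seed)
  if (cfg$n_patterned + cfg$n_silent > cfg$n_genes) {
    stop("n_patterned + n_silent must not exceed n_genes")
  }
  if (cfg$effect_size_h <= 0 || cfg$effect_size_h > pi) {
    stop("effect_size_h must lie in (0, pi]")
  }
  for (f in c("baseline_logsd", "batch_logsd", "dispersion",
              "library_size_logsd")) {
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  }
  if (cfg$intermediate_fraction < 0 || cfg$intermediate_fraction > 1) {
    stop("intermediate_fraction must lie in [0, 1]")
  }
  bad <- vapply(cfg$pattern_set, function(b) {
    length(b) != length(cell_types) || !all(b %in% c(0L, 1L)) ||
      sum(b) < 1 || sum(b) > length(cell_types) - 1
  }, logical(1))
  if (any(bad)) stop("pattern_set entries must be 0/1 vectors with 1..",
                     length(cell_types) - 1, " ON cells")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a synthetic-embryo count dataset with ground truth
#'
#' Runs the generative model of [sim_config()]:
#' (1) draw a baseline expected proportion per gene from a log-normal;
#' (2) for patterned genes, set the ON level to the baseline (redrawn until
#' the target effect size is feasible) and the OFF level so that the
#' difference of phi values of the renormalised proportions equals
#' `effect_size_h`; intermediate-class genes have two designated pattern
#' cells placed between ON and OFF;
#' (3) multiply every gene x embryo by a shared log-normal batch factor;
#' (4) renormalise each sample's expected proportions to sum to 1;
#' (5) draw library sizes from a log-normal; and
#' (6) draw counts from a negative binomial with those means.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (a [count_matrix()] including spike rows),
#'   `sheet` (a `sample_sheet`, one sample per embryo x cell type,
#'   platform `"sim"`), `truth` (data frame: `gene_id`, `class` in
#'   patterned/intermediate/uniform/silent/spike, `pattern` bit string or
#'   NA, `intermediate_cells`, `on_prop`, `off_prop`, `realised_h`), and
#'   `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_ct <- length(cfg$cell_types)
  n_pat <- cfg$n_patterned
  n_int <- floor(cfg$intermediate_fraction * n_pat)
  gene_ids <- sprintf("gene%0*d", nchar(cfg$n_genes), seq_len(cfg$n_genes))
  class <- rep("uniform", cfg$n_genes)
  if (n_pat > 0) class[seq_len(n_pat)] <- "patterned"
  if (n_int > 0) class[seq_len(n_int)] <- "intermediate"
  if (cfg$n_silent > 0) {
    class[(cfg$n_genes - cfg$n_silent + 1):cfg$n_genes] <- "silent"
  }

  b <- stats::rlnorm(cfg$n_genes, cfg$baseline_logmean, cfg$baseline_logsd)
  b[class == "silent"] <- 0

  # spikes: fixed expected levels spanning ~3 decades, scaled so they take
  # spike_fraction of the expected library
  spike_ids <- character(0)
  spike_levels <- numeric(0)
  if (cfg$n_spikes > 0) {
    spike_ids <- sprintf("ERCC-%05d", seq_len(cfg$n_spikes))
    raw <- 10^seq(0, 3, length.out = cfg$n_spikes)
    target <- sum(b) * cfg$spike_fraction / (1 - cfg$spike_fraction)
    spike_levels <- raw / sum(raw) * target
  }
  total0 <- sum(b) + sum(spike_levels)  # provisional normalising total

  # expected level per gene x cell type, before batch effects
  E <- matrix(rep(b, n_ct), nrow = cfg$n_genes, ncol = n_ct,
              dimnames = list(gene_ids, cfg$cell_types))
  pattern_str <- rep(NA_character_, cfg$n_genes)
  inter_cells <- rep(NA_character_, cfg$n_genes)
  on_prop <- rep(NA_real_, cfg$n_genes)
  off_prop <- rep(NA_real_, cfg$n_genes)

  if (n_pat > 0) {
    # intermediate placement needs >= 3 ON cells to leave an ON majority
    pat_pool <- cfg$pattern_set
    int_pool <- Filter(function(bb) sum(bb) >= 3, pat_pool)
    if (n_int > 0 && !length(int_pool)) {
      stop("intermediate_fraction > 0 requires pattern_set entries with >= 3 ON cells")
    }
    assigned <- rep(seq_along(pat_pool), length.out = n_pat)
    for (k in seq_len(n_pat)) {
      g <- k
      bits <- if (class[g] == "intermediate") {
        int_pool[[rep(seq_along(int_pool), length.out = n_int)[k]]]
      } else {
        pat_pool[[assigned[k]]]
      }
      # redraw the baseline until the target h is feasible (ON phi > h)
      tries <- 0
      repeat {
        p_on <- b[g] / total0
        if (phi_transform(min(p_on, 1)) > cfg$effect_size_h) break
        tries <- tries + 1
        if (tries > 1000) {
          stop("infeasible effect size: cannot place an OFF level below ON for gene ", gene_ids[g])
        }
        b[g] <- stats::rlnorm(1, cfg$baseline_logmean, cfg$baseline_logsd)
      }
      phi_on <- phi_transform(p_on)
      phi_off <- phi_on - cfg$effect_size_h
      p_off <- sin(phi_off / 2)^2
      lev_on <- p_on * total0
      lev_off <- p_off * total0
      E[g, ] <- ifelse(bits == 1, lev_on, lev_off)
      if (class[g] == "intermediate") {
        on_ct <- which(bits == 1)
        demote <- utils::tail(on_ct, 2)
        lev_mid <- if (cfg$intermediate_placement == "geomean") {
          sqrt(lev_on * lev_off)
        } else {
          sin((phi_on + phi_off) / 4)^2 * total0
        }
        E[g, demote] <- lev_mid
        inter_cells[g] <- paste(cfg$cell_types[demote], collapse = ",")
      }
      pattern_str[g] <- pattern_string(bits)
      on_prop[g] <- p_on
      off_prop[g] <- p_off
    }
  }

  embryos <- sprintf("E%d", seq_len(cfg$n_embryos))
  batch <- matrix(exp(stats::rnorm(cfg$n_genes * cfg$n_embryos, 0,
                                   cfg$batch_logsd)),
                  nrow = cfg$n_genes)

  sample_ids <- as.vector(outer(cfg$cell_types, embryos,
                                function(ct, e) paste(e, ct, sep = "_")))
  sheet <- sample_sheet(data.frame(
    sample_id = sample_ids,
    embryo = rep(embryos, each = n_ct),
    cell_type = rep(cfg$cell_types, cfg$n_embryos),
    platform = "sim",
    stringsAsFactors = FALSE), cell_types = cfg$cell_types)

  n_samples <- length(sample_ids)
  lib <- stats::rlnorm(n_samples, log(cfg$library_size_mean),
                       cfg$library_size_logsd)
  n_total <- cfg$n_genes + cfg$n_spikes
  counts <- matrix(0, n_total, n_samples,
                   dimnames = list(c(gene_ids, spike_ids), sample_ids))
  size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else Inf
  for (j in seq_len(n_samples)) {
    e <- match(sheet$embryo[j], embryos)
    ct <- match(sheet$cell_type[j], cfg$cell_types)
    w <- c(E[, ct] * batch[, e], spike_levels)
    p <- w / sum(w)
    mu <- p * lib[j]
    counts[, j] <- if (is.finite(size)) {
      stats::rnbinom(n_total, mu = mu, size = size)
    } else {
      stats::rpois(n_total, mu)
    }
  }

  truth <- data.frame(
    gene_id = c(gene_ids, spike_ids),
    class = c(class, rep("spike", cfg$n_spikes)),
    pattern = c(pattern_str, rep(NA_character_, cfg$n_spikes)),
    intermediate_cells = c(inter_cells, rep(NA_character_, cfg$n_spikes)),
    on_prop = c(on_prop, rep(NA_real_, cfg$n_spikes)),
    off_prop = c(off_prop, rep(NA_real_, cfg$n_spikes)),
    stringsAsFactors = FALSE)
  truth$realised_h <- ifelse(is.na(truth$on_prop), NA_real_,
                             cohens_h(truth$on_prop, truth$off_prop))

  list(counts = count_matrix(counts), sheet = sheet, truth = truth,
       config = cfg)
}

#' Score pattern recovery against simulation ground truth
#'
#' Quantifies how well a ranked call list recovers the planted patterns:
#' the fraction of planted (patterned + intermediate) genes appearing in
#' the top `top_n` ranks, the fraction of those recovered whose called bit
#' vector is exactly the planted one, the median rank of planted genes, and
#' a rank summary for silent and uniform genes.
#'
#' @param calls Ranked `pattern_calls` over the endogenous genes.
#' @param truth Truth data frame from [simulate_dataset()].
#' @param top_n Rank window; defaults to the number of planted genes.
#' @return List of class `recovery_metrics`: `n_planted`, `top_n`,
#'   `frac_recovered`, `frac_exact_pattern`, `median_planted_rank`,
#'   `null_rank_summary`. With zero planted genes the fractions are `NA`.
#' @export
evaluate_recovery <- function(calls, truth, top_n = NULL) {
  endo <- truth[truth$class != "spike", , drop = FALSE]
  if (!setequal(endo$gene_id, calls$gene_id)) {
    stop("calls and truth cover different gene sets")
  }
  planted <- endo[endo$class %in% c("patterned", "intermediate"), ,
                  drop = FALSE]
  if (is.null(top_n)) top_n <- nrow(planted)
  if (nrow(planted) == 0) {
    return(structure(list(n_planted = 0L, top_n = top_n,
                          frac_recovered = NA_real_,
                          frac_exact_pattern = NA_real_,
                          median_planted_rank = NA_real_,
                          null_rank_summary = NULL),
                     class = "recovery_metrics"))
  }
  cell_types <- attr(calls, "cell_types")
  bits <- as.matrix(as.data.frame(calls)[, cell_types, drop = FALSE])
  called_str <- apply(bits, 1, pattern_string)
  rank_of <- stats::setNames(calls$rank, calls$gene_id)
  called_of <- stats::setNames(called_str, calls$gene_id)

  pr <- rank_of[planted$gene_id]
  recovered <- pr <= top_n
  exact <- called_of[planted$gene_id] == planted$pattern
  null_genes <- endo$gene_id[endo$class %in% c("uniform", "silent")]
  structure(
    list(n_planted = nrow(planted), top_n = top_n,
         frac_recovered = mean(recovered),
         frac_exact_pattern = if (any(recovered)) mean(exact[recovered]) else NA_real_,
         median_planted_rank = stats::median(pr),
         null_rank_summary = summary(rank_of[null_genes])),
    class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf(
    "recovery: %d planted genes, %.1f%% in top %d ranks, %.1f%% of those with exact pattern (median planted rank %.1f)\n",
    x$n_planted, 100 * x$frac_recovered, x$top_n,
    100 * x$frac_exact_pattern, x$median_planted_rank))
  invisible(x)
}

#' Write simulation outputs to a directory
#'
#' Writes the count table, sample sheet, ground truth and configuration
#' (YAML-like key: value text) as plain-text files.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(sim$sheet, file.path(dir, "samples.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  scalar <- Filter(function(x) is.atomic(x) && length(x) == 1,
                   unclass(cfg))
  lines <- c(
    vapply(names(scalar), function(k) paste0(k, ": ", format(scalar[[k]])),
           character(1)),
    paste0("cell_types: [", paste(cfg$cell_types, collapse = ", "), "]"),
    paste0("pattern_set: [",
           paste(vapply(cfg$pattern_set, pattern_string, character(1)),
                 collapse = ", "), "]"))
  writeLines(lines, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
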