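#' Number of detected genes per sample
#'
#' A gene counts as detected in a sample when its measured count is greater
#' than zero. Spike-in rows are excluded by default.
#'
#' @param x A [count_matrix()].
#' @param include_spikes Count spike-in rows too (default `FALSE`).
#' @return Named integer vector, one entry per sample.
#' @export
detected_genes_per_sample <- function(x, include_spikes = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  if (!include_spikes) m <- m[!x$is_spike, , drop = FALSE]
  colSums(m > 0)
}

#' Sample-sample correlation of normalised expression
#'
#' Pearson (or Spearman) correlation between sample columns of a phi or
#' proportion matrix, after optionally removing genes with zero values in
#' every sample. A constant column has undefined correlation; affected
#' entries are reported as `NA`, never silently zero.
#'
#' @param x A `phi_matrix`, `proportion_matrix`, or plain genes x samples
#'   matrix (spike rows are assumed already excluded upstream by
#'   [to_proportions()]).
#' @param drop_all_zero_genes Remove genes that are zero in all samples
#'   before correlating (default `TRUE`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(x, drop_all_zero_genes = TRUE,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  v <- if (is.list(x)) x$values else x
  if (ncol(v) < 2) stop("need at least 2 samples")
  if (drop_all_zero_genes) v <- v[rowSums(v != 0) > 0, , drop = FALSE]
  r <- suppressWarnings(stats::cor(v, method = method))
  diag(r) <- 1
  r
}

#' Fraction of variance explained per principal component
#'
#' PCA of the gene-centered sample matrix (samples as observations,
#' covariance, no scaling): each gene's mean across samples is subtracted,
#' and the eigen-spectrum of the resulting sample covariance gives the
#' variance fraction per component, in descending order.
#'
#' @param x A `phi_matrix` or plain genes x samples matrix.
#' @return Numeric vector of variance fractions, summing to 1.
#' @export
pca_variance_explained <- function(x) {
  v <- if (is.list(x)) x$values else x
  if (ncol(v) < 2) stop("need at least 2 samples")
  pr <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  vars <- pr$sdev^2
  vars / sum(vars)
}

#' Assemble a quality-control report
#'
#' Bundles the standard QC surfaces: detected genes per sample, the
#' sample correlation matrix of phi-transformed proportions (spikes and
#' all-zero genes excluded), a single-linkage sample ordering for heat-map
#' display (using the same linkage machinery as pattern discovery, on
#' 1 - correlation), and PCA variance fractions.
#'
#' @param counts A [count_matrix()].
#' @param sheet A `sample_sheet`.
#' @param method Correlation method, see [sample_correlation()].
#' @return List of class `qc_report` with elements `detected`,
#'   `correlation`, `sample_order`, `pca_variance`, `pc12_percent`.
#' @export
qc_report <- function(counts, sheet, method = "pearson") {
  phi <- phi_transform(to_proportions(counts, exclude_spikes = TRUE))
  detected <- detected_genes_per_sample(counts)
  r <- sample_correlation(phi, drop_all_zero_genes = TRUE, method = method)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "single")
  vf <- pca_variance_explained(phi)
  structure(
    list(detected = detected,
         correlation = r,
         sample_order = colnames(r)[hc$order],
         pca_variance = vf,
         pc12_percent = 100 * sum(vf[seq_len(min(2, length(vf)))])),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples; detected genes %d-%d; PC1+PC2 explain %.1f%% of variance\n",
              length(x$detected), min(x$detected), max(x$detected),
              x$pc12_percent))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report`.
#' @param path Output JSON path.
#' @export
write_qc_report <- function(report, path) {
  out <- list(
    detected = as.list(report$detected),
    correlation = report$correlation,
    sample_order = report$sample_order,
    pca_variance = report$pca_variance,
    pc12_percent = report$pc12_percent)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
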