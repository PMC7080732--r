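#' Construct a validated count matrix
#'
#' The basic container for the pipeline: a genes x samples matrix of
#' non-negative integer counts, with a per-gene flag marking spike-in rows
#' (identified by gene-id prefix, ERCC-style).
#'
#' @param counts Numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids). All entries must
#'   be non-negative integers.
#' @param spike_prefix Gene-id prefix identifying spike-in rows
#'   (default `"ERCC-"`).
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (the integer matrix), `gene_ids`, `sample_ids`, `is_spike`
#'   (logical per gene), and `spike_prefix`.
#' @export
count_matrix <- function(counts, spike_prefix = "ERCC-") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("counts must have rownames (gene ids) and colnames (sample ids)")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(counts)) + 1
    j <- ((bad[1] - 1) %/% nrow(counts)) + 1
    stop(sprintf(
      "counts must be non-negative integers; offending value %s at gene '%s', sample '%s'",
      format(counts[i, j]), gene_ids[i], sample_ids[j]))
  }
  storage.mode(counts) <- "double"  # counts can exceed .Machine$integer.max
  structure(
    list(counts = counts,
         gene_ids = gene_ids,
         sample_ids = sample_ids,
         is_spike = startsWith(gene_ids, spike_prefix),
         spike_prefix = spike_prefix),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d spike-in rows, prefix '%s')\n",
              length(x$gene_ids), length(x$sample_ids),
              sum(x$is_spike), x$spike_prefix))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a genes x samples count table from TSV
#'
#' Expects a tab-delimited file with a header row of sample ids and the gene
#' id in the first column. Cells must be non-negative integers; violations
#' are reported with the offending gene and sample.
#'
#' @param path Path to the TSV file.
#' @param spike_prefix Gene-id prefix marking spike-in rows.
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, spike_prefix = "ERCC-") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a gene-id column and >= 1 sample column")
  gene_ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    # locate the first non-numeric cell for the error message
    for (j in seq_len(ncol(mat))) {
      v <- suppressWarnings(as.numeric(mat[, j]))
      if (anyNA(v)) {
        i <- which(is.na(v))[1]
        stop(sprintf("non-numeric count '%s' at gene '%s', sample '%s'",
                     mat[i, j], gene_ids[i], colnames(mat)[j]))
      }
    }
    storage.mode(mat) <- "double"
  }
  rownames(mat) <- gene_ids
  count_matrix(mat, spike_prefix = spike_prefix)
}

#' Read a MatrixMarket count matrix with gene/sample sidecar files
#'
#' Alternative input dialect for the same container: a sparse `.mtx` file
#' plus one-id-per-line gene and sample files (genes in rows).
#'
#' @param mtx_path Path to the MatrixMarket file.
#' @param genes_path,samples_path Paths to plain-text files with one gene id
#'   (respectively sample id) per line, ordered as in the matrix.
#' @param spike_prefix Gene-id prefix marking spike-in rows.
#' @return A [count_matrix()].
#' @export
read_count_mtx <- function(mtx_path, genes_path, samples_path,
                           spike_prefix = "ERCC-") {
  m <- as.matrix(Matrix::readMM(mtx_path))
  gene_ids <- readLines(genes_path)
  sample_ids <- readLines(samples_path)
  if (nrow(m) != length(gene_ids) || ncol(m) != length(sample_ids)) {
    stop(sprintf("matrix is %d x %d but sidecars list %d genes and %d samples",
                 nrow(m), ncol(m), length(gene_ids), length(sample_ids)))
  }
  dimnames(m) <- list(gene_ids, sample_ids)
  count_matrix(m, spike_prefix = spike_prefix)
}

#' Write a count matrix to TSV
#'
#' @param x A [count_matrix()].
#' @param path Output path.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene_id = x$gene_ids, x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet maps each sample to an embryo (batch) and one of the
#' canonical cell types, with an optional free `platform` tag (e.g.
#' HiSeq/MiSeq). Each (embryo, cell_type, platform) combination may occur at
#' most once.
#'
#' @param path Path to a TSV with header columns `sample_id`, `embryo`,
#'   `cell_type` and optionally `platform`.
#' @param cell_types Allowed cell-type vocabulary, in canonical order.
#'   Defaults to the eight 16-cell Ciona blastomere types.
#' @return A `data.frame` of class `sample_sheet` with character columns
#'   `sample_id`, `embryo`, `cell_type` and, if present, `platform`.
#' @export
read_sample_sheet <- function(path, cell_types = ciona_cell_types()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  sample_sheet(df, cell_types = cell_types)
}

#' Validate a sample sheet data frame
#'
#' @param df Data frame with columns `sample_id`, `embryo`, `cell_type`,
#'   optionally `platform`.
#' @inheritParams read_sample_sheet
#' @return The validated `sample_sheet`.
#' @export
sample_sheet <- function(df, cell_types = ciona_cell_types()) {
  need <- c("sample_id", "embryo", "cell_type")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$embryo <- as.character(df$embryo)
  df$cell_type <- as.character(df$cell_type)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  unknown <- setdiff(df$cell_type, cell_types)
  if (length(unknown)) {
    stop(sprintf("unknown cell_type '%s'; allowed: %s",
                 unknown[1], paste(cell_types, collapse = ", ")))
  }
  key <- if ("platform" %in% names(df)) {
    paste(df$embryo, df$cell_type, df$platform, sep = "\r")
  } else {
    paste(df$embryo, df$cell_type, sep = "\r")
  }
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE]
    stop(sprintf("duplicate (embryo, cell_type%s) assignment: embryo '%s', cell_type '%s'",
                 if ("platform" %in% names(df)) ", platform" else "",
                 d$embryo[1], d$cell_type[1]))
  }
  attr(df, "cell_types") <- cell_types
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet to TSV
#'
#' @param sheet A `sample_sheet`.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
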