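#' Write ranked pattern calls to TSV
#'
#' Columns: `gene_id`, one 0/1 column per cell type in canonical order,
#' `tqr` (15 significant digits), `rank`. Calls must be sorted by rank with
#' ranks unique; reading the file back reproduces patterns and ranks
#' bit-exactly and TQR scores to well beyond 12 significant digits.
#'
#' @param calls A `pattern_calls` data frame (see [discover_and_rank()]).
#' @param path Output path.
#' @export
write_pattern_calls <- function(calls, path) {
  cell_types <- attr(calls, "cell_types")
  if (is.null(cell_types)) {
    cell_types <- setdiff(names(calls), c("gene_id", "tqr", "rank"))
  }
  need <- c("gene_id", cell_types, "tqr", "rank")
  missing <- setdiff(need, names(calls))
  if (length(missing)) stop("calls missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(calls)) {
    if (anyDuplicated(calls$rank) || is.unsorted(calls$rank)) {
      stop("calls must be sorted by unique ranks")
    }
  }
  df <- as.data.frame(calls)[, need, drop = FALSE]
  df$tqr <- vapply(df$tqr, function(x) sprintf("%.15g", x), character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pattern-call table written by [write_pattern_calls()]
#'
#' @param path Path to the TSV.
#' @param cell_types Cell-type columns expected, in canonical order.
#' @return A `pattern_calls` data frame.
#' @export
read_pattern_calls <- function(path, cell_types = ciona_cell_types()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene_id", cell_types, "tqr", "rank")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("call table missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, need, drop = FALSE]
  for (ct in cell_types) {
    if (!all(df[[ct]] %in% c(0L, 1L))) stop("non-binary pattern bit in column ", ct)
    df[[ct]] <- as.integer(df[[ct]])
  }
  df$rank <- as.integer(df$rank)
  attr(df, "cell_types") <- cell_types
  class(df) <- c("pattern_calls", "data.frame")
  df
}
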