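#' Encode a set of ON cells as a pattern bit vector
#'
#' @param on_cells Character vector of ON cell types (subset of the
#'   canonical set; may be empty for a catalogue value, though a clustering
#'   call always has 1..7 ON cells).
#' @param cell_types Canonical cell-type order.
#' @return Named integer 0/1 vector over `cell_types`.
#' @export
#' @examples
#' encode_pattern("B5.2")                       # 00000001
#' encode_pattern(c("a5.3","a5.4","b5.3","b5.4"))  # animal hemisphere
encode_pattern <- function(on_cells, cell_types = ciona_cell_types()) {
  unknown <- setdiff(on_cells, cell_types)
  if (length(unknown)) {
    stop("unknown cell type(s): ", paste(unknown, collapse = ", "))
  }
  stats::setNames(as.integer(cell_types %in% on_cells), cell_types)
}

#' Decode a pattern bit vector to its ON cells
#'
#' @param bits 0/1 vector in canonical cell-type order.
#' @param cell_types Canonical cell-type order.
#' @return Character vector of ON cell types.
#' @export
decode_pattern <- function(bits, cell_types = ciona_cell_types()) {
  if (length(bits) != length(cell_types)) stop("bit vector has wrong length")
  if (!all(bits %in% c(0, 1))) stop("bits must be 0/1")
  cell_types[bits == 1]
}

# compact string form used as a hash key, e.g. "00000001"
pattern_string <- function(bits) paste(as.integer(bits), collapse = "")

#' Named reference expression patterns of the 16-cell embryo
#'
#' Nine named territory patterns used as the reference set for
#' novel-pattern detection: animal and vegetal hemispheres, anterior and
#' posterior halves, the posterior-vegetal and anterior-vegetal pairs,
#' expression in B5.2 only (the postplasmic/PEM territory), everything
#' except B5.2, and the vegetal territory minus B5.2. Membership beyond
#' the textually attested patterns (animal, anterior, B5.2-only,
#' all-except-B5.2) is a synthetic stand-in for the published reference
#' set.
#'
#' @param cell_types Canonical cell-type order.
#' @return Named list of 0/1 bit vectors.
#' @export
reference_patterns <- function(cell_types = ciona_cell_types()) {
  enc <- function(...) encode_pattern(c(...), cell_types)
  list(
    animal            = enc("a5.3", "a5.4", "b5.3", "b5.4"),
    vegetal           = enc("A5.1", "A5.2", "B5.1", "B5.2"),
    anterior          = enc("a5.3", "a5.4", "A5.1", "A5.2"),
    posterior         = enc("b5.3", "b5.4", "B5.1", "B5.2"),
    anterior_vegetal  = enc("A5.1", "A5.2"),
    posterior_vegetal = enc("B5.1", "B5.2"),
    b52_only          = enc("B5.2"),
    all_except_b52    = enc("a5.3", "a5.4", "b5.3", "b5.4", "A5.1", "A5.2", "B5.1"),
    vegetal_except_b52 = enc("A5.1", "A5.2", "B5.1")
  )
}

#' Load a known-pattern catalogue from TSV
#'
#' Each row is a gene id followed either by 8 bit columns (the known in
#' situ pattern in canonical cell-type order) or the single word
#' `unknown`. An optional trailing column may list alternate acceptable
#' patterns as comma-separated 8-character bit strings (used where an in
#' situ probe cross-detects paralogues, so more than one pattern counts as
#' a match).
#'
#' @param path Path to the catalogue TSV (no header).
#' @param cell_types Canonical cell-type order.
#' @param reference Named list of reference bit vectors used to flag novel
#'   patterns; defaults to [reference_patterns()].
#' @return Object of class `known_catalogue`: list with `patterns` (named
#'   list, gene id -> bit vector or NULL for unknown), `alternates`
#'   (gene id -> list of alternate bit vectors), and `reference`.
#' @export
load_catalogue <- function(path, cell_types = ciona_cell_types(),
                           reference = reference_patterns(cell_types)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  patterns <- list()
  alternates <- list()
  n_ct <- length(cell_types)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    gene <- f[1]
    rest <- f[-1]
    if (length(rest) == 1 && rest == "unknown") {
      patterns[gene] <- list(NULL)
      next
    }
    alt_field <- NULL
    if (length(rest) == n_ct + 1) {
      alt_field <- rest[n_ct + 1]
      rest <- rest[seq_len(n_ct)]
    }
    if (length(rest) != n_ct) {
      stop(sprintf("gene '%s': expected %d bit columns or 'unknown', got %d fields",
                   gene, n_ct, length(rest)))
    }
    bits <- suppressWarnings(as.integer(rest))
    if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
      stop(sprintf("gene '%s': malformed pattern bits", gene))
    }
    patterns[[gene]] <- stats::setNames(bits, cell_types)
    if (!is.null(alt_field) && nzchar(alt_field)) {
      alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
      alternates[[gene]] <- lapply(alts, function(s) {
        ab <- as.integer(strsplit(s, "")[[1]])
        if (length(ab) != n_ct || anyNA(ab) || !all(ab %in% c(0L, 1L))) {
          stop(sprintf("gene '%s': malformed alternate pattern '%s'", gene, s))
        }
        stats::setNames(ab, cell_types)
      })
    }
  }
  structure(list(patterns = patterns, alternates = alternates,
                 reference = reference, cell_types = cell_types),
            class = "known_catalogue")
}

#' The packaged synthetic stand-in catalogue
#'
#' Loads `known_patterns_synthetic.tsv` shipped with the package: marker
#' genes assigned to the nine named reference patterns. Gene-to-pattern
#' assignments beyond those attested in the text are synthetic stand-ins,
#' for demonstration and testing only.
#'
#' @return A `known_catalogue`.
#' @export
default_catalogue <- function() {
  load_catalogue(system.file("extdata", "known_patterns_synthetic.tsv",
                             package = "tqrpatterns", mustWork = TRUE))
}

#' Compare ranked calls to a known-pattern catalogue
#'
#' Takes the top `top_n` ranked calls and reports: how many exactly match
#' their catalogue pattern (a match to any listed alternate also counts),
#' which mismatch (with the Hamming distance between called and known
#' pattern, for diagnostics), which are absent from the catalogue or
#' recorded as `unknown` (candidates for validation), the number of
#' distinct called patterns, which called patterns are absent from the
#' named reference set (novel), and per-pattern gene tallies.
#'
#' @param calls Ranked `pattern_calls`.
#' @param cat A `known_catalogue`.
#' @param top_n Number of top-ranked calls to assess.
#' @return List of class `match_report`; see Details.
#' @export
compare_to_catalogue <- function(calls, cat, top_n = 40) {
  if (top_n <= 0) stop("top_n must be positive")
  if (top_n > nrow(calls)) stop("top_n exceeds number of calls")
  cell_types <- attr(calls, "cell_types")
  top <- as.data.frame(calls)[seq_len(top_n), , drop = FALSE]
  bits <- as.matrix(top[, cell_types, drop = FALSE])
  called <- apply(bits, 1, pattern_string)

  matched <- character()
  mismatched <- data.frame(gene_id = character(), called = character(),
                           known = character(), hamming = integer(),
                           stringsAsFactors = FALSE)
  unknown_genes <- character()
  for (i in seq_len(top_n)) {
    g <- top$gene_id[i]
    known <- cat$patterns[[g]]
    if (is.null(known) || !g %in% names(cat$patterns)) {
      unknown_genes <- c(unknown_genes, g)
      next
    }
    accepted <- c(list(known), cat$alternates[[g]])
    hit <- any(vapply(accepted, function(b) pattern_string(b) == called[i],
                      logical(1)))
    if (hit) {
      matched <- c(matched, g)
    } else {
      mismatched <- rbind(mismatched, data.frame(
        gene_id = g, called = called[i], known = pattern_string(known),
        hamming = sum(bits[i, ] != known), stringsAsFactors = FALSE))
    }
  }
  tally <- table(called)
  ref_strings <- vapply(cat$reference, pattern_string, character(1))
  distinct <- unique(called)
  novel <- setdiff(distinct, ref_strings)
  structure(
    list(top_n = top_n,
         matched = length(matched), matched_genes = matched,
         mismatched = mismatched,
         unknown_genes = unknown_genes,
         distinct_patterns = length(distinct),
         novel_patterns = novel,
         pattern_tally = as.data.frame(tally, responseName = "n_genes",
                                       stringsAsFactors = FALSE)),
    class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("Top %d calls vs catalogue: %d matched, %d mismatched, %d not in catalogue\n",
              x$top_n, x$matched, nrow(x$mismatched), length(x$unknown_genes)))
  cat(sprintf("%d distinct patterns (%d not in the named reference set)\n",
              x$distinct_patterns, length(x$novel_patterns)))
  tally <- x$pattern_tally[order(-x$pattern_tally$n_genes), , drop = FALSE]
  for (i in seq_len(nrow(tally))) {
    cat(sprintf("  %s  %3d gene(s)%s\n", tally$called[i], tally$n_genes[i],
                if (tally$called[i] %in% x$novel_patterns) "  [novel]" else ""))
  }
  invisible(x)
}

#' Write a match report as JSON
#'
#' @param report A `match_report`.
#' @param path Output JSON path.
#' @export
write_match_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
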