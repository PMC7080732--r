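#' Canonical blastomere types of the 16-cell Ciona embryo
#'
#' The eight individually identifiable cell types of one (right) half of a
#' 16-cell Ciona embryo, in the canonical order used throughout the package
#' for pattern bit vectors and serialisation: animal row then vegetal row,
#' anterior to posterior. Lowercase letters are animal-hemisphere cells,
#' uppercase vegetal (Conklin nomenclature); `a`/`A` anterior, `b`/`B`
#' posterior. Postplasmic/PEM maternal RNAs localise to B5.2, the last cell
#' in the order.
#'
#' @return Character vector of length 8:
#'   `a5.3, a5.4, b5.3, b5.4, A5.1, A5.2, B5.1, B5.2`.
#' @export
#' @examples
#' ciona_cell_types()
ciona_cell_types <- function() {
  c("a5.3", "a5.4", "b5.3", "b5.4", "A5.1", "A5.2", "B5.1", "B5.2")
}
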