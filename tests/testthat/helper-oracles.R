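# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: different formula routes, brute-force loops.

# Hyndman-Fan type 5 via plotting positions p_k = (k - 0.5) / n and
# straight-line interpolation between adjacent order statistics.
oracle_quantile_type5 <- function(values, p) {
  x <- sort(values)
  n <- length(x)
  pk <- (seq_len(n) - 0.5) / n
  vapply(p, function(pp) {
    if (pp <= pk[1]) return(x[1])
    if (pp >= pk[n]) return(x[n])
    k <- max(which(pk <= pp))
    x[k] + (pp - pk[k]) / (pk[k + 1] - pk[k]) * (x[k + 1] - x[k])
  }, numeric(1))
}

# Two-cluster cut via Kruskal's MST (union-find over sorted edges), then
# deleting the single largest MST edge. Returns a 2-element list of sorted
# index vectors, the one containing item 1 first.
oracle_mst_two_cut <- function(d) {
  n <- nrow(d)
  edges <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[upper.tri(d)])
  edges <- edges[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  mst <- matrix(0L, 0, 2)
  for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) {
      parent[a] <- b
      mst <- rbind(mst, edges[k, , drop = FALSE])
      if (nrow(mst) == n - 1) break
    }
  }
  w <- d[mst]
  drop <- which.max(w)
  keep <- mst[-drop, , drop = FALSE]
  parent <- seq_len(n)
  for (k in seq_len(nrow(keep))) {
    a <- find(keep[k, 1]); b <- find(keep[k, 2])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ca <- sort(which(comp == comp[1]))
  cb <- sort(which(comp != comp[1]))
  list(ca, cb)
}

# random symmetric distance matrix with zero diagonal, generic (tie-free)
random_distance_matrix <- function(n) {
  pts <- matrix(stats::runif(n * 3), n, 3)
  as.matrix(stats::dist(pts))
}

# cell-types x embryos phi profile with given per-cell-type expected levels
# and additive noise, clamped to [0, pi]
make_profile <- function(levels, n_embryos = 4, noise_sd = 0,
                         cell_types = ciona_cell_types()) {
  stopifnot(length(levels) == length(cell_types))
  m <- matrix(rep(levels, n_embryos), nrow = length(cell_types),
              dimnames = list(cell_types, paste0("E", seq_len(n_embryos))))
  if (noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, noise_sd),
                                    nrow = nrow(m))
  pmin(pmax(m, 0), pi)
}

# random ranked pattern_calls table for round-trip tests
random_pattern_calls <- function(n, cell_types = ciona_cell_types()) {
  bits <- matrix(0L, n, length(cell_types),
                 dimnames = list(NULL, cell_types))
  for (i in seq_len(n)) {
    k <- sample(seq_len(length(cell_types) - 1), 1)
    bits[i, sample(length(cell_types), k)] <- 1L
  }
  tqr <- sort(stats::rnorm(n, 0, 0.3), decreasing = TRUE)
  out <- data.frame(gene_id = sprintf("g%03d", seq_len(n)), bits,
                    tqr = tqr, rank = seq_len(n),
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "cell_types") <- cell_types
  class(out) <- c("pattern_calls", "data.frame")
  out
}

# tiny literal count table on disk; returns the path
write_toy_counts <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "counts.tsv")
  writeLines(lines, path)
  path
}
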