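test_that("cell-type distances are Euclidean over replicate vectors", {
  prof <- rbind(u = c(0, 0, 0, 0), v = c(3, 4, 0, 0))
  d <- celltype_distances(prof)
  expect_equal(d["u", "v"], 5)
  expect_equal(diag(d), c(u = 0, v = 0))

  set.seed(3)
  prof <- matrix(runif(32, 0, pi), 8, 4,
                 dimnames = list(ciona_cell_types(), NULL))
  d <- celltype_distances(prof)
  brute <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    brute[i, j] <- sqrt(sum((prof[i, ] - prof[j, ])^2))
  }
  expect_equal(unname(d), brute, tolerance = 1e-12)
  prof[2, 3] <- NA
  expect_error(celltype_distances(prof), "missing")
})

test_that("two-cluster cut separates the obvious groups", {
  d1 <- as.matrix(dist(c(A = 0, B = 0.1, C = 0.9, D = 1.0)))
  cut <- single_linkage_two_cut(d1)
  expect_setequal(cut$cluster_a, 1:2)
  expect_setequal(cut$cluster_b, 3:4)
  expect_equal(cut$merge_height, 0.8)

  d2 <- as.matrix(dist(c(A = 0, B = 0.05, C = 0.1, D = 2.0)))
  cut <- single_linkage_two_cut(d2)
  expect_setequal(cut$cluster_a, 1:3)  # singleton side allowed
  expect_setequal(cut$cluster_b, 4L)

  d3 <- matrix(c(0, 1, 1, 0), 2, 2)
  cut <- single_linkage_two_cut(d3)
  expect_equal(cut$cluster_a, 1L)
  expect_equal(cut$cluster_b, 2L)

  expect_error(single_linkage_two_cut(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(single_linkage_two_cut(matrix(0, 1, 1)), "at least 2")
})

test_that("the cut equals the MST max-edge bipartition and hclust's 2-cut", {
  set.seed(101)
  for (rep in 1:300) {
    n <- sample(3:8, 1)
    d <- random_distance_matrix(n)
    cut <- single_linkage_two_cut(d)
    oracle <- oracle_mst_two_cut(d)
    expect_equal(sort(cut$cluster_a), oracle[[1]])
    expect_equal(sort(cut$cluster_b), oracle[[2]])
    # independent library route on the same (tie-free) matrix
    k2 <- stats::cutree(stats::hclust(stats::as.dist(d), method = "single"), 2)
    expect_setequal(cut$cluster_a, which(k2 == k2[1]))
  }
})

test_that("type-5 quantiles match the hand formula and reference routes", {
  expect_equal(quantile_type5(c(1, 2, 3, 4), 0.25), 1.5)
  expect_equal(quantile_type5(5, 0.99), 5)
  expect_equal(quantile_type5(c(10, 20), 0.5), 15)
  expect_error(quantile_type5(numeric(0), 0.5), "non-empty")
  expect_error(quantile_type5(1:3, 1.1), "\\[0, 1\\]")

  set.seed(202)
  for (rep in 1:500) {
    n <- sample(c(1, 2, 3, 5, 17, 100), 1)
    x <- rnorm(n)
    p <- c(0, 1, runif(4))
    got <- quantile_type5(x, p)
    expect_equal(got, oracle_quantile_type5(x, p), tolerance = 1e-12)
    expect_equal(got, unname(stats::quantile(x, p, type = 5)),
                 tolerance = 1e-12)
    expect_true(all(diff(quantile_type5(x, sort(p))) >= -1e-12))  # monotone in p
  }
})

test_that("TQR scores the worked example and degenerate lists correctly", {
  expect_equal(tqr_score(c(0.8, 0.9, 1.0, 1.1), c(0.0, 0.1, 0.2, 0.3)), 0.60)
  x <- c(0.2, 0.5, 0.9, 1.4)
  expect_lte(tqr_score(x, x), 0)  # Q1 <= Q3 of the same list
  expect_equal(tqr_score(rep(0.3, 4), rep(0.3, 4)), 0)
  expect_error(tqr_score(numeric(0), 1), "non-empty")
})

test_that("TQR grows with mean separation and shrinks with spread", {
  spread <- function(m, s) c(m - s, m - s / 3, m + s / 3, m + s)
  seps <- seq(0.1, 1.5, length.out = 12)
  tqr_by_sep <- vapply(seps, function(m) tqr_score(spread(m, 0.05), spread(0, 0.05)),
                       numeric(1))
  expect_true(all(diff(tqr_by_sep) > 0))

  spreads <- seq(0.01, 0.3, length.out = 12)
  tqr_by_spread <- vapply(spreads, function(s) tqr_score(spread(1, s), spread(0, s)),
                          numeric(1))
  expect_true(all(diff(tqr_by_spread) < 0))
})

test_that("call_pattern recovers constructed single-cell and territory patterns", {
  ct <- ciona_cell_types()
  set.seed(5)
  prof <- make_profile(ifelse(ct == "B5.2", 0.05, 0.001), noise_sd = 1e-4)
  call <- call_pattern(prof, gene_id = "gB52")
  expect_equal(call$pattern, encode_pattern("B5.2"))
  expect_gt(call$tqr, 0)
  expect_equal(sort(c(call$on_values, call$off_values)), sort(as.vector(prof)))

  # anterior territory: high in a5.3, a5.4, A5.1, A5.2
  anterior <- c("a5.3", "a5.4", "A5.1", "A5.2")
  prof <- make_profile(ifelse(ct %in% anterior, 0.08, 0.004), noise_sd = 2e-4)
  call <- call_pattern(prof)
  expect_equal(call$pattern, encode_pattern(anterior))
  expect_equal(call$on_cells, c("a5.3", "a5.4", "A5.1", "A5.2"))
})

test_that("constant and all-zero profiles yield a valid cut with TQR zero", {
  flat <- make_profile(rep(0.2, 8))
  call <- call_pattern(flat)
  expect_equal(call$tqr, 0)
  expect_true(sum(call$pattern) >= 1 && sum(call$pattern) <= 7)
  zero <- make_profile(rep(0, 8))
  expect_equal(call_pattern(zero)$tqr, 0)
})

test_that("ranking sorts by TQR descending with gene-id tie-break", {
  ct <- ciona_cell_types()
  sheet <- sample_sheet(data.frame(
    sample_id = paste0("s", 1:16), embryo = rep(1:2, each = 8),
    cell_type = rep(ct, 2)))
  phi <- rbind(
    gA = rep(c(0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.001, 0.3), 2),
    gB = rep(0.05, 16),
    gC = rep(c(0.001, 0.2, rep(0.001, 6)), 2),
    gB2 = rep(0.05, 16))
  colnames(phi) <- paste0("s", 1:16)
  calls <- discover_and_rank(phi, sheet)
  expect_equal(calls$rank, 1:4)
  expect_true(all(diff(calls$tqr) <= 0))
  # the two constant genes tie at TQR 0 and sort by gene id
  flat <- calls$gene_id[calls$tqr == 0]
  expect_equal(flat, sort(flat))
})

test_that("ranked discovery is invariant to sample column order", {
  sim <- simulate_dataset(sim_config(n_genes = 60, n_patterned = 6,
                                     n_silent = 4, n_spikes = 5, seed = 9))
  phi <- phi_transform(to_proportions(sim$counts))
  calls1 <- discover_and_rank(phi, sim$sheet)
  set.seed(1)
  perm <- sample(ncol(phi$values))
  phi2 <- phi
  phi2$values <- phi$values[, perm]
  phi2$sample_ids <- phi$sample_ids[perm]
  sheet2 <- sim$sheet[rev(seq_len(nrow(sim$sheet))), ]
  attr(sheet2, "cell_types") <- attr(sim$sheet, "cell_types")
  calls2 <- discover_and_rank(phi2, sheet2)
  expect_identical(as.data.frame(calls1), as.data.frame(calls2))
})

test_that("platform filtering restricts discovery to one platform's samples", {
  sim <- simulate_dataset(sim_config(n_genes = 40, n_patterned = 4,
                                     n_silent = 2, n_spikes = 3, seed = 13))
  phi <- phi_transform(to_proportions(sim$counts))
  calls <- discover_and_rank(phi, sim$sheet, platform = "sim")
  expect_equal(nrow(calls), 40L)
  expect_error(discover_and_rank(phi, sim$sheet, platform = "HiSeq"),
               "no samples")
  # a sheet missing one sample is reported by name
  short <- sim$sheet[-1, ]
  attr(short, "cell_types") <- attr(sim$sheet, "cell_types")
  expect_error(discover_and_rank(phi, short),
               sim$sheet$sample_id[1], fixed = TRUE)
})

test_that("per-cell-mean quartiles are available behind the pooled flag", {
  ct <- ciona_cell_types()
  set.seed(21)
  prof <- make_profile(ifelse(ct %in% c("B5.1", "B5.2"), 0.1, 0.01),
                       noise_sd = 2e-3)
  pooled <- call_pattern(prof, pooled = TRUE)
  bycell <- call_pattern(prof, pooled = FALSE)
  expect_equal(pooled$pattern, bycell$pattern)  # same cut, different quartile base
  expect_equal(bycell$tqr,
               tqr_score(rowMeans(prof[c("B5.1", "B5.2"), ]),
                         rowMeans(prof[setdiff(ct, c("B5.1", "B5.2")), ])))
})
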