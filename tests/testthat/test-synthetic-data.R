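test_that("the simulator honours the shape contract and flags classes", {
  cfg <- sim_config(n_genes = 200, n_patterned = 12, n_silent = 15,
                    n_spikes = 10, seed = 2)
  sim <- simulate_dataset(cfg)
  expect_equal(dim(sim$counts), c(210L, 32L))
  expect_equal(sum(sim$counts$is_spike), 10L)
  expect_equal(nrow(sim$sheet), 32L)
  expect_equal(as.vector(table(sim$sheet$cell_type)[ciona_cell_types()]),
               rep(4L, 8))
  expect_equal(as.vector(table(sim$truth$class)[c("patterned", "silent", "spike")]),
               c(12L, 15L, 10L))
  # silent genes draw no counts at all
  silent <- sim$truth$gene_id[sim$truth$class == "silent"]
  expect_true(all(sim$counts$counts[silent, ] == 0))
  # planted effect sizes realise the target h
  planted <- sim$truth[sim$truth$class == "patterned", ]
  expect_equal(planted$realised_h, rep(cfg$effect_size_h, nrow(planted)),
               tolerance = 1e-9)
})

test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_genes = 100, n_patterned = 8, n_silent = 5,
                    n_spikes = 5, seed = 42)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(sim_config(n_genes = 100, n_patterned = 8,
                                   n_silent = 5, n_spikes = 5, seed = 43))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_genes = 10, n_patterned = 8, n_silent = 5),
               "exceed n_genes")
  expect_error(sim_config(effect_size_h = 0), "\\(0, pi\\]")
  expect_error(sim_config(effect_size_h = 4), "\\(0, pi\\]")
  expect_error(sim_config(batch_logsd = -1), "batch_logsd")
  expect_error(sim_config(pattern_set = list(rep(1L, 8))), "ON cells")
  # an effect size no baseline can reach errors rather than silently shrinking
  expect_error(simulate_dataset(
    sim_config(n_genes = 50, n_patterned = 2, n_silent = 0, n_spikes = 0,
               effect_size_h = 3, baseline_logsd = 0.01, seed = 1)),
    "infeasible effect size")
})

test_that("expected proportions sum to one by construction pre-noise", {
  # with zero batch noise and dispersion, counts/library approximate the
  # expected proportions, whose per-sample sum is 1
  cfg <- sim_config(n_genes = 150, n_patterned = 10, n_silent = 5,
                    n_spikes = 10, batch_logsd = 0, dispersion = 0,
                    library_size_mean = 1e6, library_size_logsd = 0, seed = 8)
  sim <- simulate_dataset(cfg)
  totals <- colSums(sim$counts$counts)
  expect_true(all(abs(totals - 1e6) / 1e6 < 0.05))  # Poisson noise only
})

test_that("same-embryo samples correlate more than same-cell-type samples", {
  hits <- 0L
  for (s in 1:5) {
    sim <- simulate_dataset(sim_config(n_genes = 400, n_patterned = 20,
                                       n_silent = 20, n_spikes = 10,
                                       seed = 300 + s))
    phi <- phi_transform(to_proportions(sim$counts))
    r <- sample_correlation(phi)
    sh <- sim$sheet[match(colnames(r), sim$sheet$sample_id), ]
    same_emb <- outer(sh$embryo, sh$embryo, "==") & upper.tri(r)
    same_ct <- outer(sh$cell_type, sh$cell_type, "==") & upper.tri(r)
    if (mean(r[same_emb & !same_ct]) > mean(r[same_ct & !same_emb])) {
      hits <- hits + 1L
    }
  }
  expect_equal(hits, 5L)
})

test_that("recovery metrics are exact on a perfect ranking and null truth", {
  sim <- simulate_dataset(sim_config(n_genes = 50, n_patterned = 5,
                                     n_silent = 5, n_spikes = 4, seed = 6))
  truth <- sim$truth[sim$truth$class != "spike", ]
  ct <- ciona_cell_types()
  # construct calls that rank all planted genes first with their true bits
  planted <- truth[truth$class == "patterned", ]
  others <- truth[truth$class != "patterned", ]
  bits <- rbind(
    do.call(rbind, lapply(planted$pattern, function(s)
      as.integer(strsplit(s, "")[[1]]))),
    matrix(rep(c(1L, rep(0L, 7)), nrow(others)), ncol = 8, byrow = TRUE))
  colnames(bits) <- ct
  calls <- data.frame(gene_id = c(planted$gene_id, others$gene_id), bits,
                      tqr = seq(1, 0, length.out = nrow(truth)),
                      rank = seq_len(nrow(truth)),
                      check.names = FALSE, stringsAsFactors = FALSE)
  attr(calls, "cell_types") <- ct
  class(calls) <- c("pattern_calls", "data.frame")
  met <- evaluate_recovery(calls, sim$truth)
  expect_equal(met$frac_recovered, 1)
  expect_equal(met$frac_exact_pattern, 1)
  expect_equal(met$median_planted_rank, (5 + 1) / 2)

  # zero planted genes: defined nulls, no crash
  sim0 <- simulate_dataset(sim_config(n_genes = 30, n_patterned = 0,
                                      n_silent = 3, n_spikes = 2, seed = 7))
  calls0 <- discover_patterns(sim0$counts, sim0$sheet)
  met0 <- evaluate_recovery(calls0, sim0$truth)
  expect_equal(met0$n_planted, 0L)
  expect_true(is.na(met0$frac_recovered))

  # mismatched gene sets are an error
  expect_error(evaluate_recovery(calls0, sim$truth), "different gene sets")
})

test_that("mean recovery rises with the planted effect size", {
  mean_rec <- vapply(c(0.02, 0.05, 0.1), function(h) {
    recs <- vapply(1:10, function(s) {
      sim <- simulate_dataset(sim_config(n_genes = 300, n_patterned = 15,
                                         n_silent = 15, n_spikes = 8,
                                         effect_size_h = h, seed = 500 + s))
      calls <- discover_patterns(sim$counts, sim$sheet)
      evaluate_recovery(calls, sim$truth)$frac_recovered
    }, numeric(1))
    mean(recs)
  }, numeric(1))
  expect_true(all(diff(mean_rec) > 0))
})

test_that("simulation outputs round-trip through the plain-text writers", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(n_genes = 40, n_patterned = 4,
                                     n_silent = 4, n_spikes = 4, seed = 11))
  write_simulation(sim, dir)
  expect_setequal(list.files(dir),
                  c("counts.tsv", "samples.tsv", "truth.tsv", "sim_config.yaml"))
  cm <- read_count_table(file.path(dir, "counts.tsv"))
  expect_identical(cm$counts, sim$counts$counts)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(sheet$sample_id, sim$sheet$sample_id)
})

# Characterisation of the Lefty-type failure mode: pattern cells with
# expression clearly nearer the OFF level join the OFF cluster. A flat,
# low baseline keeps ON barely above the feasibility threshold, so OFF is
# near zero and the geometric-mean placement sits far below the phi
# midpoint — the scenario the characterisation is about.
lefty_config <- function(seed, placement) {
  sim_config(n_genes = 40, n_patterned = 8, n_silent = 2, n_spikes = 5,
             baseline_logsd = 0.1, effect_size_h = 0.3,
             intermediate_fraction = 0.5, intermediate_placement = placement,
             seed = seed)
}

test_that("intermediate cells below the phi midpoint are clustered OFF", {
  for (s in 1:4) {
    sim <- simulate_dataset(lefty_config(700 + s, "geomean"))
    calls <- discover_patterns(sim$counts, sim$sheet)
    inter <- sim$truth[sim$truth$class == "intermediate", ]
    bits <- as.data.frame(calls)[match(inter$gene_id, calls$gene_id), ,
                                 drop = FALSE]
    for (i in seq_len(nrow(inter))) {
      cells <- strsplit(inter$intermediate_cells[i], ",")[[1]]
      expect_equal(unname(unlist(bits[i, cells])), rep(0L, length(cells)),
                   label = sprintf("seed %d gene %s intermediate cells", 700 + s,
                                   inter$gene_id[i]))
    }
  }
})

test_that("midpoint-placed intermediates are ambiguous: both calls occur", {
  on_calls <- off_calls <- 0L
  for (s in 1:12) {
    sim <- simulate_dataset(lefty_config(800 + s, "phi_mid"))
    calls <- discover_patterns(sim$counts, sim$sheet)
    inter <- sim$truth[sim$truth$class == "intermediate", ]
    bits <- as.data.frame(calls)[match(inter$gene_id, calls$gene_id), ,
                                 drop = FALSE]
    for (i in seq_len(nrow(inter))) {
      cells <- strsplit(inter$intermediate_cells[i], ",")[[1]]
      v <- unlist(bits[i, cells])
      on_calls <- on_calls + sum(v == 1)
      off_calls <- off_calls + sum(v == 0)
    }
  }
  expect_gt(on_calls, 0L)
  expect_gt(off_calls, 0L)
})
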