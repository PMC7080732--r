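#!/usr/bin/env Rscript
# Step 1: generate the synthetic-embryo dataset the downstream steps analyse.
#
# Default study design: 1000 endogenous genes (40 with a planted pattern
# drawn from the nine named reference patterns, 50 silent), 30 ERCC-style
# spike-in rows, 8 cell types x 4 embryos = 32 samples, embryo batch
# effects larger than within-embryo noise, ~200k reads per sample.

suppressPackageStartupMessages(library(tqrpatterns))

out_dir <- "results/sim"
cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg)
write_simulation(sim, out_dir)

cat(sprintf("simulated %d genes (+%d spikes) x %d samples -> %s\n",
            cfg$n_genes, cfg$n_spikes, nrow(sim$sheet), out_dir))
cat(sprintf("planted classes: %s\n",
            paste(sprintf("%s=%d", names(table(sim$truth$class)),
                          table(sim$truth$class)), collapse = ", ")))
cat(sprintf("library sizes: %s-%s counts\n",
            format(min(colSums(sim$counts$counts)), big.mark = ","),
            format(max(colSums(sim$counts$counts)), big.mark = ",")))
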