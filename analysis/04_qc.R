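#!/usr/bin/env Rscript
# Step 4: quality-control surfaces — detected genes per sample, the sample
# correlation matrix of phi-transformed proportions (spikes and all-zero
# genes excluded), a single-linkage sample ordering, and PCA variance
# fractions. Checks that the embryo batch structure dominates: samples from
# the same embryo correlate more strongly than the same cell type across
# embryos.

suppressPackageStartupMessages(library(tqrpatterns))

counts <- read_count_table("results/sim/counts.tsv")
sheet <- read_sample_sheet("results/sim/samples.tsv")

qc <- qc_report(counts, sheet)
print(qc)
write_qc_report(qc, "results/qc_report.json")

r <- qc$correlation
sh <- sheet[match(colnames(r), sheet$sample_id), ]
same_emb <- outer(sh$embryo, sh$embryo, "==") & upper.tri(r)
same_ct <- outer(sh$cell_type, sh$cell_type, "==") & upper.tri(r)
cat(sprintf("mean correlation, same embryo / different cell type: %.3f\n",
            mean(r[same_emb & !same_ct])))
cat(sprintf("mean correlation, same cell type / different embryo: %.3f\n",
            mean(r[same_ct & !same_emb])))
cat(sprintf("PC1+PC2 explain %.1f%% of variance\n", qc$pc12_percent))
cat("wrote results/qc_report.json\n")
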