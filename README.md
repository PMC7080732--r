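# tqrpatterns

Cell-type-specific expression pattern discovery for small, fully labelled
single-cell RNA-seq designs — the motivating case is the 16-cell *Ciona*
embryo, where each of the eight blastomere types of one embryo half
(`a5.3, a5.4, b5.3, b5.4, A5.1, A5.2, B5.1, B5.2`) is dissected and
sequenced across four replicate embryos. Instead of clustering cells, the
method clusters *cell types per gene*: every gene gets its own binary
ON/OFF pattern over the known cell types, plus a reliability score.

## Method

For gene *i* and sample *j* with count *k<sub>ij</sub>* and sample total
*N<sub>j</sub>* (endogenous genes only):

- **φ transform**: φ<sub>ij</sub> = 2·arcsin√(k<sub>ij</sub>/N<sub>j</sub>),
  the arcsine-square-root variance stabilisation of proportions; a
  difference of φ values is Cohen's *h*, so distances are effect sizes.
- **Per-gene two-cut**: each cell type is a vector of replicate φ values
  (one per embryo); single-linkage agglomeration of the Euclidean
  distances between these vectors, stopped before the final merge, yields
  the two top-level clusters — ON (larger pooled mean) and OFF. The cut
  equals deleting the largest edge of a minimum spanning tree.
- **Transquartile Range**: TQR = Q1(ON values) − Q3(OFF values), with
  type-5 ("hydrologist") quantile interpolation over the clusters' pooled
  replicate values. Genes are ranked by TQR, descending; no parametric
  dispersion estimate is involved.

The package also provides catalogue comparison against known *in situ*
patterns (exact bit-vector matching, distinct/novel pattern tallies), QC
surfaces (gene detection, sample correlation excluding spikes and all-zero
genes, PCA variance fractions), and a negative-binomial synthetic-embryo
generator with planted patterns, embryo batch effects and ERCC-style
spike-ins for recovery benchmarking.

## Worked example

The `analysis/` drivers run the whole workflow on a simulated dataset
(1000 genes, 40 planted patterns, 8 cell types × 4 embryos, seed 1):

```sh
Rscript analysis/01_simulate.R          # counts, sample sheet, truth -> results/sim/
Rscript analysis/02_discover_rank.R     # ranked calls -> results/calls.tsv
Rscript analysis/03_compare_catalogue.R # recovery + top-40 pattern summary
Rscript analysis/04_qc.R                # correlation / PCA QC -> results/qc_report.json
```

Step 2 prints the ranked head of the call table — each line is a gene, its
8-bit ON/OFF pattern in canonical cell-type order, and its TQR:

```
ranked 1000 genes; 72 with TQR > 0
top 10 calls:
   1. gene0001  11110000  TQR 0.0858
   2. gene0029  00001111  TQR 0.0752
   3. gene0035  11111110  TQR 0.0751
   ...
```

`11110000` is the animal hemisphere (first four cells ON), `00001111` the
vegetal; the TQR of ~0.086 means the first quartile of the ON cells' φ
values clears the third quartile of the OFF cells' by 0.086 — a solid call
at the planted effect size of *h* = 0.08. Step 3 scores the run against
the planted truth:

```
recovery: 40 planted genes, 100.0% in top 40 ranks,
          100.0% of those with exact pattern (median planted rank 20.5)
9 distinct patterns (0 not in the named reference set)
```

and step 4 shows the embryo batch structure the generator plants (and real
embryos show): same-embryo samples correlate at 0.922 versus 0.868 for the
same cell type across embryos, with PC1+PC2 explaining 38.8% of variance.

In code, the same pipeline is three calls:

```r
library(tqrpatterns)
sim   <- simulate_dataset(sim_config(seed = 1))
calls <- discover_patterns(sim$counts, sim$sheet)   # proportions -> phi -> two-cut -> TQR
evaluate_recovery(calls, sim$truth, top_n = 40)
```

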