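#!/usr/bin/env Rscript
# Step 3: compare the ranked calls with the planted truth and summarise the
# top-40 patterns catalogue-style (distinct patterns, novel vs the named
# reference set).

suppressPackageStartupMessages(library(tqrpatterns))

calls <- read_pattern_calls("results/calls.tsv")
# pattern bit strings must stay character: "00001111" is not the number 1111
truth <- utils::read.delim("results/sim/truth.tsv", stringsAsFactors = FALSE,
                           colClasses = c(pattern = "character",
                                          intermediate_cells = "character"))

met <- evaluate_recovery(calls, truth, top_n = 40)
print(met)

# catalogue-style summary of the top 40 against the named reference set;
# simulated gene ids are absent from the packaged catalogue, so the useful
# output here is the distinct/novel pattern tally
report <- compare_to_catalogue(calls, default_catalogue(), top_n = 40)
print(report)
write_match_report(report, "results/top40_report.json")
cat("wrote results/top40_report.json\n")
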