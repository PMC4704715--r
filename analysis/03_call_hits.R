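#!/usr/bin/env Rscript
# Rank strains by mean log2 RLU and select the upper and lower 5% tails as
# the High and Low extracellular-ATP groups; score recovery of the planted
# sets.

suppressPackageStartupMessages(library(atpscreen))

scores <- read_scores_table("results/scores.tsv")
truth <- read.delim("results/sim/truth.tsv")

groups <- select_tails(scores, fraction = 0.05)
writeLines(groups$low, "results/groups.low.txt")
writeLines(groups$high, "results/groups.high.txt")
jsonlite::write_json(list(fraction = groups$fraction,
                          n_scored = groups$n_scored,
                          n_per_tail = groups$n_per_tail),
                     "results/groups.summary.json", auto_unbox = TRUE)

low_set <- truth$strain[truth$low_set]
high_set <- truth$strain[truth$high_set]
cat("scored strains:", groups$n_scored, "-> tails of", groups$n_per_tail,
    "strains each\n")
cat("planted-low recovery in Low tail:",
    round(mean(low_set %in% groups$low), 3), "\n")
cat("planted-high recovery in High tail:",
    round(mean(high_set %in% groups$high), 3), "\n")
cat("wrote results/groups.{low,high}.txt and groups.summary.json\n")
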