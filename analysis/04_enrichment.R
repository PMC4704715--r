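#!/usr/bin/env Rscript
# Hypergeometric term enrichment of the Low and High tails against the
# measured background, with fold-enrichment reporting, Jaccard redundancy
# trimming, and a direction-aware overlap test of the planted Low set
# (the synthetic analogue of a respiration-deficient strain list).

suppressPackageStartupMessages(library(atpscreen))

scores <- read_scores_table("results/scores.tsv")
truth <- read.delim("results/sim/truth.tsv")
sets <- read_gmt("results/sim/annotations.gmt")
low <- readLines("results/groups.low.txt")
high <- readLines("results/groups.high.txt")

universe <- scores$strain[!is.na(scores$mean_log2_rlu)]
coll <- gene_set_collection(sets, universe)

for (side in c("low", "high")) {
  group <- if (side == "low") low else high
  rows <- enrich_terms(group, coll, p_cutoff = 0.01, fold_min = 2.0)
  trimmed <- trim_redundant(rows, jaccard_threshold = 0.8)
  out <- file.path("results", paste0("enrichment.", side, ".tsv"))
  write.table(trimmed[, setdiff(names(trimmed), "hit_genes")], out,
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- trimmed[trimmed$significant, ]
  cat(toupper(side), "tail:", nrow(rows), "terms with overlap,",
      nrow(sig), "significant after trimming; top terms:\n")
  print(head(sig[, c("term", "k", "K", "fold", "p")], 5), row.names = FALSE)
  cat("wrote", out, "\n")
}

# overlap of the Low tail with the full planted-low membership list
low_set <- truth$strain[truth$low_set]
ov <- set_overlap_test(low, low_set, universe)
cat(sprintf("planted-low list: %d of %d measured members in the Low tail (%s, fold %.1f, p = %.3g)\n",
            ov$k, ov$K, ov$direction, ov$fold, ov$p))
ov_high <- set_overlap_test(high, low_set, universe)
cat(sprintf("same list in the High tail: k = %d (%s, p = %.3f)\n",
            ov_high$k, ov_high$direction, ov_high$p))
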