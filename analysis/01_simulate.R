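#!/usr/bin/env Rscript
# Generate the synthetic screen used by the downstream analysis steps:
# a 4609-strain deletion library on 96-well plates, three biological
# replicates per source plate, eight blank plates, 5% planted Low/High
# tails, plus a matched annotation collection, an interaction network with
# planted dense modules, and retest/time-course tables.

suppressPackageStartupMessages(library(atpscreen))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260929L)
sim <- simulate_screen(cfg)
write_sim_screen(sim, out)

sets <- simulate_annotations(sim$truth, n_planted_terms = 6,
                             n_null_terms = 40,
                             term_size_range = c(10L, 60L),
                             planted_overlap = 0.8,
                             planted_sets = c("low", "low", "low",
                                              "high", "high", "high"),
                             seed = cfg$seed + 1L)
write_gmt(sets, file.path(out, "annotations.gmt"))

net <- simulate_network(
  sim$truth,
  module_specs = list(list(set = "low", n_nodes = 12, within_density = 0.8),
                      list(set = "low", n_nodes = 8, within_density = 0.9),
                      list(set = "high", n_nodes = 6, within_density = 0.9)),
  background_density = 2e-4, seed = cfg$seed + 2L)
write_network_tsv(net, file.path(out, "network.tsv"))

retest <- simulate_retest(
  effects = c(BY4743 = 0, vps25 = -0.8, snf7 = -1.0, gtr1 = 1.2,
              meh1 = 0.9, gap1 = 0, bul1 = -2.7),
  n_replicates = 6, seed = cfg$seed + 3L)
write.table(retest$table, file.path(out, "retest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(retest$blanks, file.path(out, "retest_blanks.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

timecourse <- simulate_retest(
  effects = c(BY4743 = 0, gtr1 = 1.2, srn2 = -1.0, gap1 = 0),
  timepoints = c(0, 4, 8, 12, 21, 26, 48, 72, 96),
  n_replicates = 6, seed = cfg$seed + 4L)
write.table(timecourse$table, file.path(out, "timecourse.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

n_plates <- length(unique(paste(sim$plates$plate_id, sim$plates$replicate_id)))
cat("simulated", nrow(sim$truth$strains), "strains on",
    length(unique(sim$map$plate_id)), "source plates;",
    n_plates, "assay/blank plates written to", out, "\n")
cat("planted:", sum(sim$truth$strains$low_set), "low,",
    sum(sim$truth$strains$high_set), "high,",
    sum(sim$truth$strains$slow_grower), "slow growers\n")
cat("annotations:", length(sets), "terms (",
    length(attr(sets, "planted")), "planted );",
    "network:", igraph::ecount(net), "edges\n")
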