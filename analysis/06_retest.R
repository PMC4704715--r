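#!/usr/bin/env Rscript
# Retest statistics: background-corrected extracellular ATP of selected
# mutants relative to the parent strain with per-cell t-tests, and a
# time-course normalized to each strain's time-zero (background) level.

suppressPackageStartupMessages(library(atpscreen))

retest <- read.delim("results/sim/retest.tsv")
blanks <- read.delim("results/sim/retest_blanks.tsv")
res <- retest_analysis(retest, reference = "BY4743", blanks = blanks)
write.table(res, "results/retest.endpoint.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("endpoint retest vs BY4743:\n")
print(res[, c("strain", "n", "fold", "t", "p", "stars")], row.names = FALSE,
      digits = 3)

tc <- read.delim("results/sim/timecourse.tsv")
tres <- retest_analysis(tc, reference = "BY4743", timecourse = TRUE)
write.table(tres, "results/retest.timecourse.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\ntime-course, fold over each strain's time-zero level:\n")
wide <- reshape(tres[, c("strain", "timepoint", "fold")],
                idvar = "strain", timevar = "timepoint", direction = "wide")
names(wide) <- sub("^fold\\.", "t", names(wide))
print(wide, row.names = FALSE, digits = 3)
sig <- tres[!is.na(tres$p) & tres$p < 0.05, ]
cat("\n", nrow(sig), "strain x timepoint cells differ from BY4743 at p < 0.05\n")
cat("wrote results/retest.{endpoint,timecourse}.tsv\n")
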