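test_that("background correction subtracts blank means", {
  tab <- data.frame(strain = c("BY4743", "mut"), od660 = c(0.54, 0.54),
                    lum = c(1000, 500))
  blanks <- data.frame(od660 = c(0.04, 0.04), lum = c(100, 100))
  out <- background_correct(tab, blanks)
  expect_equal(out$lum_corr, c(900, 400))
  expect_equal(out$od660_corr, c(0.5, 0.5))
  expect_equal(out$signal, out$lum_corr)  # per-culture by default
  per_cell <- background_correct(tab, blanks, per_cell = TRUE)
  expect_equal(per_cell$signal, c(900, 400) / 0.5)
})

test_that("backgrounds above the readings floor at epsilon with a warning", {
  tab <- data.frame(strain = "a", od660 = 0.5, lum = 50)
  blanks <- data.frame(od660 = 0.04, lum = 100)
  expect_warning(out <- background_correct(tab, blanks), "floored")
  expect_gt(out$signal, 0)
})

test_that("fold change versus the parent is the ratio of cell means", {
  tab <- data.frame(strain = rep(c("BY4743", "gtr1"), each = 3),
                    condition = "none", timepoint = NA_real_,
                    replicate = rep(1:3, 2),
                    od660 = 0.54,
                    lum = c(1000, 1000, 1000, 2000, 2000, 2000))
  blanks <- data.frame(od660 = 0.04, lum = 0)
  corr <- background_correct(tab, blanks)
  folds <- fold_vs_reference(corr, "BY4743")
  expect_equal(folds$fold[folds$strain == "gtr1"], 2.0)
  expect_equal(folds$fold[folds$strain == "BY4743"], 1.0)
  expect_error(fold_vs_reference(corr, "nosuch"), "absent")
})

test_that("the pooled t-test matches hand computation and is symmetric", {
  tab <- data.frame(strain = rep(c("ref", "mut"), each = 3),
                    condition = "none", timepoint = NA_real_,
                    replicate = rep(1:3, 2), od660 = 0.5,
                    lum = c(4, 5, 6, 1, 2, 3) + 10)
  blanks <- data.frame(od660 = 0, lum = 10)
  corr <- background_correct(tab, blanks)
  res <- ttest_vs_reference(corr, "ref")
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)
  expect_equal(res$stars, "*")
  # swapping the roles negates t and preserves p
  res2 <- ttest_vs_reference(corr, "mut")
  expect_equal(res2$t, -res$t, tolerance = 1e-12)
  expect_equal(res2$p, res$p, tolerance = 1e-12)
})

test_that("degenerate variance cases resolve to p = 1 or flagged p = 0", {
  mk <- function(mut_vals) {
    data.frame(strain = rep(c("ref", "mut"), each = 3), condition = "none",
               timepoint = NA_real_, replicate = rep(1:3, 2), od660 = 0.5,
               lum = c(5, 5, 5, mut_vals),
               od660_corr = 0.46, lum_corr = 1,
               signal = c(5, 5, 5, mut_vals))
  }
  same <- ttest_vs_reference(mk(c(5, 5, 5)), "ref")
  expect_equal(same$p, 1)
  expect_equal(same$stars, "")
  expect_false(same$degenerate)
  diff <- ttest_vs_reference(mk(c(7, 7, 7)), "ref")
  expect_equal(diff$p, 0)
  expect_true(diff$degenerate)
})

test_that("star coding thresholds are exact at the boundaries", {
  expect_equal(star_code(c(0.004999, 0.005, 0.009999, 0.01, 0.049999,
                           0.05, 0.5, NA)),
               c("***", "**", "**", "*", "*", "", "", ""))
})

test_that("t-test false-positive rate is calibrated at nominal alpha", {
  set.seed(1234)
  reps <- 2000
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(6); y <- rnorm(6)
    tab <- data.frame(strain = rep(c("ref", "mut"), each = 6),
                      condition = "none", timepoint = NA_real_,
                      replicate = rep(1:6, 2), od660 = 0.5,
                      lum = 100 + c(x, y) * 10,
                      od660_corr = 0.5, lum_corr = 1,
                      signal = c(x, y))
    p[i] <- ttest_vs_reference(tab, "ref")$p
  }
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})

test_that("a planted parent-relative effect is recovered as a ~2-fold change", {
  sim <- simulate_retest(effects = c(BY4743 = 0, gtr1 = 1, srn2 = -1),
                         n_replicates = 6, sigma_noise = 0.1, seed = 31L)
  res <- retest_analysis(sim$table, "BY4743", blanks = sim$blanks)
  expect_equal(res$fold[res$strain == "gtr1"], 2, tolerance = 0.25)
  expect_equal(res$fold[res$strain == "srn2"], 0.5, tolerance = 0.15)
  expect_true(res$p[res$strain == "gtr1"] < 0.05)
})

test_that("time-course folds recover the planted rise over background", {
  sim <- simulate_retest(
    effects = c(BY4743 = 0, gtr1 = 1),
    timepoints = c(0, 8, 21, 48),
    profile = function(t) 1 + 6.5 * pmin(t / 21, 1),
    n_replicates = 6, sigma_noise = 0.08, seed = 37L)
  res <- retest_analysis(sim$table, "BY4743", timecourse = TRUE)
  wt21 <- res$fold[res$strain == "BY4743" & res$timepoint == 21]
  expect_equal(wt21, 7.5, tolerance = 0.15)
  # the planted +1 log2 strain roughly doubles the rise over background
  g21 <- res$fold[res$strain == "gtr1" & res$timepoint == 21]
  expect_equal((g21 - 1) / (wt21 - 1), 2, tolerance = 0.3)
  # identical t=0 and later rows give fold 1 everywhere
  flat <- data.frame(strain = rep("BY4743", 8), condition = "none",
                     timepoint = rep(c(0, 21), each = 4),
                     replicate = rep(1:4, 2), od660 = 0.04, lum = 50)
  fres <- suppressWarnings(
    retest_analysis(flat, "BY4743", timecourse = TRUE))
  expect_equal(fres$fold, 1, tolerance = 1e-12)
})
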