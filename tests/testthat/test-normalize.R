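make_blanks <- function(values_by_plate) {
  wells <- all_wells()
  pw <- parse_well(wells)
  do.call(rbind, lapply(seq_along(values_by_plate), function(i) {
    data.frame(plate_id = paste0("blank", i), replicate_id = "b1",
               well = wells, row = pw$row, col = pw$col,
               od660 = values_by_plate[[i]], lum = 0, role = "blank",
               stringsAsFactors = FALSE)
  }))
}

test_that("background profile averages blank plates per well", {
  prof <- compute_background(make_blanks(rep(list(0.05), 8)))
  expect_equal(nrow(prof), 96L)
  expect_true(all(prof$bg_od660 == 0.05))
  expect_true(all(prof$n_blanks == 8L))

  two <- make_blanks(list(0.04, 0.06))
  prof2 <- compute_background(two)
  expect_equal(prof2$bg_od660[prof2$well == "A01"], 0.05)
})

test_that("background estimates concentrate around the generating mean", {
  cfg <- small_config(bg_od_mean = 0.04, bg_od_sd = 0.005, seed = 11L)
  sim <- simulate_screen(cfg)
  prof <- compute_background(sim$plates)
  # CLT bound over 96 well means of 8 blanks each: 4 sd / sqrt(8)
  expect_true(all(abs(prof$bg_od660 - 0.04) < 4 * 0.005 / sqrt(8)))
  expect_lt(abs(mean(prof$bg_od660) - 0.04), 3 * 0.005 / sqrt(8 * 96))
})

test_that("the linear range is a closed interval", {
  r <- linear_range(0.1, 1.0)
  wells <- parse_well(c("A1", "A2", "A3", "A4"))
  ps <- data.frame(plate_id = "p", replicate_id = "r1", well = wells$well,
                   row = wells$row, col = wells$col,
                   od660 = c(0.1, 1.0, 1.0 + 1e-9, 0.0999), lum = 100,
                   role = "sample")
  fl <- apply_linear_range(ps, r)
  expect_equal(fl$in_linear_range, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(linear_range(1, 0.5))
})

test_that("log2 RLU matches hand arithmetic and flags domain edges", {
  wells <- parse_well(c("A1", "A2", "A3", "A4"))
  prof <- data.frame(well = wells$well, row = wells$row, col = wells$col,
                     bg_od660 = 0.1, bg_lum = 0, n_blanks = 8)
  ps <- data.frame(plate_id = "p", replicate_id = "r1", well = wells$well,
                   row = wells$row, col = wells$col,
                   od660 = c(0.5, 0.5, 0.08, 0.5),
                   lum = c(1000, 2000, 1000, 0), role = "sample")
  rlu <- compute_rlu(ps, prof)
  # lum 1000 over net OD 0.4 -> log2(2500)
  expect_equal(rlu$log2_rlu[1], log2(2500), tolerance = 1e-12)
  expect_equal(rlu$log2_rlu[1], 11.2877, tolerance = 1e-4)
  # doubling lum raises log2 RLU by exactly 1
  expect_equal(rlu$log2_rlu[2] - rlu$log2_rlu[1], 1, tolerance = 1e-12)
  expect_equal(rlu$reason[3], "nonpositive_net_od")
  expect_equal(rlu$reason[4], "zero_lum")
  expect_false(any(rlu$valid[3:4]))
})

test_that("positional centering removes per-well means and ignores shifts", {
  w <- parse_well("B02")
  rlu <- data.frame(plate_id = c("p1", "p2", "p3"), replicate_id = "r1",
                    well = w$well, row = w$row, col = w$col,
                    log2_rlu = c(1, 2, 3), valid = TRUE, reason = "")
  out <- normalize_positional(rlu)
  expect_equal(out$log2_rlu, c(-1, 0, 1))

  shifted <- rlu
  shifted$log2_rlu <- shifted$log2_rlu + 0.7
  expect_equal(normalize_positional(shifted)$log2_rlu, out$log2_rlu)
})

test_that("after centering every well's across-plate mean of valid entries is 0", {
  sim <- simulate_screen(small_config(seed = 3L))
  res <- score_screen(sim$plates, sim$map)
  rlu <- res$rlu
  means <- tapply(ifelse(rlu$valid, rlu$log2_rlu, NA), rlu$well,
                  mean, na.rm = TRUE)
  expect_true(all(abs(means) < 1e-9))
})

test_that("invalid entries do not contaminate well means", {
  w <- parse_well("C03")
  rlu <- data.frame(plate_id = c("p1", "p2", "p3"), replicate_id = "r1",
                    well = w$well, row = w$row, col = w$col,
                    log2_rlu = c(1, 3, NA), valid = c(TRUE, TRUE, FALSE),
                    reason = c("", "", "zero_lum"))
  out <- normalize_positional(rlu)
  expect_equal(out$log2_rlu[1:2], c(-1, 1))
  expect_true(is.na(out$log2_rlu[3]))
})

test_that("a position on a single plate is centred to zero with a warning", {
  w <- parse_well("D04")
  rlu <- data.frame(plate_id = "p1", replicate_id = "r1", well = w$well,
                    row = w$row, col = w$col, log2_rlu = 5, valid = TRUE,
                    reason = "")
  expect_warning(out <- normalize_positional(rlu), "only one plate")
  expect_equal(out$log2_rlu, 0)
})

test_that("positional normalization suppresses the well-position variance share", {
  cfg <- small_config(n_strains = 384L, well_effect_scale = 0.5, seed = 5L)
  sim <- simulate_screen(cfg)
  bg <- compute_background(sim$plates)
  samples <- apply_linear_range(sim$plates[sim$plates$role == "sample", ],
                                linear_range(0.1, 1.0))
  raw <- compute_rlu(samples, bg)
  centred <- normalize_positional(raw)
  share <- function(rlu) {
    v <- rlu$log2_rlu[rlu$valid]
    w <- rlu$well[rlu$valid]
    wm <- tapply(v, w, mean)
    stats::var(wm[w]) / stats::var(v)
  }
  expect_gt(share(raw), 0.1)       # planted positional effects dominate
  expect_lt(share(centred), 0.01)  # and are removed by centering
})

test_that("the zero-nuisance chain recovers block-constant effects exactly", {
  scr <- block_effect_screen(c(p1 = 0.5, p2 = -0.25, p3 = 1.0))
  res <- score_screen(scr$plates, scr$map)
  m <- res$scores
  truth <- scr$effects[sub("_.*", "", m$strain)]
  resid <- m$mean_log2_rlu - truth
  # recovery up to one global additive constant
  expect_lt(max(resid) - min(resid), 1e-9)
  expect_equal(stats::cor(m$mean_log2_rlu, unname(truth)), 1)
})
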