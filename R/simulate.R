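#' Configuration of a synthetic deletion-library screen
#'
#' Parameters of the generative model for a plate-based extracellular-ATP
#' screen: a deletion library laid out on 96-well source plates, each assay
#' run in three biological replicates plus blank (medium-only) control
#' plates. Per-strain effects are additive on the log2 luminescence-per-cell
#' scale; planted Low/High sets carry shifted effects so recovery can be
#' scored against truth; slow growers fall below the reader's linear range
#' in two or three replicates, exercising the exclusion rule.
#'
#' Defaults mirror the screen's design (4609 scored strains, 8 x 12 plates,
#' 3 replicates, 8 blank plates, 5% planted tails); noise scales are chosen
#' as realistic for saturated-culture luminescence assays.
#'
#' @param n_strains number of library strains.
#' @param plate_rows,plate_cols plate geometry.
#' @param n_replicates biological replicates per source plate.
#' @param n_blank_plates medium-only control plates.
#' @param frac_low_set,frac_high_set fractions of strains planted with
#'   decreased / increased efflux.
#' @param delta_low,delta_high planted effect magnitudes (log2 units;
#'   applied as -delta_low and +delta_high).
#' @param sigma_strain baseline strain-effect spread (log2).
#' @param sigma_noise replicate measurement noise (log2).
#' @param well_effect_scale positional-effect amplitude (log2).
#' @param plate_effect_scale per-assay-plate offset amplitude (log2).
#' @param od_mean,od_sd saturated-culture net OD660.
#' @param frac_slow fraction of slow growers; @param od_slow_mean their OD.
#' @param bg_od_mean,bg_od_sd blank-well OD660.
#' @param lum_bg_mean,lum_bg_sd blank-well luminescence (truncated at 0).
#' @param linear_lo,linear_hi reader OD660 linear range.
#' @param lum_base baseline luminescence scale (counts per OD unit).
#' @param seed RNG seed.
#' @return validated list with class `sim_config`.
#' @export
sim_config <- function(n_strains = 4609L, plate_rows = 8L, plate_cols = 12L,
                       n_replicates = 3L, n_blank_plates = 8L,
                       frac_low_set = 0.05, frac_high_set = 0.05,
                       delta_low = 1.2, delta_high = 1.2,
                       sigma_strain = 0.5, sigma_noise = 0.4,
                       well_effect_scale = 0.3, plate_effect_scale = 0.2,
                       od_mean = 0.5, od_sd = 0.05,
                       frac_slow = 0.02, od_slow_mean = 0.05,
                       bg_od_mean = 0.04, bg_od_sd = 0.005,
                       lum_bg_mean = 5, lum_bg_sd = 2,
                       linear_lo = 0.1, linear_hi = 1.0,
                       lum_base = 1000, seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(cfg$frac_low_set, cfg$frac_high_set, cfg$frac_slow)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("fractions must lie in [0,1] with frac_low_set + frac_high_set + ",
         "frac_slow <= 1")
  }
  if (any(c(cfg$sigma_strain, cfg$sigma_noise, cfg$well_effect_scale,
            cfg$plate_effect_scale, cfg$od_sd, cfg$bg_od_sd) < 0)) {
    stop("scale parameters must be >= 0")
  }
  if (cfg$linear_lo >= cfg$linear_hi) stop("linear_lo must be < linear_hi")
  structure(cfg, class = "sim_config")
}

centred_normal <- function(n, sd) {
  x <- stats::rnorm(n, 0, sd)
  if (n > 1) x - mean(x) else 0 * x
}

#' Simulate a complete plate-based screen
#'
#' Generates sample plates (one per source plate and replicate), blank
#' control plates, the plate map, and the ground truth. For sample wells,
#' `OD_raw = bg_od + OD_strain` and
#' `LUM = lum_base * 2^(effect + plate_offset + well_offset + noise) *
#' OD_strain`, so log2(LUM / (OD_raw - background)) recovers the planted
#' effect plus nuisance terms. Strains are placed on plates in seeded random
#' order, decoupling planted sets from position. Slow growers receive
#' below-linear-range OD in a random two or three of the replicates.
#'
#' @param config a [sim_config()].
#' @return list: `plates` (PlateSet data.frame, samples + blanks), `map`
#'   (plate map), `truth` (list: strains data.frame with true_log2_effect
#'   and set flags, plate_offset, well_offset, config).
#' @export
simulate_screen <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  wells_per_plate <- config$plate_rows * config$plate_cols
  n_source <- ceiling(config$n_strains / wells_per_plate)
  capacity <- n_source * wells_per_plate
  if (config$n_strains > capacity) stop("plate capacity exceeded")

  strains <- sprintf("g%05d", seq_len(config$n_strains))
  n_low <- round(config$frac_low_set * config$n_strains)
  n_high <- round(config$frac_high_set * config$n_strains)
  n_slow <- round(config$frac_slow * config$n_strains)
  roles <- sample(c(rep("low", n_low), rep("high", n_high),
                    rep("slow", n_slow),
                    rep("none", config$n_strains - n_low - n_high - n_slow)))
  effect <- stats::rnorm(config$n_strains, 0, config$sigma_strain)
  effect[roles == "low"] <- effect[roles == "low"] - config$delta_low
  effect[roles == "high"] <- effect[roles == "high"] + config$delta_high

  # randomized layout: planted sets must not be confounded with position
  slots <- expand.grid(well_idx = seq_len(wells_per_plate),
                       plate = seq_len(n_source))
  wl <- all_wells(config$plate_rows, config$plate_cols)
  placement <- sample(nrow(slots), config$n_strains)
  pw <- parse_well(wl[slots$well_idx[placement]],
                   config$plate_rows, config$plate_cols)
  map <- data.frame(plate_id = sprintf("p%02d", slots$plate[placement]),
                    well = pw$well, row = pw$row, col = pw$col,
                    strain = strains, stringsAsFactors = FALSE)

  well_offset <- stats::setNames(
    centred_normal(wells_per_plate, config$well_effect_scale), wl)
  rep_ids <- sprintf("r%d", seq_len(config$n_replicates))
  assay <- expand.grid(plate_id = sprintf("p%02d", seq_len(n_source)),
                       replicate_id = rep_ids, stringsAsFactors = FALSE)
  plate_offset <- centred_normal(nrow(assay), config$plate_effect_scale)
  names(plate_offset) <- paste(assay$plate_id, assay$replicate_id)

  # slow growers: below-linear OD in a random 2 or 3 of the replicates
  slow_reps <- lapply(which(roles == "slow"), function(i) {
    k <- sample(2:min(3, config$n_replicates), 1)
    sample(rep_ids, k)
  })
  names(slow_reps) <- strains[roles == "slow"]

  sample_rows <- map[rep(seq_len(nrow(map)), times = config$n_replicates), ]
  sample_rows$replicate_id <- rep(rep_ids, each = nrow(map))
  n <- nrow(sample_rows)
  is_slow_rep <- mapply(function(s, r) {
    !is.null(slow_reps[[s]]) && r %in% slow_reps[[s]]
  }, sample_rows$strain, sample_rows$replicate_id, USE.NAMES = FALSE)
  od_strain <- stats::rnorm(n, config$od_mean, config$od_sd)
  od_strain[is_slow_rep] <- abs(stats::rnorm(sum(is_slow_rep),
                                             config$od_slow_mean,
                                             config$od_sd / 5))
  od_strain <- pmax(od_strain, 1e-4)
  eff <- effect[match(sample_rows$strain, strains)]
  po <- plate_offset[paste(sample_rows$plate_id, sample_rows$replicate_id)]
  wo <- well_offset[sample_rows$well]
  eps <- stats::rnorm(n, 0, config$sigma_noise)
  lum <- config$lum_base * 2^(eff + po + wo + eps) * od_strain
  samples <- data.frame(plate_id = sample_rows$plate_id,
                        replicate_id = sample_rows$replicate_id,
                        well = sample_rows$well, row = sample_rows$row,
                        col = sample_rows$col,
                        od660 = config$bg_od_mean + od_strain,
                        lum = lum, role = "sample",
                        stringsAsFactors = FALSE)

  nb <- config$n_blank_plates * wells_per_plate
  gw <- parse_well(rep(wl, config$n_blank_plates))
  blanks <- data.frame(
    plate_id = rep(sprintf("blank%d", seq_len(config$n_blank_plates)),
                   each = wells_per_plate),
    replicate_id = "b1", well = gw$well, row = gw$row, col = gw$col,
    od660 = pmax(stats::rnorm(nb, config$bg_od_mean, config$bg_od_sd), 0),
    lum = pmax(stats::rnorm(nb, config$lum_bg_mean, config$lum_bg_sd), 0),
    role = "blank", stringsAsFactors = FALSE)

  truth_strains <- data.frame(strain = strains, true_log2_effect = effect,
                              low_set = roles == "low",
                              high_set = roles == "high",
                              slow_grower = roles == "slow",
                              stringsAsFactors = FALSE)
  list(plates = rbind(samples, blanks),
       map = map,
       truth = list(strains = truth_strains,
                    plate_offset = data.frame(
                      plate_id = assay$plate_id,
                      replicate_id = assay$replicate_id,
                      offset = unname(plate_offset),
                      stringsAsFactors = FALSE),
                    well_offset = data.frame(well = wl,
                                             offset = unname(well_offset),
                                             stringsAsFactors = FALSE),
                    config = config))
}

#' Simulate an annotation collection with planted enriched terms
#'
#' Planted terms draw a fixed fraction of their members from a named truth
#' set (Low or High planted strains) and the rest uniformly from the
#' remaining universe; null terms are drawn uniformly. Term sizes are
#' uniform over `term_size_range`.
#'
#' @param truth truth component of [simulate_screen()] output.
#' @param n_planted_terms,n_null_terms term counts.
#' @param term_size_range length-2 integer range of set sizes.
#' @param planted_overlap fraction of each planted term drawn from its set.
#' @param planted_sets which truth set each planted term targets ("low" /
#'   "high", recycled).
#' @param seed RNG seed.
#' @return named list of gene sets (GMT-style) with `description` attribute
#'   marking planted terms and a `planted` attribute naming them.
#' @export
simulate_annotations <- function(truth, n_planted_terms = 5L,
                                 n_null_terms = 20L,
                                 term_size_range = c(10L, 30L),
                                 planted_overlap = 0.8,
                                 planted_sets = "low", seed = 1L) {
  set.seed(seed)
  universe <- truth$strains$strain
  if (max(term_size_range) > length(universe)) {
    stop("term size exceeds universe")
  }
  pools <- list(low = truth$strains$strain[truth$strains$low_set],
                high = truth$strains$strain[truth$strains$high_set])
  targets <- rep_len(planted_sets, n_planted_terms)
  sets <- list()
  desc <- character()
  sizes_pool <- seq(term_size_range[1], term_size_range[2])
  draw_size <- function() sizes_pool[sample.int(length(sizes_pool), 1)]
  if (n_planted_terms > 0) {
    for (i in seq_len(n_planted_terms)) {
      size <- draw_size()
      pool <- pools[[targets[i]]]
      n_in <- min(round(planted_overlap * size), length(pool))
      members <- c(sample(pool, n_in),
                   sample(setdiff(universe, pool), size - n_in))
      id <- sprintf("PLANTED_%s_%02d", toupper(targets[i]), i)
      sets[[id]] <- sort(members)
      desc[id] <- paste0("planted ", targets[i], "-set term")
    }
  }
  if (n_null_terms > 0) {
    for (i in seq_len(n_null_terms)) {
      size <- draw_size()
      id <- sprintf("NULL_%03d", i)
      sets[[id]] <- sort(sample(universe, size))
      desc[id] <- "null term"
    }
  }
  attr(sets, "description") <- desc
  attr(sets, "planted") <- grep("^PLANTED", names(sets), value = TRUE)
  sets
}

# map pair indices 1..choose(n,2) to (i, j), i < j, lexicographic order
pair_from_index <- function(idx, n) {
  cum <- cumsum(seq(n - 1, 1))
  i <- findInterval(idx, cum, left.open = TRUE) + 1L
  j <- i + (idx - c(0, cum)[i])
  cbind(i, j)
}

#' Simulate a functional-interaction network with planted modules
#'
#' Background edges appear independently with probability
#' `background_density` over all strain pairs; each planted module is an
#' Erdos-Renyi graph at `within_density` over nodes sampled from a named
#' truth set, so dense modules sit inside the planted tails. Self-loops and
#' duplicate edges never occur.
#'
#' @param truth truth component of [simulate_screen()] output.
#' @param module_specs list of lists with fields `set` ("low"/"high"/"all"),
#'   `n_nodes`, `within_density`.
#' @param background_density edge probability outside modules.
#' @param seed RNG seed.
#' @return undirected [igraph::graph] over all strains (isolated nodes
#'   included), with attribute `planted_modules`: list of node vectors.
#' @export
simulate_network <- function(truth, module_specs = list(),
                             background_density = 5e-4, seed = 1L) {
  if (background_density < 0 || background_density > 1) {
    stop("density outside [0,1]")
  }
  set.seed(seed)
  strains <- truth$strains$strain
  n <- length(strains)
  npairs <- n * (n - 1) / 2
  m <- stats::rbinom(1, npairs, background_density)
  edges <- if (m > 0) {
    pr <- pair_from_index(sort(sample(npairs, m)), n)
    data.frame(from = strains[pr[, 1]], to = strains[pr[, 2]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  }
  planted <- list()
  for (spec in module_specs) {
    wd <- spec$within_density
    if (wd < 0 || wd > 1) stop("density outside [0,1]")
    pool <- switch(spec$set,
                   low = truth$strains$strain[truth$strains$low_set],
                   high = truth$strains$strain[truth$strains$high_set],
                   all = strains,
                   stop("unknown module set label: ", spec$set))
    if (spec$n_nodes > length(pool)) {
      stop("module node count exceeds '", spec$set, "' set size")
    }
    nodes <- sample(pool, spec$n_nodes)
    pairs <- utils::combn(sort(nodes), 2)
    keep <- stats::runif(ncol(pairs)) < wd
    if (any(keep)) {
      edges <- rbind(edges, data.frame(from = pairs[1, keep],
                                       to = pairs[2, keep],
                                       stringsAsFactors = FALSE))
    }
    planted <- c(planted, list(sort(nodes)))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = strains)
  g <- igraph::simplify(g)
  g$planted_modules <- planted
  g
}

#' Simulate a retest / time-course experiment
#'
#' Emulates targeted retests: replicate cultures of a parent strain and
#' mutants with planted log2 effects, optionally over a time-course whose
#' luminescence follows a supplied profile relative to the assay background
#' (time-zero cultures). Luminescence is
#' `bg_lum + lum_base * profile(t) * 2^(effect + noise)`; at `t = 0` the
#' profile is 0, leaving background only.
#'
#' @param effects named numeric vector of planted log2 effects versus the
#'   parent; the first element is taken as the reference (effect usually 0).
#' @param timepoints assay times in hours (`0` rows become the background);
#'   `NULL` gives a single endpoint assay plus blanks.
#' @param conditions character vector of condition tags (recycled over the
#'   design); per-condition log2 shifts can be given via `condition_effects`.
#' @param condition_effects named numeric, log2 shift per condition.
#' @param n_replicates biological replicates per cell.
#' @param profile function of time giving the zero-effect strain's
#'   luminescence relative to background (`profile(0)` must be 1; the
#'   default rises to 7.5x background by 21 h and plateaus).
#' @param sigma_noise replicate noise (log2).
#' @param lum_base,bg_lum,od_mean,od_sd,bg_od scales of the measurement.
#' @param seed RNG seed.
#' @return list: `table` (long RetestTable), `blanks` (blank readings, NULL
#'   when timepoints are given), `effects`, `profile`.
#' @export
simulate_retest <- function(effects = c(BY4743 = 0),
                            timepoints = NULL,
                            conditions = "none",
                            condition_effects = NULL,
                            n_replicates = 6L,
                            profile = function(t) 1 + 6.5 * pmin(t / 21, 1),
                            sigma_noise = 0.15,
                            lum_base = 1000, bg_lum = 50,
                            od_mean = 0.5, od_sd = 0.03, bg_od = 0.04,
                            seed = 1L) {
  set.seed(seed)
  stopifnot(!is.null(names(effects)))
  tp <- if (is.null(timepoints)) 30 else timepoints
  grid <- expand.grid(strain = names(effects), condition = conditions,
                      timepoint = tp, replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  eff <- effects[grid$strain]
  if (!is.null(condition_effects)) {
    ce <- condition_effects[grid$condition]
    ce[is.na(ce)] <- 0
    eff <- eff + ce
  }
  eps <- stats::rnorm(nrow(grid), 0, sigma_noise)
  if (is.null(timepoints)) {
    lum <- bg_lum + lum_base * 2^(eff + eps)
    grown <- rep(TRUE, nrow(grid))
  } else {
    # strain ATP scales the rise over background, not the background itself
    lum <- bg_lum * (1 + (profile(grid$timepoint) - 1) * 2^(eff + eps))
    grown <- profile(grid$timepoint) > 1
  }
  od <- bg_od + ifelse(grown,
                       pmax(stats::rnorm(nrow(grid), od_mean, od_sd), 1e-3),
                       0)
  table <- data.frame(strain = grid$strain, condition = grid$condition,
                      timepoint = grid$timepoint,
                      replicate = grid$replicate,
                      od660 = pmax(od + stats::rnorm(nrow(grid), 0,
                                                     bg_od / 10), 0),
                      lum = pmax(lum, 0), stringsAsFactors = FALSE)
  blanks <- NULL
  if (is.null(timepoints)) {
    table$timepoint <- NA_real_
    blanks <- data.frame(
      od660 = pmax(stats::rnorm(2 * n_replicates, bg_od, bg_od / 10), 0),
      lum = pmax(stats::rnorm(2 * n_replicates, bg_lum, bg_lum / 10), 0))
  } else {
    # time-zero cultures read at background: profile(0) must be 0
    is0 <- table$timepoint == 0
    table$lum[is0] <- pmax(stats::rnorm(sum(is0), bg_lum, bg_lum / 10), 0)
    table$od660[is0] <- pmax(stats::rnorm(sum(is0), bg_od, bg_od / 10), 0)
  }
  list(table = table, blanks = blanks, effects = effects, profile = profile)
}

#' Write a simulated screen to plate files on disk
#'
#' Serializes a [simulate_screen()] result in the same dialects the readers
#' accept: one long-format CSV per assay/blank plate, a plate-map TSV, and
#' a truth TSV.
#'
#' @param sim result of [simulate_screen()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_screen <- function(sim, dir) {
  dir.create(file.path(dir, "plates"), recursive = TRUE, showWarnings = FALSE)
  key <- paste(sim$plates$plate_id, sim$plates$replicate_id, sep = "_")
  for (k in unique(key)) {
    pp <- sim$plates[key == k, c("well", "od660", "lum")]
    utils::write.csv(pp, file.path(dir, "plates", paste0(k, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.table(sim$map[, c("plate_id", "well", "strain")],
                     file.path(dir, "plate_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$strains, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
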