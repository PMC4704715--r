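# Small screen configurations used across tests: 2 source plates x 3
# replicates keeps every stage fast while exercising the full layout.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_strains = 192L, frac_low_set = 0.05,
                   frac_high_set = 0.05, frac_slow = 0.02, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# a zero-noise configuration: every nuisance and noise scale at 0
quiet_config <- function(...) {
  small_config(sigma_noise = 0, well_effect_scale = 0,
               plate_effect_scale = 0, od_sd = 0, bg_od_sd = 0,
               lum_bg_sd = 0, frac_slow = 0, ...)
}

# build a PlateSet + map directly (bypassing the generator) in which the
# true effect is constant within each source plate, so per-well centering
# can recover effects exactly up to one global constant
block_effect_screen <- function(plate_effects = c(p1 = 0.5, p2 = -0.25,
                                                  p3 = 1.0),
                                n_replicates = 3, lum_base = 1000,
                                od = 0.5, bg = 0.04) {
  wells <- all_wells()
  pw <- parse_well(wells)
  plates <- list(); maps <- list()
  for (p in names(plate_effects)) {
    maps[[p]] <- data.frame(plate_id = p, well = wells, row = pw$row,
                            col = pw$col,
                            strain = paste0(p, "_", wells),
                            stringsAsFactors = FALSE)
    for (r in seq_len(n_replicates)) {
      plates[[paste(p, r)]] <- data.frame(
        plate_id = p, replicate_id = paste0("r", r), well = wells,
        row = pw$row, col = pw$col, od660 = bg + od,
        lum = lum_base * 2^plate_effects[[p]] * od, role = "sample",
        stringsAsFactors = FALSE)
    }
  }
  blanks <- data.frame(plate_id = "blank1", replicate_id = "b1",
                       well = wells, row = pw$row, col = pw$col,
                       od660 = bg, lum = 0.0, role = "blank",
                       stringsAsFactors = FALSE)
  list(plates = rbind(do.call(rbind, plates), blanks),
       map = do.call(rbind, maps),
       effects = plate_effects)
}
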