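#' Score a screen end to end
#'
#' Runs the full normalization chain on a PlateSet: well-specific blank
#' background, linear-range exclusion, log2 RLU per cell, positional
#' centering across plates, replicate averaging with the validity rule, and
#' tail selection.
#'
#' @param plates PlateSet data.frame holding sample and blank rows (e.g.
#'   `simulate_screen()$plates`, or rows bound from [read_plate_csv()]).
#' @param map plate map data.frame.
#' @param range a [linear_range()]; defaults to OD660 in [0.1, 1.0].
#' @param min_valid minimum valid replicates per strain (default 2).
#' @param fraction tail fraction for hit calling.
#' @param per_replicate,per_plate_centering passed to
#'   [normalize_positional()].
#' @param subtract_lum_background passed to [compute_rlu()].
#' @return list: `background`, `rlu` (centred RLUTable), `scores`
#'   (StrainScoreTable), `hits` (HitGroups).
#' @export
score_screen <- function(plates, map, range = linear_range(0.1, 1.0),
                         min_valid = 2L, fraction = 0.05,
                         per_replicate = FALSE, per_plate_centering = FALSE,
                         subtract_lum_background = FALSE) {
  background <- compute_background(plates)
  samples <- apply_linear_range(plates[plates$role == "sample", , drop = FALSE],
                                range)
  rlu <- compute_rlu(samples, background,
                     subtract_lum_background = subtract_lum_background)
  rlu <- normalize_positional(rlu, per_replicate = per_replicate,
                              per_plate_centering = per_plate_centering)
  scores <- average_replicates(rlu, map, min_valid = min_valid)
  hits <- select_tails(scores, fraction = fraction)
  list(background = background, rlu = rlu, scores = scores, hits = hits)
}
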