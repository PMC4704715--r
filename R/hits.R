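#' Average replicates into per-strain scores
#'
#' Joins normalized log2 RLU values to the plate map and averages over valid
#' replicates. Strains valid in fewer than `min_valid` replicates — e.g.
#' slow growers whose OD fell below the reader's linear range in two of
#' three replicates — are excluded and carry no mean.
#'
#' @param rlu RLUTable (normally after [normalize_positional()]).
#' @param map plate map from [read_plate_map()] or the generator.
#' @param min_valid minimum number of valid replicates for a strain to be
#'   scored (default 2, the "two of three" rule).
#' @return data.frame (StrainScoreTable): strain, one `rep_<id>` column per
#'   replicate, mean_log2_rlu, n_valid, qc_flag
#'   ("ok" | "excluded_linear_range" | "excluded_other").
#' @export
average_replicates <- function(rlu, map, min_valid = 2L) {
  keyed <- merge(rlu, map[, c("plate_id", "well", "strain")],
                 by = c("plate_id", "well"))
  if (nrow(keyed) == 0L) stop("plate map matches no RLU entries")
  reps <- sort(unique(keyed$replicate_id))
  strains <- sort(unique(keyed$strain))
  val <- matrix(NA_real_, length(strains), length(reps),
                dimnames = list(strains, reps))
  ok <- matrix(FALSE, length(strains), length(reps),
               dimnames = list(strains, reps))
  rsn <- matrix("", length(strains), length(reps),
                dimnames = list(strains, reps))
  i <- cbind(match(keyed$strain, strains), match(keyed$replicate_id, reps))
  val[i] <- ifelse(keyed$valid, keyed$log2_rlu, NA_real_)
  ok[i] <- keyed$valid
  rsn[i] <- keyed$reason
  n_valid <- rowSums(ok)
  mean_log2 <- ifelse(n_valid >= min_valid,
                      rowSums(val, na.rm = TRUE) / n_valid, NA_real_)
  qc <- rep("ok", length(strains))
  excl <- n_valid < min_valid
  lin <- rowSums(rsn == "outside_linear_range") > 0
  qc[excl] <- ifelse(lin[excl], "excluded_linear_range", "excluded_other")
  out <- data.frame(strain = strains, stringsAsFactors = FALSE)
  for (r in reps) out[[paste0("rep_", r)]] <- val[, r]
  out$mean_log2_rlu <- mean_log2
  out$n_valid <- as.integer(n_valid)
  out$qc_flag <- qc
  rownames(out) <- NULL
  out
}

#' Select distribution tails as hit groups
#'
#' Ranks scored strains by mean log2 RLU and takes the extreme
#' `floor(fraction * n_scored)` strains of each tail as the Low and High
#' groups (with 4609 scored strains and fraction 0.05, 230 per tail). Ties
#' spanning the cutoff are broken by strain identifier so the selection is
#' deterministic and insensitive to input order.
#'
#' @param scores StrainScoreTable from [average_replicates()].
#' @param fraction tail fraction in (0, 0.5).
#' @return list (HitGroups): `low`, `high` (ordered strain vectors, most
#'   extreme first), `n_per_tail`, `fraction`, `n_scored`.
#' @export
select_tails <- function(scores, fraction = 0.05) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 0.5) {
    stop("fraction must lie in (0, 0.5)")
  }
  scored <- scores[!is.na(scores$mean_log2_rlu), , drop = FALSE]
  n_scored <- nrow(scored)
  n_per_tail <- as.integer(floor(fraction * n_scored))
  if (n_per_tail < 1L) stop("too few scored strains for fraction ", fraction)
  o_low <- order(scored$mean_log2_rlu, scored$strain)
  o_high <- order(-scored$mean_log2_rlu, scored$strain)
  list(low = scored$strain[o_low][seq_len(n_per_tail)],
       high = scored$strain[o_high][seq_len(n_per_tail)],
       n_per_tail = n_per_tail, fraction = fraction, n_scored = n_scored)
}
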