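#' Well-specific background profile from blank plates
#'
#' The screen includes plates of medium without cells ("blanks"); the OD660
#' background of each well position is estimated as the arithmetic mean of
#' that well's readings across all blank plates. A mean blank luminescence
#' per well is computed alongside (used only when luminescence background
#' subtraction is requested, as in retests).
#'
#' @param blanks PlateSet rows with `role == "blank"` (rows of other roles
#'   are ignored).
#' @return data.frame (BackgroundProfile): well, row, col, bg_od660, bg_lum,
#'   n_blanks.
#' @export
compute_background <- function(blanks) {
  blanks <- blanks[blanks$role == "blank", , drop = FALSE]
  if (nrow(blanks) == 0L) stop("no blank-plate readings supplied")
  agg <- stats::aggregate(cbind(od660, lum) ~ well + row + col, data = blanks,
                          FUN = mean)
  n <- stats::aggregate(list(n_blanks = blanks$od660),
                        by = list(well = blanks$well), FUN = length)
  prof <- merge(agg, n, by = "well")
  prof <- prof[order(prof$row, prof$col), , drop = FALSE]
  names(prof)[names(prof) == "od660"] <- "bg_od660"
  names(prof)[names(prof) == "lum"] <- "bg_lum"
  rownames(prof) <- NULL
  prof
}

#' Plate-reader linear range
#'
#' OD660 readings outside the instrument's experimentally derived linear
#' range are excluded from analysis. The interval is closed: `lo` and `hi`
#' themselves are valid.
#'
#' @param lo,hi bounds in OD660 units, `0 <= lo < hi`.
#' @return list with class `linear_range`.
#' @export
linear_range <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo >= 0, lo < hi)
  structure(list(lo = lo, hi = hi), class = "linear_range")
}

#' Flag readings outside the linear range
#'
#' @param readings PlateSet data.frame.
#' @param range a [linear_range()].
#' @return `readings` with logical column `in_linear_range`.
#' @export
apply_linear_range <- function(readings, range) {
  stopifnot(inherits(range, "linear_range"))
  readings$in_linear_range <-
    readings$od660 >= range$lo & readings$od660 <= range$hi
  readings
}

#' log2 relative luminescence per cell (RLU)
#'
#' Divides each well's luminescence by its background-subtracted OD660 and
#' takes log2. Entries whose net OD is non-positive or whose luminescence is
#' zero cannot be scored; they are flagged invalid with a reason code rather
#' than raising an error, since real screens contain such wells. Readings
#' already flagged outside the linear range are likewise carried as invalid.
#'
#' @param readings sample PlateSet rows, after [apply_linear_range()] (if the
#'   `in_linear_range` column is absent all rows are treated as in range).
#' @param background BackgroundProfile from [compute_background()].
#' @param subtract_lum_background also subtract the per-well mean blank
#'   luminescence from LUM before the ratio (retest-style correction; off by
#'   default for the primary screen).
#' @return data.frame (RLUTable): plate_id, replicate_id, well, row, col,
#'   log2_rlu, valid, reason ("" for valid entries).
#' @export
compute_rlu <- function(readings, background, subtract_lum_background = FALSE) {
  readings <- readings[readings$role == "sample", , drop = FALSE]
  miss <- setdiff(unique(readings$well), background$well)
  if (length(miss)) {
    stop("well(s) absent from background profile: ",
         paste(miss, collapse = ", "))
  }
  idx <- match(readings$well, background$well)
  net_od <- readings$od660 - background$bg_od660[idx]
  lum <- readings$lum
  if (subtract_lum_background) lum <- lum - background$bg_lum[idx]
  in_range <- if ("in_linear_range" %in% names(readings)) {
    readings$in_linear_range
  } else {
    rep(TRUE, nrow(readings))
  }
  reason <- rep("", nrow(readings))
  reason[!in_range] <- "outside_linear_range"
  reason[in_range & net_od <= 0] <- "nonpositive_net_od"
  reason[in_range & net_od > 0 & lum <= 0] <- "zero_lum"
  valid <- reason == ""
  log2_rlu <- rep(NA_real_, nrow(readings))
  log2_rlu[valid] <- log2(lum[valid] / net_od[valid])
  data.frame(plate_id = readings$plate_id,
             replicate_id = readings$replicate_id,
             well = readings$well, row = readings$row, col = readings$col,
             log2_rlu = log2_rlu, valid = valid, reason = reason,
             stringsAsFactors = FALSE)
}

#' Positional normalization across plates
#'
#' For every well position, subtracts the mean log2 RLU of that position
#' taken over all assay plates sharing the layout, removing well-position
#' effects (edge effects, well-specific optics). Only valid entries enter
#' the means; after centering, the across-plate mean of valid entries at
#' each position is zero.
#'
#' @param rlu RLUTable from [compute_rlu()].
#' @param per_replicate centre within each replicate batch separately
#'   instead of over all assay plates (default FALSE: all plates at once).
#' @param per_plate_centering additionally subtract each plate's median
#'   (a true plate-offset correction; off by default).
#' @return RLUTable with `log2_rlu` centred; a `well_mean` column records
#'   the subtracted positional means.
#' @export
normalize_positional <- function(rlu, per_replicate = FALSE,
                                 per_plate_centering = FALSE) {
  grp <- if (per_replicate) paste(rlu$replicate_id, rlu$well) else rlu$well
  vals <- ifelse(rlu$valid, rlu$log2_rlu, NA_real_)
  m <- tapply(vals, grp, mean, na.rm = TRUE)
  n_valid <- tapply(!is.na(vals), grp, sum)
  single <- names(n_valid)[n_valid == 1L]
  if (length(single)) {
    warning(length(single), " well position(s) valid on only one plate; ",
            "centred to 0")
  }
  wm <- as.numeric(m[grp])
  wm[is.na(wm)] <- 0
  rlu$well_mean <- wm
  rlu$log2_rlu <- rlu$log2_rlu - wm
  if (per_plate_centering) {
    pg <- paste(rlu$plate_id, rlu$replicate_id)
    pv <- ifelse(rlu$valid, rlu$log2_rlu, NA_real_)
    pm <- tapply(pv, pg, stats::median, na.rm = TRUE)
    adj <- as.numeric(pm[pg])
    adj[is.na(adj)] <- 0
    rlu$log2_rlu <- rlu$log2_rlu - adj
  }
  rlu
}
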