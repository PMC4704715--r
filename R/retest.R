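#' Background-correct retest measurements
#'
#' Retests subtract background LUM and OD660 from the sample readings. The
#' background comes either from explicit blank rows or, for time-courses,
#' from the time-zero rows of each strain (cultures assayed immediately
#' after inoculation). The working signal is the background-corrected
#' luminescence (per-culture extracellular ATP); with `per_cell = TRUE` it
#' is divided by the background-corrected OD660.
#'
#' @param table long-format retest data.frame: strain, condition, timepoint,
#'   replicate, od660, lum. `condition` and `timepoint` may be absent (a
#'   single condition / timepoint is assumed).
#' @param blanks optional data.frame with od660 and lum columns of blank
#'   readings; their means are the background.
#' @param use_t0 derive the background from rows with `timepoint == 0`
#'   (which are then removed from the output).
#' @param per_cell divide corrected LUM by corrected OD660.
#' @param epsilon floor applied when a corrected value is non-positive (with
#'   a warning), keeping downstream ratios finite.
#' @return the table with columns od660_corr, lum_corr, signal.
#' @export
background_correct <- function(table, blanks = NULL, use_t0 = FALSE,
                               per_cell = FALSE, epsilon = 1e-6) {
  table <- normalize_retest_table(table)
  if (use_t0) {
    t0 <- table[table$timepoint == 0, , drop = FALSE]
    if (nrow(t0) == 0L) stop("use_t0 = TRUE but no timepoint-0 rows")
    bg_lum <- mean(t0$lum)
    bg_od <- mean(t0$od660)
    t0_lum <- tapply(t0$lum, t0$strain, mean)
    table <- table[table$timepoint != 0, , drop = FALSE]
    # per-strain time-zero level, the denominator for time-course folds
    table$t0_lum <- as.numeric(t0_lum[table$strain])
  } else {
    if (is.null(blanks)) stop("supply blanks or set use_t0 = TRUE")
    bg_lum <- mean(blanks$lum)
    bg_od <- mean(blanks$od660)
  }
  table$od660_corr <- table$od660 - bg_od
  table$lum_corr <- table$lum - bg_lum
  n_floor <- sum(table$lum_corr <= 0) +
    if (per_cell) sum(table$od660_corr <= 0) else 0L
  if (n_floor > 0) {
    warning("background exceeds ", n_floor,
            " corrected reading(s); floored at epsilon")
    table$lum_corr <- pmax(table$lum_corr, epsilon)
    table$od660_corr <- pmax(table$od660_corr, epsilon)
  }
  table$signal <- if (per_cell) {
    table$lum_corr / table$od660_corr
  } else {
    table$lum_corr
  }
  table
}

normalize_retest_table <- function(table) {
  stopifnot(all(c("strain", "od660", "lum") %in% names(table)))
  if (!"condition" %in% names(table)) table$condition <- "none"
  if (!"timepoint" %in% names(table)) table$timepoint <- NA_real_
  if (!"replicate" %in% names(table)) {
    table$replicate <- stats::ave(seq_len(nrow(table)),
                                  table$strain, table$condition,
                                  table$timepoint, FUN = seq_along)
  }
  table
}

#' Fold change versus a reference strain or time zero
#'
#' Means the corrected signal per (strain, condition, timepoint) cell and
#' reports each cell's mean divided by the matched reference cell: the
#' parent strain at the same condition and timepoint, or — for time-courses
#' normalized within strain — each strain's own time-zero (assay
#' background) level, so the fold is the raw luminescence relative to the
#' level at inoculation. Cells with no matching reference are skipped with
#' a warning.
#'
#' @param table background-corrected table from [background_correct()].
#' @param reference reference strain identifier (e.g. the parent "BY4743").
#' @param within_strain if TRUE, fold is each cell's mean raw luminescence
#'   over the strain's time-zero mean (requires the `t0_lum` column written
#'   by `background_correct(use_t0 = TRUE)`).
#' @return data.frame: strain, condition, timepoint, n, mean_signal,
#'   sd_signal, fold.
#' @export
fold_vs_reference <- function(table, reference, within_strain = FALSE) {
  stopifnot("signal" %in% names(table))
  # explicit keys: a missing timepoint is a legitimate (single) cell
  key <- paste(table$strain, table$condition, table$timepoint, sep = "\r")
  cells <- unique(table[, c("strain", "condition", "timepoint")])
  ck <- paste(cells$strain, cells$condition, cells$timepoint, sep = "\r")
  cells$mean_signal <- as.numeric(tapply(table$signal, key, mean)[ck])
  cells$sd_signal <- as.numeric(tapply(table$signal, key, stats::sd)[ck])
  cells$n <- as.integer(tapply(table$signal, key, length)[ck])
  if (within_strain) {
    if (!"t0_lum" %in% names(table)) {
      stop("within_strain folds need the t0_lum column from ",
           "background_correct(use_t0 = TRUE)")
    }
    t0 <- tapply(table$t0_lum, table$strain, `[`, 1L)
    ref_val <- as.numeric(t0[cells$strain])
    cells$mean_lum <- as.numeric(tapply(table$lum, key, mean)[ck])
    skipped <- is.na(ref_val) | ref_val <= 0
    if (any(skipped)) {
      warning(sum(skipped), " cell(s) lack a positive time-zero level")
    }
    cells$fold <- ifelse(skipped, NA_real_, cells$mean_lum / ref_val)
    cells <- cells[order(cells$strain, cells$condition, cells$timepoint), ,
                   drop = FALSE]
    rownames(cells) <- NULL
    return(cells[, c("strain", "condition", "timepoint", "n", "mean_signal",
                     "sd_signal", "fold")])
  } else {
    if (!reference %in% cells$strain) {
      stop("reference strain ", reference, " absent from the table")
    }
    ref_rows <- cells[cells$strain == reference, , drop = FALSE]
    ref_val <- ref_rows$mean_signal[match(paste(cells$condition, cells$timepoint),
                                          paste(ref_rows$condition,
                                                ref_rows$timepoint))]
  }
  skipped <- is.na(ref_val) | ref_val <= 0
  if (any(skipped & !is.na(cells$mean_signal))) {
    warning(sum(skipped), " cell(s) lack a positive matching reference; ",
            "fold set to NA")
  }
  cells$fold <- ifelse(skipped, NA_real_, cells$mean_signal / ref_val)
  cells <- cells[order(cells$strain, cells$condition, cells$timepoint), ,
                 drop = FALSE]
  rownames(cells) <- NULL
  cells[, c("strain", "condition", "timepoint", "n", "mean_signal",
            "sd_signal", "fold")]
}

#' Significance stars for retest p-values
#'
#' Pure threshold coding used on the retest figures:
#' `***` p < 0.005, `**` p < 0.01, `*` p < 0.05, otherwise "".
#'
#' @param p numeric vector of p-values.
#' @return character vector of star codes.
#' @export
star_code <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.005, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Per-cell t-tests of each strain against the reference
#'
#' Within every (condition, timepoint) cell, the replicate signals of each
#' strain are compared to the reference strain's replicates with a
#' two-sided Student's t-test (pooled variance, df = n1 + n2 - 2; Welch by
#' flag). Degenerate cells (zero variance on both sides) give p = 1 when
#' the means agree and p = 0 (flagged) when they differ.
#'
#' @param table background-corrected table from [background_correct()].
#' @param reference reference strain identifier.
#' @param var_equal pooled-variance Student's test (default); FALSE for
#'   Welch.
#' @return data.frame: strain, condition, timepoint, n, n_ref, t, df, p,
#'   stars, degenerate.
#' @export
ttest_vs_reference <- function(table, reference, var_equal = TRUE) {
  stopifnot("signal" %in% names(table))
  if (!reference %in% table$strain) {
    stop("reference strain ", reference, " absent from the table")
  }
  cells <- unique(table[table$strain != reference,
                        c("strain", "condition", "timepoint")])
  if (nrow(cells) == 0L) {
    res <- data.frame(strain = character(), condition = character(),
                      timepoint = numeric(), n = integer(),
                      n_ref = integer(), t = numeric(), df = numeric(),
                      p = numeric(), degenerate = logical(),
                      stars = character(), stringsAsFactors = FALSE)
    return(res)
  }
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    sel <- table$condition == cc$condition &
      (table$timepoint %in% cc$timepoint |
         (is.na(cc$timepoint) & is.na(table$timepoint)))
    x <- table$signal[sel & table$strain == cc$strain]
    y <- table$signal[sel & table$strain == reference]
    out <- data.frame(strain = cc$strain, condition = cc$condition,
                      timepoint = cc$timepoint, n = length(x),
                      n_ref = length(y), t = NA_real_, df = NA_real_,
                      p = NA_real_, degenerate = FALSE,
                      stringsAsFactors = FALSE)
    if (length(x) < 2L || length(y) < 2L) return(out)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      out$degenerate <- mean(x) != mean(y)
      out$p <- if (mean(x) == mean(y)) 1 else 0
      out$t <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y))
      out$df <- length(x) + length(y) - 2
      return(out)
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- tt$p.value
    out
  })
  res <- do.call(rbind, rows)
  res$stars <- star_code(res$p)
  rownames(res) <- NULL
  res
}

#' Full retest analysis
#'
#' Background correction, per-cell means, fold change versus the parent (or
#' time zero for time-courses), and per-cell t-tests with star annotation,
#' in one call.
#'
#' @inheritParams background_correct
#' @inheritParams ttest_vs_reference
#' @param timecourse normalize folds within strain to the earliest
#'   timepoint and take the background from time-zero rows.
#' @return data.frame joining fold-change and test columns per
#'   (strain, condition, timepoint).
#' @export
retest_analysis <- function(table, reference, blanks = NULL,
                            timecourse = FALSE, per_cell = FALSE,
                            var_equal = TRUE) {
  corr <- background_correct(table, blanks = blanks, use_t0 = timecourse,
                             per_cell = per_cell)
  folds <- fold_vs_reference(corr, reference, within_strain = timecourse)
  tests <- ttest_vs_reference(corr, reference, var_equal = var_equal)
  out <- merge(folds, tests[, c("strain", "condition", "timepoint", "t",
                                "df", "p", "stars", "degenerate")],
               by = c("strain", "condition", "timepoint"), all.x = TRUE)
  out <- out[order(out$strain, out$condition, out$timepoint), , drop = FALSE]
  rownames(out) <- NULL
  out
}
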