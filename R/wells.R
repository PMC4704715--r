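#' Parse microtiter well addresses
#'
#' Converts reader-style well labels ("A1", "a01", "H12") into row/column
#' indices on a rectangular plate. Case and zero padding are ignored, so
#' "A1" and "a01" name the same well.
#'
#' @param x character vector of well labels.
#' @param plate_rows,plate_cols plate geometry (default 8 x 12, a 96-well
#'   plate).
#' @return data.frame with columns `well` (canonical label, e.g. "A01"),
#'   `row` (integer), `col` (integer).
#' @export
parse_well <- function(x, plate_rows = 8L, plate_cols = 12L) {
  x0 <- toupper(trimws(as.character(x)))
  m <- regmatches(x0, regexec("^([A-Z])0*([0-9]+)$", x0))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("unparseable well address(es): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  row <- match(vapply(m, `[`, character(1), 2L), LETTERS)
  col <- as.integer(vapply(m, `[`, character(1), 3L))
  out <- row > plate_rows | col < 1L | col > plate_cols | is.na(row)
  if (any(out)) {
    stop("well address(es) outside ", plate_rows, "x", plate_cols,
         " plate: ", paste(unique(x[out]), collapse = ", "))
  }
  data.frame(well = well_label(row, col), row = row, col = col,
             stringsAsFactors = FALSE)
}

#' Canonical well label from row/column indices
#' @param row,col integer indices (1-based).
#' @return character vector like "A01", "H12".
#' @export
well_label <- function(row, col) {
  sprintf("%s%02d", LETTERS[row], as.integer(col))
}

#' All well labels of a plate in row-major order
#' @param plate_rows,plate_cols plate geometry.
#' @return character vector of length `plate_rows * plate_cols`.
#' @export
all_wells <- function(plate_rows = 8L, plate_cols = 12L) {
  g <- expand.grid(col = seq_len(plate_cols), row = seq_len(plate_rows))
  well_label(g$row, g$col)
}
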