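#' Default plate-reader export dialect
#'
#' Describes how to interpret a plate export: delimiter, column names for the
#' long (one row per well) format, or `format = "matrix"` for 8 x 12 grid
#' exports. A dialect can also be loaded from a YAML file with
#' [read_dialect()].
#'
#' @param delim field delimiter ("," or "\t").
#' @param format "long" (well, od660, lum columns) or "matrix" (row-letter
#'   first column, one column per plate column; one measurement per file).
#' @param well,od660,lum column names used in long format.
#' @return a list with class `plate_dialect`.
#' @export
plate_dialect <- function(delim = ",", format = c("long", "matrix"),
                          well = "well", od660 = "od660", lum = "lum") {
  format <- match.arg(format)
  structure(list(delim = delim, format = format, well = well,
                 od660 = od660, lum = lum),
            class = "plate_dialect")
}

#' Load a plate dialect from a YAML config
#' @param path YAML file with any of the keys of [plate_dialect()].
#' @return a `plate_dialect` list.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(plate_dialect, cfg[names(cfg) %in%
                               c("delim", "format", "well", "od660", "lum")])
}

#' Read one plate-reader export (long format)
#'
#' Reads a single plate's (well, OD660, luminescence) export. Well addresses
#' are normalized ("A1" and "A01" collapse); duplicate wells, unparseable
#' addresses and negative readings are hard errors that name the offending
#' row.
#'
#' @param path file path.
#' @param plate_id,replicate_id identifiers attached to every reading;
#'   default to the file name stem and "r1".
#' @param role "sample" or "blank".
#' @param dialect a [plate_dialect()].
#' @param plate_rows,plate_cols plate geometry.
#' @return data.frame (a PlateSet fragment) with columns plate_id,
#'   replicate_id, well, row, col, od660, lum, role.
#' @export
read_plate_csv <- function(path, plate_id = NULL, replicate_id = "r1",
                           role = c("sample", "blank"),
                           dialect = plate_dialect(),
                           plate_rows = 8L, plate_cols = 12L) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("no such plate file: ", path)
  if (is.null(plate_id)) plate_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, sep = dialect$delim, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c(dialect$well, dialect$od660, dialect$lum)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("plate file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  wells <- parse_well(raw[[dialect$well]], plate_rows, plate_cols)
  od <- as.numeric(raw[[dialect$od660]])
  lum <- as.numeric(raw[[dialect$lum]])
  bad <- which(!is.finite(od) | !is.finite(lum) | od < 0 | lum < 0)
  if (length(bad)) {
    stop("negative or unreadable measurement in ", path, " at data row(s) ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(wells$well)) {
    dup <- unique(wells$well[duplicated(wells$well)])
    stop("duplicate well(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  data.frame(plate_id = plate_id, replicate_id = replicate_id,
             well = wells$well, row = wells$row, col = wells$col,
             od660 = od, lum = lum, role = role,
             stringsAsFactors = FALSE)
}

#' Read a plate exported as two 8 x 12 matrices (OD and LUM files)
#'
#' Matrix exports carry one measurement per file: a row-letter first column
#' and one column per plate column.
#'
#' @param od_path,lum_path files holding the OD660 and luminescence grids.
#' @inheritParams read_plate_csv
#' @return PlateSet fragment as for [read_plate_csv()].
#' @export
read_plate_matrix <- function(od_path, lum_path, plate_id = NULL,
                              replicate_id = "r1",
                              role = c("sample", "blank"),
                              dialect = plate_dialect(format = "matrix"),
                              plate_rows = 8L, plate_cols = 12L) {
  role <- match.arg(role)
  if (is.null(plate_id)) plate_id <- sub("\\.[^.]*$", "", basename(od_path))
  read_grid <- function(path) {
    g <- utils::read.delim(path, sep = dialect$delim, row.names = 1,
                           check.names = FALSE)
    if (nrow(g) != plate_rows || ncol(g) != plate_cols) {
      stop("matrix export ", path, " is not ", plate_rows, "x", plate_cols)
    }
    m <- as.matrix(g)
    if (any(!is.finite(m)) || any(m < 0)) {
      stop("negative or unreadable measurement in ", path)
    }
    m
  }
  od <- read_grid(od_path)
  lum <- read_grid(lum_path)
  g <- expand.grid(row = seq_len(plate_rows), col = seq_len(plate_cols))
  data.frame(plate_id = plate_id, replicate_id = replicate_id,
             well = well_label(g$row, g$col), row = g$row, col = g$col,
             od660 = od[cbind(g$row, g$col)], lum = lum[cbind(g$row, g$col)],
             role = role, stringsAsFactors = FALSE)
}

#' Read a plate map
#'
#' A plate map assigns strains to (plate, well) positions, TSV with columns
#' plate_id, well, strain. Wells marked "EMPTY" (case-insensitive) are
#' dropped from the strain universe. A strain may occupy only one well of
#' one source plate.
#'
#' @param path TSV path.
#' @param empty_token sentinel marking unused wells.
#' @return data.frame with plate_id, well, row, col, strain.
#' @export
read_plate_map <- function(path, empty_token = "EMPTY") {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well", "strain")
  if (!all(need %in% names(raw))) {
    stop("plate map must have columns: ", paste(need, collapse = ", "))
  }
  raw <- raw[!toupper(raw$strain) %in% toupper(empty_token), , drop = FALSE]
  wells <- parse_well(raw$well)
  map <- data.frame(plate_id = as.character(raw$plate_id), well = wells$well,
                    row = wells$row, col = wells$col,
                    strain = as.character(raw$strain),
                    stringsAsFactors = FALSE)
  key <- paste(map$plate_id, map$well)
  if (anyDuplicated(key)) {
    stop("plate map assigns multiple strains to: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (anyDuplicated(map$strain)) {
    dup <- unique(map$strain[duplicated(map$strain)])
    stop("strain(s) mapped to more than one position: ",
         paste(dup, collapse = ", "))
  }
  map
}

#' Write / read the per-strain score table
#'
#' The screen's results table: one row per strain with per-replicate log2
#' RLU values, the mean over valid replicates, the number of valid
#' replicates, and a QC flag. Values round-trip at 6 decimal places.
#'
#' @param scores a StrainScoreTable from [average_replicates()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores_table <- function(scores, path) {
  out <- scores
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) round(v, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_scores_table
#' @export
read_scores_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read / write gene-set collections in GMT format
#'
#' GMT: one set per line, tab-separated as `term_id<TAB>description<TAB>`
#' followed by member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors; the `description` attribute
#'   carries the per-set description fields.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3L
  if (any(short)) stop("malformed GMT line(s): ", paste(which(short), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[`, character(1), 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description")
    if (is.null(descriptions)) descriptions <- rep("", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
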