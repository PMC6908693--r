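#' @title Validated CSV table readers and writers
#' @description Thin wrappers over [utils::read.csv()] that check the
#'   expected schema (column names and numeric types) and fail with the
#'   offending column or row, so malformed inputs stop the pipeline at
#'   the door rather than downstream.
#' @name cli_io
NULL

read_checked_csv <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) {
    stop("missing ", what, " file: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    stop("empty ", what, " file: ", path, call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty ", what, " table: ", path, call. = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop(what, " table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in numeric_cols) {
    v <- tab[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & v != "" & v != "NA")
      if (length(bad) > 0L) {
        stop(what, " column '", col, "' is not numeric at row ",
             bad[1], call. = FALSE)
      }
      tab[[col]] <- parsed
    }
  }
  tab
}

#' Read an abundance table (taxa x weeks, cells/L)
#'
#' Expects a CSV with a \code{taxon} column followed by one numeric column
#' per sample.
#'
#' @param path CSV path.
#' @return Taxa x samples numeric matrix with dimnames.
#' @export
read_abundance <- function(path) {
  tab <- read_checked_csv(path, required = "taxon",
                          numeric_cols = character(0), what = "abundance")
  sample_cols <- setdiff(names(tab), "taxon")
  if (length(sample_cols) < 2L) {
    stop("abundance table needs at least 2 sample columns", call. = FALSE)
  }
  mat <- as.matrix(tab[, sample_cols, drop = FALSE])
  if (!is.numeric(mat)) {
    stop("abundance sample columns must be numeric", call. = FALSE)
  }
  rownames(mat) <- tab$taxon
  check_abundance(mat)
  mat
}

#' Read an oxylipin peak table
#' @param path CSV path with columns sample, analyte, area, standard_area,
#'   volume.
#' @return Data frame.
#' @export
read_peaks <- function(path) {
  read_checked_csv(path,
                   required = c("sample", "analyte", "area",
                                "standard_area", "volume"),
                   numeric_cols = c("area", "standard_area", "volume"),
                   what = "peaks")
}

#' Read an environmental series
#' @param path CSV path with columns sample, week, salinity (other
#'   covariate columns are kept as-is).
#' @return Data frame.
#' @export
read_environment <- function(path) {
  read_checked_csv(path, required = c("sample", "week", "salinity"),
                   numeric_cols = c("week", "salinity"),
                   what = "environment")
}

#' Read a station table of transcript and metagenome abundances
#' @param path CSV path.
#' @return Data frame.
#' @export
read_tara <- function(path) {
  tab <- read_checked_csv(path,
                          required = c("station", "size_class",
                                       "lox_transcripts",
                                       "total_diatom_transcripts",
                                       "diatom_metagenome"),
                          numeric_cols = c("lox_transcripts",
                                           "total_diatom_transcripts",
                                           "diatom_metagenome"),
                          what = "tara")
  validate_tara(tab)
  tab
}
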