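#' Normalize LOX transcript abundance by total diatom transcripts
#'
#' Adds a \code{normalized_lox} column: lipoxygenase (LOX) transcript
#' abundance divided by the total transcript abundance of diatom-annotated
#' unigenes in the same sample. Rows with zero LOX abundance are retained
#' in the table but are excluded from downstream log-log regression; their
#' count is recorded.
#'
#' @param table Station table: data frame with columns \code{station},
#'   \code{size_class}, \code{lox_transcripts} (>= 0),
#'   \code{total_diatom_transcripts} (> 0) and \code{diatom_metagenome}
#'   (> 0), all in relative units.
#' @return The table with \code{normalized_lox} added and attribute
#'   \code{n_zero_lox}.
#' @export
normalize_lox <- function(table) {
  validate_tara(table)
  table$normalized_lox <- table$lox_transcripts /
    table$total_diatom_transcripts
  attr(table, "n_zero_lox") <- sum(table$lox_transcripts == 0)
  table
}

validate_tara <- function(table) {
  required <- c("station", "size_class", "lox_transcripts",
                "total_diatom_transcripts", "diatom_metagenome")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0L) {
    stop("station table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(table$lox_transcripts < 0, na.rm = TRUE)) {
    stop("LOX transcript abundances cannot be negative", call. = FALSE)
  }
  if (any(table$total_diatom_transcripts <= 0, na.rm = TRUE)) {
    stop("total diatom transcript abundances must be positive",
         call. = FALSE)
  }
  if (any(table$diatom_metagenome <= 0, na.rm = TRUE)) {
    stop("diatom metagenome abundances must be positive", call. = FALSE)
  }
  invisible(table)
}

#' Global regression of normalized LOX expression on diatom metagenomes
#'
#' Fits log10(normalized LOX) on log10(diatom metagenome abundance) by
#' ordinary least squares, pooled over all rows and separately per size
#' class. Stations appearing in several size classes contribute one row
#' per size class to the pooled fit; whether duplicates are present is
#' reported. A size class whose metagenome abundance is constant (or with
#' fewer than 3 usable rows) yields \code{NULL} with a message in
#' \code{class_errors}; the pooled fit proceeds regardless.
#'
#' @param table Station table (see [normalize_lox()], which is applied if
#'   the \code{normalized_lox} column is absent).
#' @return List with \code{pooled} (a \code{regression_result}),
#'   \code{per_class} (named list of results or \code{NULL}),
#'   \code{class_errors} (named character), \code{n_used},
#'   \code{n_excluded_zero} and \code{stations_repeated} (logical).
#' @export
fit_tara <- function(table) {
  if (!"normalized_lox" %in% names(table)) table <- normalize_lox(table)
  usable <- table$lox_transcripts > 0
  n_zero <- sum(!usable)
  sub <- table[usable, , drop = FALSE]
  if (nrow(sub) < 3L) {
    stop("need at least 3 rows with non-zero LOX abundance", call. = FALSE)
  }
  x <- log10(sub$diatom_metagenome)
  y <- log10(sub$normalized_lox)
  pooled <- fit_simple(x, y)

  per_class <- list()
  class_errors <- character(0)
  for (cl in unique(sub$size_class)) {
    sel <- sub$size_class == cl
    res <- try(fit_simple(x[sel], y[sel]), silent = TRUE)
    if (inherits(res, "try-error")) {
      per_class[cl] <- list(NULL)
      class_errors[cl] <- conditionMessage(attr(res, "condition"))
    } else {
      per_class[[cl]] <- res
    }
  }
  list(pooled = pooled, per_class = per_class,
       class_errors = class_errors, n_used = nrow(sub),
       n_excluded_zero = n_zero,
       stations_repeated = anyDuplicated(sub$station) > 0)
}
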