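#' Build a per-sample LOFA profile from a peak table
#'
#' Runs the full quantification chain: internal-standard quantification,
#' per-litre normalization, optional per-cell normalization against total
#' diatom density, and aggregation by fatty-acid precursor and oxidation
#' class.
#'
#' @param peaks Peak table (see [quantify()]).
#' @param panel Analyte panel.
#' @param diatom_density Optional named numeric vector of total diatom
#'   density (cells/L) with names matching the sample ids in \code{peaks}.
#' @return An object of class \code{lofa_profile}: a data frame with one row
#'   per sample and, for each analyte, columns \code{ng.<analyte>},
#'   \code{ngL.<analyte>}, \code{fgcell.<analyte>}, plus aggregate columns
#'   produced by [aggregate_classes()] and, when density is supplied, the
#'   total density and the [classify_production()] label of the total
#'   per-cell production.
#' @export
lofa_profile <- function(peaks, panel = default_panel(),
                         diatom_density = NULL) {
  q <- quantify(peaks, panel)
  q$ng_per_litre <- normalize_per_litre(q$ng, q$volume)

  samples <- unique(q$sample)
  wide <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (a in panel$analyte) {
    rows <- q[q$analyte == a, c("sample", "ng", "ng_per_litre")]
    idx <- match(wide$sample, rows$sample)
    wide[[paste0("ng.", a)]] <- ifelse(is.na(idx), 0, rows$ng[idx])
    wide[[paste0("ngL.", a)]] <- ifelse(is.na(idx), 0, rows$ng_per_litre[idx])
  }

  if (!is.null(diatom_density)) {
    dens <- diatom_density[match(wide$sample, names(diatom_density))]
    wide$diatom_density <- unname(dens)
    for (a in panel$analyte) {
      wide[[paste0("fgcell.", a)]] <-
        normalize_per_cell(wide[[paste0("ngL.", a)]], dens)
    }
  }

  wide <- aggregate_classes(wide, panel)
  if (!is.null(diatom_density)) {
    wide$production_class <- classify_production(wide$fgcell.total)
  }
  class(wide) <- c("lofa_profile", "data.frame")
  wide
}

#' Aggregate analyte columns by precursor and oxidation class
#'
#' Sums per-analyte columns into per-precursor (HTrA-, EPA-, DHA-derived),
#' per-oxidation-class (hydroxy acids, epoxy-alcohols) and grand-total
#' aggregates, for every unit prefix present (\code{ng}, \code{ngL},
#' \code{fgcell}). By construction the two oxidation-class aggregates and
#' the three precursor aggregates each sum to the total.
#'
#' @param profile Data frame with \code{<prefix>.<analyte>} columns.
#' @param panel Analyte panel.
#' @return \code{profile} with added \code{<prefix>.<class>} and
#'   \code{<prefix>.total} columns.
#' @export
aggregate_classes <- function(profile, panel = default_panel()) {
  validate_panel(panel)
  oxid_tag <- c("hydroxy-acid" = "hydroxy", "epoxy-alcohol" = "epoxy")
  for (prefix in c("ng", "ngL", "fgcell")) {
    cols <- paste0(prefix, ".", panel$analyte)
    if (!all(cols %in% names(profile))) next
    for (p in unique(panel$precursor)) {
      members <- paste0(prefix, ".", panel$analyte[panel$precursor == p])
      profile[[paste0(prefix, ".", p)]] <-
        rowSums(profile[, members, drop = FALSE])
    }
    for (o in unique(panel$oxidation)) {
      members <- paste0(prefix, ".", panel$analyte[panel$oxidation == o])
      profile[[paste0(prefix, ".", oxid_tag[[o]])]] <-
        rowSums(profile[, members, drop = FALSE])
    }
    profile[[paste0(prefix, ".total")]] <-
      rowSums(profile[, cols, drop = FALSE])
  }
  profile
}
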