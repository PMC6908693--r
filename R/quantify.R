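#' Quantify oxylipins against the internal standard
#'
#' Converts integrated chromatogram peak areas into absolute nanogram
#' amounts using the internal-standard rule ng = area_x * 1000 / area_S,
#' i.e. the analyte amount relative to 1 ug (1000 ng) of internal standard
#' (16-hydroxyhexadecanoic acid) spiked into every sample.
#'
#' @param peaks Peak table: a data frame with columns \code{sample},
#'   \code{analyte}, \code{area} (analyte peak area, >= 0),
#'   \code{standard_area} (internal-standard peak area, > 0, one value per
#'   sample) and \code{volume} (filtered volume in litres, > 0).
#' @param panel Analyte panel, see [default_panel()]. Every analyte code in
#'   \code{peaks} must appear in the panel.
#' @return The peak table with an added \code{ng} column.
#' @examples
#' pk <- data.frame(sample = "w1", analyte = "HEPE",
#'                  area = 250, standard_area = 1000, volume = 1)
#' quantify(pk)$ng  # 250
#' @export
quantify <- function(peaks, panel = default_panel()) {
  validate_panel(panel)
  validate_peaks(peaks, panel)
  peaks$ng <- peaks$area * 1000 / peaks$standard_area
  peaks
}

validate_peaks <- function(peaks, panel) {
  required <- c("sample", "analyte", "area", "standard_area", "volume")
  missing <- setdiff(required, names(peaks))
  if (length(missing) > 0L) {
    stop("peak table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(peaks$analyte), panel$analyte)
  if (length(unknown) > 0L) {
    stop("peak table contains analytes not in the panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(peaks$area < 0, na.rm = TRUE)) {
    stop("negative peak areas are not allowed", call. = FALSE)
  }
  if (any(peaks$standard_area <= 0, na.rm = TRUE)) {
    stop("internal-standard areas must be positive", call. = FALSE)
  }
  # one standard area per sample
  spl <- split(peaks$standard_area, peaks$sample)
  multi <- names(spl)[vapply(spl, function(v) length(unique(v)) > 1L,
                             logical(1))]
  if (length(multi) > 0L) {
    stop("multiple internal-standard areas for sample(s): ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  invisible(peaks)
}

#' Normalize absolute amounts by filtered volume
#'
#' @param ng Absolute amount in nanograms (>= 0).
#' @param volume Filtered seawater volume in litres (> 0; field protocols
#'   filter 0.5-2 L).
#' @return Concentration in ng/L.
#' @examples
#' normalize_per_litre(1000, 2)  # 500 ng/L
#' @export
normalize_per_litre <- function(ng, volume) {
  if (any(volume <= 0, na.rm = TRUE)) {
    stop("filtered volume must be positive", call. = FALSE)
  }
  ng / volume
}

#' Express per-litre concentration as per-cell production
#'
#' fg per diatom cell = (ng/L * 1e6) / (cells/L); 1 ng = 1e6 fg. Weeks with
#' zero or missing diatom density yield \code{NA} (the ratio is undefined),
#' which propagates as missing through downstream statistics.
#'
#' @param ng_per_litre Concentration in ng/L.
#' @param density Total diatom density in cells/L (>= 0).
#' @return Production in fg per diatom cell, \code{NA} where density is zero
#'   or missing.
#' @examples
#' normalize_per_cell(100, 1e6)  # 100 fg/cell
#' @export
normalize_per_cell <- function(ng_per_litre, density) {
  if (any(density < 0, na.rm = TRUE)) {
    stop("diatom density cannot be negative", call. = FALSE)
  }
  out <- ng_per_litre * 1e6 / density
  out[is.na(density) | density == 0] <- NA_real_
  out
}

#' Convert biovolume and density to carbon biomass
#'
#' Per-cell carbon follows the standard diatom power law pg C =
#' c1 * V^c2 with V the cell biovolume in um^3; the default coefficients
#' (0.288, 0.811) are the widely used diatom values from the
#' biovolume-to-carbon literature and are exposed as arguments.
#'
#' @param biovolume Cell biovolume in cubic micrometres (> 0).
#' @param density Cell density in cells/L (>= 0).
#' @param c1,c2 Power-law coefficients.
#' @return Carbon biomass in ng-C/L.
#' @examples
#' biomass_carbon(1, 1000)  # 0.288 pg/cell * 1000 cells / 1000 = 0.288 ng-C/L
#' @export
biomass_carbon <- function(biovolume, density, c1 = 0.288, c2 = 0.811) {
  if (any(biovolume <= 0, na.rm = TRUE)) {
    stop("biovolume must be positive", call. = FALSE)
  }
  if (any(density < 0, na.rm = TRUE)) {
    stop("density cannot be negative", call. = FALSE)
  }
  pg_per_cell <- c1 * biovolume^c2
  pg_per_cell * density / 1000
}

#' Classify per-cell oxylipin production into low/medium/high ranges
#'
#' The ranges 0-100, 100-300 and >300 fg per diatom cell partition samples
#' into "low", "medium" and "high" producers. Boundaries are assigned
#' upward (100 is medium, 300 is high) so that ">300" stays literal.
#'
#' @param fg_per_cell Per-cell production in fg/cell (>= 0 or \code{NA}).
#' @return Factor with levels \code{low < medium < high}; \code{NA} where
#'   the input is missing.
#' @examples
#' classify_production(c(50, 100, 299.9, 300, NA))
#' @export
classify_production <- function(fg_per_cell) {
  if (any(fg_per_cell < 0, na.rm = TRUE)) {
    stop("fg/cell values cannot be negative", call. = FALSE)
  }
  cut(fg_per_cell, breaks = c(-Inf, 100, 300, Inf),
      labels = c("low", "medium", "high"),
      right = FALSE, ordered_result = TRUE)
}
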