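#' Default targeted LOFA analyte panel
#'
#' The six linear oxygenated fatty acids (LOFAs) routinely targeted in
#' particulate oxylipin surveys of diatom communities: one hydroxy acid and
#' one epoxy-alcohol for each of the three main fatty-acid precursors,
#' hexadecatrienoic acid (HTrA, C16:3), eicosapentaenoic acid (EPA, C20:5)
#' and docosahexaenoic acid (DHA, C22:6).
#'
#' @return A data frame with one row per analyte and columns
#'   \code{analyte} (short code), \code{precursor} (one of
#'   \code{"HTrA"}, \code{"EPA"}, \code{"DHA"}), \code{oxidation}
#'   (\code{"hydroxy-acid"} or \code{"epoxy-alcohol"}) and \code{name}
#'   (display name).
#' @examples
#' default_panel()
#' @export
default_panel <- function() {
  panel <- data.frame(
    analyte   = c("HHTrE", "EHHDE", "HEPE", "EHETE", "HDoHE", "EHDPE"),
    precursor = c("HTrA", "HTrA", "EPA", "EPA", "DHA", "DHA"),
    oxidation = c("hydroxy-acid", "epoxy-alcohol",
                  "hydroxy-acid", "epoxy-alcohol",
                  "hydroxy-acid", "epoxy-alcohol"),
    name = c("hydroxy-hexadecatrienoic acid",
             "epoxy-hydroxy-hexadecadienoic acid",
             "hydroxy-eicosapentaenoic acid",
             "epoxy-hydroxy-eicosatetraenoic acid",
             "hydroxy-docosahexaenoic acid",
             "epoxy-hydroxy-docosapentaenoic acid"),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("analyte_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  required <- c("analyte", "precursor", "oxidation")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0L) {
    stop("panel is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(panel$analyte)) {
    stop("panel analyte codes must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(panel$oxidation), c("hydroxy-acid", "epoxy-alcohol"))
  if (length(bad) > 0L) {
    stop("unknown oxidation class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(panel)
}
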