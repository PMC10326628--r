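#' Amino-acid peak assignment catalog
#'
#' Characteristic Raman bands used for internal-standard relative
#' quantification of seven amino acids in spent embryo culture medium, plus
#' the phenylalanine ring-breathing band at 1003 cm-1 that serves as the
#' internal standard (the most intense signal in the fingerprint region).
#' All positions lie in the 600-1800 cm-1 biological fingerprint band.
#'
#' @param window_halfwidth Half-width, in cm-1, of the window around each
#'   nominal position inside which the peak intensity is read (default 5,
#'   wide enough to absorb the position doublets reported for several bands).
#'
#' @return A data frame with one row per band and columns `analyte`,
#'   `position` (cm-1), `vibration_mode`, `window_halfwidth` and
#'   `is_standard` (`TRUE` only for phenylalanine).
#' @export
#' @examples
#' peak_catalog()
peak_catalog <- function(window_halfwidth = 5) {
  stopifnot(is.numeric(window_halfwidth), window_halfwidth > 0)
  cat <- data.frame(
    analyte = c("aspartic_acid", "glycine", "tryptophan", "tyrosine",
                "taurine", "serine", "proline", "phenylalanine"),
    position = c(941, 900, 758, 853, 1032, 1326, 828, 1003),
    vibration_mode = c(
      "C-H bending",
      "COOH scissoring / C-C stretching",
      "aromatic C-H bending",
      "C-C stretch / C-C-C bending",
      "S=O stretching",
      "C-N stretching",
      "C-C-C bending",
      "ring breathing (internal standard)"),
    window_halfwidth = window_halfwidth,
    is_standard = FALSE,
    stringsAsFactors = FALSE
  )
  cat$is_standard[cat$analyte == "phenylalanine"] <- TRUE
  bad <- cat$position < 600 | cat$position > 1800
  if (any(bad)) {
    stop("catalog positions outside the fingerprint band [600, 1800]: ",
         paste(cat$analyte[bad], collapse = ", "))
  }
  cat
}

## Outcome labels used throughout; first level is the ROC positive class.
outcome_levels <- function() c("pregnancy", "non_pregnancy")

#' @keywords internal
check_label <- function(label) {
  label <- as.character(label)
  bad <- !is.na(label) & !(label %in% outcome_levels())
  if (any(bad)) {
    stop("unknown outcome label(s): ", paste(unique(label[bad]), collapse = ", "),
         "; expected one of ", paste(outcome_levels(), collapse = ", "))
  }
  label
}
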