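#' Construct a Raman spectrum
#'
#' The atomic object every pipeline stage transforms: a strictly increasing
#' Raman-shift axis (cm-1) with one intensity per channel, plus acquisition
#' metadata (sample, replicate, platform, optional outcome label).
#'
#' @param shifts Numeric vector of Raman shifts in cm-1, strictly increasing.
#' @param intensities Numeric vector of intensities, same length as `shifts`.
#' @param spectrum_id Character id, unique within a cohort.
#' @param sample_id Character id of the biological sample (several replicate
#'   spectra share one sample).
#' @param replicate Integer replicate index within the sample.
#' @param platform Acquisition platform tag, `"p532"` or `"p785"`.
#' @param label Optional outcome label, `"pregnancy"` or `"non_pregnancy"`.
#'
#' @return An object of class `raman_spectrum`.
#' @export
#' @examples
#' s <- raman_spectrum(600:700, rnorm(101, 100, 1), "demo_r1")
#' s
raman_spectrum <- function(shifts, intensities, spectrum_id,
                           sample_id = NA_character_, replicate = NA_integer_,
                           platform = NA_character_, label = NA_character_) {
  shifts <- as.numeric(shifts)
  intensities <- as.numeric(intensities)
  if (length(shifts) != length(intensities)) {
    stop("shifts and intensities differ in length (", length(shifts), " vs ",
         length(intensities), ")")
  }
  if (length(shifts) < 16) {
    stop("a spectrum needs at least 16 channels, got ", length(shifts))
  }
  if (anyNA(shifts) || anyNA(intensities)) stop("NA/NaN values in spectrum")
  if (any(diff(shifts) <= 0)) stop("shifts must be strictly increasing")
  structure(
    list(shifts = shifts, intensities = intensities,
         spectrum_id = as.character(spectrum_id),
         sample_id = as.character(sample_id),
         replicate = as.integer(replicate),
         platform = as.character(platform),
         label = check_label(label)),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum %s> %d channels, %.1f-%.1f cm-1",
              x$spectrum_id, length(x$shifts), min(x$shifts), max(x$shifts)))
  if (!is.na(x$sample_id)) cat(sprintf(", sample %s", x$sample_id))
  if (!is.na(x$label)) cat(sprintf(" [%s]", x$label))
  cat("\n")
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ..., type = "l",
                                xlab = expression(paste("Raman shift (", cm^-1, ")")),
                                ylab = "Intensity") {
  graphics::plot(x$shifts, x$intensities, type = type,
                 xlab = xlab, ylab = ylab, main = x$spectrum_id, ...)
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$shifts)

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(shift_cm1 = x$shifts, intensity = x$intensities)
}

## Replace intensities, keeping metadata; used by every preprocessing stage.
#' @keywords internal
set_intensities <- function(s, intensities, shifts = s$shifts) {
  s$shifts <- shifts
  s$intensities <- intensities
  s
}

#' Stack a batch of spectra into a channels matrix
#'
#' @param batch List of `raman_spectrum` objects sharing one axis.
#' @return Numeric matrix, one row per spectrum (rownames = spectrum ids),
#'   one column per channel.
#' @export
spectra_matrix <- function(batch) {
  stopifnot(length(batch) >= 1)
  ax <- batch[[1]]$shifts
  for (s in batch) {
    if (length(s$shifts) != length(ax) || any(s$shifts != ax)) {
      stop("spectra do not share a common axis (offender: ", s$spectrum_id, ")")
    }
  }
  m <- do.call(rbind, lapply(batch, function(s) s$intensities))
  rownames(m) <- vapply(batch, function(s) s$spectrum_id, character(1))
  m
}
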