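#' Preprocessing configuration
#'
#' Parameters of the five-stage preprocessing chain applied to every raw
#' spectrum: cosmic-ray despiking, fingerprint band clipping, Savitzky-Golay
#' smoothing, SNIP baseline subtraction and min-max normalization, plus the
#' PCA-Mahalanobis outlier screen applied batch-wise afterwards.
#'
#' @param band_low,band_high Retained fingerprint band in cm-1 (defaults
#'   600 and 1800).
#' @param sg_window Savitzky-Golay window length in channels, odd
#'   (default 11).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @param snip_iterations SNIP clipping half-window start; the window
#'   decreases from this value to 1 (default 60 channels).
#' @param spike_mad_k Modified z-score threshold for spike flagging
#'   (default 8).
#' @param spike_max_width Maximum run length, in channels, still treated as
#'   a cosmic-ray spike (default 4); broader excursions are kept as genuine
#'   bands.
#' @param outlier_pc_count Number of leading principal components used for
#'   the Mahalanobis outlier screen (default 3).
#' @param outlier_mahal_quantile Chi-square quantile beyond which a spectrum
#'   is rejected (default 0.999).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low = 600, band_high = 1800,
                              sg_window = 11, sg_order = 3,
                              snip_iterations = 60,
                              spike_mad_k = 8, spike_max_width = 4,
                              outlier_pc_count = 3,
                              outlier_mahal_quantile = 0.999) {
  if (!(band_low < band_high)) stop("band_low must be < band_high")
  if (sg_window %% 2 != 1) stop("sg_window must be odd")
  if (!(sg_window > sg_order)) stop("sg_window must exceed sg_order")
  if (snip_iterations < 1) stop("snip_iterations must be >= 1")
  if (!(outlier_mahal_quantile > 0 && outlier_mahal_quantile < 1))
    stop("outlier_mahal_quantile must lie in (0, 1)")
  structure(list(band_low = band_low, band_high = band_high,
                 sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 snip_iterations = as.integer(snip_iterations),
                 spike_mad_k = spike_mad_k,
                 spike_max_width = as.integer(spike_max_width),
                 outlier_pc_count = as.integer(outlier_pc_count),
                 outlier_mahal_quantile = outlier_mahal_quantile),
            class = "preprocess_config")
}

#' Remove cosmic-ray spikes
#'
#' Flags channels whose residual against a rolling median has a modified
#' z-score above `spike_mad_k` and that belong to a run of at most
#' `spike_max_width` channels. A candidate run is confirmed as a spike only
#' when it also towers over the linear interpolation of its flanking
#' channels (cosmic spikes are several-fold excursions above the local
#' signal, while the sharp top of a genuine band barely exceeds its own
#' slope). Confirmed runs are replaced by the flank interpolation; all other
#' channels are returned bit-identical, so a spike-free spectrum passes
#' through unchanged.
#'
#' @param s A [raman_spectrum()].
#' @param cfg A [preprocess_config()].
#' @return The despiked spectrum, with an attribute `spike_channels` listing
#'   the replaced channel indices.
#' @export
remove_cosmic_spikes <- function(s, cfg = preprocess_config()) {
  y <- s$intensities
  n <- length(y)
  k <- min(2L * cfg$spike_max_width + 3L, if (n %% 2 == 0) n - 1L else n)
  if (k %% 2 == 0) k <- k - 1L
  med <- stats::runmed(y, k, endrule = "median")
  resid <- y - med
  scale <- stats::mad(resid)
  if (scale <= 0) scale <- stats::sd(resid)
  if (is.na(scale) || scale <= 0) {
    out <- s
    attr(out, "spike_channels") <- integer(0)
    return(out)
  }
  flagged <- abs(resid) / scale > cfg$spike_mad_k
  if (!any(flagged)) {
    out <- s
    attr(out, "spike_channels") <- integer(0)
    return(out)
  }
  # candidate runs short enough to be spikes; a run is confirmed only if it
  # towers over the linear interpolation of its flanks, which separates
  # cosmic spikes (5-20x the local signal) from the sharp tops of genuine
  # bands whose flanks sit on the band slope
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  spike_idx <- integer(0)
  for (j in seq_along(r$values)) {
    if (!r$values[j] || r$lengths[j] > cfg$spike_max_width) next
    run <- starts[j]:ends[j]
    good <- setdiff(seq_len(n), run)
    interp <- stats::approx(s$shifts[good], y[good],
                            xout = s$shifts[run], rule = 2)$y
    delta <- max(y[run] - interp)
    if (delta > cfg$spike_mad_k * scale &&
        delta > 0.5 * max(abs(interp), scale)) {
      spike_idx <- c(spike_idx, run)
    }
  }
  if (length(spike_idx)) {
    good <- setdiff(seq_len(n), spike_idx)
    y[spike_idx] <- stats::approx(s$shifts[good], y[good],
                                  xout = s$shifts[spike_idx], rule = 2)$y
  }
  out <- set_intensities(s, y)
  attr(out, "spike_channels") <- spike_idx
  out
}

#' Clip a spectrum to the fingerprint band
#'
#' Retains exactly the channels with `band_low <= shift <= band_high`
#' (defaults 600-1800 cm-1, the biological fingerprint region), preserving
#' order.
#'
#' @inheritParams remove_cosmic_spikes
#' @return The clipped spectrum.
#' @export
clip_band <- function(s, cfg = preprocess_config()) {
  keep <- s$shifts >= cfg$band_low & s$shifts <= cfg$band_high
  if (!any(keep)) {
    stop("band error: [", cfg$band_low, ", ", cfg$band_high,
         "] does not intersect the axis of ", s$spectrum_id)
  }
  set_intensities(s, s$intensities[keep], s$shifts[keep])
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing (window `sg_window`, order
#' `sg_order`); edges are handled by the polynomial fit on the truncated
#' window, so polynomials up to the fit order pass through exactly.
#'
#' @inheritParams remove_cosmic_spikes
#' @return The smoothed spectrum.
#' @export
smooth_sg <- function(s, cfg = preprocess_config()) {
  if (length(s$shifts) < cfg$sg_window) {
    stop("parameter error: spectrum ", s$spectrum_id, " has ",
         length(s$shifts), " channels, shorter than sg_window = ",
         cfg$sg_window)
  }
  y <- as.numeric(signal::sgolayfilt(s$intensities, p = cfg$sg_order,
                                     n = cfg$sg_window))
  set_intensities(s, y)
}

#' SNIP baseline estimation and subtraction
#'
#' Statistics-sensitive non-linear iterative peak clipping: intensities are
#' taken through the log-log-square-root (LLS) compression, clipped against
#' the symmetric two-point average with a half-window decreasing from
#' `snip_iterations` down to 1 (the decreasing window reduces peak erosion),
#' and transformed back. The estimated baseline never exceeds the signal
#' (up to numerical tolerance), and `corrected + baseline` reconstructs the
#' input exactly.
#'
#' @inheritParams remove_cosmic_spikes
#' @return List with elements `baseline` and `corrected`, both
#'   [raman_spectrum()] objects on the input axis.
#' @export
snip_baseline <- function(s, cfg = preprocess_config()) {
  y <- s$intensities
  n <- length(y)
  off <- min(y)
  v <- log(log(sqrt(y - off + 1) + 1) + 1)
  m_max <- min(cfg$snip_iterations, (n - 1L) %/% 2L)
  for (m in seq(m_max, 1L)) {
    i <- (m + 1L):(n - m)
    v[i] <- pmin(v[i], (v[i - m] + v[i + m]) / 2)
  }
  b <- (exp(exp(v) - 1) - 1)^2 - 1 + off
  list(baseline = set_intensities(s, b),
       corrected = set_intensities(s, y - b))
}

#' Min-max normalization to \[0, 1\]
#'
#' @param s A [raman_spectrum()].
#' @return The spectrum rescaled as `(x - min) / (max - min)`, attaining both
#'   0 and 1.
#' @export
normalize_minmax <- function(s) {
  rng <- range(s$intensities)
  if (rng[2] <= rng[1]) {
    stop("degenerate input: spectrum ", s$spectrum_id,
         " is constant; min-max normalization undefined")
  }
  set_intensities(s, (s$intensities - rng[1]) / (rng[2] - rng[1]))
}

#' Full preprocessing chain for one spectrum
#'
#' Composition despike -> clip -> smooth -> SNIP baseline subtraction ->
#' min-max normalization. Optionally keeps every intermediate stage for QC.
#'
#' @inheritParams remove_cosmic_spikes
#' @param keep_stages If `TRUE`, attach a `stages` attribute with the
#'   intermediate spectra (`despiked`, `clipped`, `smoothed`, `baseline`,
#'   `corrected`).
#' @return The preprocessed spectrum (band-clipped, baseline-corrected,
#'   normalized to \[0, 1\]).
#' @export
preprocess_pipeline <- function(s, cfg = preprocess_config(),
                                keep_stages = FALSE) {
  d <- remove_cosmic_spikes(s, cfg)
  cl <- clip_band(d, cfg)
  sm <- smooth_sg(cl, cfg)
  sn <- snip_baseline(sm, cfg)
  out <- normalize_minmax(sn$corrected)
  if (keep_stages) {
    attr(out, "stages") <- list(despiked = d, clipped = cl, smoothed = sm,
                                baseline = sn$baseline,
                                corrected = sn$corrected)
  }
  out
}

#' Preprocess a batch of spectra
#'
#' @param batch List of [raman_spectrum()].
#' @inheritParams preprocess_pipeline
#' @return List of preprocessed spectra, order preserved.
#' @export
preprocess_batch <- function(batch, cfg = preprocess_config()) {
  lapply(batch, preprocess_pipeline, cfg = cfg)
}

#' PCA-Mahalanobis outlier screening
#'
#' Projects the preprocessed batch on its first `outlier_pc_count` principal
#' components and rejects spectra whose squared Mahalanobis distance in
#' score space exceeds the `outlier_mahal_quantile` chi-square quantile.
#' Degenerate (zero-variance) components are ignored; a batch of identical
#' spectra rejects nothing. A sample loses all representation only if every
#' one of its replicates is rejected.
#'
#' @param batch List of preprocessed spectra on a common axis (>= 10).
#' @param cfg A [preprocess_config()].
#' @return List with `kept` and `rejected` (lists of spectra), and `report`,
#'   a data frame of spectrum id, squared distance, threshold and decision.
#' @export
detect_outlier_spectra <- function(batch, cfg = preprocess_config()) {
  if (length(batch) < 10) stop("outlier screening needs at least 10 spectra")
  x <- spectra_matrix(batch)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(cfg$outlier_pc_count, ncol(pc$x))
  vars <- pc$sdev[seq_len(k)]^2
  usable <- vars > 1e-12
  if (!any(usable)) {
    report <- data.frame(spectrum_id = rownames(x), distance2 = 0,
                         threshold = Inf, rejected = FALSE,
                         stringsAsFactors = FALSE)
    return(list(kept = batch, rejected = list(), report = report))
  }
  scores <- pc$x[, seq_len(k), drop = FALSE][, usable, drop = FALSE]
  d2 <- rowSums(sweep(scores^2, 2, vars[usable], "/"))
  thr <- stats::qchisq(cfg$outlier_mahal_quantile, df = sum(usable))
  rej <- d2 > thr
  report <- data.frame(spectrum_id = rownames(x), distance2 = d2,
                       threshold = thr, rejected = rej,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(kept = batch[!rej], rejected = batch[rej], report = report)
}
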