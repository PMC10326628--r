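## Small generator configurations shared across tests.

## Noise-free cohort on a zero flat baseline: each spectrum is exactly the
## analytic sum of its Gaussian bands (ground truth holds the effective
## per-spectrum amplitudes).
noiseless_config <- function(n_samples = 6, replicates = 2, seed = 7, ...) {
  generator_config(n_samples = n_samples, replicates_per_sample = replicates,
                   noise_sd = 0, spike_rate = 0,
                   baseline_params = list(family = "flat", magnitude = 0),
                   seed = seed, ...)
}

small_config <- function(n_samples = 12, replicates = 2, seed = 3, ...) {
  generator_config(n_samples = n_samples, replicates_per_sample = replicates,
                   seed = seed, ...)
}

## Direct evaluation of the generator's band formula (independent of the
## package's internal helpers).
band_sum <- function(axis, amplitudes, positions, fwhm = 12) {
  out <- numeric(length(axis))
  for (i in seq_along(amplitudes)) {
    out <- out + amplitudes[i] *
      exp(-4 * log(2) * ((axis - positions[i]) / fwhm)^2)
  }
  out
}

## Balanced multi-replicate manifest without spectra on disk.
toy_manifest <- function(n_samples = 10, replicates = 5) {
  ids <- sprintf("T%03d", seq_len(n_samples))
  lab <- rep(c("pregnancy", "non_pregnancy"), length.out = n_samples)
  data.frame(
    spectrum_file = paste0(rep(ids, each = replicates), "_r",
                           rep(seq_len(replicates), n_samples), ".csv"),
    spectrum_id = paste0(rep(ids, each = replicates), "_r",
                         rep(seq_len(replicates), n_samples)),
    sample_id = rep(ids, each = replicates),
    replicate = rep(seq_len(replicates), n_samples),
    platform = "p532",
    label = rep(lab, each = replicates),
    stringsAsFactors = FALSE)
}

## Two well-separated Gaussian clusters of feature vectors, grouped in
## 1-spectrum samples; linearly separable by construction. "subset" shifts
## only the first five features; "all" additionally shifts the whole vector,
## which gives tree learners strong marginal splits and convolutional
## learners a signal that survives pooling.
separable_scores <- function(n_samples = 80, p = 30, shift = 3, seed = 1,
                             mode = c("subset", "all")) {
  mode <- match.arg(mode)
  set.seed(seed)
  lab <- rep(c("pregnancy", "non_pregnancy"), each = n_samples / 2)
  x <- matrix(stats::rnorm(n_samples * p), n_samples, p)
  pregnant <- lab == "pregnancy"
  x[pregnant, 1:5] <- x[pregnant, 1:5] + shift
  if (mode == "all") x[pregnant, ] <- x[pregnant, ] + 2
  list(x = x, labels = lab, groups = sprintf("G%03d", seq_len(n_samples)))
}

## Swap intensities without going through the exported constructors.
set_intensities_for_test <- function(s, y) {
  s$intensities <- y
  s
}
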