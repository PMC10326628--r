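#' Configuration for the synthetic cohort generator
#'
#' Describes a simulated acquisition campaign: cohort size, replicate
#' structure, shift axis, platform preset, class balance, planted group
#' effects on amino-acid band amplitudes, fluorescence background, noise and
#' cosmic-ray spike rate. Defaults emulate the study design: 107 samples
#' acquired five times each over 50-2000 cm-1, a near-1:1 outcome split
#' (54 non-pregnancy / 53 pregnancy), and tyrosine, tryptophan and serine
#' bands elevated in the non-pregnancy group.
#'
#' The `p785` platform preset mimics the liquid-sample desktop instrument:
#' halved band amplitudes and planted effects and doubled noise, i.e. lower
#' peak signal-to-noise, against the crystalline-sample `p532` preset.
#'
#' @param n_samples Number of biological samples.
#' @param replicates_per_sample Spectra acquired per sample (default 5).
#' @param axis_start,axis_end,axis_step Shift axis in cm-1 (defaults 50,
#'   2000, 1).
#' @param platform `"p532"` (default) or `"p785"`.
#' @param class_balance Fraction of non-pregnancy samples (default 54/107).
#' @param effect_sizes Named numeric vector of standardized mean differences
#'   (non-pregnancy minus pregnancy, in units of the between-sample SD) of
#'   amino-acid band amplitudes. Default plants +1 on tyrosine, tryptophan
#'   and serine (`p532`; halved under the `p785` preset).
#' @param baseline_params List with `family` (`"poly4_exp"`: random 4th-order
#'   polynomial plus a broad exponential fluorescence hump; or `"flat"`) and
#'   `magnitude` (intensity units; default 800, so the background dominates
#'   the raw signal).
#' @param noise_sd Gaussian noise SD in intensity units (default 3 for p532).
#' @param spike_rate Expected number of cosmic-ray spikes per spectrum
#'   (default 0.2).
#' @param band_fwhm Full width at half maximum of the Gaussian bands, cm-1
#'   (default 12, a typical solution-phase Raman linewidth).
#' @param amplitude_scale Overall multiplier on band amplitudes (platform
#'   preset; 1 for p532, 0.5 for p785).
#' @param seed Integer RNG seed; identical configurations reproduce
#'   bit-identical cohorts.
#'
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_samples = 107, replicates_per_sample = 5,
                             axis_start = 50, axis_end = 2000, axis_step = 1,
                             platform = c("p532", "p785"),
                             class_balance = 54 / 107,
                             effect_sizes = NULL,
                             baseline_params = list(family = "poly4_exp",
                                                    magnitude = 800),
                             noise_sd = NULL, spike_rate = 0.2,
                             band_fwhm = 12, amplitude_scale = NULL,
                             seed = 1) {
  platform <- match.arg(platform)
  if (is.null(noise_sd)) noise_sd <- if (platform == "p785") 6 else 3
  if (is.null(amplitude_scale)) amplitude_scale <- if (platform == "p785") 0.5 else 1
  if (is.null(effect_sizes)) {
    d <- if (platform == "p785") 0.5 else 1
    effect_sizes <- c(tyrosine = d, tryptophan = d, serine = d)
  }
  cfg <- structure(
    list(n_samples = n_samples, replicates_per_sample = replicates_per_sample,
         axis_start = axis_start, axis_end = axis_end, axis_step = axis_step,
         platform = platform, class_balance = class_balance,
         effect_sizes = effect_sizes, baseline_params = baseline_params,
         noise_sd = noise_sd, spike_rate = spike_rate, band_fwhm = band_fwhm,
         amplitude_scale = amplitude_scale, seed = as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @keywords internal
validate_generator_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid generator configuration: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_samples) || cfg$n_samples < 1) bad("n_samples", "must be >= 1")
  if (!is.numeric(cfg$replicates_per_sample) || cfg$replicates_per_sample < 1)
    bad("replicates_per_sample", "must be >= 1")
  if (!(cfg$axis_start < cfg$axis_end)) bad("axis_start", "must be < axis_end")
  if (!(cfg$axis_step > 0)) bad("axis_step", "must be > 0")
  if (!(cfg$class_balance > 0 && cfg$class_balance < 1))
    bad("class_balance", "must lie strictly between 0 and 1")
  if (!(cfg$noise_sd >= 0)) bad("noise_sd", "must be >= 0")
  if (!(cfg$spike_rate >= 0)) bad("spike_rate", "must be >= 0")
  if (!(cfg$band_fwhm > 0)) bad("band_fwhm", "must be > 0")
  es <- cfg$effect_sizes
  if (length(es) && (is.null(names(es)) || any(!nzchar(names(es)))))
    bad("effect_sizes", "must be a named numeric vector (analyte -> effect)")
  unknown <- setdiff(names(es), peak_catalog()$analyte)
  if (length(unknown))
    bad("effect_sizes", paste0("names unknown analytes: ",
                               paste(unknown, collapse = ", ")))
  if (!is.list(cfg$baseline_params) ||
      !cfg$baseline_params$family %in% c("poly4_exp", "flat"))
    bad("baseline_params", "family must be 'poly4_exp' or 'flat'")
  if (!is.numeric(cfg$baseline_params$magnitude) || cfg$baseline_params$magnitude < 0)
    bad("baseline_params", "magnitude must be >= 0")
  invisible(cfg)
}

## Band model: group-sensitive amino-acid bands from the assignment catalog
## plus constant matrix bands that give the spectrum a realistic fingerprint.
## mean = typical peak height (intensity units, p532 scale), sd = between-
## sample SD on which standardized effects act.
generator_bands <- function(cfg) {
  cat <- peak_catalog()
  amino <- data.frame(
    band = cat$analyte, position = cat$position,
    mean = c(45, 50, 40, 55, 40, 45, 35, 120),
    sd   = c(8, 8, 8, 8, 8, 8, 8, 10),
    group_sensitive = !cat$is_standard,
    stringsAsFactors = FALSE)
  matrix_bands <- data.frame(
    band = c("bg_621", "bg_1071", "bg_1127", "bg_1243", "bg_1447",
             "bg_1556", "bg_1657"),
    position = c(621, 1071, 1127, 1243, 1447, 1556, 1657),
    mean = c(15, 60, 25, 35, 55, 20, 50),
    sd = c(2, 4, 2, 3, 4, 2, 4),
    group_sensitive = FALSE,
    stringsAsFactors = FALSE)
  bands <- rbind(amino, matrix_bands)
  bands$mean <- bands$mean * cfg$amplitude_scale
  bands$sd <- bands$sd * cfg$amplitude_scale
  bands$effect <- 0
  idx <- match(names(cfg$effect_sizes), bands$band)
  bands$effect[idx[!is.na(idx)]] <- cfg$effect_sizes[!is.na(idx)]
  # the internal standard never carries a group effect
  bands$effect[bands$band == "phenylalanine"] <- 0
  bands
}

## Gaussian band profile with unit peak height.
gauss_band <- function(x, position, fwhm) {
  exp(-4 * log(2) * ((x - position) / fwhm)^2)
}

draw_baseline <- function(axis, params, magnitude) {
  if (params$family == "flat") return(rep(magnitude, length(axis)))
  u <- (axis - mean(range(axis))) / diff(range(axis))  # in [-0.5, 0.5]
  a <- c(stats::runif(1, 0.8, 1.2), stats::runif(4, -0.3, 0.3))
  poly <- a[1] + a[2] * u + a[3] * u^2 + a[4] * u^3 + a[5] * u^4
  hump <- stats::runif(1, 1, 2) * exp(-(axis - axis[1]) / stats::runif(1, 400, 800))
  magnitude * (poly + hump)
}

#' Generate a synthetic labeled Raman cohort
#'
#' Simulates `n_samples * replicates_per_sample` spectra. Each spectrum is a
#' sum of Gaussian bands at the catalog positions (amplitude = sample-level
#' analyte amplitude times a small multiplicative log-normal replicate
#' jitter, sigma 0.05), an internal-standard phenylalanine band at 1003 cm-1,
#' a smooth fluorescence-like baseline, Gaussian noise, and a Poisson number
#' of 1-3-channel cosmic-ray spikes of 5-20 times the local signal. Outcome
#' labels are assigned at the sample level with deterministic rounding of the
#' class balance; for every analyte with a planted effect the non-pregnancy
#' mean amplitude exceeds the pregnancy mean by the configured standardized
#' difference.
#'
#' @param config A [generator_config()].
#' @return A list of class `raman_cohort` with elements `spectra` (list of
#'   [raman_spectrum()]), `manifest` (data frame with columns
#'   `spectrum_file`, `spectrum_id`, `sample_id`, `replicate`, `platform`,
#'   `label`) and `truth` (ground truth: per-sample labels and analyte
#'   amplitudes, and per-spectrum effective band amplitudes, injected
#'   baseline curves and spike positions).
#' @export
#' @examples
#' co <- generate_cohort(generator_config(n_samples = 4, seed = 7))
#' length(co$spectra)  # 20
generate_cohort <- function(config) {
  validate_generator_config(config)
  set.seed(config$seed)
  axis <- seq(config$axis_start, config$axis_end, by = config$axis_step)
  n <- as.integer(config$n_samples)
  reps <- as.integer(config$replicates_per_sample)
  bands <- generator_bands(config)

  sample_id <- sprintf("S%03d", seq_len(n))
  n_non <- max(1L, min(n - 1L, as.integer(round(n * config$class_balance))))
  label <- rep(outcome_levels()[1], n)
  label[sample(n, n_non)] <- outcome_levels()[2]

  # sample-level amplitudes: mean shifted by effect * sd for non-pregnancy
  amp <- matrix(0, n, nrow(bands), dimnames = list(sample_id, bands$band))
  for (b in seq_len(nrow(bands))) {
    mu <- bands$mean[b] + bands$effect[b] * bands$sd[b] *
      (label == "non_pregnancy")
    amp[, b] <- pmax(0, stats::rnorm(n, mu, bands$sd[b]))
  }

  spectra <- vector("list", n * reps)
  truth_spectra <- vector("list", n * reps)
  files <- character(n * reps)
  k <- 0L
  profile <- sapply(seq_len(nrow(bands)), function(b)
    gauss_band(axis, bands$position[b], config$band_fwhm))
  for (i in seq_len(n)) {
    for (r in seq_len(reps)) {
      k <- k + 1L
      jitter <- stats::rlnorm(nrow(bands), 0, 0.05)
      a_eff <- amp[i, ] * jitter
      signal <- as.vector(profile %*% a_eff)
      base <- draw_baseline(axis, config$baseline_params,
                            config$baseline_params$magnitude)
      y <- signal + base
      if (config$noise_sd > 0) y <- y + stats::rnorm(length(axis), 0, config$noise_sd)
      n_spikes <- stats::rpois(1, config$spike_rate)
      spike_pos <- integer(0)
      if (n_spikes > 0) {
        for (sp in seq_len(n_spikes)) {
          pos <- sample(length(axis), 1)
          width <- sample(1:3, 1)
          idx <- pos:min(length(axis), pos + width - 1L)
          y[idx] <- y[idx] + stats::runif(1, 5, 20) * max(abs(y[pos]), 1)
          spike_pos <- c(spike_pos, idx)
        }
      }
      sid <- sprintf("%s_r%d", sample_id[i], r)
      spectra[[k]] <- raman_spectrum(axis, y, sid, sample_id[i], r,
                                     config$platform, label[i])
      truth_spectra[[k]] <- list(spectrum_id = sid,
                                 band_amplitudes = a_eff,
                                 baseline = base,
                                 spike_channels = sort(unique(spike_pos)))
      files[k] <- paste0(sid, ".csv")
    }
  }
  names(truth_spectra) <- vapply(truth_spectra, `[[`, "", "spectrum_id")

  manifest <- data.frame(
    spectrum_file = files,
    spectrum_id = names(truth_spectra),
    sample_id = rep(sample_id, each = reps),
    replicate = rep(seq_len(reps), n),
    platform = config$platform,
    label = rep(label, each = reps),
    stringsAsFactors = FALSE)

  truth <- list(
    samples = data.frame(sample_id = sample_id, label = label,
                         stringsAsFactors = FALSE),
    amplitudes = amp,
    bands = bands,
    spectra = truth_spectra)
  structure(list(spectra = spectra, manifest = manifest, truth = truth,
                 config = config),
            class = "raman_cohort")
}

#' Generate a cohort with guaranteed planted group effects
#'
#' Same contract as [generate_cohort()] but requires at least one nonzero
#' planted effect size, so the cohort is usable as a positive control for
#' group-difference recovery.
#'
#' @inheritParams generate_cohort
#' @return See [generate_cohort()].
#' @export
planted_effect_cohort <- function(config) {
  if (!length(config$effect_sizes) || all(config$effect_sizes == 0)) {
    stop("invalid generator configuration: field 'effect_sizes' must contain ",
         "at least one nonzero effect for a planted-effect cohort",
         call. = FALSE)
  }
  generate_cohort(config)
}

#' @export
print.raman_cohort <- function(x, ...) {
  cat(sprintf("<raman_cohort> %d spectra = %d samples x %d replicates (%s)\n",
              length(x$spectra), x$config$n_samples,
              x$config$replicates_per_sample, x$config$platform))
  print(table(x$truth$samples$label))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Persists each spectrum as a two-column CSV (`shift_cm1,intensity`), the
#' manifest as TSV, and the ground truth as JSON.
#'
#' @param cohort A `raman_cohort`.
#' @param dir Output directory (created if missing).
#' @param truth Write the ground-truth JSON as well (default `TRUE`).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$spectra)) {
    write_spectrum(cohort$spectra[[i]],
                   file.path(dir, cohort$manifest$spectrum_file[i]))
  }
  mpath <- file.path(dir, "manifest.tsv")
  write_manifest(cohort$manifest, mpath)
  if (truth) {
    jsonlite::write_json(
      list(samples = cohort$truth$samples,
           amplitudes = cohort$truth$amplitudes,
           bands = cohort$truth$bands,
           spectra = cohort$truth$spectra),
      file.path(dir, "ground_truth.json"),
      digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  }
  invisible(mpath)
}
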