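test_that("injected cosmic spikes are removed, clean channels untouched", {
  co <- generate_cohort(small_config(n_samples = 2, replicates = 1,
                                     spike_rate = 0, seed = 21))
  clean <- co$spectra[[1]]
  spiked <- clean
  idx <- c(900, 901)  # 2-channel spike, 10x the local signal
  spiked$intensities[idx] <- spiked$intensities[idx] +
    10 * abs(spiked$intensities[idx])
  out <- remove_cosmic_spikes(spiked)
  expect_setequal(attr(out, "spike_channels"), idx)
  expect_lt(max(abs(out$intensities[idx] - clean$intensities[idx])),
            3 * co$config$noise_sd)
  # all unflagged channels are bit-identical to the input
  expect_identical(out$intensities[-idx], spiked$intensities[-idx])
})

test_that("a spike-free spectrum passes through despiking unchanged", {
  co <- generate_cohort(small_config(n_samples = 2, replicates = 1,
                                     spike_rate = 0, seed = 22))
  out <- remove_cosmic_spikes(co$spectra[[1]])
  expect_identical(out$intensities, co$spectra[[1]]$intensities)
  expect_length(attr(out, "spike_channels"), 0)
})

test_that("broad genuine bands survive despiking", {
  # band of FWHM 12 at 10x the noise floor: run lengths exceed the spike cap
  set.seed(23)
  axis <- seq(600, 1800, 1)
  noise_sd <- 3
  y <- 30 * exp(-4 * log(2) * ((axis - 1200) / 12)^2) +
    rnorm(length(axis), 0, noise_sd)
  s <- raman_spectrum(axis, y, "band")
  out <- remove_cosmic_spikes(s)
  inband <- abs(axis - 1200) < 30
  expect_identical(out$intensities[inband], s$intensities[inband])
})

test_that("band clipping retains exactly the fingerprint channels", {
  s <- raman_spectrum(seq(50, 2000, 1), rnorm(1951), "clip")
  cl <- clip_band(s)
  expect_equal(length(cl), 1201)
  expect_equal(range(cl$shifts), c(600, 1800))
  # an already-clipped spectrum is unchanged
  expect_identical(clip_band(cl)$intensities, cl$intensities)
  # empty intersection errors
  s2 <- raman_spectrum(seq(50, 580, 1), rnorm(531), "low")
  expect_error(clip_band(s2), "band error")
})

test_that("Savitzky-Golay reproduces polynomials up to its order exactly", {
  axis <- seq(600, 1800, 1)
  u <- axis / 1000
  y <- 2 - 3 * u + 0.5 * u^2 + 0.25 * u^3
  sm <- smooth_sg(raman_spectrum(axis, y, "cubic"))
  expect_lt(max(abs(sm$intensities - y)), 1e-9)
})

test_that("Savitzky-Golay impulse response equals the direct least-squares fit", {
  # oracle: the SG output at channel t is the value at t of the order-3
  # polynomial fit to the 11 surrounding samples
  axis <- seq_len(41) + 599
  y <- numeric(41); y[21] <- 1
  sm <- smooth_sg(raman_spectrum(axis, y, "impulse"))
  oracle <- sapply(6:36, function(t) {
    w <- (t - 5):(t + 5)
    fit <- lm(y[w] ~ poly(w, 3, raw = TRUE))
    unname(predict(fit, data.frame(w = t)))
  })
  expect_equal(sm$intensities[6:36], oracle, tolerance = 1e-8)
})

test_that("Savitzky-Golay reduces white-noise variance", {
  for (seed in 1:20) {
    set.seed(seed)
    y <- rnorm(1201)
    sm <- smooth_sg(raman_spectrum(seq(600, 1800, 1), y, "noise"))
    expect_lt(sd(sm$intensities), sd(y))
  }
})

test_that("SNIP baseline stays under the signal and reconstructs exactly", {
  co <- generate_cohort(small_config(n_samples = 3, replicates = 1, seed = 31))
  for (s in co$spectra) {
    sm <- smooth_sg(clip_band(s))
    sn <- snip_baseline(sm)
    expect_true(all(sn$baseline$intensities <= sm$intensities + 1e-9))
    expect_lt(max(abs(sn$corrected$intensities + sn$baseline$intensities -
                      sm$intensities)), 1e-9)
  }
})

test_that("SNIP recovers a smooth peakless background", {
  co <- generate_cohort(generator_config(
    n_samples = 3, replicates_per_sample = 1, noise_sd = 0, spike_rate = 0,
    amplitude_scale = 1e-9, seed = 32))  # bands vanish, baseline remains
  for (s in co$spectra) {
    cl <- clip_band(s)
    sn <- snip_baseline(cl)
    expect_lt(max(abs(sn$corrected$intensities)),
              0.05 * max(sn$baseline$intensities))
  }
})

test_that("SNIP isolates a single band on a flat baseline", {
  axis <- seq(600, 1800, 1)
  y <- 100 + 50 * exp(-4 * log(2) * ((axis - 1000) / 12)^2)
  sn <- snip_baseline(raman_spectrum(axis, y, "one-band"))
  peak <- which.min(abs(axis - 1000))
  expect_lt(abs(sn$corrected$intensities[peak] - 50), 0.1 * 50)
  away <- abs(axis - 1000) > 50
  expect_lt(max(abs(sn$baseline$intensities[away] - 100)), 0.05 * 100)
})

test_that("SNIP of an all-zero spectrum is zero", {
  sn <- snip_baseline(raman_spectrum(seq(600, 1800, 1), numeric(1201), "zero"))
  expect_equal(sn$baseline$intensities, numeric(1201))
  expect_equal(sn$corrected$intensities, numeric(1201))
})

test_that("min-max normalization attains exact bounds and is affine-invariant", {
  s <- raman_spectrum(1:16 + 600, c(2, 4, 6, rnorm(13, 4, 1)), "mm")
  nm <- normalize_minmax(s)
  expect_equal(min(nm$intensities), 0)
  expect_equal(max(nm$intensities), 1)
  expect_equal(normalize_minmax(raman_spectrum(1:16, c(2, 4, 6, seq(2.1, 5.9,
    length.out = 13)), "tri"))$intensities[1:3], c(0, 0.5, 1))
  # already-normalized spectrum attaining both bounds is a fixed point
  expect_equal(normalize_minmax(nm)$intensities, nm$intensities)
  # affine transforms a*x + b (a > 0) normalize identically
  set.seed(41)
  for (i in 1:10) {
    a <- runif(1, 0.1, 50); b <- runif(1, -100, 100)
    s2 <- raman_spectrum(s$shifts, a * s$intensities + b, "aff")
    expect_equal(normalize_minmax(s2)$intensities, nm$intensities,
                 tolerance = 1e-10)
  }
  expect_error(normalize_minmax(raman_spectrum(1:16, rep(1, 16), "const")),
               "degenerate")
})

test_that("the full chain yields 1201 channels in [0,1], order preserved", {
  co <- generate_cohort(small_config(n_samples = 5, replicates = 2, seed = 33))
  out <- preprocess_batch(co$spectra)
  expect_length(out, 10)
  for (i in seq_along(out)) {
    expect_identical(out[[i]]$spectrum_id, co$spectra[[i]]$spectrum_id)
    expect_equal(length(out[[i]]), 1201)
    expect_gte(min(out[[i]]$intensities), 0)
    expect_lte(max(out[[i]]$intensities), 1)
  }
})

test_that("a second pipeline pass is stable apart from smoothing and clipping", {
  co <- generate_cohort(small_config(n_samples = 2, replicates = 1, seed = 34))
  once <- preprocess_pipeline(co$spectra[[1]])
  # despiking and band clipping are exact fixed points on the output
  d2 <- remove_cosmic_spikes(once)
  expect_identical(d2$intensities, once$intensities)
  expect_identical(length(clip_band(once)), length(once))
  # the full second pass changes the result only through re-smoothing and a
  # second round of baseline erosion, both bounded
  twice <- preprocess_pipeline(once)
  rms <- sqrt(mean((twice$intensities - once$intensities)^2))
  expect_lt(rms, 0.15)
  sm2 <- smooth_sg(once)
  expect_lt(sqrt(mean((sm2$intensities - once$intensities)^2)), 0.02)
})

test_that("outlier screening flags planted junk and spares clean batches", {
  co <- generate_cohort(small_config(n_samples = 30, replicates = 2, seed = 35))
  pre <- preprocess_batch(co$spectra)
  # clean batch: at most 1% rejected on average (chi-square 0.999 tail)
  scr <- detect_outlier_spectra(pre)
  expect_lte(sum(scr$report$rejected), ceiling(0.02 * length(pre)))
  # replace 5 spectra by pure noise: they take the 5 largest distances
  set.seed(36)
  junk_idx <- c(3, 11, 25, 40, 52)
  for (j in junk_idx) {
    pre[[j]] <- set_intensities_for_test(pre[[j]], runif(1201))
  }
  scr2 <- detect_outlier_spectra(pre)
  worst5 <- order(scr2$report$distance2, decreasing = TRUE)[1:5]
  expect_setequal(scr2$report$spectrum_id[worst5],
                  scr2$report$spectrum_id[junk_idx])
  # a batch of identical spectra degenerates gracefully
  same <- replicate(12, pre[[1]], simplify = FALSE)
  scr3 <- detect_outlier_spectra(same)
  expect_equal(sum(scr3$report$rejected), 0)
})
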