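test_that("peak intensity reads the in-window maximum", {
  axis <- seq(600, 1800, 1)
  cat <- peak_catalog()
  tyr <- cat[cat$analyte == "tyrosine", ]
  # single noiseless Gaussian at 853: in-window max is the amplitude
  y <- 42 * exp(-4 * log(2) * ((axis - 853) / 12)^2)
  s <- raman_spectrum(axis, y, "tyr")
  expect_equal(peak_intensity(s, tyr), 42, tolerance = 1e-6)
  # flat zero region reads 0
  asp <- cat[cat$analyte == "aspartic_acid", ]
  expect_equal(peak_intensity(s, asp), max(y[abs(axis - 941) <= 5]))
  expect_lt(peak_intensity(s, asp), 1e-6)
  # two overlapping bands: max of their sum, against dense evaluation
  y2 <- band_sum(axis, c(30, 20), c(850, 858))
  s2 <- raman_spectrum(axis, y2, "twin")
  expect_equal(peak_intensity(s2, tyr), max(y2[abs(axis - 853) <= 5]))
  # window off the axis errors
  far <- list(analyte = "ghost", position = 2500, window_halfwidth = 5)
  expect_error(peak_intensity(s, far), "assignment error")
})

test_that("the internal-standard log ratio anchors and scale invariance hold", {
  expect_equal(quant_ratio(7, 7), 0)
  expect_equal(quant_ratio(10, 1), 1)
  expect_equal(quant_ratio(50, 5), 1)
  set.seed(5)
  for (i in 1:20) {
    a <- runif(1, 1e-3, 1e3)
    it <- runif(1, 0.1, 10); is <- runif(1, 0.1, 10)
    expect_equal(quant_ratio(a * it, a * is), quant_ratio(it, is),
                 tolerance = 1e-12)
  }
  expect_error(quant_ratio(0, 1), "undefined ratio")
  expect_error(quant_ratio(1, -2), "undefined ratio")
})

test_that("quant_table yields one row per spectrum and analyte", {
  co <- generate_cohort(small_config(n_samples = 4, replicates = 2, seed = 51))
  pre <- preprocess_batch(co$spectra)
  qt <- quant_table(pre)
  expect_lte(nrow(qt), 8 * 7)
  qt1 <- quant_table(pre[1])
  expect_equal(nrow(qt1), 7)
  expect_setequal(qt1$analyte,
                  setdiff(peak_catalog()$analyte, "phenylalanine"))
})

test_that("noise-free generator amplitudes are recovered through the full chain", {
  co <- generate_cohort(noiseless_config(n_samples = 6, replicates = 2))
  pre <- preprocess_batch(co$spectra)
  qt <- quant_table(pre)
  expect_equal(nrow(qt), 12 * 7)
  truth <- co$truth$spectra
  err <- mapply(function(sid, analyte, ratio) {
    a <- truth[[sid]]$band_amplitudes
    abs(ratio - log10(a[[analyte]] / a[["phenylalanine"]]))
  }, qt$spectrum_id, qt$analyte, qt$ratio)
  expect_lt(max(err), 0.02)
})

test_that("group comparison recovers planted effects with the right direction", {
  cfg <- generator_config(n_samples = 120, replicates_per_sample = 1,
                          effect_sizes = c(tyrosine = 1.5), seed = 53)
  co <- planted_effect_cohort(cfg)
  qt <- quant_table(preprocess_batch(co$spectra))
  cmp <- compare_groups(qt, co$manifest)
  tyr <- cmp[cmp$analyte == "tyrosine", ]
  expect_true(tyr$tier %in% c("*", "**"))
  expect_equal(tyr$direction, 1)
})

test_that("identical groups give p = 1 and tier ns for every analyte", {
  co <- generate_cohort(small_config(n_samples = 6, replicates = 1, seed = 54))
  qt <- quant_table(preprocess_batch(co$spectra))
  # copy the same ratios into both labels
  qt2 <- rbind(qt, qt)
  qt2$label <- rep(c("pregnancy", "non_pregnancy"), each = nrow(qt))
  cmp <- compare_groups(qt2)
  expect_equal(cmp$p_value, rep(1, 7))
  expect_equal(cmp$tier, rep("ns", 7))
})

test_that("group comparison guards small groups and supports options", {
  co <- generate_cohort(small_config(n_samples = 10, replicates = 1, seed = 55))
  qt <- quant_table(preprocess_batch(co$spectra))
  lab <- unique(co$manifest[, c("sample_id", "label")])
  # starve one group below 3 observations
  keep <- lab$sample_id[lab$label == "pregnancy"][1:2]
  qt_small <- qt[qt$sample_id %in% c(keep,
    lab$sample_id[lab$label == "non_pregnancy"]), ]
  expect_error(compare_groups(qt_small, co$manifest), "insufficient data")
  # Welch, per-sample aggregation and BH adjustment all run
  cmp <- compare_groups(qt, co$manifest, test = "welch", per_sample = TRUE,
                        p_adjust = "BH")
  expect_equal(nrow(cmp), 7)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
})
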