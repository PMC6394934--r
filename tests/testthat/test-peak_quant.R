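test_that("integrate_peak recovers closed-form Gaussian properties", {
  tr <- gaussian_trace(rt = 4.5, height = 1e6, sigma = 0.05)
  pk <- integrate_peak(tr, expected_rt = 4.5)
  expect_true(pk$found)
  expect_equal(pk$retention_time, 4.5, tolerance = 1e-6)
  expect_equal(pk$area, 1e6 * 0.05 * sqrt(2 * pi), tolerance = 0.005)
  # FWHM of a Gaussian: 2 sqrt(2 ln 2) sigma = 2.3548 sigma
  expect_equal(pk$width_at_half_height, 2.3548 * 0.05, tolerance = 0.01)

  # flat zero trace: nothing found
  flat <- data.frame(time_min = seq(3, 6, by = 0.005), intensity = 0)
  expect_false(integrate_peak(flat, 4.5)$found)

  expect_error(integrate_peak(flat[0, ], 4.5), "empty")
  expect_error(integrate_peak(flat, 20), "window")
})

test_that("peak detection follows the S/N = 3 rule on noisy baselines", {
  set.seed(42)
  t <- seq(3, 6, by = 0.005)
  noise <- rnorm(length(t), 1000, 50)
  # peak at 10x noise SD: found
  big <- data.frame(time_min = t,
                    intensity = noise + 500 * exp(-(t - 4.5)^2 / (2 * 0.05^2)))
  pk <- integrate_peak(big, 4.5)
  expect_true(pk$found)
  expect_gt(pk$snr, 3)
  # peak at 1x noise SD: not found
  small <- data.frame(time_min = t,
                      intensity = noise + 50 * exp(-(t - 4.5)^2 / (2 * 0.05^2)))
  expect_false(integrate_peak(small, 4.5)$found)
  # noise estimate is in the right ballpark (MAD-based)
  expect_equal(pk$noise_sd, 50, tolerance = 0.25)
})

test_that("fit_calibration meets its contract", {
  # perfect proportionality
  lv <- data.frame(nominal = c(1, 2, 4, 8, 16), ratio = 0.04 * c(1, 2, 4, 8, 16))
  fit <- fit_calibration(lv)
  expect_equal(fit$r_squared, 1.0)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$slope, 0.04)

  # blank excluded: zero level does not enter the fit
  lv0 <- rbind(data.frame(nominal = 0, ratio = 0.5), lv)
  expect_equal(fit_calibration(lv0)$n_levels, 5)

  expect_error(fit_calibration(lv[1:2, ]), "3 non-zero")
  expect_error(fit_calibration(transform(lv, ratio = 1)), "identical")

  # saturation at the top strictly degrades linearity
  sat <- lv
  sat$ratio[5] <- 0.6 * sat$ratio[5]
  expect_lt(fit_calibration(sat)$r_squared, fit$r_squared)

  # r_squared invariant under affine rescaling of responses
  resc <- transform(lv0, ratio = 3.7 * ratio + 0.2)
  set.seed(1)
  noisy <- transform(lv, ratio = ratio * rnorm(5, 1, 0.05))
  noisy_resc <- transform(noisy, ratio = 3.7 * ratio + 0.2)
  expect_equal(fit_calibration(noisy_resc)$r_squared,
               fit_calibration(noisy)$r_squared, tolerance = 1e-9)
})

test_that("quantify inverts the calibration line", {
  fit <- fit_calibration(data.frame(nominal = c(1, 4, 16, 64),
                                    ratio = 0.02 + 0.04 * c(1, 4, 16, 64)))
  found_pk <- function(area) {
    structure(list(area = area, found = TRUE), class = "peak_result")
  }
  # ratio = slope * 16 + intercept -> 16 uM
  ratio <- fit$slope * 16 + fit$intercept
  q <- quantify(found_pk(ratio * 100), found_pk(100), fit)
  expect_equal(q$readout, 16, tolerance = 1e-9)

  # analyte not found: 0 with below-LOD flag
  missing_pk <- structure(list(area = 0, found = FALSE), class = "peak_result")
  q0 <- quantify(missing_pk, found_pk(100), fit)
  expect_equal(q0$readout, 0)
  expect_true(q0$below_lod)

  # IS missing: failed injection
  expect_error(quantify(found_pk(1), missing_pk, fit), "injection")
})

test_that("quantitation round-trip holds within 1% over [1, 256] uM", {
  series <- generate_calibrator_series(bundled, noise = 0, seed = 1)
  fits <- calibrate_series(series, bundled)
  an <- bundled$analytes
  analytes <- an$analyte[!an$is_internal_standard]
  for (conc in c(1, 16, 256)) {
    conc_map <- setNames(rep(conc, length(analytes)), analytes)
    d <- run_design(conc_map, noise_sd = 0, seed = 1)
    traces <- generate_chromatogram(d, bundled)
    q <- quantify_sample(traces, bundled, fits)
    expect_true(all(abs(q$readout_uM / conc - 1) < 0.01),
                info = paste("conc", conc))
  }
})

test_that("readout is invariant to doubling all intensities", {
  series <- generate_calibrator_series(bundled, noise = 0, seed = 1,
                                       analytes = "Xanthine")
  fits <- calibrate_series(series, bundled)
  d <- run_design(c(Xanthine = 32), noise_sd = 0, seed = 1)
  traces <- generate_chromatogram(d, bundled)
  q1 <- quantify_sample(traces, bundled, fits["Xanthine"])
  traces$intensity <- traces$intensity * 2
  q2 <- quantify_sample(traces, bundled, fits["Xanthine"])
  expect_equal(q2$readout_uM, q1$readout_uM, tolerance = 1e-9)
})

test_that("round-trip through urine prep recovers the urine concentration", {
  # forward: 12.5 mmol/mol at Cr 2.0 -> readout on calibrator scale -> back
  series <- generate_calibrator_series(bundled, noise = 0, seed = 1,
                                       analytes = "Uracil")
  fits <- calibrate_series(series, bundled)
  prep <- plan_urine_prep(2.0)
  # uncapped prep: calibrator-scale readout equals mmol/mol, so simulate at
  # the numeric value directly
  d <- run_design(c(Uracil = 12.5), noise_sd = 0, seed = 1)
  q <- quantify_sample(generate_chromatogram(d, bundled), bundled,
                       fits, prep = prep)
  expect_equal(q$mmol_per_mol, 12.5, tolerance = 1e-3)
})

test_that("carryover check passes on blanks and catches spikes", {
  blank <- run_design(setNames(numeric(0), character(0)),
                      sample_label = "blank", noise_sd = 200, seed = 8)
  an <- bundled$analytes
  analytes <- an$analyte[!an$is_internal_standard]
  zero <- setNames(rep(0, length(analytes)), analytes)
  traces <- generate_chromatogram(run_design(zero, sample_label = "blank",
                                             noise_sd = 200, seed = 8),
                                  bundled)
  res <- carryover_check(traces, bundled)
  expect_true(all(res$pass))

  # spike uracil at 10x noise: uracil fails, everything else still passes
  spiked <- traces
  ch <- spiked$analyte == "Uracil" & spiked$channel_role == "quantifier"
  t <- spiked$time_min[ch]
  spiked$intensity[ch] <- spiked$intensity[ch] +
    2000 * exp(-(t - 2.00)^2 / (2 * 0.05^2))
  res2 <- carryover_check(spiked, bundled)
  expect_false(res2$pass[res2$analyte == "Uracil"])
  expect_true(all(res2$pass[res2$analyte != "Uracil"]))

  # empty panel of traces: vacuous pass
  expect_equal(nrow(carryover_check(traces[0, ], bundled)), 0)
})

test_that("ion ratio check accepts the generated 0.35 ratio", {
  d <- run_design(c(Adenine = 16), noise_sd = 0, seed = 1)
  traces <- generate_chromatogram(d, bundled)
  rt <- 3.32
  quant <- integrate_peak(get_channel(traces, "Adenine", "quantifier"), rt)
  qual <- integrate_peak(get_channel(traces, "Adenine", "qualifier"), rt)
  chk <- ion_ratio_check(quant, qual)
  expect_true(chk$pass)
  expect_equal(chk$ratio, 0.35, tolerance = 0.02)
  # a qualifier at half the expected ratio fails the +/-30% window
  halved <- qual
  halved$area <- qual$area / 2
  expect_false(ion_ratio_check(quant, halved)$pass)
})
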