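test_that("resolution implements 1.18 dt / (w1 + w2)", {
  expect_equal(resolution(5.0, 5.0, 0.2, 0.2), 0)       # coincident peaks
  expect_equal(resolution(5.0, 5.5, 0.2, 0.2), 1.475)   # direct arithmetic
  expect_error(resolution(5, 5.5, 0, 0.2), "positive")
  expect_error(resolution(5.5, 5.0, 0.2, 0.2), "t2")

  # translation- and scale-invariance: scaling t and w by c leaves Rs fixed
  for (c in c(0.5, 2, 10)) {
    expect_equal(resolution(3 * c, 3.4 * c, 0.1 * c, 0.12 * c),
                 resolution(3, 3.4, 0.1, 0.12))
  }
  expect_equal(resolution(3 + 2, 3.4 + 2, 0.1, 0.12),
               resolution(3, 3.4, 0.1, 0.12))
})

test_that("two equal-width Gaussians 4 sigma apart measure Rs ~ 1.002", {
  sigma <- 0.05
  t1 <- 4.0
  t2 <- 4.0 + 4 * sigma
  p1 <- integrate_peak(gaussian_trace(t1, 1e5, sigma), t1)
  p2 <- integrate_peak(gaussian_trace(t2, 1e5, sigma), t2)
  rs <- resolution(p1$retention_time, p2$retention_time,
                   p1$width_at_half_height, p2$width_at_half_height)
  expect_equal(rs, 1.18 * 4 / (2 * 2.35482), tolerance = 0.01)
})

test_that("critical pairs of the bundled panel are baseline resolved", {
  res <- critical_pair_resolution(bundled)
  expect_equal(nrow(res), nrow(bundled$critical_pairs))
  expect_true(all(res$baseline_resolved))
  expect_true(all(res$Rs >= 1.5))
})

test_that("determine_lod applies the S/N = 3 definition", {
  series <- data.frame(conc = c(0.5, 1, 2), snr = c(1.5, 3.0, 6.0))
  expect_equal(determine_lod(series)$lod, 1)

  # all levels above S/N 3: lowest tested with a below-range flag
  hot <- data.frame(conc = c(0.5, 1, 2), snr = c(4, 8, 16))
  r <- determine_lod(hot)
  expect_equal(r$lod, 0.5)
  expect_true(r$below_range)

  # no level reaches S/N 3
  cold <- data.frame(conc = c(0.5, 1, 2), snr = c(0.5, 1, 2))
  expect_true(determine_lod(cold)$undefined)

  # interpolation between bracketing levels is monotone and flagged
  ri <- determine_lod(series, interpolate = TRUE)
  expect_true(ri$interpolated)
  expect_true(ri$lod > 0.5 && ri$lod <= 1)
})

test_that("determine_lloq matches brute-force search and flags non-monotone CVs", {
  brute_lloq <- function(reps, limit = 20) {
    conc <- sort(as.numeric(names(reps)))
    for (c0 in conc) {
      x <- reps[[as.character(c0)]]
      if (100 * sd(x) / mean(x) < limit) return(c0)
    }
    NA_real_
  }
  # constructed CV ladder {1: 35%, 2: 18%, 4: 9%} -> 2 uM
  make <- function(cv, mean = 10, n = 5) {
    x <- scale(seq_len(n))[, 1]
    mean + x * (cv / 100 * mean)
  }
  reps <- list("1" = make(35), "2" = make(18), "4" = make(9))
  r <- determine_lloq(reps)
  expect_equal(r$lloq, 2)
  expect_equal(r$lloq, brute_lloq(reps))
  expect_false(r$non_monotone)

  # identical replicates: CV 0 at the lowest level
  same <- list("1" = rep(5, 3), "2" = rep(10, 3))
  expect_equal(determine_lloq(same)$lloq, 1)

  # single replicate: CV undefined
  expect_error(determine_lloq(list("1" = 5)), "replicates")

  # non-monotone: low level passes, middle fails -> first pass above failure
  nm <- list("1" = make(10), "2" = make(30), "4" = make(5))
  rn <- determine_lloq(nm)
  expect_equal(rn$lloq, 4)
  expect_true(rn$non_monotone)

  # randomized equivalence with the oracle on monotone ladders
  set.seed(7)
  for (i in 1:20) {
    cvs <- sort(runif(5, 2, 40), decreasing = TRUE)
    reps <- setNames(lapply(cvs, make), 2^(0:4))
    r <- determine_lloq(reps)
    expect_equal(r$lloq, brute_lloq(reps))
  }
})

test_that("determine_uloq finds the top of the linear range", {
  noms <- c(1, 2, 4, 8, 16, 32, 64, 128, 256)
  lin <- data.frame(nominal = noms, ratio = 0.04 * noms)
  expect_equal(determine_uloq(lin)$uloq, 256)

  # saturation at 256 (response at 60% of the linear prediction) -> 128
  sat <- lin
  sat$ratio[9] <- 0.6 * sat$ratio[9]
  r <- determine_uloq(sat)
  expect_equal(r$uloq, 128)
  expect_lt(r$r2_by_level[["256"]], 0.99)

  # minimal 3-level linear series: top level
  expect_equal(determine_uloq(lin[1:3, ])$uloq, 4)
  expect_error(determine_uloq(lin[1:2, ]), "3 non-zero")

  # brute-force prefix-search oracle agreement on perturbed series
  brute_uloq <- function(series, limit = 0.99) {
    use <- series[series$nominal > 0, ]
    use <- use[order(use$nominal), ]
    best <- NA_real_
    for (i in 3:nrow(use)) {
      if (fit_calibration(use[1:i, ])$r_squared > limit) best <- use$nominal[i]
    }
    best
  }
  set.seed(21)
  for (i in 1:10) {
    pert <- lin
    pert$ratio <- pert$ratio * rnorm(9, 1, 0.05)
    expect_equal(determine_uloq(pert)$uloq, brute_uloq(pert))
  }
})

test_that("precision_and_recovery computes CV and recovery", {
  r <- precision_and_recovery(c(19, 20, 21), nominal = 20)
  expect_equal(r$cv_pct, 100 * sd(c(19, 20, 21)) / 20)
  expect_equal(r$cv_pct, 5.0)
  expect_equal(r$recovery_pct, 100.0)

  r2 <- precision_and_recovery(rep(20, 5), nominal = 20)
  expect_equal(r2$cv_pct, 0)
  expect_equal(r2$recovery_pct, 100)

  expect_error(precision_and_recovery(20, 20), "replicates")
  expect_error(precision_and_recovery(c(19, 21), 0), "nominal")

  # EQC-style: 10 replicates at generative CV 5% -> estimate in [2.5, 8]%
  set.seed(99)
  reps <- 20 * rnorm(10, 1, 0.05)
  est <- precision_and_recovery(reps, nominal = 20)
  expect_gt(est$cv_pct, 2.5)
  expect_lt(est$cv_pct, 8)
})

test_that("CV estimates are unbiased within Monte-Carlo error", {
  # sampling distribution of the CV at n = 10, 1e4 repetitions
  set.seed(123)
  cvs <- replicate(1e4, {
    x <- rnorm(10, 100, 5)
    100 * sd(x) / mean(x)
  })
  # E[CV-hat] ~ cv * (1 - 1/(4(n-1))) ~ 4.86 for cv = 5, n = 10
  expect_equal(mean(cvs), 5 * (1 - 1 / 36), tolerance = 0.02)
})

test_that("stability_check thresholds at CV 15%", {
  ok <- c(fresh = 20, chilled_48h = 19.8, frozen_7d = 20.4)
  r <- stability_check(ok)
  expect_true(r$pass)
  expect_lt(r$cv_pct, 2)

  bad <- c(fresh = 20, degraded = 10)
  r2 <- stability_check(bad)
  expect_false(r2$pass)
  expect_gt(r2$cv_pct, 30)

  expect_error(stability_check(c(only = 20)), "conditions")
})

test_that("validation_report enforces limit ordering", {
  r <- validation_report("Uracil", lod = 0.1, lloq = 0.5, uloq = 256,
                         r_squared = 0.999)
  expect_s3_class(r, "validation_report")
  expect_error(validation_report("Uracil", lod = 1, lloq = 0.5, uloq = 256),
               "lod <= lloq")
  expect_error(validation_report("Uracil", cv_interday = -1), "CV")
})
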