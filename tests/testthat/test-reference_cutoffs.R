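test_that("trim_extremes drops only values strictly above the 99.5th percentile", {
  set.seed(5)
  x <- rlnorm(251, 2, 0.7)
  kept <- trim_extremes(x)
  cut <- oracle_quantile(x, 0.995)
  expect_setequal(kept, x[x <= cut])
  # with distinct values and n = 251 at most 2 are removed
  expect_lte(length(x) - length(kept), 2)

  # constant vector: nothing removed (ties at the percentile retained)
  expect_length(trim_extremes(rep(3, 30)), 30)
  expect_error(trim_extremes(rnorm(10)), ">= 20")

  # one extreme outlier: removed, and the remaining 97.5th is unaffected
  clean <- rlnorm(250, 2, 0.7)
  spiked <- c(clean, 100 * median(clean))
  kept2 <- trim_extremes(spiked)
  expect_false(max(spiked) %in% kept2)
  expect_equal(percentile_cutoff(kept2, 0.975),
               percentile_cutoff(clean[clean <= quantile(clean, 0.995)], 0.975),
               tolerance = 0.02)
})

test_that("percentile_cutoff equals the sort-based oracle", {
  expect_equal(percentile_cutoff(1:100, 0.975), oracle_quantile(1:100, 0.975))
  expect_equal(percentile_cutoff(rep(4, 10), 0.975), 4)
  expect_error(percentile_cutoff(numeric(0)), "empty")

  set.seed(11)
  for (i in 1:25) {
    x <- rlnorm(sample(20:300, 1), rnorm(1), runif(1, 0.2, 1))
    q <- runif(1, 0.01, 0.99)
    expect_equal(percentile_cutoff(x, q), oracle_quantile(x, q))
  }

  # large-sample convergence to the analytic log-normal quantile
  set.seed(12)
  x <- rlnorm(1e4, log(10), 0.5)
  expect_equal(percentile_cutoff(x, 0.975), qlnorm(0.975, log(10), 0.5),
               tolerance = 0.02)
})

test_that("cutoff pipeline is permutation- and scale-equivariant", {
  set.seed(31)
  ages <- runif(240, 0, 18)
  vals <- rlnorm(240, 1, 0.7)
  r1 <- test_age_dependency(vals, ages, cutoff_config(), seed = 3)
  perm <- sample(240)
  r2 <- test_age_dependency(vals[perm], ages[perm], cutoff_config(), seed = 3)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)

  # scaling all values by c > 0 scales the cutoff by c
  expect_equal(percentile_cutoff(3.7 * vals, 0.975),
               3.7 * percentile_cutoff(vals, 0.975))
  expect_equal(trim_extremes(2 * vals), 2 * trim_extremes(vals))
})

test_that("test_age_dependency handles degenerate configurations", {
  set.seed(41)
  ages <- c(runif(30, 0, 1), runif(30, 1, 3), runif(30, 3, 6), runif(30, 6, 18))
  vals <- rlnorm(120, 0, 0.7)
  # alpha = 0: never split
  r <- test_age_dependency(vals, ages, cutoff_config(alpha = 0), seed = 1)
  expect_false(r$split)
  expect_equal(r$groups, rep(1L, 4))
  # an empty bin is an error naming the bin
  expect_error(
    test_age_dependency(vals[ages >= 1], ages[ages >= 1], cutoff_config()),
    "\\[0, 1\\)")
})

test_that("quantile ANOVA controls type-I error and detects a x3 age effect", {
  # 200 seeded repetitions each; permutation p-values are exact under
  # exchangeability, so the rejection rate should sit near alpha = 0.05
  cc <- cutoff_config()
  reject <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    ages <- c(runif(60, 0, 1), runif(60, 1, 3), runif(60, 3, 6),
              runif(60, 6, 18))
    vals <- rlnorm(240, 0, 0.7)
    test_age_dependency(vals, ages, cc, seed = 2000 + i)$split
  }, logical(1))
  expect_gte(mean(reject), 0.01)
  expect_lte(mean(reject), 0.10)

  # power: infants scaled x3 (the dihydrouracil-like pattern), n = 60/bin
  detected <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    ages <- c(runif(60, 0, 1), runif(60, 1, 3), runif(60, 3, 6),
              runif(60, 6, 18))
    vals <- rlnorm(240, 0, 0.7) * rep(c(3, 1, 1, 1), each = 60)
    test_age_dependency(vals, ages, cc, seed = 4000 + i)$split
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})

test_that("build_cutoff_table recovers the generating age structure", {
  coh <- generate_cohort(cohort_spec(n = 251, seed = 1), bundled)
  tab <- build_cutoff_table(coh, cutoff_config(), bundled, seed = 1)

  # emitted table validates against the registry cutoff invariants
  reg2 <- bundled
  reg2$cutoffs <- tab
  expect_length(validate_panel(reg2), 0)

  # analytes generated with a strong (>= 2.5x) age effect are split; the
  # xanthine-like 1.4x effect is below reliable power at ~63 samples/bin
  age_split_strong <- c("Dihydrouracil", "Beta-Ureidopropionic acid",
                        "Beta-Ureidoisobutyric acid", "Inosine")
  n_rules <- table(tab$analyte)
  for (a in age_split_strong) {
    expect_gt(n_rules[[a]], 1)
  }
  # false splits among the no-age-effect analytes stay within binomial
  # bounds for alpha = 0.05 (P(X >= 5 | n = 20, p = 0.05) < 0.003)
  no_effect <- setdiff(unique(tab$analyte),
                       c(age_split_strong, "Xanthine", "Pseudouridine",
                         "Allopurinol"))
  false_splits <- sum(vapply(no_effect, function(a) n_rules[[a]] > 1,
                             logical(1)))
  expect_lte(false_splits, 4)

  # pseudouridine keeps its lower cutoff near the generating 2.5th pct
  psu <- tab[tab$analyte == "Pseudouridine", ]
  expect_true(all(!is.na(psu$lower)))
  expect_true(all(psu$lower < psu$upper))

  # allopurinol: detection-is-abnormal
  expect_true(tab$detection_is_abnormal[tab$analyte == "Allopurinol"])
})

test_that("emitted cutoffs recover the generating quantiles within sampling error", {
  coh <- generate_cohort(cohort_spec(n = 251, seed = 1), bundled)
  tab <- build_cutoff_table(coh, cutoff_config(), bundled, seed = 1)
  errs <- numeric(0)
  for (i in seq_len(nrow(tab))) {
    if (tab$detection_is_abnormal[i]) next
    mid <- (tab$age_min[i] + tab$age_max[i]) / 2
    truth <- get_cutoff(bundled, tab$analyte[i], mid)$upper
    errs <- c(errs, abs(tab$upper[i] / truth - 1))
  }
  # the 97.5th percentile at n = 251 carries ~12% relative sampling error
  # per analyte; recovery is judged on the median across the panel
  expect_lte(median(errs), 0.10)

  # convergence: at n = 2500 the pooled-analyte cutoffs tighten markedly
  coh_big <- generate_cohort(cohort_spec(n = 2500, seed = 2), bundled)
  v <- coh_big$value[coh_big$analyte == "Uracil"]
  v <- v[v <= quantile(v, 0.995)]
  expect_equal(percentile_cutoff(v, 0.975), 30, tolerance = 0.06)
})

test_that("clinical override forces a merge", {
  coh <- generate_cohort(cohort_spec(n = 251, seed = 1), bundled)
  cc <- cutoff_config(clinical_override = list(Dihydrouracil = "merge"))
  tab <- build_cutoff_table(coh, cc, bundled, seed = 1)
  expect_equal(sum(tab$analyte == "Dihydrouracil"), 1)
})
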