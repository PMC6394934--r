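# Reference-interval estimation ----------------------------------------------
#
# The published procedure, per metabolite: (1) exclude values strictly above
# the 99.5th percentile; (2) the 97.5th percentile of the remaining data is
# the upper cutoff (pseudouridine additionally gets a 2.5th-percentile lower
# cutoff); (3) test whether the target percentile differs between the age
# groups 0-1, 1-3, 3-6 and 6-18 years ("quantile ANOVA") and, where it does
# and a clinical override permits, emit age-stratified cutoffs with adjacent
# groups merged when they do not differ.
#
# All empirical quantiles use linear interpolation between order statistics
# (stats::quantile type 7); the cited work states no convention, and every
# oracle in the test suite shares this one. The quantile-ANOVA is realized
# as a permutation test of the between-group dispersion of the bin-level
# percentile (exact type-I control under exchangeability); a bootstrap
# variant is available behind a flag.

DEFAULT_AGE_BINS <- matrix(c(0, 1, 1, 3, 3, 6, 6, 18), ncol = 2, byrow = TRUE)

#' Configuration of the cutoff-estimation pipeline
#'
#' @param trim_quantile exclusion threshold (values strictly above this
#'   percentile are dropped), default 0.995
#' @param upper_quantile upper-cutoff percentile, default 0.975
#' @param lower_quantile lower-cutoff percentile (pseudouridine), default 0.025
#' @param alpha significance level of the age test, default 0.05
#' @param n_perm permutations (or bootstrap draws) for the age test
#' @param method `"permutation"` or `"bootstrap"`
#' @param clinical_override named list analyte -> `"merge"` (never split) or
#'   `"split"` (always honour a significant test); models the consulted
#'   clinical judgement as explicit configuration
#' @return a `cutoff_config`
#' @export
cutoff_config <- function(trim_quantile = 0.995, upper_quantile = 0.975,
                          lower_quantile = 0.025, alpha = 0.05,
                          n_perm = 199L, method = c("permutation", "bootstrap"),
                          clinical_override = list()) {
  method <- match.arg(method)
  stopifnot(0 < lower_quantile, lower_quantile < upper_quantile,
            upper_quantile < trim_quantile, trim_quantile < 1,
            alpha >= 0, alpha <= 1, n_perm >= 19)
  structure(list(trim_quantile = trim_quantile,
                 upper_quantile = upper_quantile,
                 lower_quantile = lower_quantile,
                 age_bins = DEFAULT_AGE_BINS, alpha = alpha,
                 n_perm = as.integer(n_perm), method = method,
                 clinical_override = clinical_override),
            class = "cutoff_config")
}

#' Exclude extreme values above the trim percentile
#'
#' Removes values strictly above the `trim_quantile` percentile of the
#' input ("values above the 99.5th percentile were excluded"); ties at the
#' percentile are retained.
#'
#' @param values numeric vector (n >= 20; a percentile this extreme is
#'   meaningless below that)
#' @param trim_quantile percentile, default 0.995
#' @return the retained values
#' @export
trim_extremes <- function(values, trim_quantile = 0.995) {
  values <- values[!is.na(values)]
  if (length(values) < 20) {
    stop("need >= 20 values to trim at the ", trim_quantile * 100,
         "th percentile", call. = FALSE)
  }
  cut <- quantile(values, trim_quantile, names = FALSE, type = 7)
  values[values <= cut]
}

#' Empirical percentile cutoff
#'
#' Linear-interpolation empirical quantile (type 7) of the retained values.
#'
#' @param values numeric vector (non-empty)
#' @param q quantile in (0, 1), e.g. 0.975
#' @return the cutoff on the scale of `values`
#' @export
percentile_cutoff <- function(values, q = 0.975) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("empty input", call. = FALSE)
  stopifnot(q > 0, q < 1)
  quantile(values, q, names = FALSE, type = 7)
}

assign_bins <- function(ages, bins = DEFAULT_AGE_BINS) {
  idx <- rep(NA_integer_, length(ages))
  for (b in seq_len(nrow(bins))) {
    hit <- ages >= bins[b, 1] &
      (ages < bins[b, 2] | (b == nrow(bins) & ages <= bins[b, 2]))
    idx[hit] <- b
  }
  idx
}

# between-group dispersion of the bin-level percentile, weighted by bin size
quantile_anova_stat <- function(values, bin, q) {
  qs <- tapply(values, bin, percentile_cutoff, q = q)
  ns <- tapply(values, bin, length)
  pooled <- percentile_cutoff(values, q)
  sum(ns * (qs - pooled)^2)
}

#' Test age dependency of a percentile cutoff
#'
#' One-way "quantile ANOVA": the observed between-age-group dispersion of
#' the target percentile is compared against its permutation (or bootstrap)
#' null distribution obtained by shuffling ages across samples.
#'
#' @param values numeric vector of (already trimmed) concentrations
#' @param ages ages in years, same length
#' @param config a [cutoff_config()]
#' @param q the percentile under test (defaults to the config's upper)
#' @param seed RNG seed for the resampling
#' @return list: `p_value`, `statistic`, `split` (significant at alpha),
#'   `groups` (per-bin merged-group labels; adjacent merging), `bin_n`
#' @export
test_age_dependency <- function(values, ages, config = cutoff_config(),
                                q = NULL, seed = 1L) {
  stopifnot(length(values) == length(ages))
  q <- q %||% config$upper_quantile
  bin <- assign_bins(ages, config$age_bins)
  if (any(is.na(bin))) stop("ages outside [0, 18]", call. = FALSE)
  bin_n <- table(factor(bin, levels = seq_len(nrow(config$age_bins))))
  if (any(bin_n == 0)) {
    empty <- which(bin_n == 0)[1]
    stop("age bin [", config$age_bins[empty, 1], ", ",
         config$age_bins[empty, 2], ") contains no samples", call. = FALSE)
  }
  if (any(bin_n < 10)) {
    warning("age bin with < 10 samples: the ", q * 100,
            "th percentile is poorly determined")
  }

  # canonical sample order: the permutation stream, and hence the p-value,
  # must not depend on how the input rows happened to be sorted
  ord <- order(values, bin)
  values <- values[ord]
  bin <- bin[ord]

  obs <- quantile_anova_stat(values, bin, q)
  null <- with_seed(seed, {
    vapply(seq_len(config$n_perm), function(i) {
      if (config$method == "permutation") {
        quantile_anova_stat(values, sample(bin), q)
      } else {
        idx <- sample.int(length(values), replace = TRUE)
        quantile_anova_stat(values[idx], bin, q)
      }
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (config$n_perm + 1)
  split <- config$alpha > 0 && p < config$alpha

  groups <- merge_adjacent_groups(values, bin, q, config, split, seed)
  list(p_value = p, statistic = obs, split = split, groups = groups,
       bin_n = as.integer(bin_n))
}

# After a significant joint test, adjacent bins are merged when their
# pairwise permutation test is not significant; otherwise all bins pooled.
merge_adjacent_groups <- function(values, bin, q, config, split, seed) {
  n_bins <- nrow(config$age_bins)
  if (!split) return(rep(1L, n_bins))
  groups <- seq_len(n_bins)
  g <- 1L
  groups[1] <- g
  for (b in 2:n_bins) {
    x <- values[bin == b - 1]
    y <- values[bin == b]
    p <- pairwise_quantile_test(x, y, q, config$n_perm,
                                derive_seed(seed, b))
    if (p >= config$alpha) {
      groups[b] <- g
    } else {
      g <- g + 1L
      groups[b] <- g
    }
  }
  groups
}

pairwise_quantile_test <- function(x, y, q, n_perm, seed) {
  obs <- abs(percentile_cutoff(x, q) - percentile_cutoff(y, q))
  pooled <- sort(c(x, y))  # canonical order for a sample-order-free stream
  nx <- length(x)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), nx)
      abs(percentile_cutoff(pooled[idx], q) -
            percentile_cutoff(pooled[-idx], q))
    }, numeric(1))
  })
  (1 + sum(null >= obs)) / (n_perm + 1)
}

#' Build a cutoff table from a reference cohort
#'
#' Per analyte: trim extremes, test age dependency of the target percentile,
#' then emit either one pooled rule or per-merged-group rules. Pseudouridine
#' additionally receives a lower cutoff at the configured lower percentile
#' (its age test is run on the lower percentile as well; a split on either
#' side splits the rule). The emitted table validates against the registry's
#' cutoff invariants and is written in the same dialect [load_panel()] reads.
#'
#' @param cohort long data.frame from [generate_cohort()] (`sample_id`,
#'   `age`, `analyte`, `value`)
#' @param config a [cutoff_config()]
#' @param registry a `panel_registry`
#' @param lower_analytes analytes that also get a lower cutoff
#' @param seed RNG seed for the age tests
#' @return data.frame in the panel cutoff dialect (`analyte`, `age_min`,
#'   `age_max`, `lower`, `upper`, `detection_is_abnormal`) plus a
#'   `p_value` column
#' @export
build_cutoff_table <- function(cohort, config = cutoff_config(), registry,
                               lower_analytes = "Pseudouridine", seed = 1L) {
  stopifnot(inherits(registry, "panel_registry"),
            all(c("age", "analyte", "value") %in% names(cohort)))
  an <- registry$analytes
  panel_analytes <- an$analyte[!an$is_internal_standard]
  missing <- setdiff(panel_analytes, unique(cohort$analyte))
  missing <- setdiff(missing, "Allopurinol")  # normally-absent marker
  if (length(missing)) {
    stop("cohort lacks panel analyte(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  rows <- list()
  for (a in intersect(panel_analytes, unique(cohort$analyte))) {
    sub <- cohort[cohort$analyte == a, ]
    if (a == "Allopurinol" || all(sub$value == 0)) {
      rows[[a]] <- data.frame(analyte = a, age_min = 0, age_max = 18,
                              lower = NA_real_, upper = NA_real_,
                              detection_is_abnormal = TRUE, p_value = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    keep <- sub$value <= quantile(sub$value, config$trim_quantile,
                                  names = FALSE, type = 7)
    vals <- sub$value[keep]
    ages <- sub$age[keep]

    test <- test_age_dependency(vals, ages, config,
                                q = config$upper_quantile,
                                seed = derive_seed(seed, match(a, panel_analytes)))
    groups <- test$groups
    wants_lower <- a %in% lower_analytes
    if (wants_lower) {
      test_lo <- test_age_dependency(vals, ages, config,
                                     q = config$lower_quantile,
                                     seed = derive_seed(seed, 500L +
                                                          match(a, panel_analytes)))
      if (test_lo$split && !test$split) groups <- test_lo$groups
    }
    override <- config$clinical_override[[a]]
    if (identical(override, "merge")) groups <- rep(1L, nrow(config$age_bins))

    bin <- assign_bins(ages, config$age_bins)
    for (g in unique(groups)) {
      bins_g <- which(groups == g)
      in_g <- bin %in% bins_g
      rows[[paste(a, g)]] <- data.frame(
        analyte = a,
        age_min = config$age_bins[min(bins_g), 1],
        age_max = config$age_bins[max(bins_g), 2],
        lower = if (wants_lower)
          percentile_cutoff(vals[in_g], config$lower_quantile) else NA_real_,
        upper = percentile_cutoff(vals[in_g], config$upper_quantile),
        detection_is_abnormal = FALSE,
        p_value = test$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cutoff table in the panel dialect
#'
#' @param cutoffs data.frame from [build_cutoff_table()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cutoff_table <- function(cutoffs, path) {
  out <- data.frame(
    analyte = cutoffs$analyte, age_min = cutoffs$age_min,
    age_max = cutoffs$age_max,
    lower = ifelse(is.na(cutoffs$lower), "", format(cutoffs$lower)),
    upper = ifelse(cutoffs$detection_is_abnormal, "n.d.",
                   format(cutoffs$upper)),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
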