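# Synthetic data generation --------------------------------------------------
#
# Desk-scale emulation of every input the pipeline consumes: MRM chromatogram
# traces (Gaussian peaks on noisy baselines inside the 3-min acquisition
# window), the 10-level calibrator series, a pediatric reference cohort with
# age-dependent log-normal marker distributions, and per-disorder
# pathological urine profiles. All generators are deterministic for a fixed
# seed. Response factors, peak widths and retention times are fictional
# fixtures: the published assay prints none of them.

PEAK_SIGMA_MIN <- 0.05        # common Gaussian peak sigma (min)
TRACE_DT_MIN <- 0.005         # sampling interval of synthetic traces (min)
VIAL_DILUTION <- 5            # pre-preparation scale -> vial scale (100/500)
IS_VIAL_UM <- 5               # every prepared sample carries 5 uM IS
DEFAULT_RESPONSE_FACTOR <- 5e5   # counts per uM (vial scale)
DEFAULT_NOISE_FRACTION <- 0.1    # baseline SD relative to the Cal02 peak height
CALIBRATOR_UM <- c(0, 2^(0:8))   # Cal01..Cal10 pre-preparation concentrations

#' Describe one simulated injection
#'
#' @param concentrations named numeric vector, uM on the pre-preparation
#'   calibrator scale, one entry per analyte to simulate
#' @param sample_label label written into the `sample` column of the traces
#' @param noise_sd baseline noise SD in counts; the default scales
#'   [DEFAULT_NOISE_FRACTION] of the Cal02 (1 uM) peak height
#' @param response_factor counts per uM of vial-scale concentration; scalar
#'   or named per-analyte vector
#' @param peak_sigma Gaussian peak sigma in minutes
#' @param seed RNG seed for the baseline noise
#' @return a `run_design` list
#' @export
run_design <- function(concentrations, sample_label = "sample",
                       noise_sd = NULL, response_factor = DEFAULT_RESPONSE_FACTOR,
                       peak_sigma = PEAK_SIGMA_MIN, seed = 1L) {
  stopifnot(is.numeric(concentrations), all(concentrations >= 0),
            all(response_factor > 0), peak_sigma > 0)
  if (is.null(names(concentrations)) && length(concentrations)) {
    stop("concentrations must be a named vector (analyte -> uM)",
         call. = FALSE)
  }
  if (is.null(noise_sd)) {
    noise_sd <- DEFAULT_NOISE_FRACTION * mean(response_factor) / VIAL_DILUTION
  }
  stopifnot(noise_sd >= 0)
  structure(list(sample_label = sample_label,
                 concentrations = concentrations, noise_sd = noise_sd,
                 response_factor = response_factor, peak_sigma = peak_sigma,
                 seed = as.integer(seed)),
            class = "run_design")
}

rf_for <- function(design, analyte) {
  rf <- design$response_factor
  if (length(rf) == 1 && is.null(names(rf))) return(rf)
  out <- rf[analyte]
  if (is.na(out)) stop("no response factor for '", analyte, "'", call. = FALSE)
  unname(out)
}

gaussian_channel <- function(rt, height, sigma, noise_sd) {
  times <- seq(rt - 1.5, rt + 1.5, by = TRACE_DT_MIN)
  signal <- height * exp(-(times - rt)^2 / (2 * sigma^2))
  if (noise_sd > 0) {
    # noisy channels ride on a positive baseline at 4 SD so that the
    # truncation at zero counts stays a rare event, as on a real detector
    signal <- signal + 4 * noise_sd + rnorm(length(times), 0, noise_sd)
  }
  data.frame(time_min = times, intensity = pmax(signal, 0))
}

#' Simulate the MRM chromatogram of one injection
#'
#' Each analyte named in the design gets a quantifier and a qualifier channel
#' (qualifier at a fixed 0.35 ion ratio); every internal standard in the
#' registry always contributes its `IS-quantifier`/`IS-qualifier` channels at
#' the fixed 5 uM vial concentration. Peaks are Gaussian, centered at the
#' registry retention time, with height `response_factor * vial
#' concentration`, on an i.i.d. Gaussian baseline truncated at zero.
#'
#' @param design a [run_design()]
#' @param registry a `panel_registry`
#' @return long-format data.frame: `sample`, `analyte`, `channel_role`,
#'   `time_min`, `intensity`
#' @export
generate_chromatogram <- function(design, registry) {
  stopifnot(inherits(design, "run_design"), inherits(registry, "panel_registry"))
  an <- registry$analytes
  unknown <- setdiff(names(design$concentrations), an$analyte)
  if (length(unknown)) {
    stop("analyte(s) not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  with_seed(design$seed, {
    pieces <- list()
    for (a in names(design$concentrations)) {
      height <- rf_for(design, a) *
        design$concentrations[[a]] / VIAL_DILUTION
      rt <- channel_rt(registry, a)
      for (role in c("quantifier", "qualifier")) {
        h <- if (role == "qualifier") 0.35 * height else height
        ch <- gaussian_channel(rt, h, design$peak_sigma, design$noise_sd)
        ch$sample <- design$sample_label
        ch$analyte <- a
        ch$channel_role <- role
        pieces[[length(pieces) + 1L]] <- ch
      }
    }
    is_names <- an$analyte[an$is_internal_standard]
    for (a in is_names) {
      height <- rf_for(design, a) * IS_VIAL_UM
      rt <- channel_rt(registry, a)
      roles <- unique(registry$transitions$role[registry$transitions$analyte == a])
      for (role in roles) {
        h <- if (role == "qualifier") 0.35 * height else height
        ch <- gaussian_channel(rt, h, design$peak_sigma, design$noise_sd)
        ch$sample <- design$sample_label
        ch$analyte <- a
        ch$channel_role <- paste0("IS-", role)
        pieces[[length(pieces) + 1L]] <- ch
      }
    }
    out <- do.call(rbind, pieces)
    out[, c("sample", "analyte", "channel_role", "time_min", "intensity")]
  })
}

#' Extract one channel of a long-format trace table
#'
#' @param traces data.frame from [generate_chromatogram()] or [read_traces()]
#' @param analyte analyte (or internal standard) name
#' @param channel_role `"quantifier"`, `"qualifier"`, `"IS-quantifier"` or
#'   `"IS-qualifier"`; quantifier requests on an IS channel are resolved to
#'   the `IS-` prefixed role automatically
#' @param sample optional sample label filter
#' @return data.frame with `time_min`, `intensity`, time-sorted
#' @export
get_channel <- function(traces, analyte, channel_role = "quantifier",
                        sample = NULL) {
  sel <- traces$analyte == analyte
  if (!is.null(sample)) sel <- sel & traces$sample == sample
  roles <- unique(traces$channel_role[sel])
  if (!(channel_role %in% roles) && paste0("IS-", channel_role) %in% roles) {
    channel_role <- paste0("IS-", channel_role)
  }
  sel <- sel & traces$channel_role == channel_role
  if (!any(sel)) {
    stop("no channel '", channel_role, "' for analyte '", analyte, "'",
         call. = FALSE)
  }
  out <- traces[sel, c("time_min", "intensity")]
  out[order(out$time_min), ]
}

#' Simulate the ten-level calibrator series
#'
#' Pre-preparation concentrations follow the published design: Cal01 = 0 uM
#' and Cal02..Cal10 = 1, 2, 4, ..., 256 uM for every non-IS analyte.
#' `noise` applies a multiplicative log-normal-free jitter to peak heights
#' (relative SD), emulating injection-to-injection response variability, on
#' top of the additive baseline noise.
#'
#' @param registry a `panel_registry`
#' @param noise relative (fractional) response noise, e.g. 0.02 for 2%
#' @param seed RNG seed
#' @param analytes analytes to include; defaults to all non-IS analytes
#' @param baseline_noise_sd additive baseline SD in counts (0 = noiseless)
#' @return list with `designs` (list of `run_design`) and `traces` (long df)
#' @export
generate_calibrator_series <- function(registry, noise = 0, seed = 1L,
                                       analytes = NULL,
                                       baseline_noise_sd = 0) {
  stopifnot(noise >= 0)
  an <- registry$analytes
  if (is.null(analytes)) analytes <- an$analyte[!an$is_internal_standard]
  designs <- list()
  traces <- list()
  for (k in seq_along(CALIBRATOR_UM)) {
    label <- sprintf("Cal%02d", k)
    conc <- rep(CALIBRATOR_UM[k], length(analytes))
    names(conc) <- analytes
    level_seed <- derive_seed(seed, k)
    jitter <- with_seed(derive_seed(level_seed, 1000L), {
      if (noise > 0) rnorm(length(analytes), 1, noise) else rep(1, length(analytes))
    })
    rf <- DEFAULT_RESPONSE_FACTOR * pmax(jitter, 0)
    names(rf) <- analytes
    rf_full <- c(rf, structure(rep(DEFAULT_RESPONSE_FACTOR,
                                   sum(an$is_internal_standard)),
                               names = an$analyte[an$is_internal_standard]))
    d <- run_design(conc, sample_label = label,
                    noise_sd = baseline_noise_sd,
                    response_factor = rf_full, seed = level_seed)
    designs[[label]] <- d
    traces[[label]] <- generate_chromatogram(d, registry)
  }
  list(designs = designs, traces = do.call(rbind, traces))
}

# Default cohort model: log-normal per analyte, median at 1/4 of the
# age-resolved upper cutoff and sdlog = log(4)/qnorm(0.975), so that the true
# 97.5th percentile equals the bundled cutoff. Pseudouridine (two-sided
# interval) uses the geometric midpoint of its bounds with sdlog chosen so
# the 2.5th/97.5th percentiles hit the bounds. Allopurinol (normally absent)
# is identically zero.
default_cohort_params <- function(registry) {
  co <- registry$cutoffs
  an <- registry$analytes
  co <- co[co$analyte %in% an$analyte[!an$is_internal_standard], ]
  z <- qnorm(0.975)
  rows <- lapply(seq_len(nrow(co)), function(i) {
    r <- co[i, ]
    if (r$detection_is_abnormal) {
      meanlog <- -Inf; sdlog <- 0       # degenerate: value 0
    } else if (!is.na(r$lower)) {
      meanlog <- log(sqrt(r$lower * r$upper))
      sdlog <- log(r$upper / r$lower) / (2 * z)
    } else {
      meanlog <- log(r$upper / 4)
      sdlog <- log(4) / z
    }
    data.frame(analyte = r$analyte, age_min = r$age_min, age_max = r$age_max,
               meanlog = meanlog, sdlog = sdlog, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Specify a synthetic reference cohort
#'
#' @param n number of urine samples (the published reference set used 251)
#' @param seed RNG seed
#' @param age_weights sampling weights of the four age bins
#'   `[0,1), [1,3), [3,6), [6,18]`; ages are uniform within a bin
#' @param params optional data.frame `analyte, age_min, age_max, meanlog,
#'   sdlog` overriding the default log-normal model (which centers each
#'   analyte at 1/4 of its age-resolved cutoff; see vignette)
#' @return a `cohort_spec`
#' @export
cohort_spec <- function(n = 251, seed = 1L,
                        age_weights = c(0.25, 0.25, 0.25, 0.25),
                        params = NULL) {
  stopifnot(n >= 1, length(age_weights) == 4, all(age_weights >= 0))
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 age_weights = age_weights / sum(age_weights),
                 params = params),
            class = "cohort_spec")
}

draw_ages <- function(n, age_weights) {
  bins <- matrix(c(0, 1, 1, 3, 3, 6, 6, 18), ncol = 2, byrow = TRUE)
  idx <- sample.int(4, n, replace = TRUE, prob = age_weights)
  runif(n, bins[idx, 1], bins[idx, 2])
}

lookup_params <- function(params, analyte, age) {
  rows <- params[params$analyte == analyte, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  hit <- rows$age_min <= age & (age < rows$age_max |
                                  (age == 18 & rows$age_max == 18))
  rows[which(hit)[1], ]
}

#' Generate a synthetic pediatric reference cohort
#'
#' Draws `n` samples with ages from the bin mixture and, for every non-IS
#' analyte, a log-normal concentration whose location may depend on age.
#'
#' @param spec a [cohort_spec()]
#' @param registry a `panel_registry`
#' @return long data.frame: `sample_id`, `age`, `analyte`, `value`
#'   (mmol/mol creatinine)
#' @export
generate_cohort <- function(spec, registry) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(registry, "panel_registry"))
  params <- spec$params %||% default_cohort_params(registry)
  an <- registry$analytes
  analytes <- intersect(an$analyte[!an$is_internal_standard],
                        unique(params$analyte))
  with_seed(spec$seed, {
    ages <- draw_ages(spec$n, spec$age_weights)
    out <- vector("list", length(analytes))
    for (j in seq_along(analytes)) {
      a <- analytes[j]
      rows <- params[params$analyte == a, , drop = FALSE]
      vals <- numeric(spec$n)
      for (r in seq_len(nrow(rows))) {
        p <- rows[r, ]
        hit <- ages >= p$age_min &
          (ages < p$age_max | (p$age_max == 18 & ages == 18))
        if (!any(hit)) next
        vals[hit] <- if (!is.finite(p$meanlog)) 0
          else if (p$sdlog == 0) exp(p$meanlog)
          else rlnorm(sum(hit), p$meanlog, p$sdlog)
      }
      out[[j]] <- data.frame(sample_id = sprintf("N%04d", seq_len(spec$n)),
                             age = ages, analyte = a, value = vals,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' A single urine profile
#'
#' @param values named numeric vector, mmol/mol creatinine per analyte
#' @param age age in years
#' @param sample_id label
#' @param allopurinol_detected whether an allopurinol peak was found
#' @return a `urine_profile`
#' @export
urine_profile <- function(values, age, sample_id = "sample",
                          allopurinol_detected = NULL) {
  stopifnot(is.numeric(values), !is.null(names(values)), all(values >= 0))
  if (is.null(allopurinol_detected)) {
    allopurinol_detected <- isTRUE(values["Allopurinol"] > 0)
  }
  if (age < 0) stop("age must be non-negative", call. = FALSE)
  if (age > 18) {
    warning("age ", age, " above 18 y: adult sample, >1y cutoffs will apply")
  }
  structure(list(sample_id = sample_id, age = age, values = values,
                 allopurinol_detected = allopurinol_detected),
            class = "urine_profile")
}

#' Generate a pathological urine profile for one disorder
#'
#' All analytes are first drawn from the normal cohort model at the given
#' age; the signature's `required_high` markers are then forced to
#' `fold x` their age-resolved upper cutoff and `required_low` markers to
#' `lower bound / fold`.
#'
#' @param disorder_code signature code, e.g. `"ADSL"`
#' @param fold multiple of the cutoff for the required markers (>= 1)
#' @param age age in years
#' @param registry a `panel_registry`
#' @param seed RNG seed for the normal background draws
#' @return a `urine_profile`
#' @examples
#' reg <- load_panel()
#' p <- generate_patient_profile("ADSL", fold = 5, age = 6, registry = reg)
#' p$values[c("SAICAr", "Succinyladenosine")]
#' @export
generate_patient_profile <- function(disorder_code, fold = 5, age = 6,
                                     registry, seed = 1L) {
  stopifnot(inherits(registry, "panel_registry"), fold >= 1)
  sig <- registry$signatures[[disorder_code]]
  if (is.null(sig)) {
    stop("unknown disorder code '", disorder_code, "'", call. = FALSE)
  }
  params <- default_cohort_params(registry)
  an <- registry$analytes
  analytes <- an$analyte[!an$is_internal_standard]
  values <- with_seed(seed, {
    vapply(analytes, function(a) {
      p <- lookup_params(params, a, age)
      if (is.null(p) || !is.finite(p$meanlog)) return(0)
      if (p$sdlog == 0) exp(p$meanlog) else rlnorm(1, p$meanlog, p$sdlog)
    }, numeric(1))
  })
  names(values) <- analytes
  for (a in sig$required_high) {
    rule <- get_cutoff(registry, a, age)
    if (rule$detection_is_abnormal) {
      values[a] <- fold  # any positive amount is abnormal
    } else {
      values[a] <- fold * rule$upper
    }
  }
  for (a in sig$required_low) {
    rule <- get_cutoff(registry, a, age)
    if (!is.na(rule$lower)) values[a] <- rule$lower / fold
  }
  urine_profile(values, age = age,
                sample_id = paste0("synthetic-", disorder_code))
}
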