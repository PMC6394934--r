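# Assay-validation statistics -------------------------------------------------
#
# Definitional thresholds of the validated assay:
#   LOD   — lowest concentration with S/N = 3
#   LLOQ  — lowest concentration measured with CV < 20%
#   ULOQ  — upper end of the range with linear response (R^2 > 0.99)
#   Rs    — chromatographic resolution 1.18 (t2 - t1) / (w0.5,1 + w0.5,2),
#           baseline resolution at Rs >= 1.5
# CVs use the sample (n - 1) standard deviation throughout: replicate counts
# are small (n = 10 in the QC design).

#' Chromatographic resolution of two peaks
#'
#' `Rs = 1.18 (t2 - t1) / (w1 + w2)` with `w` the peak widths at half
#' height. `Rs >= 1.5` is baseline resolution.
#'
#' @param t1,t2 retention times (min), `t2 >= t1`
#' @param w1,w2 widths at half height (min), both > 0
#' @return Rs (dimensionless)
#' @examples
#' resolution(5.0, 5.5, 0.2, 0.2)  # 1.475
#' @export
resolution <- function(t1, t2, w1, w2) {
  if (any(c(w1, w2) <= 0)) stop("peak widths must be positive", call. = FALSE)
  if (t2 < t1) stop("t2 must be >= t1", call. = FALSE)
  1.18 * (t2 - t1) / (w1 + w2)
}

#' Resolution of the panel's critical analyte pairs
#'
#' Simulates a noiseless default injection, integrates the two channels of
#' every critical pair listed in the registry and applies [resolution()].
#'
#' @param registry a `panel_registry`
#' @param conc_uM concentration used for analyte channels (uM)
#' @return data.frame: `pair_id`, `t1`, `t2`, `w1`, `w2`, `Rs`,
#'   `baseline_resolved`
#' @export
critical_pair_resolution <- function(registry, conc_uM = 16) {
  cp <- registry$critical_pairs
  if (!nrow(cp)) {
    return(data.frame(pair_id = character(), t1 = numeric(), t2 = numeric(),
                      w1 = numeric(), w2 = numeric(), Rs = numeric(),
                      baseline_resolved = logical()))
  }
  an <- registry$analytes
  targets <- unique(c(cp$analyte_1, cp$analyte_2))
  conc_targets <- setdiff(targets, an$analyte[an$is_internal_standard])
  conc <- rep(conc_uM, length(conc_targets))
  names(conc) <- conc_targets
  design <- run_design(conc, sample_label = "critical-pairs", noise_sd = 0)
  traces <- generate_chromatogram(design, registry)

  rows <- lapply(seq_len(nrow(cp)), function(i) {
    p1 <- integrate_peak(get_channel(traces, cp$analyte_1[i], cp$channel_1[i]),
                         channel_rt(registry, cp$analyte_1[i]))
    p2 <- integrate_peak(get_channel(traces, cp$analyte_2[i], cp$channel_2[i]),
                         channel_rt(registry, cp$analyte_2[i]))
    ts <- sort(c(p1$retention_time, p2$retention_time))
    rs <- resolution(ts[1], ts[2], p1$width_at_half_height,
                     p2$width_at_half_height)
    data.frame(pair_id = cp$pair_id[i], t1 = ts[1], t2 = ts[2],
               w1 = p1$width_at_half_height, w2 = p2$width_at_half_height,
               Rs = rs, baseline_resolved = rs >= 1.5,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Limit of detection from a dilution series
#'
#' Returns the lowest concentration whose signal-to-noise ratio reaches 3.
#' With `interpolate = TRUE` the crossing is linearly interpolated between
#' the bracketing levels and flagged as such.
#'
#' @param series data.frame with columns `conc` (uM) and `snr`, sorted by
#'   concentration
#' @param interpolate interpolate between bracketing levels?
#' @return list: `lod` (uM), `interpolated`, `below_range` (all levels
#'   already above S/N 3). When no level reaches S/N 3, `lod` is `NA` and
#'   `undefined` is `TRUE`.
#' @export
determine_lod <- function(series, interpolate = FALSE) {
  stopifnot(is.data.frame(series), all(c("conc", "snr") %in% names(series)))
  series <- series[order(series$conc), ]
  ok <- series$snr >= SNR_FOUND
  if (!any(ok)) {
    return(list(lod = NA_real_, interpolated = FALSE, below_range = FALSE,
                undefined = TRUE))
  }
  first <- which(ok)[1]
  if (first == 1L) {
    return(list(lod = series$conc[1], interpolated = FALSE,
                below_range = TRUE, undefined = FALSE))
  }
  if (interpolate) {
    lod <- approx(x = series$snr[c(first - 1L, first)],
                  y = series$conc[c(first - 1L, first)],
                  xout = SNR_FOUND)$y
    return(list(lod = lod, interpolated = TRUE, below_range = FALSE,
                undefined = FALSE))
  }
  list(lod = series$conc[first], interpolated = FALSE, below_range = FALSE,
       undefined = FALSE)
}

cv_pct <- function(x) 100 * sd(x) / mean(x)

#' Lower limit of quantitation from replicate measurements
#'
#' The lowest level measured with CV below 20%. If a low level qualifies but
#' a higher one fails (non-monotone precision), the lowest qualifying level
#' above the highest failing level is returned and flagged.
#'
#' @param replicates named list: level (uM, as names) -> numeric vector of
#'   measured concentrations (>= 3 replicates each)
#' @param cv_limit CV threshold in percent (default 20)
#' @return list: `lloq` (uM, `NA` when undefined), `cv_by_level`,
#'   `non_monotone`, `undefined`
#' @export
determine_lloq <- function(replicates, cv_limit = 20) {
  stopifnot(is.list(replicates), length(replicates) >= 1)
  if (any(vapply(replicates, length, integer(1)) < 2)) {
    stop("every level needs >= 2 replicates to compute a CV", call. = FALSE)
  }
  conc <- as.numeric(names(replicates))
  if (any(is.na(conc))) stop("replicate list must be named by concentration",
                             call. = FALSE)
  ord <- order(conc)
  conc <- conc[ord]
  cvs <- vapply(replicates[ord], cv_pct, numeric(1))
  ok <- cvs < cv_limit
  if (!any(ok)) {
    return(list(lloq = NA_real_, cv_by_level = setNames(cvs, conc),
                non_monotone = FALSE, undefined = TRUE))
  }
  last_fail <- if (any(!ok)) max(which(!ok)) else 0L
  non_monotone <- any(ok[seq_len(last_fail)])
  candidates <- which(ok & seq_along(ok) > last_fail)
  if (!length(candidates)) {
    return(list(lloq = NA_real_, cv_by_level = setNames(cvs, conc),
                non_monotone = non_monotone, undefined = TRUE))
  }
  list(lloq = conc[candidates[1]], cv_by_level = setNames(cvs, conc),
       non_monotone = non_monotone, undefined = FALSE)
}

#' Upper limit of quantitation from a calibration series
#'
#' The largest level `L` such that the calibration fit over all levels up to
#' `L` keeps `R^2 > 0.99`.
#'
#' @param series data.frame with columns `nominal` (uM) and `ratio`
#' @param r2_limit linearity threshold (default 0.99)
#' @return list: `uloq` (uM, `NA` when no prefix of >= 3 non-zero levels
#'   qualifies), `r2_by_level`, `undefined`
#' @export
determine_uloq <- function(series, r2_limit = 0.99) {
  stopifnot(is.data.frame(series), all(c("nominal", "ratio") %in% names(series)))
  use <- series[series$nominal > 0, ]
  use <- use[order(use$nominal), ]
  if (nrow(use) < 3) stop("need at least 3 non-zero levels", call. = FALSE)
  r2 <- rep(NA_real_, nrow(use))
  for (i in 3:nrow(use)) {
    r2[i] <- fit_calibration(use[1:i, ])$r_squared
  }
  ok <- which(!is.na(r2) & r2 > r2_limit)
  if (!length(ok)) {
    return(list(uloq = NA_real_,
                r2_by_level = setNames(r2, use$nominal), undefined = TRUE))
  }
  list(uloq = use$nominal[max(ok)],
       r2_by_level = setNames(r2, use$nominal), undefined = FALSE)
}

#' Precision and recovery of replicate QC measurements
#'
#' @param measured numeric vector of replicate measured concentrations (uM)
#' @param nominal nominal concentration (uM), > 0 for recovery
#' @param design label: `"interday"`, `"intraday"` or `"injection"`
#' @return list: `cv_pct` (100 sd/mean, n-1 denominator), `recovery_pct`
#'   (100 mean/nominal), `n`, `design`
#' @examples
#' precision_and_recovery(c(19, 20, 21), nominal = 20)
#' @export
precision_and_recovery <- function(measured, nominal,
                                   design = c("interday", "intraday",
                                              "injection")) {
  design <- match.arg(design)
  if (length(measured) < 2) stop("need >= 2 replicates", call. = FALSE)
  if (nominal <= 0) stop("recovery undefined for nominal <= 0", call. = FALSE)
  list(cv_pct = cv_pct(measured),
       recovery_pct = 100 * mean(measured) / nominal,
       n = length(measured), design = design)
}

#' Storage-stability check across conditions
#'
#' Stability holds when the CV across storage conditions stays below 15%.
#'
#' @param timepoint_measurements named numeric vector: condition -> measured
#'   concentration (uM)
#' @param cv_limit percent threshold (default 15)
#' @return list: `cv_pct`, `pass`
#' @export
stability_check <- function(timepoint_measurements, cv_limit = 15) {
  if (length(timepoint_measurements) < 2) {
    stop("need measurements from >= 2 storage conditions", call. = FALSE)
  }
  cv <- cv_pct(timepoint_measurements)
  list(cv_pct = cv, pass = cv < cv_limit)
}

#' Assemble a per-analyte validation report
#'
#' @param analyte analyte name
#' @param lod,lloq,uloq limits in uM (NA when undefined)
#' @param r_squared linearity of the full calibration
#' @param cv_interday,cv_intraday,cv_injection precision CVs in percent
#' @param recovery recovery in percent
#' @param resolution_entries optional data.frame from
#'   [critical_pair_resolution()]
#' @return a `validation_report` list; construction fails when the limits
#'   are not ordered `lod <= lloq <= uloq`
#' @export
validation_report <- function(analyte, lod = NA, lloq = NA, uloq = NA,
                              r_squared = NA, cv_interday = NA,
                              cv_intraday = NA, cv_injection = NA,
                              recovery = NA, resolution_entries = NULL) {
  lims <- c(lod, lloq, uloq)
  def <- !is.na(lims)
  if (sum(def) >= 2 && is.unsorted(lims[def])) {
    stop("limits must satisfy lod <= lloq <= uloq", call. = FALSE)
  }
  cvs <- c(cv_interday, cv_intraday, cv_injection)
  if (any(!is.na(cvs) & cvs < 0)) stop("CVs must be >= 0", call. = FALSE)
  structure(list(analyte = analyte, lod = lod, lloq = lloq, uloq = uloq,
                 r_squared = r_squared, cv_interday = cv_interday,
                 cv_intraday = cv_intraday, cv_injection = cv_injection,
                 recovery = recovery,
                 resolution_entries = resolution_entries),
            class = "validation_report")
}
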