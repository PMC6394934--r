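# Peak detection, integration and internal-standard calibration --------------
#
# Apex search happens inside the acquisition window (expected retention time
# +/- 1.5 min). The baseline and its noise are estimated from the window
# margins (outer 10% on each side); the noise SD uses the MAD with the
# Gaussian consistency factor 1.4826 so a peak shoulder entering a margin
# does not inflate it. A peak is "found" when the baseline-subtracted apex
# reaches 3x the noise SD — the same S/N = 3 rule that defines the LOD.

PEAK_BOUND_FRACTION <- 0.05   # integration bounds: descent to 5% of apex
SNR_FOUND <- 3                # detection threshold (S/N = 3)
ION_RATIO_TARGET <- 0.35      # generator's qualifier/quantifier ratio
ION_RATIO_TOL <- 0.30         # +/- 30% relative acceptance window

#' Integrate one MRM peak
#'
#' @param trace data.frame with `time_min` and `intensity` columns (one
#'   channel), or a two-column data.frame in that order
#' @param expected_rt expected retention time (min)
#' @param window_halfwidth half-width of the acquisition window (min); the
#'   assay acquires within retention time +/- 1.5 min
#' @param search_halfwidth half-width of the apex search region around
#'   `expected_rt` (min); retention times are stable in the validated
#'   assay, and a narrow search keeps baseline noise extremes from
#'   masquerading as peaks
#' @return a `peak_result` list: `retention_time`, `height`, `area`,
#'   `width_at_half_height`, `baseline`, `noise_sd`, `snr`, `found`
#' @examples
#' t <- seq(3, 6, by = 0.005)
#' tr <- data.frame(time_min = t,
#'                  intensity = 1e6 * exp(-(t - 4.5)^2 / (2 * 0.05^2)))
#' integrate_peak(tr, expected_rt = 4.5)$area  # ~ 1e6 * 0.05 * sqrt(2*pi)
#' @export
integrate_peak <- function(trace, expected_rt, window_halfwidth = 1.5,
                           search_halfwidth = 0.25) {
  if (is.null(dim(trace)) || nrow(trace) == 0) {
    stop("empty trace", call. = FALSE)
  }
  time <- trace$time_min %||% trace[[1]]
  intensity <- trace$intensity %||% trace[[2]]
  ord <- order(time)
  time <- time[ord]; intensity <- intensity[ord]

  in_win <- time >= expected_rt - window_halfwidth &
    time <= expected_rt + window_halfwidth
  if (sum(in_win) < 5) {
    stop("search window [", expected_rt - window_halfwidth, ", ",
         expected_rt + window_halfwidth, "] outside trace time range",
         call. = FALSE)
  }
  t <- time[in_win]; y <- intensity[in_win]
  n <- length(t)

  # margins: outer 10% of points on each side
  m <- max(3L, ceiling(0.1 * n))
  margin <- c(y[seq_len(m)], y[seq.int(n - m + 1L, n)])
  baseline <- median(margin)
  noise_sd <- mad(margin, constant = 1.4826)

  ysub <- y - baseline
  # apex located on a lightly smoothed signal: the raw max over ~600 noise
  # points sits near 3 SD and would defeat the S/N = 3 detection rule
  k <- min(11L, if (n %% 2L) n else n - 1L)
  ysm <- stats::filter(ysub, rep(1 / k, k), sides = 2)
  ysm[is.na(ysm)] <- 0
  sm_margin <- c(ysm[seq_len(m)], ysm[seq.int(n - m + 1L, n)])
  noise_sm <- mad(sm_margin, constant = 1.4826)

  searchable <- abs(t - expected_rt) <= search_halfwidth
  if (!any(searchable)) searchable <- rep(TRUE, n)
  apex_i <- which(searchable)[which.max(ysm[searchable])]
  # raw apex height in the immediate neighbourhood of the smoothed apex
  nb <- max(1L, apex_i - 2L):min(n, apex_i + 2L)
  height <- max(ysub[nb])
  apex_i <- nb[which.max(ysub[nb])]
  snr <- if (noise_sd > 0) height / noise_sd else if (height > 0) Inf else 0
  # detection: the raw apex clears S/N = 3 and the smoothed signal agrees,
  # so single-sample baseline excursions do not count as peaks
  smooth_ok <- if (noise_sm > 0) ysm[apex_i] >= SNR_FOUND * noise_sm else
    ysm[apex_i] > 0
  found <- is.finite(height) && height > 0 && snr >= SNR_FOUND && smooth_ok

  if (!found) {
    return(structure(list(retention_time = NA_real_, height = max(height, 0),
                          area = 0, width_at_half_height = NA_real_,
                          baseline = baseline, noise_sd = noise_sd,
                          snr = max(snr, 0), found = FALSE),
                     class = "peak_result"))
  }

  # integration bounds: walk out from the apex to the descent at 5% of the
  # apex, then follow any remaining monotone decay so a clean Gaussian is
  # integrated to the baseline (the strict 5% cut would clip 1.4% of it)
  walk <- function(dir) {
    i <- apex_i
    repeat {
      j <- i + dir
      if (j < 1L || j > n) break
      if (ysm[j] > PEAK_BOUND_FRACTION * height ||
          (ysm[j] < ysm[i] && ysm[j] > 0)) i <- j else break
    }
    i
  }
  idx <- walk(-1L):walk(1L)
  area <- sum(diff(t[idx]) * (head(ysub[idx], -1) + tail(ysub[idx], -1)) / 2)

  structure(list(retention_time = t[apex_i], height = height, area = area,
                 width_at_half_height = half_height_width(t, ysub, apex_i),
                 baseline = baseline, noise_sd = noise_sd, snr = snr,
                 found = TRUE),
            class = "peak_result")
}

# width at half height with linear interpolation of the crossings
half_height_width <- function(t, y, apex_i) {
  half <- y[apex_i] / 2
  left <- NA_real_
  for (i in seq.int(apex_i, 2L)) {
    if (y[i - 1] <= half && y[i] >= half) {
      left <- t[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) *
        (t[i] - t[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq.int(apex_i, length(t) - 1L)) {
    if (y[i] >= half && y[i + 1] <= half) {
      right <- t[i] + (y[i] - half) / (y[i] - y[i + 1]) * (t[i + 1] - t[i])
      break
    }
  }
  right - left
}

#' @export
print.peak_result <- function(x, ...) {
  if (x$found) {
    cat(sprintf("<peak at %.3f min: height %.3g, area %.3g, FWHM %.4f min, S/N %.1f>\n",
                x$retention_time, x$height, x$area, x$width_at_half_height,
                x$snr))
  } else {
    cat(sprintf("<no peak found (S/N %.2f < %d)>\n", x$snr, SNR_FOUND))
  }
  invisible(x)
}

#' Fit an internal-standard calibration line
#'
#' Ordinary (or 1/x-weighted) least squares of the analyte/IS response ratio
#' on the nominal pre-preparation concentration. The blank level (0 uM) is
#' excluded: it serves the carryover and LOD logic, and with the log-spaced
#' calibrator design it would otherwise dominate leverage.
#'
#' @param levels data.frame with columns `nominal` (uM) and `ratio`
#'   (analyte area / IS area)
#' @param weighting `"none"` (default) or `"1/x"`
#' @return a `calibration_fit`: `slope`, `intercept`, `r_squared`,
#'   `weighting`, `level_range_used`, `n_levels`
#' @export
fit_calibration <- function(levels, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(levels), all(c("nominal", "ratio") %in% names(levels)))
  use <- levels[levels$nominal > 0 & is.finite(levels$ratio), ]
  if (nrow(use) < 3) {
    stop("calibration needs at least 3 non-zero levels", call. = FALSE)
  }
  if (length(unique(use$ratio)) == 1) {
    stop("all responses identical: cannot fit a calibration line",
         call. = FALSE)
  }
  w <- if (weighting == "1/x") 1 / use$nominal else rep(1, nrow(use))
  fit <- lm(ratio ~ nominal, data = use, weights = w)
  ss_res <- sum(w * fit$residuals^2)
  ss_tot <- sum(w * (use$ratio - sum(w * use$ratio) / sum(w))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot,
                 weighting = weighting,
                 level_range_used = range(use$nominal),
                 n_levels = nrow(use)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration: ratio = %.4g * conc %+.4g, R^2 = %.5f, %s weights, %d levels (%g-%g uM)>\n",
              x$slope, x$intercept, x$r_squared, x$weighting, x$n_levels,
              x$level_range_used[1], x$level_range_used[2]))
  invisible(x)
}

#' Read a concentration off the calibration line
#'
#' @param analyte_peak,is_peak `peak_result`s of the analyte quantifier and
#'   its internal-standard channel
#' @param fit a `calibration_fit`
#' @return list: `readout` (uM, pre-preparation scale, floored at 0),
#'   `below_lod` flag
#' @export
quantify <- function(analyte_peak, is_peak, fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (!is_peak$found) {
    stop("internal-standard peak not found: failed injection", call. = FALSE)
  }
  if (!analyte_peak$found) {
    return(list(readout = 0, below_lod = TRUE))
  }
  ratio <- analyte_peak$area / is_peak$area
  list(readout = max((ratio - fit$intercept) / fit$slope, 0),
       below_lod = FALSE)
}

#' Check the qualifier/quantifier ion ratio
#'
#' @param quantifier_peak,qualifier_peak `peak_result`s
#' @param expected expected qualifier/quantifier area ratio
#' @param tolerance relative acceptance half-width (default +/- 30%)
#' @return list: `ratio`, `pass`
#' @export
ion_ratio_check <- function(quantifier_peak, qualifier_peak,
                            expected = ION_RATIO_TARGET,
                            tolerance = ION_RATIO_TOL) {
  if (!quantifier_peak$found || !qualifier_peak$found) {
    return(list(ratio = NA_real_, pass = FALSE))
  }
  ratio <- qualifier_peak$area / quantifier_peak$area
  list(ratio = ratio, pass = abs(ratio - expected) <= tolerance * expected)
}

#' Carryover check on a blank injected after the top calibrator
#'
#' @param blank_traces long-format traces of a blank injection
#' @param registry a `panel_registry`
#' @return data.frame: `analyte`, `snr`, `pass` (pass iff no peak, S/N < 3)
#' @export
carryover_check <- function(blank_traces, registry) {
  stopifnot(inherits(registry, "panel_registry"))
  an <- registry$analytes
  analytes <- intersect(an$analyte[!an$is_internal_standard],
                        unique(blank_traces$analyte))
  if (!length(analytes)) {
    return(data.frame(analyte = character(), snr = numeric(),
                      pass = logical()))
  }
  rows <- lapply(analytes, function(a) {
    ch <- get_channel(blank_traces, a, "quantifier")
    pk <- integrate_peak(ch, channel_rt(registry, a))
    data.frame(analyte = a, snr = pk$snr, pass = !pk$found,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Quantify every analyte of one sample's traces
#'
#' Convenience wrapper chaining [integrate_peak()] and [quantify()] over all
#' non-IS analytes present in the traces.
#'
#' @param traces long-format traces of one injection
#' @param registry a `panel_registry`
#' @param fits named list of `calibration_fit`s (one per analyte)
#' @param prep optional urine `prep_record`; when given, readouts are
#'   back-calculated to mmol/mol creatinine
#' @return data.frame: `analyte`, `readout_uM`, `mmol_per_mol`, `snr`,
#'   `below_lod`
#' @export
quantify_sample <- function(traces, registry, fits, prep = NULL) {
  an <- registry$analytes
  analytes <- intersect(an$analyte[!an$is_internal_standard],
                        unique(traces$analyte))
  rows <- lapply(analytes, function(a) {
    apk <- integrate_peak(get_channel(traces, a, "quantifier"),
                          channel_rt(registry, a))
    is_name <- an$internal_standard[match(a, an$analyte)]
    ipk <- integrate_peak(get_channel(traces, is_name, "quantifier"),
                          channel_rt(registry, is_name))
    q <- quantify(apk, ipk, fits[[a]])
    data.frame(analyte = a, readout_uM = q$readout,
               mmol_per_mol = if (is.null(prep)) NA_real_ else
                 back_calculate(q$readout, prep),
               snr = apk$snr, below_lod = q$below_lod,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit calibration lines for all analytes from a simulated series
#'
#' @param series output of [generate_calibrator_series()]
#' @param registry a `panel_registry`
#' @param weighting passed to [fit_calibration()]
#' @return named list of `calibration_fit`s
#' @export
calibrate_series <- function(series, registry, weighting = "none") {
  an <- registry$analytes
  analytes <- intersect(an$analyte[!an$is_internal_standard],
                        unique(series$traces$analyte))
  fits <- lapply(analytes, function(a) {
    is_name <- an$internal_standard[match(a, an$analyte)]
    lv <- lapply(names(series$designs), function(label) {
      d <- series$designs[[label]]
      nominal <- d$concentrations[[a]]
      if (nominal == 0) return(NULL)
      tr <- series$traces[series$traces$sample == label, ]
      apk <- integrate_peak(get_channel(tr, a, "quantifier"),
                            channel_rt(registry, a))
      ipk <- integrate_peak(get_channel(tr, is_name, "quantifier"),
                            channel_rt(registry, is_name))
      data.frame(nominal = nominal, ratio = apk$area / ipk$area)
    })
    fit_calibration(do.call(rbind, lv), weighting = weighting)
  })
  names(fits) <- analytes
  fits
}
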