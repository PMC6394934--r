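# Sample preparation arithmetic ---------------------------------------------
#
# Every sample is brought to 0.25 mM creatinine in 400 ul (urine diluted with
# water; calibrators/QCs mixed 100 ul + 300 ul synthetic urine of 0.333 mM
# creatinine), then 100 ul of 25 uM internal-standard mix is added, giving
# 500 ul at 0.20 mM creatinine and 5 uM IS. Because the urine aliquot is
# chosen inversely to its creatinine, the calibrator-scale readout of an
# uncapped urine sample *is* its mmol/mol creatinine value; the capped branch
# (very dilute urines) needs the explicit dilution-factor correction.

FIRST_STAGE_VOLUME_UL <- 400
IS_VOLUME_UL <- 100
IS_WORKING_UM <- 25
FIRST_STAGE_CREATININE_MM <- 0.25
SYNTHETIC_URINE_CREATININE_MM <- 0.333

new_prep_record <- function(kind, urine_creatinine = NA_real_,
                            urine_volume = 0, water_volume = 0,
                            synthetic_urine_volume = 0, capped = FALSE) {
  total <- FIRST_STAGE_VOLUME_UL + IS_VOLUME_UL
  first_stage <- if (kind == "urine") {
    urine_creatinine * urine_volume / FIRST_STAGE_VOLUME_UL
  } else {
    SYNTHETIC_URINE_CREATININE_MM * synthetic_urine_volume /
      FIRST_STAGE_VOLUME_UL
  }
  structure(
    list(sample_kind = kind,
         urine_creatinine = urine_creatinine,
         urine_volume = urine_volume,
         water_volume = water_volume,
         synthetic_urine_volume = synthetic_urine_volume,
         is_volume = IS_VOLUME_UL,
         total_volume = total,
         first_stage_creatinine = first_stage,
         final_creatinine = first_stage * FIRST_STAGE_VOLUME_UL / total,
         final_is = IS_WORKING_UM * IS_VOLUME_UL / total,
         capped = capped),
    class = "prep_record"
  )
}

#' Plan the dilution of one urine sample
#'
#' Picks the urine aliquot that brings the first 400 ul stage to 0.25 mM
#' creatinine, fills with water, and adds 100 ul of 25 uM internal standard.
#' Urines below 0.25 mM creatinine cannot reach the target; they are used
#' neat (400 ul) and flagged `capped`, and [back_calculate()] applies the
#' corresponding dilution-factor correction.
#'
#' @param urine_creatinine urinary creatinine in mM (must be > 0)
#' @return a `prep_record`
#' @examples
#' plan_urine_prep(2.0)   # 50 ul urine + 350 ul water
#' @export
plan_urine_prep <- function(urine_creatinine) {
  if (!is.numeric(urine_creatinine) || length(urine_creatinine) != 1 ||
      is.na(urine_creatinine) || urine_creatinine <= 0) {
    stop("urine creatinine must be a single positive number (mM)",
         call. = FALSE)
  }
  target_vol <- FIRST_STAGE_CREATININE_MM * FIRST_STAGE_VOLUME_UL /
    urine_creatinine
  capped <- target_vol >= FIRST_STAGE_VOLUME_UL
  urine_vol <- min(target_vol, FIRST_STAGE_VOLUME_UL)
  new_prep_record("urine", urine_creatinine = urine_creatinine,
                  urine_volume = urine_vol,
                  water_volume = FIRST_STAGE_VOLUME_UL - urine_vol,
                  capped = capped)
}

#' Plan the preparation of a calibrator or QC sample
#'
#' 100 ul of calibrator/QC is mixed with 300 ul synthetic urine (0.333 mM
#' creatinine) and 100 ul internal standard, matching the 0.20 mM / 5 uM
#' final state of urine samples to within 1% and diluting the vial 1:5
#' relative to the pre-preparation calibrator scale.
#'
#' @param kind `"calibrator"` or `"qc"`
#' @return a `prep_record`
#' @export
plan_calibrator_prep <- function(kind = c("calibrator", "qc")) {
  kind <- match.arg(kind)
  new_prep_record(kind, urine_volume = IS_VOLUME_UL,
                  water_volume = 0, synthetic_urine_volume = 300)
}

#' Convert an instrument readout to mmol/mol creatinine
#'
#' The calibration curve reports concentrations on the pre-preparation
#' calibrator scale (uM). For a urine record the urine-level concentration is
#' `readout * 100 / urine_volume` uM, and dividing by the urinary creatinine
#' (mM) yields umol/mmol, i.e. mmol/mol creatinine. For uncapped preps this
#' reduces to the identity `result = readout`.
#'
#' @param readout concentration on the pre-preparation calibrator scale (uM)
#' @param prep a urine `prep_record`
#' @return concentration in mmol/mol creatinine
#' @export
back_calculate <- function(readout, prep) {
  stopifnot(inherits(prep, "prep_record"))
  if (prep$sample_kind != "urine") {
    stop("back_calculate needs a urine prep record, got '",
         prep$sample_kind, "'", call. = FALSE)
  }
  if (any(readout < 0)) stop("readout must be non-negative", call. = FALSE)
  urine_conc <- readout * IS_VOLUME_UL / prep$urine_volume
  urine_conc / prep$urine_creatinine
}

#' @export
print.prep_record <- function(x, ...) {
  cat(sprintf("<prep_record: %s>\n", x$sample_kind))
  if (x$sample_kind == "urine") {
    cat(sprintf("  urine %.1f ul (Cr %.3f mM) + water %.1f ul\n",
                x$urine_volume, x$urine_creatinine, x$water_volume))
  } else {
    cat(sprintf("  vial %.1f ul + synthetic urine %.1f ul\n",
                x$urine_volume, x$synthetic_urine_volume))
  }
  cat(sprintf("  + IS %.0f ul of %.0f uM -> %.0f ul total\n",
              x$is_volume, IS_WORKING_UM, x$total_volume))
  cat(sprintf("  final creatinine %.4f mM, final IS %.2f uM%s\n",
              x$final_creatinine, x$final_is,
              if (x$capped) "  [capped: low-creatinine urine]" else ""))
  invisible(x)
}

#' Bench worksheet for a batch of urine samples
#'
#' @param creatinine_mM named numeric vector of urinary creatinine levels
#' @return data.frame with one pipetting row per sample
#' @export
prep_worksheet <- function(creatinine_mM) {
  recs <- lapply(creatinine_mM, plan_urine_prep)
  data.frame(
    sample = names(creatinine_mM) %||% seq_along(creatinine_mM),
    creatinine_mM = as.numeric(creatinine_mM),
    urine_ul = vapply(recs, `[[`, numeric(1), "urine_volume"),
    water_ul = vapply(recs, `[[`, numeric(1), "water_volume"),
    is_ul = IS_VOLUME_UL,
    capped = vapply(recs, `[[`, logical(1), "capped"),
    stringsAsFactors = FALSE
  )
}
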