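# Rule-based disorder screening ----------------------------------------------
#
# Interpretation mirrors the fold-over-cutoff presentation of the assay's
# proficiency-testing results: each marker is expressed as its multiple of
# the age-resolved upper cutoff, a signature matches when every required
# marker exceeds its cutoff (fold > 1), and matches are ranked by (number of
# required markers matched, maximal fold). Allopurinol therapy is a known
# confound: it elevates orotidine (and orotic acid), which then must not by
# itself support an orotic-aciduria (UMPS) call.

#' Fold over cutoff for every analyte of a profile
#'
#' @param profile a [urine_profile()]
#' @param registry a `panel_registry`
#' @return data.frame: `analyte`, `value`, `upper`, `lower`, `fold`
#'   (value/upper), `direction` (`"high"`, `"low"`, `"normal"` or
#'   `"detected"` for detection-is-abnormal analytes)
#' @export
fold_over_cutoff <- function(profile, registry) {
  stopifnot(inherits(profile, "urine_profile"),
            inherits(registry, "panel_registry"))
  age <- min(profile$age, 18)  # adults: nearest (oldest) bin with a warning
  an <- registry$analytes
  panel <- an$analyte[!an$is_internal_standard]
  present <- intersect(panel, names(profile$values))
  absent <- setdiff(panel, names(profile$values))
  if (length(absent)) {
    warning("profile ", profile$sample_id, " lacks analyte(s): ",
            paste(absent, collapse = ", "))
  }
  rows <- lapply(present, function(a) {
    rule <- get_cutoff(registry, a, age)
    value <- unname(profile$values[a])
    if (rule$detection_is_abnormal) {
      return(data.frame(analyte = a, value = value, upper = NA_real_,
                        lower = NA_real_, fold = NA_real_,
                        direction = if (value > 0) "detected" else "normal",
                        stringsAsFactors = FALSE))
    }
    fold <- value / rule$upper
    direction <- if (fold > 1) "high"
      else if (!is.na(rule$lower) && value < rule$lower) "low"
      else "normal"
    data.frame(analyte = a, value = value, upper = rule$upper,
               lower = rule$lower, fold = fold, direction = direction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Match disorder signatures against a urine profile
#'
#' A signature is called when all of its `required_high` markers are above
#' cutoff (fold > 1) and all `required_low` markers below their lower
#' bounds. Calls are ranked by number of matched required markers, then by
#' maximal fold, with alphabetical code as the deterministic tie-break.
#' Confound annotation/suppression ([flag_confounds()]) is applied unless
#' `apply_confounds = FALSE`.
#'
#' @param profile a [urine_profile()]
#' @param registry a `panel_registry`
#' @param signatures signature list; defaults to the registry's
#' @param apply_confounds run [flag_confounds()] on the result?
#' @return a `disorder_calls` data.frame: `rank`, `code`,
#'   `matched_required`, `matched_optional`, `max_fold`, `confounds`;
#'   zero rows for a normal profile
#' @export
classify <- function(profile, registry, signatures = NULL,
                     apply_confounds = TRUE) {
  stopifnot(inherits(profile, "urine_profile"))
  signatures <- signatures %||% registry$signatures
  folds <- fold_over_cutoff(profile, registry)
  high <- folds$analyte[folds$direction == "high"]
  low <- folds$analyte[folds$direction == "low"]
  fold_of <- setNames(folds$fold, folds$analyte)

  calls <- list()
  for (s in signatures) {
    if (!length(s$required_high)) next
    req_ok <- all(s$required_high %in% high)
    low_ok <- all(s$required_low %in% low)
    if (req_ok && low_ok) {
      matched_opt <- intersect(s$optional_high, high)
      calls[[s$code]] <- data.frame(
        code = s$code,
        matched_required = paste(s$required_high, collapse = ";"),
        matched_optional = paste(matched_opt, collapse = ";"),
        n_required = length(s$required_high),
        max_fold = max(fold_of[c(s$required_high, matched_opt)]),
        confounds = "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) {
    out <- data.frame(rank = integer(), code = character(),
                      matched_required = character(),
                      matched_optional = character(), n_required = integer(),
                      max_fold = numeric(), confounds = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("disorder_calls", class(out))
    return(out)
  }
  out <- do.call(rbind, calls)
  out <- out[order(-out$n_required, -out$max_fold, out$code), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("rank", "code", "matched_required", "matched_optional",
                 "n_required", "max_fold", "confounds")]
  class(out) <- c("disorder_calls", class(out))
  if (apply_confounds) out <- flag_confounds(profile, out, registry)
  out
}

#' Annotate treatment-related confounds on a call list
#'
#' When allopurinol is detected and orotidine (or orotic acid) is elevated,
#' those elevations are annotated as allopurinol-related. A UMPS call whose
#' required markers are fully explained by the confound is suppressed;
#' calls of other disorders keep their rank but carry the annotation.
#'
#' @param profile a [urine_profile()]
#' @param calls a `disorder_calls` data.frame from [classify()]
#' @param registry a `panel_registry`
#' @return the annotated (possibly shortened) `disorder_calls`
#' @export
flag_confounds <- function(profile, calls, registry) {
  if (!nrow(calls) || !isTRUE(profile$allopurinol_detected)) return(calls)
  confounded <- c("Orotidine", "Orotic acid")
  folds <- fold_over_cutoff(profile, registry)
  elevated_conf <- intersect(confounded,
                             folds$analyte[folds$direction == "high"])
  if (!length(elevated_conf)) return(calls)

  note <- paste0(paste(elevated_conf, collapse = " and "),
                 " elevation consistent with allopurinol treatment")
  drop <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    req <- strsplit(calls$matched_required[i], ";", fixed = TRUE)[[1]]
    if (all(req %in% confounded)) {
      drop[i] <- TRUE  # e.g. UMPS supported only by the treatment artifact
    } else {
      calls$confounds[i] <- note
    }
  }
  out <- calls[!drop, , drop = FALSE]
  if (nrow(out)) out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.disorder_calls <- function(x, ...) {
  if (!nrow(x)) {
    cat("No disorder pattern matched: profile within reference intervals.\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%d. %s  (required: %s%s; max fold %.1f)%s\n",
                x$rank[i], x$code[i], x$matched_required[i],
                if (nzchar(x$matched_optional[i]))
                  paste0("; optional: ", x$matched_optional[i]) else "",
                x$max_fold[i],
                if (nzchar(x$confounds[i]))
                  paste0("  [", x$confounds[i], "]") else ""))
  }
  invisible(x)
}
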