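# Panel registry: machine-readable model of the MRM assay panel -------------
#
# The registry bundles four pieces of configuration:
#   * transitions — one row per MRM channel (parent/daughter m/z, polarity,
#     quantifier/qualifier role, cone and collision voltages, retention time)
#   * cutoffs     — age-conditional decision limits in mmol/mol creatinine
#   * signatures  — rule-based disorder definitions (required/optional markers)
#   * critical_pairs — analyte pairs whose MRM channels interfere and must be
#     chromatographically resolved
# Retention times are synthetic: the published assay prints elution order but
# not numeric times, so the bundled panel spaces peaks over 2-8.5 min
# preserving that order (see the methods vignette).

#' Load an MRM panel registry
#'
#' Reads the tab-separated transition table, the age-stratified cutoff table
#' and the JSON disorder signatures into a validated `panel_registry` object.
#'
#' @param path directory containing `panel_transitions.tsv`,
#'   `panel_cutoffs.tsv`, `disorder_signatures.json` and (optionally)
#'   `critical_pairs.tsv`, or the string `"bundled"` (default) for the panel
#'   shipped with the package.
#' @return an object of class `panel_registry` with elements `transitions`,
#'   `analytes`, `cutoffs`, `signatures`, `critical_pairs`.
#' @examples
#' reg <- load_panel()
#' nrow(reg$analytes)
#' @export
load_panel <- function(path = "bundled") {
  if (identical(path, "bundled")) {
    files <- list(
      transitions = uripp_extdata("panel_transitions.tsv"),
      cutoffs = uripp_extdata("panel_cutoffs.tsv"),
      signatures = uripp_extdata("disorder_signatures.json"),
      critical_pairs = uripp_extdata("critical_pairs.tsv")
    )
  } else {
    if (!dir.exists(path)) stop("panel directory not found: ", path, call. = FALSE)
    files <- list(
      transitions = file.path(path, "panel_transitions.tsv"),
      cutoffs = file.path(path, "panel_cutoffs.tsv"),
      signatures = file.path(path, "disorder_signatures.json"),
      critical_pairs = file.path(path, "critical_pairs.tsv")
    )
  }

  tr <- tryCatch(
    read.delim(files$transitions, stringsAsFactors = FALSE,
               colClasses = "character", na.strings = NULL),
    error = function(e) stop("cannot parse transition table '",
                             files$transitions, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  needed <- c("analyte", "class", "is_internal_standard", "internal_standard",
              "esi_mode", "role", "parent_mz", "daughter_mz", "cone_v",
              "collision_v", "retention_time_min")
  if (nrow(tr) == 0 || !all(needed %in% names(tr))) {
    stop("transition table is empty or lacks required columns: ",
         paste(setdiff(needed, names(tr)), collapse = ", "), call. = FALSE)
  }
  tr$is_internal_standard <- tr$is_internal_standard == "1"
  for (col in c("parent_mz", "daughter_mz", "cone_v", "collision_v",
                "retention_time_min")) {
    tr[[col]] <- as.numeric(tr[[col]])
  }
  tr$internal_standard[!nzchar(tr$internal_standard)] <- NA_character_

  cutoffs <- read_cutoff_table(files$cutoffs)
  signatures <- read_signatures(files$signatures)
  critical_pairs <- if (file.exists(files$critical_pairs)) {
    read.delim(files$critical_pairs, stringsAsFactors = FALSE)
  } else {
    data.frame(pair_id = character(), analyte_1 = character(),
               channel_1 = character(), analyte_2 = character(),
               channel_2 = character(), reason = character())
  }

  analytes <- build_analyte_table(tr)
  registry <- structure(
    list(transitions = tr, analytes = analytes, cutoffs = cutoffs,
         signatures = signatures, critical_pairs = critical_pairs),
    class = "panel_registry"
  )

  violations <- validate_panel(registry)
  fatal <- grepl("references missing internal standard|more than one quantifier",
                 violations)
  if (any(fatal)) {
    stop("panel failed validation:\n  ",
         paste(violations[fatal], collapse = "\n  "), call. = FALSE)
  }
  registry
}

read_cutoff_table <- function(path) {
  co <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
               na.strings = NULL),
    error = function(e) stop("cannot parse cutoff table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  needed <- c("analyte", "age_min", "age_max", "lower", "upper")
  if (nrow(co) == 0 || !all(needed %in% names(co))) {
    stop("cutoff table is empty or lacks required columns", call. = FALSE)
  }
  co$age_min <- as.numeric(co$age_min)
  co$age_max <- as.numeric(co$age_max)
  co$detection_is_abnormal <- co$upper == "n.d."
  co$upper <- suppressWarnings(as.numeric(co$upper))
  co$lower <- suppressWarnings(as.numeric(co$lower))
  co
}

read_signatures <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sigs <- lapply(raw$signatures, function(s) {
    list(code = s$code, name = s$name %||% s$code,
         required_high = vapply(s$required_high, identity, character(1)),
         optional_high = if (length(s$optional_high))
           vapply(s$optional_high, identity, character(1)) else character(),
         required_low = if (length(s$required_low))
           vapply(s$required_low, identity, character(1)) else character(),
         confound_notes = s$confound_notes %||% "")
  })
  names(sigs) <- vapply(sigs, `[[`, character(1), "code")
  sigs
}

build_analyte_table <- function(tr) {
  key <- !duplicated(tr$analyte)
  data.frame(
    analyte = tr$analyte[key],
    class = tr$class[key],
    is_internal_standard = tr$is_internal_standard[key],
    internal_standard = tr$internal_standard[key],
    retention_time_min = tr$retention_time_min[key],
    acquisition_window_halfwidth = 1.5,  # MRMs acquired in rt +/- 1.5 min windows
    stringsAsFactors = FALSE
  )
}

#' Validate a panel registry
#'
#' Checks every structural invariant of the panel: mass ordering, voltage
#' positivity, one quantifier per (analyte, ESI mode), resolvable internal
#' standards, gap/overlap-free age partitions of `[0, 18]`, ordered bounds,
#' and that signature markers exist in the panel. Violations are returned as
#' data, not thrown.
#'
#' @param registry a `panel_registry`
#' @return character vector of human-readable violations; empty when valid
#' @export
validate_panel <- function(registry) {
  stopifnot(inherits(registry, "panel_registry"))
  tr <- registry$transitions
  v <- character()

  bad_mass <- !(tr$parent_mz > tr$daughter_mz & tr$daughter_mz > 0)
  if (any(bad_mass)) {
    v <- c(v, paste0(tr$analyte[bad_mass],
                     ": parent_mz must exceed daughter_mz > 0"))
  }
  bad_volt <- !(tr$cone_v > 0 & tr$collision_v > 0)
  if (any(bad_volt)) {
    v <- c(v, paste0(tr$analyte[bad_volt], ": voltages must be > 0"))
  }

  quant <- tr[tr$role == "quantifier", ]
  counts <- table(paste(quant$analyte, quant$esi_mode, sep = " / "))
  dup <- names(counts)[counts > 1]
  if (length(dup)) {
    v <- c(v, paste0(dup, ": more than one quantifier transition"))
  }
  modes <- unique(tr[, c("analyte", "esi_mode")])
  has_quant <- paste(quant$analyte, quant$esi_mode, sep = " / ")
  missing_q <- setdiff(paste(modes$analyte, modes$esi_mode, sep = " / "),
                       has_quant)
  if (length(missing_q)) {
    v <- c(v, paste0(missing_q, ": no quantifier transition"))
  }

  an <- registry$analytes
  is_names <- an$analyte[an$is_internal_standard]
  needs_is <- an[!an$is_internal_standard, ]
  bad_is <- is.na(needs_is$internal_standard) |
    !(needs_is$internal_standard %in% is_names)
  if (any(bad_is)) {
    v <- c(v, paste0(needs_is$analyte[bad_is],
                     ": references missing internal standard '",
                     needs_is$internal_standard[bad_is], "'"))
  }

  co <- registry$cutoffs
  for (a in unique(co$analyte)) {
    rows <- co[co$analyte == a, ]
    rows <- rows[order(rows$age_min), ]
    if (rows$age_min[1] != 0 || rows$age_max[nrow(rows)] != 18) {
      v <- c(v, paste0(a, ": cutoff ages do not span [0, 18]"))
    }
    if (nrow(rows) > 1 &&
        any(abs(rows$age_max[-nrow(rows)] - rows$age_min[-1]) > 1e-9)) {
      v <- c(v, paste0(a, ": cutoff age intervals have gaps or overlaps"))
    }
    both <- !is.na(rows$lower) & !is.na(rows$upper)
    if (any(both & rows$lower >= rows$upper)) {
      v <- c(v, paste0(a, ": lower cutoff must be below upper cutoff"))
    }
    if (!(a %in% an$analyte)) {
      v <- c(v, paste0(a, ": cutoff refers to analyte absent from panel"))
    }
  }

  for (s in registry$signatures) {
    refs <- c(s$required_high, s$optional_high, s$required_low)
    missing <- setdiff(refs, an$analyte)
    if (length(missing)) {
      v <- c(v, paste0("signature ", s$code, ": unknown analyte(s) ",
                       paste(missing, collapse = ", ")))
    }
    if (!length(s$required_high) && !nzchar(s$confound_notes)) {
      v <- c(v, paste0("signature ", s$code, ": empty required_high"))
    }
  }

  cp <- registry$critical_pairs
  if (nrow(cp)) {
    missing <- setdiff(c(cp$analyte_1, cp$analyte_2), an$analyte)
    if (length(missing)) {
      v <- c(v, paste0("critical pair refers to unknown analyte ", missing))
    }
  }
  v
}

#' Resolve the cutoff rule for an analyte at a given age
#'
#' Age intervals are half-open `[min, max)` except the last, which is closed
#' at 18 years. Analytes with an `n.d.` cutoff (normally absent compounds such
#' as allopurinol) return `detection_is_abnormal = TRUE` with no numeric upper
#' bound.
#'
#' @param registry a `panel_registry`
#' @param analyte analyte name as in the panel
#' @param age age in years, within `[0, 18]`
#' @return list with `analyte`, `age_min`, `age_max`, `lower` (NA when
#'   absent), `upper` (NA for detection-is-abnormal analytes) and
#'   `detection_is_abnormal`
#' @examples
#' reg <- load_panel()
#' get_cutoff(reg, "Xanthine", 0.5)$upper
#' @export
get_cutoff <- function(registry, analyte, age) {
  stopifnot(inherits(registry, "panel_registry"))
  if (!is.numeric(age) || length(age) != 1 || is.na(age)) {
    stop("age must be a single number", call. = FALSE)
  }
  if (age < 0 || age > 18) {
    stop("age ", age, " outside the supported range [0, 18]", call. = FALSE)
  }
  rows <- registry$cutoffs[registry$cutoffs$analyte == analyte, , drop = FALSE]
  if (!nrow(rows)) stop("no cutoff defined for analyte '", analyte, "'",
                        call. = FALSE)
  hit <- rows$age_min <= age &
    (age < rows$age_max | (age == 18 & rows$age_max == 18))
  if (sum(hit) != 1) {
    stop("cutoff age partition for '", analyte, "' did not resolve uniquely",
         call. = FALSE)
  }
  row <- rows[hit, ]
  list(analyte = analyte, age_min = row$age_min, age_max = row$age_max,
       lower = row$lower, upper = row$upper,
       detection_is_abnormal = row$detection_is_abnormal)
}

#' Write a panel registry back to disk
#'
#' Emits the same delimited dialect that [load_panel()] reads, so that
#' `load_panel(write_panel(reg, dir))` round-trips.
#'
#' @param registry a `panel_registry`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_panel <- function(registry, dir) {
  stopifnot(inherits(registry, "panel_registry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- registry$transitions
  tr$is_internal_standard <- as.integer(tr$is_internal_standard)
  tr$internal_standard[is.na(tr$internal_standard)] <- ""
  write.table(tr, file.path(dir, "panel_transitions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  co <- registry$cutoffs
  out <- data.frame(analyte = co$analyte, age_min = co$age_min,
                    age_max = co$age_max,
                    lower = ifelse(is.na(co$lower), "", format(co$lower)),
                    upper = ifelse(co$detection_is_abnormal, "n.d.",
                                   format(co$upper)),
                    stringsAsFactors = FALSE)
  write.table(out, file.path(dir, "panel_cutoffs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  sigs <- lapply(unname(registry$signatures), function(s) {
    list(code = s$code, name = s$name,
         required_high = as.list(s$required_high),
         optional_high = as.list(s$optional_high),
         required_low = as.list(s$required_low),
         confound_notes = s$confound_notes)
  })
  jsonlite::write_json(list(signatures = sigs),
                       file.path(dir, "disorder_signatures.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (nrow(registry$critical_pairs)) {
    write.table(registry$critical_pairs, file.path(dir, "critical_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.panel_registry <- function(x, ...) {
  an <- x$analytes
  cat("<panel_registry>\n")
  cat("  analytes:           ", sum(!an$is_internal_standard),
      "(", sum(!an$is_internal_standard & an$class == "purine"), "purine /",
      sum(!an$is_internal_standard & an$class == "pyrimidine"),
      "pyrimidine )\n")
  cat("  internal standards: ", sum(an$is_internal_standard), "\n")
  cat("  transitions:        ", nrow(x$transitions), "\n")
  cat("  cutoff rules:       ", nrow(x$cutoffs), "\n")
  cat("  disorder signatures:", length(x$signatures), "\n")
  invisible(x)
}

# Channel retention time: ISs carry their own rows; analyte channels use the
# analyte's retention time.
channel_rt <- function(registry, analyte) {
  an <- registry$analytes
  i <- match(analyte, an$analyte)
  if (is.na(i)) stop("unknown analyte '", analyte, "'", call. = FALSE)
  an$retention_time_min[i]
}
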