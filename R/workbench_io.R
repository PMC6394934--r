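# Shared I/O, configuration and the pipeline driver ---------------------------
#
# Everything on disk is plain text: tab-separated tables and JSON. Writers
# prepend a comment header carrying the tool version, the configuration hash
# and the seed, so any artifact can be traced back to the run that made it.

uripp_version <- function() {
  as.character(utils::packageVersion("uripp"))
}

config_hash <- function(config) {
  # output location is volatile and must not change the content hash
  keep <- config[setdiff(names(config), c("hash", "out"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(keep), vapply(keep, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

artifact_header <- function(config) {
  c(sprintf("# uripp %s", uripp_version()),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %s", config$seed))
}

#' Read a run configuration file
#'
#' Flat `key: value` text (a YAML-style dialect restricted to scalars).
#' Recognised keys: `seed`, `panel`, `out`, `traces`, `profiles`,
#' `cohort`, `alpha`, `weighting`, `noise`, `verbosity`. Referenced paths
#' must exist.
#'
#' @param path configuration file
#' @return a `run_config` list
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  bad <- !grepl("^[^:]+:", lines)
  if (any(bad)) {
    stop("malformed config line(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]+:", "", lines))
  config <- as.list(setNames(vals, keys))
  for (k in c("seed", "alpha", "noise", "fold")) {
    if (!is.null(config[[k]])) config[[k]] <- as.numeric(config[[k]])
  }
  config$seed <- as.integer(config$seed %||% 1L)
  for (k in c("panel", "traces", "profiles", "cohort")) {
    p <- config[[k]]
    if (!is.null(p) && !identical(p, "bundled") && !file.exists(p)) {
      stop("config path '", k, "' does not exist: ", p, call. = FALSE)
    }
  }
  structure(config, class = "run_config")
}

#' Write long-format MRM traces
#'
#' @param traces data.frame from [generate_chromatogram()]
#' @param path output file
#' @param config run configuration recorded in the header
#' @return `path`, invisibly
#' @export
write_traces <- function(traces, path, config = list(seed = NA)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header(config), con)
  utils::write.table(traces, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read long-format MRM traces
#'
#' Expects the dialect written by [write_traces()]: comment headers, then
#' tab-separated `sample`, `analyte`, `channel_role`, `time_min`,
#' `intensity`. Malformed rows are reported with their line numbers; a
#' channel whose time stamps do not form a single increasing uniform grid is
#' an error.
#'
#' @param path input file
#' @return data.frame of traces, time-sorted within channel; zero rows (with
#'   a warning) for an empty file
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  body_at <- which(!grepl("^#", lines))
  if (!length(body_at)) {
    warning("no trace rows in ", path)
    return(data.frame(sample = character(), analyte = character(),
                      channel_role = character(), time_min = numeric(),
                      intensity = numeric()))
  }
  header_line <- body_at[1]
  cols <- strsplit(lines[header_line], "\t", fixed = TRUE)[[1]]
  needed <- c("sample", "analyte", "channel_role", "time_min", "intensity")
  if (!all(needed %in% cols)) {
    stop("trace file lacks required columns: ",
         paste(setdiff(needed, cols), collapse = ", "), call. = FALSE)
  }
  data_lines <- lines[body_at[-1]]
  line_no <- body_at[-1]
  if (!length(data_lines)) {
    warning("no trace rows in ", path)
    return(data.frame(sample = character(), analyte = character(),
                      channel_role = character(), time_min = numeric(),
                      intensity = numeric()))
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- nfield != length(cols)
  out <- as.data.frame(do.call(rbind, parts[!bad]), stringsAsFactors = FALSE)
  names(out) <- cols
  out$time_min <- suppressWarnings(as.numeric(out$time_min))
  out$intensity <- suppressWarnings(as.numeric(out$intensity))
  bad_num <- is.na(out$time_min) | is.na(out$intensity)
  if (any(bad) || any(bad_num)) {
    bad_lines <- sort(c(line_no[bad], line_no[!bad][bad_num]))
    stop("malformed trace row(s) at line ",
         paste(bad_lines, collapse = ", "), " of ", path, call. = FALSE)
  }
  out <- out[order(out$sample, out$analyte, out$channel_role, out$time_min), ]
  rownames(out) <- NULL

  key <- paste(out$sample, out$analyte, out$channel_role, sep = "\r")
  for (k in unique(key)) {
    t <- out$time_min[key == k]
    if (length(t) > 2) {
      steps <- diff(t)
      if (any(steps <= 0) || diff(range(steps)) > 1e-6) {
        stop("channel '", gsub("\r", " / ", k),
             "' has a non-uniform or non-increasing time grid", call. = FALSE)
      }
    }
  }
  out
}

#' Read quantified urine profiles
#'
#' Tab-separated with columns `sample_id`, `age`, `analyte`, `value`
#' (mmol/mol creatinine); comment lines ignored.
#'
#' @param path input file
#' @return list of [urine_profile()] objects
#' @export
read_profiles <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("sample_id", "age", "analyte", "value")
  if (!all(needed %in% names(df))) {
    stop("profile table lacks columns: ",
         paste(setdiff(needed, names(df)), collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$sample_id), function(sub) {
    urine_profile(setNames(sub$value, sub$analyte), age = sub$age[1],
                  sample_id = sub$sample_id[1])
  })
}

#' Write urine profiles as a long table
#'
#' @param profiles list of [urine_profile()]s
#' @param path output file
#' @param config run configuration recorded in the header
#' @return `path`, invisibly
#' @export
write_profiles <- function(profiles, path, config = list(seed = NA)) {
  rows <- lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id, age = p$age,
               analyte = names(p$values), value = unname(p$values),
               stringsAsFactors = FALSE)
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header(config), con)
  utils::write.table(do.call(rbind, rows), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

log_msg <- function(verbosity, ...) {
  if (!identical(verbosity, "quiet")) message("[uripp] ", ...)
}

#' Run one pipeline stage
#'
#' Composes the package's modules behind a small driver suitable for
#' `Rscript` use. Subcommands:
#' \describe{
#'   \item{simulate}{write calibrator-series traces and a disorder profile
#'     panel}
#'   \item{quantify}{calibrate on simulated traces and quantify a sample}
#'   \item{validate}{linearity / LOD / resolution summary on simulated data}
#'   \item{cutoffs}{generate a cohort and emit an estimated cutoff table}
#'   \item{diagnose}{classify profiles against the panel}
#'   \item{report}{diagnose plus a human-readable summary}
#' }
#' Identical config and seed give byte-identical artifacts.
#'
#' @param subcommand one of the stages above
#' @param config a `run_config` (or list with at least `seed`, `out`)
#' @return named list of artifact paths, invisibly
#' @export
run_pipeline <- function(subcommand = c("simulate", "quantify", "validate",
                                        "cutoffs", "diagnose", "report"),
                         config) {
  subcommand <- match.arg(subcommand)
  if (is.null(config$out)) stop("config needs an 'out' directory", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  config$seed <- seed
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  registry <- load_panel(config$panel %||% "bundled")
  verbosity <- config$verbosity %||% "normal"
  artifacts <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (subcommand == "simulate") {
    run_stage("simulate", {
      log_msg(verbosity, "simulating calibrator series (seed ", seed, ")")
      series <- generate_calibrator_series(registry,
                                           noise = config$noise %||% 0.02,
                                           seed = seed)
      artifacts$traces <- file.path(config$out, "calibrator_traces.tsv")
      write_traces(series$traces, artifacts$traces, config)

      codes <- strsplit(config$disorders %||%
                          "ADSL;APRT;HGPRT;UPB1", ";")[[1]]
      profiles <- lapply(codes, function(code)
        generate_patient_profile(code, fold = config$fold %||% 5, age = 6,
                                 registry = registry,
                                 seed = derive_seed(seed, match(code, codes))))
      artifacts$profiles <- file.path(config$out, "profiles.tsv")
      write_profiles(profiles, artifacts$profiles, config)
    })
  } else if (subcommand == "quantify") {
    run_stage("quantify", {
      series <- generate_calibrator_series(registry,
                                           noise = config$noise %||% 0.02,
                                           seed = seed)
      fits <- calibrate_series(series, registry)
      traces <- if (!is.null(config$traces)) read_traces(config$traces) else
        series$traces[series$traces$sample == "Cal06", ]
      sample_ids <- unique(traces$sample)
      res <- do.call(rbind, lapply(sample_ids, function(s) {
        q <- quantify_sample(traces[traces$sample == s, ], registry, fits)
        cbind(sample = s, q)
      }))
      artifacts$quantified <- file.path(config$out, "quantified.tsv")
      con <- file(artifacts$quantified, "w")
      writeLines(artifact_header(config), con)
      utils::write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
      artifacts$fits <- file.path(config$out, "calibration_fits.json")
      jsonlite::write_json(lapply(fits, unclass), artifacts$fits,
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
  } else if (subcommand == "validate") {
    run_stage("validate", {
      series <- generate_calibrator_series(registry,
                                           noise = config$noise %||% 0.02,
                                           seed = seed)
      fits <- calibrate_series(series, registry)
      res <- critical_pair_resolution(registry)
      report <- list(
        r_squared = lapply(fits, `[[`, "r_squared"),
        min_r_squared = min(vapply(fits, `[[`, numeric(1), "r_squared")),
        critical_pairs = res,
        all_baseline_resolved = all(res$baseline_resolved))
      artifacts$validation <- file.path(config$out, "validation.json")
      jsonlite::write_json(c(list(tool = paste("uripp", uripp_version()),
                                  config_hash = config_hash(config),
                                  seed = seed), report),
                           artifacts$validation, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA, dataframe = "rows")
    })
  } else if (subcommand == "cutoffs") {
    run_stage("cutoffs", {
      cohort <- if (!is.null(config$cohort)) {
        read.delim(config$cohort, comment.char = "#",
                   stringsAsFactors = FALSE)
      } else {
        generate_cohort(cohort_spec(n = 251, seed = seed), registry)
      }
      cc <- cutoff_config(alpha = config$alpha %||% 0.05)
      tab <- build_cutoff_table(cohort, cc, registry, seed = seed)
      artifacts$cutoffs <- file.path(config$out, "estimated_cutoffs.tsv")
      write_cutoff_table(tab, artifacts$cutoffs)
    })
  } else {  # diagnose / report
    run_stage(subcommand, {
      profiles <- if (!is.null(config$profiles)) {
        read_profiles(config$profiles)
      } else {
        stop("diagnose needs a 'profiles' path in the config")
      }
      calls <- lapply(profiles, classify, registry = registry)
      artifacts$calls <- file.path(config$out, "calls.json")
      jsonlite::write_json(
        c(list(tool = paste("uripp", uripp_version()),
               config_hash = config_hash(config), seed = seed),
          list(calls = lapply(calls, function(x) unclass(as.data.frame(x))))),
        artifacts$calls, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      if (subcommand == "report") {
        artifacts$report <- file.path(config$out, "report.txt")
        con <- file(artifacts$report, "w")
        writeLines(artifact_header(config), con)
        for (id in names(calls)) {
          writeLines(paste0("== ", id, " =="), con)
          writeLines(utils::capture.output(print(calls[[id]])), con)
        }
        close(con)
      }
    })
  }
  invisible(artifacts)
}
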