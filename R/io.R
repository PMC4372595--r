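## --- formats, manifests, and the pipeline stages ---------------------------

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an instrument trace CSV
#'
#' Traces are two-column text files with header `time_s,signal` (comma or
#' tab delimited, auto-detected). Malformed rows are reported with their
#' line numbers; non-monotone or duplicated timestamps are rejected. If a
#' sidecar JSON (same path, `.json` extension) exists, channel metadata is
#' taken from it.
#'
#' @param path file path.
#' @return an [instrument_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  delim <- detect_delim(path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("time_s", "signal") %in% names(raw)))
    stop("trace file must have header time_s,signal: ", path)
  t <- suppressWarnings(as.numeric(raw$time_s))
  y <- suppressWarnings(as.numeric(raw$signal))
  bad <- which(!is.finite(t) | !is.finite(y))
  if (length(bad))
    stop("malformed rows in ", path, " at line(s): ",
         paste(bad + 1L, collapse = ", "))   # +1 for the header line
  dup <- which(diff(t) == 0)
  if (length(dup))
    stop("duplicated timestamp in ", path, " at line ", dup[1] + 2L)
  if (any(diff(t) < 0))
    stop("time_s is not strictly increasing in ", path)

  channel <- "O2"; units <- NULL; injections <- numeric()
  sidecar <- sub("\\.[^.]+$", ".json", path)
  if (!identical(sidecar, path) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$channel)) channel <- meta$channel
    if (!is.null(meta$units)) units <- meta$units
    if (!is.null(meta$injections)) injections <- as.numeric(meta$injections)
  }
  instrument_trace(t, y, channel = channel, units = units,
                   injections = injections)
}

#' @param trace an [instrument_trace()].
#' @param sidecar write the channel-metadata JSON next to the CSV.
#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path, sidecar = TRUE) {
  stopifnot(inherits(trace, "instrument_trace"))
  utils::write.csv(as.data.frame(trace)[, c("time_s", "signal")], path,
                   row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(channel = attr(trace, "channel"),
                 units = attr(trace, "units"),
                 injections = attr(trace, "injections"))
    jsonlite::write_json(meta, sub("\\.[^.]+$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read / write a titration event log CSV
#'
#' Columns `time_s`, `reagent`, `final_concentration`, `state` (state may
#' be empty for reoxygenation injections). Delimiter auto-detected as for
#' [read_trace_csv()].
#'
#' @param path file path.
#' @return data frame of events.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  delim <- detect_delim(path)
  ev <- utils::read.table(path, sep = delim, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          na.strings = c("", "NA"))
  need <- c("time_s", "reagent", "state")
  if (!all(need %in% names(ev)))
    stop("event file must have columns time_s, reagent, state: ", path)
  ev$time_s <- as.numeric(ev$time_s)
  if (any(diff(ev$time_s) < 0)) stop("event times must be non-decreasing")
  ev
}

#' @param events event data frame.
#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a run manifest
#'
#' Records the seed, a digest of the configuration, and the input/output
#' paths of a pipeline invocation, so any output table can be regenerated
#' bit-identically.
#'
#' @param path JSON file to write.
#' @param seed integer seed used for the run.
#' @param config list of parameters that defined the run.
#' @param inputs,outputs character vectors of file paths.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, config = list(),
                           inputs = character(), outputs = character()) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)
  manifest <- list(config_hash = unname(tools::md5sum(tf)),
                   seed = seed,
                   package_version = as.character(
                     utils::packageVersion("suitflux")),
                   inputs = inputs, outputs = outputs,
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a simulated cohort to disk
#'
#' One trace CSV (+ sidecar JSON) and one event CSV per run, a metadata
#' JSON, the ground-truth rate table, and a manifest.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "suit_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (run in cohort$runs) {
    tp <- file.path(dir, paste0(run$run_id, "_trace.csv"))
    ep <- file.path(dir, paste0(run$run_id, "_events.csv"))
    write_trace_csv(run$trace, tp)
    write_events_csv(run$events, ep)
    files <- c(files, tp, ep)
  }
  meta <- lapply(cohort$runs, function(run)
    c(as.list(run$group), run$meta[c("preparation", "protein_mg",
                                     "thorax_count", "chamber_volume_mL")],
      list(run_id = run$run_id, regime = run$protocol$regime$name,
           assay = run$protocol$assay)))
  mp <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  gp <- file.path(dir, "ground_truth.csv")
  utils::write.csv(cohort$truth, gp, row.names = FALSE, quote = FALSE)
  files <- c(files, mp, gp)
  write_manifest(file.path(dir, "manifest.json"), seed = cohort$spec$seed,
                 config = cohort$spec[setdiff(names(cohort$spec),
                                              "group_stats")],
                 outputs = files)
  invisible(files)
}

#' Process a cohort into a tidy state-rate table
#'
#' The pipeline's processing stage: fits every run with [suit_fit()] and
#' returns one row per run and metabolic state. Fluorimetric (ROS) cohorts
#' are converted to pmol H2O2/min/mg through the cohort's per-condition
#' calibration curves.
#'
#' @param cohort a [simulate_cohort()] result (in-memory cohort).
#' @param calibration named list of calibration curves; defaults to the
#'   cohort's own.
#' @param ... passed to [suit_fit()] (e.g. `settle_s`, `window_points`).
#' @return tidy data frame: `run_id`, `sex`, `preparation`, `regime`,
#'   `state`, `rate`, `units`, `qc`.
#' @export
process_cohort <- function(cohort, calibration = NULL, ...) {
  stopifnot(inherits(cohort, "suit_cohort"))
  if (is.null(calibration)) calibration <- cohort$calibration
  out <- lapply(cohort$runs, function(run) {
    fit <- suit_fit(run$trace, run$events, run$protocol, run$meta, ...)
    tab <- fit$rates
    if (attr(run$trace, "channel") == "fluorescence") {
      conv <- h2o2_rates(fit, calibration)
      tab$rate <- conv$rate
      tab$units <- conv$units
    }
    data.frame(run_id = run$run_id, sex = run$group$sex,
               preparation = run$group$preparation,
               regime = run$group$regime,
               state = tab$state, rate = tab$rate, units = tab$units,
               qc = tab$qc, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Group summary of a tidy rate or contribution table
#'
#' Mean, SD and n per group and state/site -- the shape in which cohort
#' tables are conventionally reported.
#'
#' @param tab tidy data frame (e.g. from [process_cohort()] or
#'   [decompose_rate_table()]).
#' @param value name of the value column.
#' @param by grouping columns present in `tab`.
#' @return data frame of group summaries.
#' @export
summarize_rates <- function(tab, value = "rate",
                            by = intersect(c("sex", "preparation", "regime",
                                             "state", "site"), names(tab))) {
  agg <- stats::aggregate(tab[[value]], tab[by], function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  out <- cbind(agg[by], as.data.frame(agg$x))
  names(out) <- c(by, "mean", "sd", "n")
  out
}
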