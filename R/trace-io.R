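# Plain-text I/O: per-cell trace tables (long CSV), protocol schedules
# (YAML) and per-cell results tables (CSV). Files store time in seconds,
# matching acquisition; the analysis layer works in minutes.

TRACE_COLUMNS <- c("experiment_id", "cell_id", "time_s", "f420", "f490",
                   "cell_line", "compartment", "treatment", "ph")

#' Per-cell dual-channel acquisition trace
#'
#' @param cell_id cell label
#' @param time_s strictly increasing sample times (seconds)
#' @param f420,f490 fluorescence at 420/490 nm excitation (a.u., > 0)
#' @param metadata named list; recognised entries: `experiment_id`,
#'   `cell_line`, `compartment`, `treatment`, `ph`
#' @return object of class `acquisition_trace`
#' @export
acquisition_trace <- function(cell_id, time_s, f420, f490,
                              metadata = list()) {
  n <- length(time_s)
  if (length(f420) != n || length(f490) != n)
    hk_stop("time_s, f420 and f490 must have equal length",
            "hyperkin_validation_error")
  if (n > 1 && any(diff(time_s) <= 0))
    hk_stop(sprintf("non-monotone sample times for cell '%s'", cell_id),
            "hyperkin_validation_error")
  if (any(!is.finite(f420)) || any(!is.finite(f490)) ||
      any(f420 <= 0) || any(f490 <= 0))
    hk_stop(sprintf("fluorescence must be finite and positive (cell '%s')",
                    cell_id),
            "hyperkin_validation_error")
  structure(list(cell_id = as.character(cell_id), time_s = as.numeric(time_s),
                 f420 = as.numeric(f420), f490 = as.numeric(f490),
                 metadata = metadata),
            class = "acquisition_trace")
}

#' @export
print.acquisition_trace <- function(x, ...) {
  cat(sprintf("<acquisition_trace> %s: %d frames, %.3g-%.3g s\n",
              x$cell_id, length(x$time_s),
              min(x$time_s), max(x$time_s)))
  invisible(x)
}

meta_field <- function(trace, field, default = NA) {
  v <- trace$metadata[[field]]
  if (is.null(v) || length(v) != 1L) default else v
}

# stable float formatting: round-trips doubles well below 1e-9 relative
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

traces_to_df <- function(traces) {
  if (!length(traces))
    return(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(TRACE_COLUMNS))),
      TRACE_COLUMNS))
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(experiment_id = meta_field(tr, "experiment_id", "exp1"),
               cell_id = tr$cell_id,
               time_s = tr$time_s, f420 = tr$f420, f490 = tr$f490,
               cell_line = meta_field(tr, "cell_line"),
               compartment = meta_field(tr, "compartment"),
               treatment = meta_field(tr, "treatment"),
               ph = meta_field(tr, "ph"),
               stringsAsFactors = FALSE)
  }))
}

#' Write acquisition traces to a long-format CSV file
#'
#' Columns (`experiment_id`, `cell_id`, `time_s`, `f420`, `f490`,
#' `cell_line`, `compartment`, `treatment`, `ph`), UTF-8, comma-delimited,
#' `.` decimal. Column order and float formatting are deterministic: two
#' writes of the same data produce byte-identical files.
#'
#' @param traces list of [acquisition_trace()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_traces <- function(traces, path) {
  df <- traces_to_df(traces)
  out <- df
  for (col in c("time_s", "f420", "f490", "ph"))
    out[[col]] <- fmt_num(as.numeric(df[[col]]))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(TRACE_COLUMNS, collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' Read acquisition traces from a long-format CSV file
#'
#' Inverse of [write_traces()]. Rows are grouped by
#' `(experiment_id, cell_id)` and sorted by time; malformed input (missing
#' required columns, non-monotone time within a cell, non-positive
#' fluorescence) is rejected with a classed error rather than coerced.
#'
#' @param path input file path
#' @return list of [acquisition_trace()]
#' @export
read_traces <- function(path) {
  if (!file.exists(path))
    hk_stop(sprintf("file not found: %s", path), "hyperkin_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("experiment_id", "cell_id", "time_s", "f420", "f490")
  missing <- setdiff(required, names(df))
  if (length(missing))
    hk_stop(sprintf("trace table missing required column(s): %s",
                    paste(missing, collapse = ", ")),
            "hyperkin_format_error")
  for (col in c("time_s", "f420", "f490")) {
    if (!is.numeric(df[[col]]))
      hk_stop(sprintf("column '%s' must be numeric", col),
              "hyperkin_format_error")
  }
  key <- interaction(df$experiment_id, df$cell_id, drop = TRUE, sep = "\r")
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_s), , drop = FALSE]
    if (anyDuplicated(d$time_s))
      hk_stop(sprintf("duplicated time points for cell '%s'", d$cell_id[1]),
              "hyperkin_validation_error")
    acquisition_trace(
      cell_id = d$cell_id[1], time_s = d$time_s,
      f420 = d$f420, f490 = d$f490,
      metadata = list(experiment_id = d$experiment_id[1],
                      cell_line = d$cell_line[1] %||% NA,
                      compartment = d$compartment[1] %||% NA,
                      treatment = d$treatment[1] %||% NA,
                      ph = d$ph[1] %||% NA))
  })
}

#' Write a protocol schedule to a YAML file
#'
#' Schema: top-level keys `duration_min`, `sample_interval_s` and `events`,
#' a list of maps with keys `t_min`, `kind` and either `conc_uM`
#' (for `pulse_start`) or `ph` (for `ph_clamp_start`).
#'
#' @param schedule a [protocol_schedule()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_protocol <- function(schedule, path) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  ev <- lapply(seq_len(nrow(schedule$events)), function(i) {
    e <- schedule$events[i, ]
    out <- list(t_min = e$t_min, kind = e$kind)
    if (is.finite(e$conc_uM)) out$conc_uM <- e$conc_uM
    if (is.finite(e$ph)) out$ph <- e$ph
    out
  })
  yaml::write_yaml(list(duration_min = schedule$duration_min,
                        sample_interval_s = schedule$sample_interval_s,
                        events = ev),
                   path)
  invisible(path)
}

#' Read a protocol schedule from a YAML file
#'
#' @param path input file path (schema of [write_protocol()])
#' @return a [protocol_schedule()]; schema violations (unknown event kind,
#'   out-of-order events, missing payloads) raise classed errors
#' @export
read_protocol <- function(path) {
  if (!file.exists(path))
    hk_stop(sprintf("file not found: %s", path), "hyperkin_io_error")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$duration_min) || is.null(raw$sample_interval_s))
    hk_stop("protocol file needs duration_min and sample_interval_s",
            "hyperkin_schema_error")
  ev <- raw$events %||% list()
  events <- data.frame(
    t_min = vapply(ev, function(e) as.numeric(e$t_min %||% NA), 0),
    kind = vapply(ev, function(e) as.character(e$kind %||% NA), ""),
    conc_uM = vapply(ev, function(e) as.numeric(e$conc_uM %||% NA), 0),
    ph = vapply(ev, function(e) as.numeric(e$ph %||% NA), 0),
    stringsAsFactors = FALSE
  )
  protocol_schedule(events, duration_min = raw$duration_min,
                    sample_interval_s = raw$sample_interval_s)
}

#' Write a per-cell results table to CSV
#'
#' One row per analyzed cell (basal ratio, response amplitudes, recovery
#' fit parameters, group labels). Deterministic column order and float
#' formatting; floats round-trip to better than 1e-9 relative.
#'
#' @param results data frame (as produced by [analyze_experiment()])
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_results <- function(results, path) {
  df <- as.data.frame(results)
  key <- paste(df$experiment_id %||% "", df$cell_id %||% "")
  if (anyDuplicated(key))
    hk_stop("duplicated (experiment_id, cell_id) rows in results table",
            "hyperkin_validation_error")
  out <- df
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- fmt_num(out[[col]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' Read a per-cell results table from CSV
#' @param path input file path
#' @return data frame
#' @export
read_results <- function(path) {
  if (!file.exists(path))
    hk_stop(sprintf("file not found: %s", path), "hyperkin_io_error")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
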