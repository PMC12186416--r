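#' Write a signal trace as two-column CSV
#'
#' Plain text interchange format: columns \code{time} (s) and
#' \code{value}; the sampling rate is recoverable from the time column.
#'
#' @param trace a \code{\link{signal_trace}}.
#' @param path output path.
#' @export
write_signal_csv <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  utils::write.csv(data.frame(time = trace_times(trace),
                              value = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column signal CSV
#'
#' @param path CSV with columns \code{time}, \code{value} (or any
#'   two-column time/value layout).
#' @param fs optional sampling rate; if \code{NULL} it is inferred from
#'   the median time step and checked for uniformity (1 percent).
#' @param unit optional unit label.
#' @return a \code{\link{signal_trace}}.
#' @export
read_signal_csv <- function(path, fs = NULL, unit = NULL) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("expected columns time,value", call. = FALSE)
  tt <- d[[1]]; v <- d[[2]]
  dt <- diff(tt)
  if (any(dt <= 0)) stop("time column must be strictly increasing",
                         call. = FALSE)
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.01 * step)
    stop("non-uniform sampling in ", path, call. = FALSE)
  if (is.null(fs)) fs <- 1 / step
  signal_trace(v, fs, t0 = tt[1], unit = unit)
}

#' Write / read the tidy per-breath table
#'
#' @param breath_table data.frame from \code{\link{process_trial}}.
#' @param path CSV path.
#' @rdname breath_table_io
#' @export
write_breath_table <- function(breath_table, path) {
  utils::write.csv(breath_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname breath_table_io
#' @export
read_breath_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load a simulation configuration from YAML
#'
#' Missing keys are filled with the \code{\link{sim_config}} defaults
#' (each substitution is reported with a message); unknown keys are
#' rejected.
#'
#' @param path YAML file of \code{sim_config} fields.
#' @return a validated \code{\link{sim_config}}.
#' @export
load_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(known, names(vals))
  if (length(missing))
    message("config keys set to defaults: ",
            paste(missing, collapse = ", "))
  do.call(sim_config, vals)
}

#' Write a simulation configuration as YAML
#' @param config a \code{\link{sim_config}}.
#' @param path output path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a simulated trial to a directory
#'
#' Serialises one simulated PS-trial in the package's interchange
#' formats: \code{semg.csv} and \code{ecg.csv} (2048 Hz), \code{vent.csv}
#' (time, paw, flow, volume at 100 Hz), \code{segments.json},
#' \code{ground_truth.json} and \code{config.yaml}.
#'
#' @param trial result of \code{\link{simulate_trial}}.
#' @param config the \code{\link{sim_config}} used.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_trial_dir <- function(trial, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_signal_csv(trial$signals$semg, file.path(dir, "semg.csv"))
  write_signal_csv(trial$signals$ecg, file.path(dir, "ecg.csv"))
  vent <- data.frame(time = trace_times(trial$signals$volume),
                     paw = trial$signals$paw$values,
                     flow = trial$signals$flow$values,
                     volume = trial$signals$volume$values)
  utils::write.csv(vent, file.path(dir, "vent.csv"), row.names = FALSE)
  jsonlite::write_json(trial$segments, file.path(dir, "segments.json"),
                       dataframe = "columns", digits = NA)
  jsonlite::write_json(trial$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  write_sim_config(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a trial directory back into signal traces
#'
#' @param dir directory written by \code{\link{write_trial_dir}} (or laid
#'   out the same way by hand).
#' @return list with \code{signals} (semg, ecg, paw, flow, volume) and
#'   \code{segments}.
#' @export
read_trial_dir <- function(dir) {
  semg <- read_signal_csv(file.path(dir, "semg.csv"), unit = "uV")
  ecg <- read_signal_csv(file.path(dir, "ecg.csv"), unit = "uV")
  vent <- utils::read.csv(file.path(dir, "vent.csv"))
  fs_v <- 1 / stats::median(diff(vent$time))
  segs <- as.data.frame(jsonlite::read_json(file.path(dir,
                                                      "segments.json"),
                                            simplifyVector = TRUE))
  list(signals = list(
    semg = semg, ecg = ecg,
    paw = signal_trace(vent$paw, fs_v, t0 = vent$time[1],
                       unit = "cmH2O"),
    flow = signal_trace(vent$flow, fs_v, t0 = vent$time[1],
                        unit = "mL/s"),
    volume = signal_trace(vent$volume, fs_v, t0 = vent$time[1],
                          unit = "mL")),
    segments = segs)
}

#' Run the pipeline from a trial directory and write all outputs
#'
#' Reads the recordings and segment annotation, runs
#' \code{\link{process_trial}}, and writes \code{breath_table.csv},
#' \code{matched.csv}, \code{nvc.json} and \code{report.json} next to the
#' inputs (or into \code{out_dir}).
#'
#' @param dir trial directory (see \code{\link{read_trial_dir}}).
#' @param out_dir output directory (default: \code{dir}).
#' @param config a \code{\link{pipeline_config}}.
#' @return the \code{trial_result}, invisibly.
#' @export
run_pipeline <- function(dir, out_dir = dir,
                         config = pipeline_config()) {
  inp <- read_trial_dir(dir)
  res <- process_trial(inp$signals, inp$segments, config = config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_breath_table(res$breath_table,
                     file.path(out_dir, "breath_table.csv"))
  utils::write.csv(res$matched, file.path(out_dir, "matched.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$nvc, file.path(out_dir, "nvc.json"),
                       dataframe = "columns", digits = NA)
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       dataframe = "columns", digits = NA, force = TRUE,
                       auto_unbox = TRUE)
  invisible(res)
}
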