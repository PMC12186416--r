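#' Uniformly sampled signal trace
#'
#' Lightweight container for one uniformly sampled channel (raw sEMG, ECG,
#' the sEAdi envelope and its moving baseline, or ventilator airway
#' pressure/flow/volume). Values carry their physical unit as metadata only;
#' no unit conversion is performed.
#'
#' @param values numeric vector of samples; must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds (default 0). All channels
#'   of one recording share a common time origin.
#' @param unit optional unit label (e.g. "uV", "mL", "cmH2O").
#' @return An object of class \code{signal_trace}: a list with elements
#'   \code{values}, \code{fs}, \code{t0}, \code{unit}.
#' @examples
#' x <- signal_trace(sin(2 * pi * 5 * seq(0, 1, by = 1 / 500)), fs = 500)
#' range(trace_times(x))
#' @export
signal_trace <- function(values, fs, t0 = 0, unit = NULL) {
  values <- as.numeric(values)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite and non-missing", call. = FALSE)
  structure(list(values = values, fs = fs, t0 = t0, unit = unit),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace: %d samples @ %g Hz, t0 = %g s%s>\n",
              length(x$values), x$fs, x$t0,
              if (is.null(x$unit)) "" else paste0(", ", x$unit)))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$values)

#' Sample times of a trace
#'
#' @param x a \code{signal_trace}.
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "signal_trace"))
  x$t0 + (seq_along(x$values) - 1L) / x$fs
}

#' Duration of a trace in seconds
#' @param x a \code{signal_trace}.
#' @export
trace_duration <- function(x) length(x$values) / x$fs

#' Percentile with linear interpolation between order statistics
#'
#' Single shared percentile convention used everywhere a quantile enters the
#' analysis: the upper-quartile reference for the relative AUB criterion, the
#' 95th-percentile reference for the relative ETPdi criterion, the 75th
#' percentile of flow-breath tidal volumes, and the Tukey outlier fences.
#' This is \code{stats::quantile} type 7 (linear interpolation between order
#' statistics), stated once and reused so all criteria agree.
#'
#' @param x numeric vector.
#' @param p percentile in \[0, 100\].
#' @return the interpolated percentile value.
#' @export
pctl <- function(x, p) {
  stopifnot(is.numeric(x), length(x) >= 1L, p >= 0, p <= 100)
  unname(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

# moving RMS via cumulative sums; centered window of `n` samples (odd),
# edges use the available part of the window
moving_rms <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  cs <- cumsum(c(0, x^2))
  k <- (n - 1L) %/% 2L
  i <- seq_along(x)
  lo <- pmax(i - k, 1L)
  hi <- pmin(i + k, length(x))
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

# moving average with the same edge convention
moving_mean <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  cs <- cumsum(c(0, x))
  k <- (n - 1L) %/% 2L
  i <- seq_along(x)
  lo <- pmax(i - k, 1L)
  hi <- pmin(i + k, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
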