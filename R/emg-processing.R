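#' Band-pass pre-filter for raw surface EMG
#'
#' Zero-phase Butterworth band-pass. The default 20-400 Hz band retains
#' the bulk of diaphragm sEMG power while attenuating motion artifact and
#' the low-frequency energy of the ECG complex; zero-phase filtering
#' (forward-backward) preserves burst timing.
#'
#' @param raw a \code{\link{signal_trace}} sampled at >= 1000 Hz.
#' @param band numeric length-2, band edges in Hz.
#' @param order filter order of the underlying Butterworth design.
#' @return filtered \code{signal_trace} on the same grid, mean ~ 0.
#' @export
preprocess_emg <- function(raw, band = c(20, 400), order = 4) {
  stopifnot(inherits(raw, "signal_trace"))
  if (raw$fs < 1000)
    stop("EMG sampling rate must be >= 1000 Hz", call. = FALSE)
  if (any(band >= raw$fs / 2))
    stop("band edges must be below the Nyquist frequency", call. = FALSE)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("`band` must be increasing positive edges", call. = FALSE)
  bf <- signal::butter(order / 2, band / (raw$fs / 2), type = "pass")
  # demean + reflect-pad to suppress zero-phase edge transients
  x <- raw$values - mean(raw$values)
  n <- length(x)
  np <- min(n - 1L, round(0.5 * raw$fs))
  xp <- c(rev(x[seq_len(np)]), x, rev(x[seq.int(n - np + 1L, n)]))
  y <- signal::filtfilt(bf, xp)[np + seq_len(n)]
  signal_trace(y, raw$fs, raw$t0, unit = raw$unit)
}

#' Detect QRS complexes in the ECG channel
#'
#' Amplitude-scale-invariant detector: the ECG is band-passed to the QRS
#' band (8-35 Hz), squared, smoothed with a 120 ms moving average, and
#' peaks above an adaptive threshold (a fixed fraction of a high quantile
#' of the detection function) are kept with a physiological refractory
#' period. Rescaling the ECG by any positive factor leaves the detections
#' unchanged.
#'
#' @param ecg a \code{\link{signal_trace}} of length >= 2 s.
#' @param refractory minimum spacing between detections, s (default 0.25).
#' @return numeric vector of R-wave times (s), strictly increasing; empty
#'   for a flat signal.
#' @export
detect_qrs <- function(ecg, refractory = 0.25) {
  stopifnot(inherits(ecg, "signal_trace"))
  if (trace_duration(ecg) < 2)
    stop("ECG must be at least 2 s long", call. = FALSE)
  x <- ecg$values - mean(ecg$values)
  if (all(abs(x) < .Machine$double.eps^.5 * max(1, abs(mean(ecg$values)))))
    return(numeric(0))
  bf <- signal::butter(2, c(8, 35) / (ecg$fs / 2), type = "pass")
  d <- signal::filtfilt(bf, x)^2
  d <- moving_mean(d, round(0.12 * ecg$fs))
  thr <- 0.25 * pctl(d, 99)
  if (thr <= 0) return(numeric(0))
  above <- d > thr
  # local maxima of the detection function among supra-threshold samples
  n <- length(d)
  core <- 2:(n - 1L)
  cand <- core[above[core] & d[core] > d[core - 1L] & d[core] >= d[core + 1L]]
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(-d[cand])]
  keep <- integer(0)
  min_gap <- refractory * ecg$fs
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_gap))
      keep <- c(keep, i)
  }
  sort(ecg$t0 + (keep - 1L) / ecg$fs)
}

#' Gate ECG artifact out of the EMG channel
#'
#' Replaces the EMG samples in a window around each detected R wave
#' (default 50 ms before to 100 ms after) with a deterministic fill: the
#' samples immediately preceding the gate, rescaled sample-by-sample to an
#' RMS level that ramps linearly from the pre-gate to the post-gate RMS.
#' The fill is a pure function of the surrounding signal, so gating is
#' idempotent and the whole pipeline stays deterministic. Outside the
#' gates the signal is returned bit-identical.
#'
#' @param emg a \code{\link{signal_trace}} (pre-filtered EMG).
#' @param qrs_times R-wave times in seconds (within the signal span).
#' @param window numeric length-2: gate limits relative to the R time, s.
#' @return gated \code{signal_trace}, same grid and length.
#' @export
gate_ecg <- function(emg, qrs_times, window = c(-0.05, 0.10)) {
  stopifnot(inherits(emg, "signal_trace"))
  if (!length(qrs_times)) return(emg)
  tmax <- emg$t0 + (length(emg$values) - 1) / emg$fs
  if (any(qrs_times < emg$t0) || any(qrs_times > tmax))
    stop("QRS times outside signal span", call. = FALSE)
  y <- emg$values
  fs <- emg$fs
  n <- length(y)
  ctx <- round(0.10 * fs)                       # 100 ms context windows
  for (rt in sort(qrs_times)) {
    i0 <- max(1L, round((rt - emg$t0 + window[1]) * fs) + 1L)
    i1 <- min(n, round((rt - emg$t0 + window[2]) * fs) + 1L)
    if (i1 < i0) next
    pre <- y[max(1L, i0 - ctx):max(1L, i0 - 1L)]
    post <- y[min(n, i1 + 1L):min(n, i1 + ctx)]
    rms_pre <- sqrt(mean(pre^2))
    rms_post <- sqrt(mean(post^2))
    m <- i1 - i0 + 1L
    target <- seq(rms_pre, rms_post, length.out = m)
    # deterministic carrier: tile the pre-gate context, normalised to unit RMS
    carrier <- rep_len(rev(pre), m)
    crms <- sqrt(mean(carrier^2))
    y[i0:i1] <- if (crms > 0) carrier / crms * target else 0
  }
  signal_trace(y, fs, emg$t0, unit = emg$unit)
}

#' sEAdi envelope by moving RMS
#'
#' Computes the surface electrical activity of the diaphragm (sEAdi) as
#' the moving RMS of the cleaned EMG (default 250 ms window) and resamples
#' it onto the 100 Hz ventilator grid, so envelope, baseline and
#' ventilator channels share one common grid for breath matching.
#'
#' @param cleaned a \code{\link{signal_trace}} at >= 1000 Hz.
#' @param rms_window RMS window length, s (default 0.25).
#' @param out_fs output sampling rate, Hz (default 100).
#' @return non-negative envelope \code{signal_trace} at \code{out_fs}.
#' @export
compute_envelope <- function(cleaned, rms_window = 0.25, out_fs = 100) {
  stopifnot(inherits(cleaned, "signal_trace"))
  if (cleaned$fs < 1000)
    stop("EMG sampling rate must be >= 1000 Hz", call. = FALSE)
  nwin <- round(rms_window * cleaned$fs)
  if (nwin > length(cleaned$values))
    stop("RMS window longer than the signal", call. = FALSE)
  env <- moving_rms(cleaned$values, nwin)
  t_in <- trace_times(cleaned)
  n_out <- floor(trace_duration(cleaned) * out_fs)
  t_out <- cleaned$t0 + (seq_len(n_out) - 1L) / out_fs
  v <- stats::approx(t_in, env, xout = t_out, rule = 2)$y
  signal_trace(pmax(v, 0), out_fs, cleaned$t0, unit = cleaned$unit)
}

#' Moving baseline of the sEAdi envelope
#'
#' Robust slow baseline under the envelope: a rolling low percentile
#' (default 33rd over 7.5 s) followed by 1 s smoothing. The percentile is
#' computed on a 10 Hz decimated grid and interpolated back, which is
#' equivalent for a baseline this slow. Robust to bursts occupying up to
#' about half the duty cycle.
#'
#' @param envelope sEAdi \code{\link{signal_trace}}, >= 30 s long.
#' @param window percentile window, s (default 7.5).
#' @param percentile percentile in \[0, 100\] (default 33).
#' @param smooth smoothing window, s (default 1).
#' @return baseline \code{signal_trace} on the envelope grid, >= 0.
#' @export
moving_baseline <- function(envelope, window = 7.5, percentile = 33,
                            smooth = 1) {
  stopifnot(inherits(envelope, "signal_trace"))
  if (trace_duration(envelope) < 30)
    stop("envelope must be at least 30 s for baseline estimation",
         call. = FALSE)
  fs <- envelope$fs
  dec <- max(1L, round(fs / 10))
  idx <- seq(1L, length(envelope$values), by = dec)
  half <- round(window * fs / 2)
  v <- envelope$values
  n <- length(v)
  q <- vapply(idx, function(i) {
    pctl(v[max(1L, i - half):min(n, i + half)], percentile)
  }, numeric(1))
  base <- stats::approx(idx, q, xout = seq_len(n), rule = 2)$y
  base <- moving_mean(base, round(smooth * fs))
  signal_trace(pmax(base, 0), fs, envelope$t0, unit = envelope$unit)
}

#' Coefficient of variation of the moving baseline
#'
#' 100 x sample SD / mean of the baseline trace. The sample (n-1) SD is
#' the package-wide convention. Used as the restlessness covariate in the
#' group-level covariate screen.
#'
#' @param baseline a \code{\link{signal_trace}} with positive mean.
#' @return CoV in percent.
#' @export
baseline_cov <- function(baseline) {
  stopifnot(inherits(baseline, "signal_trace"))
  m <- mean(baseline$values)
  if (m <= 0) stop("baseline mean must be > 0", call. = FALSE)
  100 * stats::sd(baseline$values) / m
}
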