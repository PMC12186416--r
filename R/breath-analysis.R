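#' Envelope/baseline pair
#'
#' Bundles the sEAdi envelope with its moving baseline after checking that
#' both live on the same grid and are non-negative.
#'
#' @param envelope,baseline \code{\link{signal_trace}} objects on one grid.
#' @return object of class \code{envelope_pair}.
#' @export
envelope_pair <- function(envelope, baseline) {
  stopifnot(inherits(envelope, "signal_trace"),
            inherits(baseline, "signal_trace"))
  if (length(envelope$values) != length(baseline$values) ||
      envelope$fs != baseline$fs ||
      abs(envelope$t0 - baseline$t0) > 1e-9)
    stop("envelope and baseline must share one grid", call. = FALSE)
  if (any(envelope$values < 0) || any(baseline$values < 0))
    stop("envelope and baseline must be non-negative", call. = FALSE)
  structure(list(envelope = envelope, baseline = baseline),
            class = "envelope_pair")
}

# trapezoidal integral of y over index range [i0, i1] at sampling rate fs
trapz_idx <- function(y, i0, i1, fs) {
  if (i1 <= i0) return(0)
  yy <- y[i0:i1]
  sum((yy[-1] + yy[-length(yy)]) / 2) / fs
}

#' Detect neural breaths on the sEAdi envelope
#'
#' A neural breath is the span between the two envelope-baseline crossings
#' that flank a local envelope maximum exceeding the baseline by a
#' prominence threshold. Two peaks whose separating dip never reaches the
#' baseline therefore form a single breath (crossing-to-crossing rule).
#' The default prominence is adaptive and scale-free:
#' max(0.1 uV, 0.5 x median of the positive envelope-baseline excursion).
#'
#' @param pair an \code{\link{envelope_pair}}.
#' @param prominence optional fixed prominence threshold (uV); \code{NULL}
#'   for the adaptive rule.
#' @return data.frame of breath geometry sorted by onset: \code{onset},
#'   \code{peak_time}, \code{offset} (s) and their sample indices
#'   \code{onset_i}, \code{peak_i}, \code{offset_i}. Zero rows if the
#'   envelope never exceeds the baseline.
#' @export
detect_neural_breaths <- function(pair, prominence = NULL) {
  stopifnot(inherits(pair, "envelope_pair"))
  env <- pair$envelope$values
  ex <- env - pair$baseline$values
  fs <- pair$envelope$fs
  t0 <- pair$envelope$t0
  pos <- ex > 0
  if (!any(pos)) return(empty_breaths())
  if (is.null(prominence)) {
    prominence <- max(0.1, 0.5 * stats::median(ex[pos]))
  }
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  n <- length(env)
  out <- lapply(runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- ex[i0:i1]
    if (max(seg) < prominence) return(NULL)
    pk <- i0 + which.max(seg) - 1L
    data.frame(onset_i = max(i0 - 1L, 1L), peak_i = pk,
               offset_i = min(i1 + 1L, n))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_breaths())
  out$onset <- t0 + (out$onset_i - 1L) / fs
  out$peak_time <- t0 + (out$peak_i - 1L) / fs
  out$offset <- t0 + (out$offset_i - 1L) / fs
  out[order(out$onset),
      c("onset", "peak_time", "offset", "onset_i", "peak_i", "offset_i")]
}

empty_breaths <- function() {
  data.frame(onset = numeric(0), peak_time = numeric(0),
             offset = numeric(0), onset_i = integer(0),
             peak_i = integer(0), offset_i = integer(0))
}

#' Per-breath sEAdi time-product
#'
#' ETPdi is the trapezoidal integral of the envelope over one breath span
#' (baseline crossing to baseline crossing), including the area under the
#' moving baseline (AUB); AUB is the integral of the baseline alone over
#' the same span. ETPdi - AUB is therefore the burst area above baseline.
#'
#' @param pair an \code{\link{envelope_pair}}.
#' @param onset,offset breath limits in seconds (offset > onset, both
#'   within the trace).
#' @return list with \code{etpdi} and \code{aub}, both in uV.s, >= 0.
#' @export
compute_etpdi <- function(pair, onset, offset) {
  stopifnot(inherits(pair, "envelope_pair"))
  if (offset <= onset) stop("offset must exceed onset", call. = FALSE)
  fs <- pair$envelope$fs
  t0 <- pair$envelope$t0
  n <- length(pair$envelope$values)
  i0 <- round((onset - t0) * fs) + 1L
  i1 <- round((offset - t0) * fs) + 1L
  if (i0 < 1L || i1 > n) stop("breath span outside trace", call. = FALSE)
  list(etpdi = trapz_idx(pair$envelope$values, i0, i1, fs),
       aub = trapz_idx(pair$baseline$values, i0, i1, fs))
}

#' Compute per-breath metrics for quality assessment
#'
#' Adds to each detected breath: \code{etpdi} and \code{aub}
#' (\code{\link{compute_etpdi}}); \code{snr}, the peak envelope height
#' above baseline divided by the RMS of the envelope-baseline excess over
#' non-breath periods; and \code{morphology_score}, one minus the L1
#' mismatch between the breath's excess curve and its moment-matched
#' Gaussian, relative to the area under the envelope (1 = ideal bell
#' shape, 0 = no resemblance).
#'
#' @param pair an \code{\link{envelope_pair}}.
#' @param breaths geometry from \code{\link{detect_neural_breaths}}.
#' @return the breath data.frame with metric columns appended.
#' @export
breath_metrics <- function(pair, breaths) {
  stopifnot(inherits(pair, "envelope_pair"))
  if (!nrow(breaths)) {
    breaths$etpdi <- numeric(0); breaths$aub <- numeric(0)
    breaths$snr <- numeric(0); breaths$morphology_score <- numeric(0)
    return(breaths)
  }
  env <- pair$envelope$values
  base <- pair$baseline$values
  ex <- env - base
  fs <- pair$envelope$fs
  n <- length(env)
  inb <- rep(FALSE, n)
  for (k in seq_len(nrow(breaths)))
    inb[breaths$onset_i[k]:breaths$offset_i[k]] <- TRUE
  noise_rms <- if (any(!inb)) sqrt(mean(ex[!inb]^2)) else 0

  res <- t(vapply(seq_len(nrow(breaths)), function(k) {
    i0 <- breaths$onset_i[k]; i1 <- breaths$offset_i[k]
    etp <- trapz_idx(env, i0, i1, fs)
    aub <- trapz_idx(base, i0, i1, fs)
    height <- ex[breaths$peak_i[k]]
    snr <- if (noise_rms > 0) height / noise_rms else Inf
    seg <- pmax(ex[i0:i1], 0)
    tt <- (seq.int(i0, i1) - 1L) / fs
    area <- sum(seg) / fs
    if (area > 0) {
      mu <- sum(tt * seg) / sum(seg)
      s2 <- sum((tt - mu)^2 * seg) / sum(seg)
      g <- if (s2 > 0) {
        area * stats::dnorm(tt, mu, sqrt(s2))
      } else {
        rep(0, length(tt))
      }
      mism <- sum(abs(seg - g)) / fs
      morph <- max(0, min(1, 1 - mism / max(etp, .Machine$double.eps)))
    } else morph <- 0
    c(etp, aub, snr, morph)
  }, numeric(4)))
  breaths$etpdi <- res[, 1]
  breaths$aub <- res[, 2]
  breaths$snr <- res[, 3]
  breaths$morphology_score <- res[, 4]
  breaths
}

#' Quality criteria for neural breaths
#'
#' Thresholds for the six-point quality gate. Three absolute criteria
#' (signal-to-noise ratio, baseline-dominated area fraction, peak
#' morphology) have configurable defaults; three exclusions are anchored
#' in the analysis protocol: peak duration below 0.5 s, AUB above four
#' times the recording's AUB upper quartile, and ETPdi above ten times the
#' recording's ETPdi 95th percentile (crosstalk indicators).
#'
#' @param snr_min minimum SNR (default 1.75).
#' @param aub_fraction_max maximum AUB/ETPdi fraction (default 0.8).
#' @param morphology_min minimum morphology score (default 0.6).
#' @param duration_min minimum breath duration, s (default 0.5).
#' @param rel_aub_factor multiple of the recording AUB upper quartile
#'   (default 4).
#' @param rel_etpdi_factor multiple of the recording ETPdi reference
#'   percentile (default 10).
#' @param rel_etpdi_percentile reference percentile for ETPdi (default 95).
#' @return object of class \code{quality_criteria}.
#' @export
quality_criteria <- function(snr_min = 1.75, aub_fraction_max = 0.8,
                             morphology_min = 0.6, duration_min = 0.5,
                             rel_aub_factor = 4, rel_etpdi_factor = 10,
                             rel_etpdi_percentile = 95) {
  qc <- list(snr_min = snr_min, aub_fraction_max = aub_fraction_max,
             morphology_min = morphology_min, duration_min = duration_min,
             rel_aub_factor = rel_aub_factor,
             rel_etpdi_factor = rel_etpdi_factor,
             rel_etpdi_percentile = rel_etpdi_percentile)
  for (f in names(qc))
    if (!is.numeric(qc[[f]]) || qc[[f]] <= 0)
      stop(sprintf("`%s` must be > 0", f), call. = FALSE)
  structure(qc, class = "quality_criteria")
}

#' Apply the six-point quality gate
#'
#' Flags each detected breath against the six criteria and marks it valid
#' iff no flag is raised. The relative references (AUB upper quartile,
#' ETPdi 95th percentile) are computed over all detected breaths of the
#' recording with the shared percentile convention (\code{\link{pctl}});
#' with fewer than four breaths the relative criteria are skipped and the
#' result carries attribute \code{relative_skipped = TRUE}.
#'
#' @param breaths data.frame from \code{\link{breath_metrics}} (columns
#'   \code{onset}, \code{offset}, \code{etpdi}, \code{aub}, \code{snr},
#'   \code{morphology_score}).
#' @param criteria a \code{\link{quality_criteria}}.
#' @return the data.frame with logical columns \code{flag_snr},
#'   \code{flag_aub_fraction}, \code{flag_morphology}, \code{flag_rel_aub},
#'   \code{flag_rel_etpdi}, \code{flag_duration} and \code{valid}.
#' @export
assess_quality <- function(breaths, criteria = quality_criteria()) {
  stopifnot(inherits(criteria, "quality_criteria"))
  need <- c("onset", "offset", "etpdi", "aub", "snr", "morphology_score")
  miss <- setdiff(need, names(breaths))
  if (length(miss))
    stop("missing breath columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(breaths)
  rel_ok <- n >= 4L
  q3_aub <- if (rel_ok) pctl(breaths$aub, 75) else NA_real_
  p95_etp <- if (rel_ok) pctl(breaths$etpdi, criteria$rel_etpdi_percentile)
             else NA_real_
  frac <- ifelse(breaths$etpdi > 0, breaths$aub / breaths$etpdi, 1)
  breaths$flag_snr <- breaths$snr < criteria$snr_min
  breaths$flag_aub_fraction <- frac > criteria$aub_fraction_max
  breaths$flag_morphology <-
    breaths$morphology_score < criteria$morphology_min
  breaths$flag_duration <-
    (breaths$offset - breaths$onset) < criteria$duration_min
  breaths$flag_rel_aub <- if (rel_ok)
    breaths$aub > criteria$rel_aub_factor * q3_aub else rep(FALSE, n)
  breaths$flag_rel_etpdi <- if (rel_ok)
    breaths$etpdi > criteria$rel_etpdi_factor * p95_etp else rep(FALSE, n)
  flags <- grep("^flag_", names(breaths), value = TRUE)
  breaths$valid <- !Reduce(`|`, breaths[flags])
  attr(breaths, "relative_skipped") <- !rel_ok
  attr(breaths, "aub_q3") <- q3_aub
  attr(breaths, "etpdi_p95") <- p95_etp
  breaths
}

#' Detect flow-based breaths from the ventilator volume tracing
#'
#' Candidate breaths are local maxima of the volume trace; tidal volume is
#' measured from the peak down to the preceding local minimum (robust to
#' incomplete return to zero volume). A candidate is included iff its
#' tidal volume exceeds 20 percent of the 75th percentile of all candidate
#' tidal volumes.
#'
#' @param volume a \code{\link{signal_trace}} in mL.
#' @param min_tv_frac inclusion fraction of the P75 (default 0.2).
#' @return data.frame: \code{peak_time} (s), \code{tv} (mL),
#'   \code{trough_time} (s), \code{included} (logical). Zero rows for a
#'   flat trace.
#' @export
detect_flow_breaths <- function(volume, min_tv_frac = 0.2) {
  stopifnot(inherits(volume, "signal_trace"))
  v <- volume$values
  n <- length(v)
  if (n < 3L) return(empty_flow_breaths())
  core <- 2:(n - 1L)
  pk <- core[v[core] > v[core - 1L] & v[core] >= v[core + 1L]]
  if (!length(pk)) return(empty_flow_breaths())
  prev_bound <- c(1L, pk[-length(pk)])
  trough_i <- vapply(seq_along(pk), function(k) {
    span <- prev_bound[k]:pk[k]
    span[which.min(v[span])]
  }, integer(1))
  tv <- v[pk] - v[trough_i]
  keep <- tv > 0
  pk <- pk[keep]; trough_i <- trough_i[keep]; tv <- tv[keep]
  if (!length(pk)) return(empty_flow_breaths())
  thr <- min_tv_frac * pctl(tv, 75)
  data.frame(
    peak_time = volume$t0 + (pk - 1L) / volume$fs,
    tv = tv,
    trough_time = volume$t0 + (trough_i - 1L) / volume$fs,
    included = tv > thr)
}

empty_flow_breaths <- function() {
  data.frame(peak_time = numeric(0), tv = numeric(0),
             trough_time = numeric(0), included = logical(0))
}

#' Respiratory rate from flow-based breaths
#'
#' Tbreath is the median inter-breath time between successive included
#' volume peaks (even counts use the mean of the two middle values); the
#' respiratory rate is 60 / Tbreath.
#'
#' @param flow_breaths data.frame from \code{\link{detect_flow_breaths}}.
#' @return list with \code{rr} (breaths/min) and \code{tbreath} (s).
#' @export
compute_rr <- function(flow_breaths) {
  pt <- flow_breaths$peak_time[flow_breaths$included]
  if (length(pt) < 2L)
    stop("at least 2 included flow breaths required", call. = FALSE)
  tbreath <- stats::median(diff(sort(pt)))
  list(rr = 60 / tbreath, tbreath = tbreath)
}
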