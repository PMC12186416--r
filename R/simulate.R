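#' Closed-form true neuro-ventilatory coupling of the generator
#'
#' Under the generating model TV_i = gain * drive_i + intercept + e_i with
#' e_i ~ N(0, tv_noise_sd^2) independent of drive, the population squared
#' Pearson correlation between drive and TV is
#' gain^2 Var(drive) / (gain^2 Var(drive) + tv_noise_sd^2), with
#' Var(drive) = (mean drive at the level x drive_cv)^2. This holds for any
#' drive distribution, so it is exact for the lognormal drive used here.
#'
#' @param config a \code{\link{sim_config}}.
#' @param ps_level PS level in cmH2O.
#' @return true NVC in percent (0-100).
#' @export
true_nvc <- function(config, ps_level) {
  m <- level_means(config, ps_level)
  sig2 <- (config$coupling_gain * m$drive * config$drive_cv)^2
  if (sig2 == 0 && config$tv_noise_sd == 0) return(0)
  100 * sig2 / (sig2 + config$tv_noise_sd^2)
}

# level means implied by the percentage-point response slopes, relative to
# the clinically set PS: drive and RR rise, TV falls, as PS is withdrawn
level_means <- function(config, ps_level) {
  delta <- config$clinical_ps - ps_level
  list(
    drive = config$baseline_drive *
      (1 + config$drive_slope_pp_per_cmH2O * delta / 100),
    tv = config$base_tv * (1 - config$tv_slope_pp_per_cmH2O * delta / 100),
    rr = config$base_rr * (1 + config$rr_slope_pp_per_cmH2O * delta / 100)
  )
}

#' Simulate one PS-level breath sequence
#'
#' Draws per-breath neural drive (lognormal with the configured
#' coefficient of variation) and tidal volume (linear in drive plus
#' Gaussian noise) for one pressure-support level. Breath timing is
#' periodic at the level's respiratory rate; the inspiratory time is fixed
#' at 1 s and the neural burst onset precedes the volume peak by
#' \code{neural_lead_time}.
#'
#' @param ps_level PS level in cmH2O (one of the protocol grid values).
#' @param config a \code{\link{sim_config}}.
#' @param duration segment duration in seconds.
#' @param seed optional integer seed; if \code{NULL} the current RNG stream
#'   is used.
#' @return data.frame with one row per breath: \code{onset} (inspiration
#'   onset, s), \code{peak_time} (volume peak, s), \code{neural_onset}
#'   (burst onset, s), \code{drive} (uV.s), \code{tv} (mL), \code{ibi}
#'   (inter-breath interval, s). Zero rows (with a warning) if the duration
#'   cannot hold one breath.
#' @export
simulate_breath_sequence <- function(ps_level, config, duration,
                                     seed = NULL) {
  stopifnot(inherits(config, "sim_config"), duration > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  m <- level_means(config, ps_level)
  # breath timing snapped to the 100 Hz ventilator grid: timing ground
  # truth is then exactly representable on the analysis grid
  tb <- round(60 / m$rr, 2)
  ti <- round(min(1.0, 0.45 * tb), 2)   # inspiratory time
  first <- round(max(config$neural_lead_time + 0.25, 0.5), 2)
  onsets <- seq(first, by = tb, length.out = max(
    0L, floor((duration - first - ti - 0.5) / tb) + 1L))
  n <- length(onsets)
  if (n == 0L) {
    warning("duration too short to contain one breath; empty sequence")
    return(data.frame(onset = numeric(0), peak_time = numeric(0),
                      neural_onset = numeric(0), drive = numeric(0),
                      tv = numeric(0), ibi = numeric(0)))
  }
  if (config$drive_cv > 0) {
    sdlog <- sqrt(log(1 + config$drive_cv^2))
    drive <- stats::rlnorm(n, meanlog = log(m$drive) - sdlog^2 / 2,
                           sdlog = sdlog)
  } else {
    drive <- rep(m$drive, n)
  }
  intercept <- m$tv - config$coupling_gain * m$drive
  tv <- config$coupling_gain * drive + intercept +
    stats::rnorm(n, 0, config$tv_noise_sd)
  tv <- pmax(tv, 1)    # physical floor; untouched under default noise
  data.frame(onset = onsets, peak_time = onsets + ti,
             neural_onset = onsets + ti - config$neural_lead_time,
             drive = drive, tv = tv, ibi = tb)
}

# triphasic QRS template sampled at fs over +-60 ms around the R time;
# amplitudes relative to the R peak
qrs_template <- function(fs) {
  t <- seq(-0.06, 0.06, by = 1 / fs)
  -0.25 * exp(-((t + 0.030) / 0.008)^2) +
    1.00 * exp(-((t) / 0.010)^2) -
    0.35 * exp(-((t - 0.030) / 0.009)^2)
}

# unit-RMS band-limited Gaussian noise (20-400 Hz at fs)
band_noise <- function(n, fs, band = c(20, 400)) {
  x <- stats::rnorm(n)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  s <- sqrt(mean(y^2))
  if (s > 0) y / s else y
}

#' Render raw recordings for a breath sequence
#'
#' Produces the five channels of one PS-level segment: surface EMG (2048
#' Hz) as band-limited noise amplitude-modulated by a raised-cosine (Hann)
#' burst per breath, with the burst's envelope area above baseline equal to
#' the breath's drive; an ECG channel with a stereotyped triphasic QRS
#' train (with 5 percent R-R jitter) that also contaminates the EMG
#' channel; and ventilator airway pressure, flow and volume at 100 Hz, the
#' volume rising to the breath's tidal volume and decaying passively. The
#' generator also emits its programmed (ideal) envelope and baseline as
#' ground truth for the detection geometry.
#'
#' @param breaths a breath sequence from
#'   \code{\link{simulate_breath_sequence}}.
#' @param config a \code{\link{sim_config}}.
#' @param duration segment duration in seconds.
#' @param seed optional integer seed.
#' @param ps_level PS level used only to shape the airway-pressure channel.
#' @return named list of \code{\link{signal_trace}} objects: \code{semg},
#'   \code{ecg} (2048 Hz), \code{paw}, \code{flow}, \code{volume},
#'   \code{ideal_envelope}, \code{ideal_baseline} (100 Hz).
#' @export
render_signals <- function(breaths, config, duration, seed = NULL,
                           ps_level = config$clinical_ps) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  fs_e <- 2048; fs_v <- 100
  n_e <- round(duration * fs_e)
  n_v <- round(duration * fs_v)
  t_e <- (seq_len(n_e) - 1) / fs_e
  t_v <- (seq_len(n_v) - 1) / fs_v

  dur <- config$burst_duration
  amp_of <- function(tt) {
    a <- numeric(length(tt))
    for (k in seq_len(nrow(breaths))) {
      on <- breaths$neural_onset[k]
      amp <- 2 * breaths$drive[k] / dur      # Hann integral = dur/2
      idx <- which(tt >= on & tt <= on + dur)
      if (length(idx))
        a[idx] <- a[idx] + amp * 0.5 * (1 - cos(2 * pi * (tt[idx] - on) / dur))
    }
    a
  }
  a_e <- amp_of(t_e)
  # noise floor with slow amplitude drift (period 60 s)
  floor_of <- function(tt)
    config$baseline_noise_sd +
      config$drift_amplitude * 0.5 * (1 + sin(2 * pi * tt / 60))
  f_e <- floor_of(t_e)

  semg <- numeric(n_e)
  if (any(a_e > 0)) semg <- semg + a_e * band_noise(n_e, fs_e)
  if (any(f_e > 0)) semg <- semg + f_e * band_noise(n_e, fs_e)

  # ECG: R times with 5% R-R jitter, shared by both channels
  ecg <- numeric(n_e)
  if (config$ecg_amplitude > 0) {
    rr_s <- 60 / config$ecg_rate
    r_times <- c()
    tcur <- 0.4
    while (tcur < duration - 0.1) {
      r_times <- c(r_times, tcur)
      tcur <- tcur + rr_s * stats::runif(1, 0.95, 1.05)
    }
    tmpl <- config$ecg_amplitude * qrs_template(fs_e)
    half <- (length(tmpl) - 1L) %/% 2L
    for (rt in r_times) {
      i0 <- round(rt * fs_e) + 1L - half
      ii <- seq(i0, i0 + length(tmpl) - 1L)
      keep <- ii >= 1L & ii <= n_e
      ecg[ii[keep]] <- ecg[ii[keep]] + tmpl[keep]
    }
    semg <- semg + 0.5 * ecg    # crosstalk onto the EMG electrode pair
  }

  # ventilator channels
  volume <- numeric(n_v)
  ti <- if (nrow(breaths)) breaths$peak_time[1] - breaths$onset[1] else 1
  tb <- if (nrow(breaths)) breaths$ibi[1] else 3
  tau <- max((tb - ti) / 5, 0.2)
  resid <- 0
  bounds <- c(breaths$onset, duration)
  for (k in seq_len(nrow(breaths))) {
    on <- breaths$onset[k]; pk <- on + ti
    seg <- which(t_v >= on & t_v < bounds[k + 1L])
    tt <- t_v[seg]
    up <- tt <= pk
    v <- numeric(length(tt))
    v[up] <- resid + breaths$tv[k] * 0.5 * (1 - cos(pi * (tt[up] - on) / ti))
    peak_val <- resid + breaths$tv[k]
    v[!up] <- peak_val * exp(-(tt[!up] - pk) / tau)
    volume[seg] <- v
    resid <- peak_val * exp(-(bounds[k + 1L] - pk) / tau)
  }
  flow <- c(0, diff(volume)) * fs_v            # mL/s
  paw <- rep(5, n_v)                           # PEEP
  for (k in seq_len(nrow(breaths))) {
    idx <- which(t_v >= breaths$onset[k] & t_v <= breaths$onset[k] + ti)
    if (length(idx))
      paw[idx] <- 5 + ps_level *
        pmin(1, (t_v[idx] - breaths$onset[k]) / 0.15)
  }

  a_v <- amp_of(t_v)
  f_v <- floor_of(t_v)
  ideal_env <- sqrt(a_v^2 + f_v^2)   # RMS of independent burst + floor
  list(
    semg = signal_trace(semg, fs_e, unit = "uV"),
    ecg = signal_trace(ecg, fs_e, unit = "uV"),
    paw = signal_trace(paw, fs_v, unit = "cmH2O"),
    flow = signal_trace(flow, fs_v, unit = "mL/s"),
    volume = signal_trace(volume, fs_v, unit = "mL"),
    ideal_envelope = signal_trace(ideal_env, fs_v, unit = "uV"),
    ideal_baseline = signal_trace(f_v, fs_v, unit = "uV")
  )
}

#' Simulate a full decremental PS-trial
#'
#' Runs \code{\link{make_protocol}} on the configured clinical PS level and
#' renders one segment per protocol level, in decremental order, each of
#' \code{level_duration} seconds. One sub-seed per segment is derived from
#' the trial seed so segments are individually reproducible and the whole
#' trial is bit-identical for a fixed configuration.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{signals} (concatenated
#'   \code{signal_trace} channels spanning the whole trial),
#'   \code{segments} (data.frame: \code{ps_level}, \code{t_start},
#'   \code{t_end}), and \code{ground_truth} (list: \code{breaths} —
#'   per-breath truth in trial time with PS level — and \code{nvc} — the
#'   closed-form true NVC per level).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  protocol <- make_protocol(config$clinical_ps)
  dur <- config$level_duration
  segs <- data.frame(ps_level = protocol,
                     t_start = (seq_along(protocol) - 1) * dur,
                     t_end = seq_along(protocol) * dur)
  chans <- c("semg", "ecg", "paw", "flow", "volume",
             "ideal_envelope", "ideal_baseline")
  parts <- vector("list", length(protocol))
  truth <- vector("list", length(protocol))
  for (k in seq_along(protocol)) {
    sk <- segment_seed(config$seed, k)
    br <- simulate_breath_sequence(protocol[k], config, dur, seed = sk)
    sg <- render_signals(br, config, dur, seed = segment_seed(config$seed,
                                                              k + 1000L),
                         ps_level = protocol[k])
    parts[[k]] <- sg
    off <- segs$t_start[k]
    truth[[k]] <- transform(br, onset = onset + off,
                            peak_time = peak_time + off,
                            neural_onset = neural_onset + off,
                            ps_level = protocol[k])
  }
  signals <- lapply(chans, function(ch) {
    v <- unlist(lapply(parts, function(p) p[[ch]]$values))
    signal_trace(v, parts[[1]][[ch]]$fs, t0 = 0,
                 unit = parts[[1]][[ch]]$unit)
  })
  names(signals) <- chans
  breaths <- do.call(rbind, truth)
  rownames(breaths) <- NULL
  nvc <- data.frame(ps_level = protocol,
                    nvc_true = vapply(protocol, function(p)
                      true_nvc(config, p), numeric(1)))
  list(signals = signals, segments = segs,
       ground_truth = list(breaths = breaths, nvc = nvc))
}

segment_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 8191 + k * 127) %% 2147483629)
}

#' Simulate a cohort of trial-level summaries
#'
#' Generates per-level median ETPdi, tidal volume and respiratory rate for
#' a cohort of patients with repeated PS-trials, directly from the
#' statistical model the full generator embeds: large lognormal
#' between-patient and between-trial scale heterogeneity in the absolute
#' values, the configured percentage-point response slopes within each
#' trial (anchored at the PS-12 reference level, the same anchor the
#' normalisation step uses), and multiplicative within-trial noise on the
#' level medians. This
#' is the input scale at which the group-level analyses (normalisation,
#' variance decomposition, marginal slope regression) operate.
#'
#' @param n_patients number of patients (default 13).
#' @param trials_per_patient repeated PS-trials per patient (default 2).
#' @param drive_slope,tv_slope,rr_slope programmed response slopes in pp
#'   per cmH2O of PS reduction (defaults 2.4, 2.5, 1.6).
#' @param level_noise_cv multiplicative CV of within-trial level medians
#'   around their programmed values (default 0.08).
#' @param patient_sdlog,trial_sdlog lognormal SD (log scale) of
#'   between-patient and between-trial ETPdi scale (defaults 0.8, 0.4);
#'   TV/RR heterogeneity uses a quarter of these.
#' @param seed integer seed.
#' @return data.frame: \code{patient}, \code{trial}, \code{clinical_ps},
#'   \code{ps_level}, \code{median_etpdi}, \code{median_tv}, \code{rr}.
#' @export
simulate_cohort <- function(n_patients = 13, trials_per_patient = 2,
                            drive_slope = 2.4, tv_slope = 2.5,
                            rr_slope = 1.6, level_noise_cv = 0.08,
                            patient_sdlog = 0.8, trial_sdlog = 0.4,
                            seed = 1L) {
  set.seed(as.integer(seed))
  rows <- list()
  for (p in seq_len(n_patients)) {
    clin <- sample(c(6, 8, 10, 12, 14), 1)
    p_etp <- stats::rlnorm(1, log(3), patient_sdlog)
    p_tv <- stats::rlnorm(1, log(450), patient_sdlog / 4)
    p_rr <- stats::rlnorm(1, log(18), patient_sdlog / 4)
    for (tr in seq_len(trials_per_patient)) {
      t_etp <- p_etp * stats::rlnorm(1, 0, trial_sdlog)
      t_tv <- p_tv * stats::rlnorm(1, 0, trial_sdlog / 4)
      t_rr <- p_rr * stats::rlnorm(1, 0, trial_sdlog / 4)
      levels <- make_protocol(clin)
      # slopes anchored at the common PS-12 reference, the same anchor the
      # normalisation step uses, so the programmed normalised slope is
      # exact regardless of the clinical level
      delta <- 12 - levels
      noise <- function(n) stats::rlnorm(n, 0, sqrt(log(1 + level_noise_cv^2)))
      rows[[length(rows) + 1L]] <- data.frame(
        patient = p, trial = tr, clinical_ps = clin, ps_level = levels,
        median_etpdi = t_etp * (1 + drive_slope * delta / 100) * noise(4),
        median_tv = t_tv * (1 - tv_slope * delta / 100) * noise(4),
        rr = t_rr * (1 + rr_slope * delta / 100) * noise(4))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
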