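#' Simulation configuration
#'
#' Parameters of the synthetic recording generator. Defaults encode the
#' study conditions the generator emulates: a decremental four-level
#' pressure-support (PS) trial with at least five minutes per level, neural
#' drive (ETPdi) rising by 2.4 percentage points (pp) and respiratory rate
#' by 1.6 pp per cmH2O of PS withdrawn, tidal volume falling by 2.5 pp per
#' cmH2O, tidal volume linearly coupled to per-breath drive with additive
#' Gaussian noise (the structure neuro-ventilatory coupling measures),
#' QRS-shaped ECG contamination, a noise floor, and slow baseline drift.
#'
#' @param clinical_ps clinically set PS level, cmH2O; selects the protocol
#'   row (see \code{\link{make_protocol}}).
#' @param level_duration seconds per PS level (default 300; must be >= 60
#'   for usable within-level statistics).
#' @param baseline_drive mean per-breath drive (ETPdi) at the clinical PS,
#'   in uV.s.
#' @param drive_slope_pp_per_cmH2O,tv_slope_pp_per_cmH2O,rr_slope_pp_per_cmH2O
#'   response slopes in percent of the clinical-level value per cmH2O of PS
#'   reduction. Drive and RR rise, TV falls, as PS falls.
#' @param base_tv mean tidal volume at clinical PS, mL.
#' @param base_rr respiratory rate at clinical PS, breaths/min.
#' @param coupling_gain mL of tidal volume per uV.s of drive; together with
#'   \code{tv_noise_sd} and \code{drive_cv} it sets the true per-level
#'   coupling R^2 (see \code{\link{true_nvc}}).
#' @param tv_noise_sd SD of drive-independent tidal-volume noise, mL.
#' @param drive_cv breath-to-breath coefficient of variation of drive
#'   (lognormal; dimensionless, >= 0).
#' @param ecg_rate,ecg_amplitude heart rate (bpm) and R-wave amplitude (uV)
#'   of the stereotyped triphasic QRS artifact added to both channels.
#' @param baseline_noise_sd SD of the broadband EMG noise floor, uV.
#' @param drift_amplitude amplitude of slow sinusoidal baseline drift, uV.
#' @param neural_lead_time seconds by which neural (burst) onset precedes
#'   the volume peak of the same breath.
#' @param burst_duration duration of one raised-cosine sEMG burst, s
#'   (0.8-1.5 s is physiological).
#' @param seed integer seed; the trial simulator derives one sub-seed per
#'   PS-level segment from it so segments are individually reproducible.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(clinical_ps = 8,
                       level_duration = 300,
                       baseline_drive = 3,
                       drive_slope_pp_per_cmH2O = 2.4,
                       tv_slope_pp_per_cmH2O = 2.5,
                       rr_slope_pp_per_cmH2O = 1.6,
                       base_tv = 450,
                       base_rr = 18,
                       coupling_gain = 60,
                       tv_noise_sd = 45,
                       drive_cv = 0.25,
                       ecg_rate = 80,
                       ecg_amplitude = 50,
                       baseline_noise_sd = 0.5,
                       drift_amplitude = 0.3,
                       neural_lead_time = 0.3,
                       burst_duration = 1.2,
                       seed = 1L) {
  cfg <- list(clinical_ps = clinical_ps, level_duration = level_duration,
              baseline_drive = baseline_drive,
              drive_slope_pp_per_cmH2O = drive_slope_pp_per_cmH2O,
              tv_slope_pp_per_cmH2O = tv_slope_pp_per_cmH2O,
              rr_slope_pp_per_cmH2O = rr_slope_pp_per_cmH2O,
              base_tv = base_tv, base_rr = base_rr,
              coupling_gain = coupling_gain, tv_noise_sd = tv_noise_sd,
              drive_cv = drive_cv, ecg_rate = ecg_rate,
              ecg_amplitude = ecg_amplitude,
              baseline_noise_sd = baseline_noise_sd,
              drift_amplitude = drift_amplitude,
              neural_lead_time = neural_lead_time,
              burst_duration = burst_duration,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("clinical_ps", "level_duration", "baseline_drive", "base_tv",
           "base_rr", "ecg_rate", "burst_duration")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("`%s` must be > 0", f), call. = FALSE)
  nonneg <- c("drive_cv", "tv_noise_sd", "ecg_amplitude",
              "baseline_noise_sd", "drift_amplitude", "coupling_gain",
              "neural_lead_time")
  for (f in nonneg)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("`%s` must be >= 0", f), call. = FALSE)
  if (cfg$level_duration < 60)
    stop("`level_duration` must be >= 60 s for usable statistics",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(x)) cat(sprintf("  %s: %g\n", f, x[[f]]))
  invisible(x)
}

#' Decremental PS-trial protocol
#'
#' Maps the clinically set pressure-support level to the four decremental
#' study levels. Levels live on the 3-cmH2O grid \{3, 6, ..., 21\} and a PS
#' of 12 cmH2O is a member of every protocol, which is what later anchors
#' the normalisation step. Relative to the clinical value the four levels
#' are approximately -3, +0, +3 and +6 cmH2O.
#'
#' @param clinical_ps clinically set PS level in cmH2O (> 0).
#' @return numeric vector of four PS levels in decreasing order.
#' @examples
#' make_protocol(8)   # 12 9 6 3
#' make_protocol(10)  # 15 12 9 6
#' make_protocol(16)  # 21 18 15 12
#' @export
make_protocol <- function(clinical_ps) {
  stopifnot(is.numeric(clinical_ps), length(clinical_ps) == 1L,
            clinical_ps > 0)
  if (clinical_ps <= 8)       c(12, 9, 6, 3)
  else if (clinical_ps <= 11) c(15, 12, 9, 6)
  else if (clinical_ps <= 14) c(18, 15, 12, 9)
  else                        c(21, 18, 15, 12)
}
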