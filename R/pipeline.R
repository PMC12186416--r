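#' Pipeline configuration
#'
#' All tunable constants of the per-trial processing chain in one place.
#' Defaults are the package's documented choices: 20-400 Hz zero-phase
#' band-pass, QRS gate from 50 ms before to 100 ms after each R wave,
#' 250 ms RMS envelope on the 100 Hz ventilator grid, rolling 33rd
#' percentile baseline over 7.5 s with 1 s smoothing, the six-point
#' quality gate, Tbreath/2-before to 0.5 s-after matching, Tukey fences at
#' 1.5 IQR, at least 5 pairs per level for NVC, and the 10 percent trial
#' validity rule.
#'
#' @param band,filter_order EMG band-pass edges (Hz) and order.
#' @param gate_window QRS gate relative to the R time, s.
#' @param rms_window envelope RMS window, s.
#' @param env_fs envelope/ventilator grid, Hz.
#' @param baseline_window,baseline_percentile,baseline_smooth moving
#'   baseline parameters (s, percent, s).
#' @param prominence breath-detection prominence (uV) or NULL for the
#'   adaptive rule.
#' @param quality a \code{\link{quality_criteria}}.
#' @param match_after late limit of the matching window, s.
#' @param min_pairs minimum pairs per level for NVC.
#' @param fence_k Tukey fence multiplier.
#' @param validity_fraction minimum valid-neural fraction per level.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(band = c(20, 400), filter_order = 4,
                            gate_window = c(-0.05, 0.10),
                            rms_window = 0.25, env_fs = 100,
                            baseline_window = 7.5,
                            baseline_percentile = 33,
                            baseline_smooth = 1, prominence = NULL,
                            quality = quality_criteria(),
                            match_after = 0.5, min_pairs = 5,
                            fence_k = 1.5, validity_fraction = 0.10) {
  structure(list(band = band, filter_order = filter_order,
                 gate_window = gate_window, rms_window = rms_window,
                 env_fs = env_fs, baseline_window = baseline_window,
                 baseline_percentile = baseline_percentile,
                 baseline_smooth = baseline_smooth,
                 prominence = prominence, quality = quality,
                 match_after = match_after, min_pairs = min_pairs,
                 fence_k = fence_k,
                 validity_fraction = validity_fraction),
            class = "pipeline_config")
}

# rolling polynomial hash of the deparsed configuration (report provenance)
config_hash <- function(config) {
  s <- utf8ToInt(paste(deparse(unclass(config)), collapse = ""))
  h <- 0
  for (ch in s) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Process one PS-trial end to end
#'
#' Runs the full analysis on one trial's synchronized recordings:
#' band-pass filtering and ECG gating of the sEMG, sEAdi envelope and
#' moving baseline, neural breath detection with the six-point quality
#' gate (relative references pooled over the whole recording), flow-breath
#' detection on the volume tracing, per-level respiratory rate, one-to-one
#' neural/flow matching, the 10 percent trial-validity rule, and per-level
#' NVC with Tukey-fence outlier exclusion. Entirely deterministic for
#' fixed inputs and configuration.
#'
#' @param signals named list of \code{\link{signal_trace}}s with at least
#'   \code{semg}, \code{ecg} and \code{volume}.
#' @param segments data.frame with \code{ps_level}, \code{t_start},
#'   \code{t_end} (non-overlapping, decremental protocol order).
#' @param config a \code{\link{pipeline_config}}.
#' @return list of class \code{trial_result}: \code{breath_table} (tidy
#'   per-breath rows, neural and flow), \code{matched} (pair table),
#'   \code{nvc} (per level), \code{level_summary} (per-level counts,
#'   medians, RR, dispersion), \code{valid_trial}, \code{baseline_cov},
#'   \code{envelope} (the \code{envelope_pair}), \code{report}.
#' @export
process_trial <- function(signals, segments,
                          config = pipeline_config()) {
  stopifnot(all(c("semg", "ecg", "volume") %in% names(signals)),
            all(c("ps_level", "t_start", "t_end") %in% names(segments)))
  t0s <- vapply(signals[c("semg", "ecg", "volume")], function(s) s$t0,
                numeric(1))
  if (diff(range(t0s)) > 0.010)
    stop("channel time origins differ by more than 10 ms", call. = FALSE)

  emg <- preprocess_emg(signals$semg, band = config$band,
                        order = config$filter_order)
  qrs <- detect_qrs(signals$ecg)
  gated <- gate_ecg(emg, qrs, window = config$gate_window)
  env <- compute_envelope(gated, rms_window = config$rms_window,
                          out_fs = config$env_fs)
  base <- moving_baseline(env, window = config$baseline_window,
                          percentile = config$baseline_percentile,
                          smooth = config$baseline_smooth)
  pair <- envelope_pair(env, base)
  geom <- detect_neural_breaths(pair, prominence = config$prominence)
  neural <- assess_quality(breath_metrics(pair, geom),
                           criteria = config$quality)
  neural$ps_level <- level_of(neural$peak_time, segments)
  flow <- detect_flow_breaths(signals$volume)
  flow$ps_level <- level_of(flow$peak_time, segments)

  levels <- segments$ps_level
  matched_parts <- list()
  level_rows <- list()
  for (l in levels) {
    n_sel <- which(!is.na(neural$ps_level) & neural$ps_level == l)
    f_sel <- which(!is.na(flow$ps_level) & flow$ps_level == l)
    nb <- neural[n_sel, ]
    fb <- flow[f_sel, ]
    inc <- fb[fb$included, ]
    rr <- if (nrow(inc) >= 2L) compute_rr(fb) else
      list(rr = NA_real_, tbreath = NA_real_)
    m <- if (is.finite(rr$tbreath))
      match_breaths(fb, nb, rr$tbreath, after = config$match_after)
    else empty_matches()
    if (nrow(m)) {
      m$ps_level <- l
      m$neural_row <- n_sel[m$neural_row]   # map back to trial tables
      m$flow_row <- f_sel[m$flow_row]
    }
    matched_parts[[as.character(l)]] <- m
    vals <- nb$etpdi[nb$valid]
    level_rows[[as.character(l)]] <- data.frame(
      ps_level = l,
      n_neural = nrow(nb), n_valid_neural = sum(nb$valid),
      n_flow = nrow(inc), n_matched = nrow(m),
      rr = rr$rr, tbreath = rr$tbreath,
      median_etpdi = if (length(vals)) stats::median(vals) else NA_real_,
      median_tv = if (nrow(inc)) stats::median(inc$tv) else NA_real_,
      dispersion_etpdi = if (length(vals) >= 4L && stats::median(vals) > 0)
        relative_dispersion(vals) else NA_real_)
  }
  level_summary <- do.call(rbind, level_rows)
  rownames(level_summary) <- NULL
  matched_parts <- Filter(function(m) nrow(m) > 0, matched_parts)
  matched <- do.call(rbind, matched_parts)
  if (is.null(matched)) {
    matched <- empty_matches()
    matched$ps_level <- numeric(0)
  }
  rownames(matched) <- NULL
  nvc <- if (nrow(matched))
    nvc_by_level(matched, min_pairs = config$min_pairs,
                 k = config$fence_k)
  else data.frame()
  valid_trial <- check_trial_validity(level_summary,
                                      min_fraction =
                                        config$validity_fraction)

  neural$matched <- seq_len(nrow(neural)) %in% matched$neural_row
  flow$matched <- seq_len(nrow(flow)) %in% matched$flow_row
  breath_table <- rbind(
    data.frame(type = "neural", ps_level = neural$ps_level,
               time = neural$peak_time, etpdi = neural$etpdi,
               aub = neural$aub, tv = NA_real_,
               valid = neural$valid, matched = neural$matched),
    data.frame(type = "flow", ps_level = flow$ps_level,
               time = flow$peak_time, etpdi = NA_real_, aub = NA_real_,
               tv = flow$tv, valid = flow$included,
               matched = flow$matched))
  rownames(breath_table) <- NULL

  flag_cols <- grep("^flag_", names(neural), value = TRUE)
  exclusions <- vapply(flag_cols, function(f) sum(neural[[f]]),
                       numeric(1))
  report <- list(
    n_qrs = length(qrs),
    baseline_cov_pct = baseline_cov(base),
    levels = level_summary,
    exclusion_histogram = as.list(exclusions),
    valid_trial = as.logical(valid_trial),
    nvc = nvc,
    config_hash = config_hash(config))
  structure(list(breath_table = breath_table, neural = neural,
                 flow = flow, matched = matched, nvc = nvc,
                 level_summary = level_summary,
                 valid_trial = as.logical(valid_trial),
                 baseline_cov = report$baseline_cov_pct,
                 envelope = pair, report = report),
            class = "trial_result")
}

level_of <- function(times, segments) {
  out <- rep(NA_real_, length(times))
  for (k in seq_len(nrow(segments))) {
    inside <- times >= segments$t_start[k] & times < segments$t_end[k]
    out[inside] <- segments$ps_level[k]
  }
  out
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result>\n")
  cat(sprintf("  trial valid (10%% rule): %s\n", x$valid_trial))
  cat(sprintf("  baseline CoV: %.1f%%\n", x$baseline_cov))
  print(x$level_summary)
  if (nrow(x$nvc)) {
    cat("  NVC per level:\n")
    print(x$nvc)
  }
  invisible(x)
}
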