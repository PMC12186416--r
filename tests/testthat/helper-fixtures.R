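# shared fixtures built in code

# envelope pair with a constant baseline and a triangular burst of given
# height above baseline over [t_on, t_off], peak midway, at fs Hz
triangle_pair <- function(height = 4, base_level = 1, t_on = 1, t_off = 3,
                          total = 4, fs = 100) {
  t <- seq(0, total, by = 1 / fs)
  mid <- (t_on + t_off) / 2
  half <- (t_off - t_on) / 2
  tri <- pmax(0, 1 - abs(t - mid) / half) * height
  envelope_pair(signal_trace(base_level + tri, fs),
                signal_trace(rep(base_level, length(t)), fs))
}

# envelope pair with k raised-cosine bursts on a constant baseline
burst_pair <- function(k = 5, amp = 5, dur = 1.2, period = 3,
                       base_level = 0.2, fs = 100, total = NULL) {
  if (is.null(total)) total <- k * period + 2
  t <- seq(0, total, by = 1 / fs)
  env <- rep(base_level, length(t))
  onsets <- 1 + (seq_len(k) - 1) * period
  for (on in onsets)
    env <- env + ifelse(t >= on & t <= on + dur,
                        amp * 0.5 * (1 - cos(2 * pi * (t - on) / dur)), 0)
  list(pair = envelope_pair(signal_trace(env, fs),
                            signal_trace(rep(base_level, length(t)), fs)),
       onsets = onsets, dur = dur)
}

# metric table of n well-behaved breaths passing every quality criterion
good_breaths <- function(n = 30) {
  data.frame(onset = seq_len(n) * 4, peak_time = seq_len(n) * 4 + 1,
             offset = seq_len(n) * 4 + 2,
             etpdi = 5 + 0.01 * seq_len(n), aub = 1,
             snr = 10, morphology_score = 0.9)
}

# noiseless generator configuration (no ECG, no noise floor, no drift)
noiseless_config <- function(seed = 7, level_duration = 90, ...) {
  sim_config(clinical_ps = 8, level_duration = level_duration,
             ecg_amplitude = 0, baseline_noise_sd = 0,
             drift_amplitude = 0, tv_noise_sd = 0, seed = seed, ...)
}
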