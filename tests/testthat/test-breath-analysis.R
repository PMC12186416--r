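test_that("neural breaths are bounded by baseline crossings", {
  bp <- burst_pair(k = 5)
  br <- detect_neural_breaths(bp$pair)
  expect_equal(nrow(br), 5)
  expect_true(all(br$onset < br$peak_time & br$peak_time < br$offset))
  expect_equal(br$onset, bp$onsets, tolerance = 0.011)
  expect_equal(br$offset, bp$onsets + bp$dur, tolerance = 0.011)
  # envelope identical to baseline: nothing to detect
  flatp <- envelope_pair(signal_trace(rep(1, 5000), 100),
                         signal_trace(rep(1, 5000), 100))
  expect_equal(nrow(detect_neural_breaths(flatp)), 0)
})

test_that("a sub-baseline dip is required to split two peaks", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  # two humps whose separating dip stays above baseline
  env <- 0.5 + 4 * exp(-((t - 4) / 0.5)^2) + 4 * exp(-((t - 6) / 0.5)^2)
  pair <- envelope_pair(signal_trace(env, fs),
                        signal_trace(rep(0.5 + 1e-9, length(t)), fs))
  br <- detect_neural_breaths(pair)
  expect_equal(nrow(br), 1)   # crossing-to-crossing rule merges them
})

test_that("ETPdi and AUB follow the trapezoidal closed form", {
  pair <- triangle_pair(height = 4, base_level = 1, t_on = 1, t_off = 3)
  res <- compute_etpdi(pair, 1, 3)
  expect_equal(res$aub, 2, tolerance = 1e-9)
  expect_equal(res$etpdi, 6, tolerance = 1e-9)
  # doubling the envelope doubles ETPdi - AUB exactly
  p2 <- envelope_pair(signal_trace(2 * pair$envelope$values -
                                     pair$baseline$values, 100),
                      pair$baseline)
  r2 <- compute_etpdi(p2, 1, 3)
  expect_equal(r2$etpdi - r2$aub, 2 * (res$etpdi - res$aub),
               tolerance = 1e-12)
  # degenerate spans
  zp <- envelope_pair(signal_trace(rep(0, 500), 100),
                      signal_trace(rep(0, 500), 100))
  expect_equal(compute_etpdi(zp, 1, 3), list(etpdi = 0, aub = 0))
  expect_error(compute_etpdi(pair, 3, 1), "onset")
})

test_that("each quality criterion flags its constructed violator once", {
  base <- good_breaths(30)
  viol <- rbind(
    transform(base[1, ], offset = onset + 0.4),             # DURATION
    transform(base[1, ], aub = 5, etpdi = 8),               # REL_AUB
    transform(base[1, ], etpdi = 999),                      # REL_ETPDI
    transform(base[1, ], snr = 1.0),                        # SNR
    transform(base[1, ], aub = 3.9, etpdi = 4.5),           # AUB fraction
    transform(base[1, ], morphology_score = 0.3))           # MORPHOLOGY
  all_b <- rbind(base, viol)
  # fixed point for the relative-ETPdi violator: 12 x recording P95
  p95 <- pctl(all_b$etpdi, 95)
  all_b$etpdi[nrow(base) + 3] <- 12 * p95
  expect_equal(pctl(all_b$etpdi, 95), p95)  # P95 untouched by the max
  res <- assess_quality(all_b, quality_criteria())
  expect_equal(sum(res$flag_duration), 1)
  expect_equal(sum(res$flag_rel_aub), 1)
  expect_equal(sum(res$flag_rel_etpdi), 1)
  expect_equal(sum(res$flag_snr), 1)
  expect_equal(sum(res$flag_aub_fraction), 1)
  expect_equal(sum(res$flag_morphology), 1)
  expect_equal(sum(res$valid), 30)
  expect_which <- which(!res$valid)
  expect_equal(sort(expect_which), 31:36)
})

test_that("quality thresholds anchor at the documented exclusions", {
  b <- good_breaths(20)
  b$offset[1] <- b$onset[1] + 0.49
  res <- assess_quality(b)
  expect_true(res$flag_duration[1])
  b$offset[1] <- b$onset[1] + 0.51
  expect_false(assess_quality(b)$flag_duration[1])
  # AUB at 5x the upper quartile trips the 4x rule
  b2 <- good_breaths(20)
  b2$aub[5] <- 5 * pctl(b2$aub, 75)
  expect_true(assess_quality(b2)$flag_rel_aub[5])
})

test_that("relaxing any threshold never reduces the valid count", {
  set.seed(42)
  b <- good_breaths(40)
  b$snr <- runif(40, 0.5, 12)
  b$aub <- runif(40, 0.2, 6)
  b$morphology_score <- runif(40)
  b$offset <- b$onset + runif(40, 0.3, 3)
  strict <- quality_criteria(snr_min = 3, aub_fraction_max = 0.5,
                             morphology_min = 0.8, duration_min = 1,
                             rel_aub_factor = 2, rel_etpdi_factor = 5)
  relaxed_list <- list(
    quality_criteria(snr_min = 1, aub_fraction_max = 0.5,
                     morphology_min = 0.8, duration_min = 1,
                     rel_aub_factor = 2, rel_etpdi_factor = 5),
    quality_criteria(snr_min = 3, aub_fraction_max = 0.9,
                     morphology_min = 0.8, duration_min = 1,
                     rel_aub_factor = 2, rel_etpdi_factor = 5),
    quality_criteria(snr_min = 3, aub_fraction_max = 0.5,
                     morphology_min = 0.2, duration_min = 1,
                     rel_aub_factor = 2, rel_etpdi_factor = 5),
    quality_criteria(snr_min = 3, aub_fraction_max = 0.5,
                     morphology_min = 0.8, duration_min = 0.4,
                     rel_aub_factor = 2, rel_etpdi_factor = 5),
    quality_criteria(snr_min = 3, aub_fraction_max = 0.5,
                     morphology_min = 0.8, duration_min = 1,
                     rel_aub_factor = 8, rel_etpdi_factor = 20))
  n_strict <- sum(assess_quality(b, strict)$valid)
  for (qc in relaxed_list)
    expect_gte(sum(assess_quality(b, qc)$valid), n_strict)
})

test_that("relative criteria are skipped for tiny recordings", {
  b <- good_breaths(3)
  b$aub[2] <- 100
  res <- assess_quality(b)
  expect_true(attr(res, "relative_skipped"))
  expect_false(any(res$flag_rel_aub))
})

test_that("flow-breath inclusion uses 20% of the P75 tidal volume", {
  fs <- 100
  tvs <- c(500, 480, 90, 510)
  t <- seq(0, 16, by = 1 / fs)
  v <- numeric(length(t))
  for (k in seq_along(tvs)) {
    on <- 1 + (k - 1) * 4
    rise <- t >= on & t <= on + 1
    v[rise] <- tvs[k] * 0.5 * (1 - cos(pi * (t[rise] - on)))
    fall <- t > on + 1 & t <= on + 4
    v[fall] <- tvs[k] * exp(-(t[fall] - on - 1) / 0.5)
  }
  fb <- detect_flow_breaths(signal_trace(v, fs))
  got <- fb[fb$tv > 200 | !fb$included, ]
  expect_equal(sum(fb$included), 3)
  excluded <- fb[!fb$included, ]
  expect_equal(nrow(excluded), 1)
  expect_equal(excluded$tv, 90, tolerance = 0.02)
  # oracle: threshold is 0.2 x P75 of candidate TVs, which exceeds 90
  expect_gt(0.2 * pctl(fb$tv, 75), min(fb$tv))
  # equal TVs are all included; flat trace gives nothing
  expect_equal(nrow(detect_flow_breaths(signal_trace(rep(0, 1000),
                                                     fs))), 0)
})

test_that("respiratory rate comes from the median inter-breath time", {
  mk <- function(times) data.frame(peak_time = times,
                                   tv = 500, trough_time = times - 1,
                                   included = TRUE)
  expect_equal(compute_rr(mk(c(1, 4, 7, 10))),
               list(rr = 20, tbreath = 3))
  expect_equal(compute_rr(mk(cumsum(c(1, 2, 3, 4))))$tbreath, 3)
  expect_equal(compute_rr(mk(cumsum(c(1, 2, 4))))$tbreath, 3)  # even count
  expect_equal(compute_rr(mk(cumsum(c(1, 2, 4))))$rr, 20)
  expect_error(compute_rr(mk(5)), "2 included")
})

test_that("noiseless recordings are recovered breath for breath", {
  cfg <- noiseless_config(seed = 12, level_duration = 90)
  br <- simulate_breath_sequence(6, cfg, duration = 90, seed = 12)
  sg <- render_signals(br, cfg, duration = 90, seed = 13, ps_level = 6)
  emg <- preprocess_emg(sg$semg)
  env <- compute_envelope(emg)
  base <- moving_baseline(env)
  pair <- envelope_pair(env, base)
  geom <- detect_neural_breaths(pair)
  expect_equal(nrow(geom), nrow(br))
  met <- breath_metrics(pair, geom)
  # recovered ETPdi rank-correlates with true drive; the stochastic EMG
  # carrier leaves a small per-breath area noise, so the raw-pipeline rank
  # correlation is near, not exactly, one
  expect_gte(cor(met$etpdi, br$drive, method = "spearman"), 0.95)
  expect_gte(cor(met$etpdi, br$drive), 0.97)
  # on the generator's programmed envelope the recovery is rank-perfect
  sgi <- render_signals(br, cfg, duration = 90, seed = 13, ps_level = 6)
  ideal <- envelope_pair(sgi$ideal_envelope, sgi$ideal_baseline)
  mi <- breath_metrics(ideal, detect_neural_breaths(ideal))
  expect_equal(cor(mi$etpdi, br$drive, method = "spearman"), 1)
  fb <- detect_flow_breaths(sg$volume)
  expect_equal(sum(fb$included), nrow(br))
})
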