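test_that("PS-12 normalisation is exact, idempotent and guarded", {
  df <- data.frame(patient = 1, trial = 1,
                   ps_level = c(12, 9, 6, 3),
                   median_tv = c(400, 440, 460, 480))
  norm <- normalize_to_ps12(df, "median_tv")
  expect_equal(norm$median_tv[norm$ps_level == 12], 1)
  expect_equal(norm$median_tv[norm$ps_level == 9], 1.1)
  # idempotence
  expect_equal(normalize_to_ps12(norm, "median_tv")$median_tv,
               norm$median_tv)
  # all equal values: all ones
  df$median_tv <- rep(7, 4)
  expect_equal(normalize_to_ps12(df, "median_tv")$median_tv, rep(1, 4))
  # trials without PS 12 are excluded and recorded
  df2 <- rbind(data.frame(patient = 1, trial = 1,
                          ps_level = c(12, 9), median_tv = c(1, 2)),
               data.frame(patient = 2, trial = 1,
                          ps_level = c(9, 6), median_tv = c(1, 2)))
  norm2 <- normalize_to_ps12(df2, "median_tv")
  expect_equal(unique(norm2$patient), 1)
  expect_length(attr(norm2, "excluded_trials"), 1)
})

test_that("sum-of-squares decomposition is exact and additive", {
  # hand-computed: groups {1,2,3}, {4,5,6}
  v <- variance_decomposition(c(1, 2, 3, 4, 5, 6),
                              rep(c("a", "b"), each = 3))
  expect_equal(v$ssw, 4)
  expect_equal(v$sstot, 17.5)
  expect_equal(v$ssw_pct, 100 * 4 / 17.5)
  # equal group means: all variation is within groups
  v2 <- variance_decomposition(c(1, 3, 2, 1, 3, 2),
                               rep(c("a", "b"), each = 3))
  expect_equal(v2$ssw_pct, 100)
  # zero within-group spread
  v3 <- variance_decomposition(c(1, 1, 5, 5), c("a", "a", "b", "b"))
  expect_equal(v3$ssw, 0)
  # additivity on fuzzed inputs
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(sample(10:60, 1))
    g <- sample(letters[1:5], length(x), replace = TRUE)
    if (length(unique(g)) < 2) next
    vv <- variance_decomposition(x, g)
    expect_equal(vv$ssw + vv$ssb, vv$sstot, tolerance = 1e-9)
  }
})

test_that("marginal regression recovers noiseless slopes exactly", {
  df <- expand.grid(patient = 1:6, trial = 1:2, ps_level = c(12, 9, 6, 3))
  df$y <- 1 + 0.024 * (12 - df$ps_level)
  fit <- fit_gee(100 * df$y, df$ps_level - 3, df$patient)
  expect_equal(unname(fit$coef[2]), -2.4, tolerance = 1e-9)
})

test_that("marginal estimates agree with a GLS cross-check", {
  skip_if_not_installed("nlme")
  set.seed(5)
  co <- simulate_cohort(n_patients = 10, trials_per_patient = 2, seed = 5)
  norm <- normalize_to_ps12(co, "median_etpdi")
  y <- 100 * norm$median_etpdi
  x <- norm$ps_level - 3
  fit <- fit_gee(y, x, norm$patient)
  d <- data.frame(y = y, x = x, patient = factor(norm$patient))
  gls_fit <- nlme::gls(y ~ x, data = d,
                       correlation = nlme::corCompSymm(form = ~ 1 |
                                                         patient))
  # independent route: GLS under compound symmetry, same mean model
  expect_equal(unname(fit$coef[2]), unname(coef(gls_fit)[2]),
               tolerance = 0.05)
})

test_that("single-cluster input falls back to OLS with a warning", {
  set.seed(2)
  x <- rnorm(30)
  y <- 2 + 0.5 * x + rnorm(30, 0, 0.1)
  expect_warning(fit <- fit_gee(y, x, rep(1, 30)), "single cluster")
  expect_equal(unname(fit$coef[2]), 0.5, tolerance = 0.1)
  expect_equal(fit$n_clusters, 1L)
})

test_that("slope table reports all three outcomes against centred PS", {
  co <- simulate_cohort(seed = 9)
  norm <- normalize_to_ps12(co, c("median_etpdi", "median_tv", "rr"))
  sl <- fit_ps_slopes(norm)
  expect_equal(sl$outcome, c("median_etpdi", "median_tv", "rr"))
  expect_lt(sl$slope_pp_per_cmH2O[1], 0)   # ETPdi rises as PS falls
  expect_gt(sl$slope_pp_per_cmH2O[2], 0)   # TV falls as PS falls
  expect_lt(sl$slope_pp_per_cmH2O[3], 0)   # RR rises as PS falls
  expect_true(all(sl$ci_lo < sl$slope_pp_per_cmH2O &
                  sl$slope_pp_per_cmH2O < sl$ci_hi))
})

test_that("covariate screen separates signal from null covariates", {
  set.seed(13)
  n <- 40
  etp <- rlnorm(n, 1, 0.7)
  rec <- data.frame(patient = rep(1:20, each = 2),
                    etpdi_ps12 = etp,
                    collinear = log(etp) + rnorm(n, 0, 1e-3),
                    signal = log(etp) * 2 + rnorm(n, 0, 0.3),
                    null1 = rnorm(n), null2 = rnorm(n),
                    constant = 5,
                    group2 = rep(c("a", "b"), n / 2),
                    group3 = sample(c("x", "y", "z"), n, replace = TRUE))
  res <- covariate_screen(rec,
                          continuous = c("collinear", "signal", "null1",
                                         "null2", "constant"),
                          categorical = c("group2", "group3"))
  cont <- res$continuous
  expect_equal(cont$r2_pct[cont$covariate == "collinear"], 100,
               tolerance = 1e-4)
  expect_lt(cont$p[cont$covariate == "signal"], 0.01)
  expect_false(is.na(cont$gee_p[cont$covariate == "signal"]))
  expect_true("constant" %in% res$skipped)
  expect_true(all(c("wilcoxon", "kruskal-wallis") %in%
                  res$categorical$test))
  # identical groups: rank-sum p near 1
  rec2 <- rec
  rec2$etpdi_ps12 <- rep(rlnorm(n / 2, 1, 0.5), 2)
  rec2$group2 <- rep(c("a", "b"), each = n / 2)
  res2 <- covariate_screen(rec2, categorical = "group2")
  expect_gt(res2$categorical$p, 0.9)
})

test_that("null covariates keep R^2 near its 1/(n-1) expectation", {
  set.seed(21)
  n <- 200
  r2 <- replicate(300, {
    rec <- data.frame(etpdi_ps12 = rlnorm(n, 1, 0.5), x = rnorm(n))
    covariate_screen(rec, continuous = "x")$continuous$r2_pct
  })
  expect_equal(mean(r2), 100 / (n - 1),
               tolerance = 5 * sd(r2) / sqrt(length(r2)) / (100 / (n - 1)))
})

test_that("dispersion-NVC association is detected with the right sign", {
  # (near-)exact linear relation: R^2 = 100
  set.seed(30)
  disp <- seq(0.1, 1, length.out = 10)
  r <- dispersion_vs_nvc(disp, 10 + 30 * disp + rnorm(10, 0, 1e-6))
  expect_equal(r$r2_pct, 100, tolerance = 1e-9)
  expect_gt(r$slope, 0)
  # generator: higher drive CV raises the true coupling at fixed noise
  cvs <- seq(0.1, 0.5, length.out = 12)
  set.seed(31)
  pts <- t(vapply(seq_along(cvs), function(i) {
    cfg <- sim_config(drive_cv = cvs[i], tv_noise_sd = 45, seed = 60 + i)
    br <- simulate_breath_sequence(8, cfg, duration = 700, seed = 60 + i)
    c(disp = relative_dispersion(br$drive),
      nvc = compute_nvc(data.frame(etpdi = br$drive, tv = br$tv))$nvc)
  }, numeric(2)))
  r2 <- dispersion_vs_nvc(pts[, "disp"], pts[, "nvc"])
  expect_gt(r2$slope, 0)
  expect_lt(r2$p, 0.05)
  # shuffled pairing destroys the association
  set.seed(32)
  shuf <- dispersion_vs_nvc(pts[, "disp"], sample(pts[, "nvc"]))
  expect_lt(shuf$r2_pct, r2$r2_pct)
  # guards
  expect_error(dispersion_vs_nvc(rep(0.5, 10), rnorm(10)), "zero-variance")
  expect_error(dispersion_vs_nvc(1:3, 1:3), "5")
})
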