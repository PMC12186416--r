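---
title: "Quantifying neuro-ventilatory coupling from diaphragm surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuro-ventilatory coupling from diaphragm surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcoupling)
```

## The problem

Patients weaned from invasive mechanical ventilation on pressure-support
ventilation (PSV) gradually take over the work of breathing. The central
respiratory drive reaching the diaphragm can be monitored non-invasively
with surface electromyography (sEMGdi), but absolute measures of drive
such as the per-breath sEAdi time-product (ETPdi) are highly variable
between patients and between days. What carries physiological meaning is
how tightly drive couples to output: the breath-by-breath squared
correlation between ETPdi and tidal volume (TV), the *neuro-ventilatory
coupling* (NVC). Near-passive patients show a quasi-random ETPdi-TV
relation (low NVC); actively breathing patients approaching liberation
couple strongly (high NVC).

`nvcoupling` implements the full chain from raw signals to group-level
statistics:

1. sEMG conditioning: 20-400 Hz zero-phase band-pass, QRS gating,
   moving-RMS envelope (sEAdi) with a slow moving baseline;
2. breath analysis: neural breaths between envelope-baseline crossings,
   ETPdi and the area under the baseline (AUB), a six-point quality gate;
   flow-based breaths and the respiratory rate from the ventilator volume
   tracing;
3. coupling: one-to-one neural/flow matching, trial validity, per-level
   NVC with Tukey-fence outlier exclusion;
4. group statistics: PS-12 normalisation, within/total variance
   decomposition, marginal (GEE-type) PS-response slopes, covariate
   screening, dispersion-NVC association.

A synthetic-data module generates structurally realistic recordings with
known ground truth, so every stage is testable without patient data.

## The measurement model

The sEAdi envelope is the moving RMS (250 ms) of the cleaned sEMG,
resampled to the 100 Hz ventilator grid so that neural and mechanical
events share one clock. A neural breath runs from one envelope-baseline
crossing to the next around a peak that exceeds the baseline by an
adaptive prominence, and

$$\mathrm{ETPdi} = \int_{t_\mathrm{on}}^{t_\mathrm{off}} \mathrm{sEAdi}(t)\,dt,
\qquad
\mathrm{AUB} = \int_{t_\mathrm{on}}^{t_\mathrm{off}} \mathrm{baseline}(t)\,dt,$$

both trapezoidal, in µV·s. ETPdi deliberately *includes* the area under
the moving baseline; ETPdi − AUB is the burst area proper. Per PS level,

$$\mathrm{NVC} = 100 \times r^2\!\left(\mathrm{ETPdi}_i, \mathrm{TV}_i\right)\ \%$$

over the matched breath pairs of that level, after removing pairs in
which either variable falls outside its own Tukey fences
(Q1 − 1.5·IQR, Q3 + 1.5·IQR).

### Quality gating

Six criteria remove unreliable neural breaths: minimum SNR (peak height
above baseline over the non-breath excess RMS, default 1.75), maximum
AUB/ETPdi fraction (default 0.8), minimum bell-shape morphology score
(L1 distance to a moment-matched Gaussian, default 0.6), minimum
duration 0.5 s, AUB above 4 times the recording's AUB upper quartile,
and ETPdi above 10 times the recording's ETPdi 95th percentile (the last
two are crosstalk guards; their reference statistics pool all detected
breaths of the PS-trial recording). The three absolute thresholds are
exposed in `quality_criteria()` because no canonical values exist; the
three protocol-anchored ones default to the stated constants. A single
percentile convention — linear interpolation between order statistics,
`pctl()` — is shared by every quantile in the package (quality
references, flow-breath P75, Tukey fences), so the criteria cannot
drift apart numerically.

### Matching and validity

Each included flow breath is linked to the nearest valid neural breath
whose peak lies within [−Tbreath/2, +0.5 s] of the volume peak, greedily
by smallest absolute lag and strictly one-to-one: neural activation
precedes or coincides with its mechanical result, and reusing a neural
breath would double-count effort. A PS-trial is analysed only if every
level retains valid neural breaths for at least 10 % of its flow-based
breaths.

## Group-level models

Absolute ETPdi, TV and RR vary over orders of magnitude between patients;
the within-trial response to PS is only visible after normalising each
trial to its own median at PS = 12 cmH2O (the one level common to all
protocols). The decomposition `variance_decomposition()` quantifies this:
the within-trial sum of squares is a small share of the total before
normalisation and a large one after.

PS-response slopes are estimated by `fit_gee()`: a Gaussian
identity-link marginal model of 100 × normalised value on PS centred at
3 cmH2O, clustered on patient with an exchangeable working correlation
and robust sandwich errors. No GEE backend is used: the IRLS/sandwich
estimator is implemented directly and cross-checked in the test suite
against `nlme::gls` under compound symmetry. Because cohorts here have
few clusters (tens of patients at most), the sandwich covariance is
inflated by G/(G−1) and inference uses a t reference with G − p degrees
of freedom; uncorrected z-based intervals undercover noticeably at
G ≈ 13.

The covariate screen regresses log ETPdi at PS 12 on each continuous
covariate (reporting R² and p), uses rank-sum/Kruskal-Wallis tests for
categorical ones, and re-tests significant continuous covariates in the
clustered marginal model. Raw p-values are reported without multiplicity
correction, and that fact is recorded in the output metadata.

## The synthetic generator

`simulate_trial()` renders one decremental PS-trial: four levels from
the protocol grid {3, 6, …, 21} cmH2O chosen by the clinical PS level
(12 cmH2O always included), each level held for `level_duration`
(default 300 s, at least 5 minutes).

Within a level with PS withdrawal $\delta$ = clinical − level:

* mean drive scales by $(1 + 0.024\,\delta)$, mean RR by
  $(1 + 0.016\,\delta)$, mean TV by $(1 - 0.025\,\delta)$ — per-cmH2O
  percentage-point responses of 2.4, 1.6 and −2.5;
* per-breath drive is lognormal with CV `drive_cv` (positivity and the
  right skew seen in real ETPdi distributions);
* TV$_i$ = `coupling_gain` × drive$_i$ + intercept + N(0, `tv_noise_sd`),
  which makes the population coupling exactly
  $R^2 = g^2\sigma_d^2 / (g^2\sigma_d^2 + \sigma_{TV}^2)$ — the closed
  form `true_nvc()` reports as ground truth;
* the sEMG is band-limited noise amplitude-modulated by a raised-cosine
  (Hann) burst per breath (default 1.2 s within the physiological
  0.8-1.5 s range) whose envelope area equals the breath's drive, plus a
  noise floor with slow sinusoidal amplitude drift and a stereotyped
  triphasic QRS train (±5 % R-R jitter) that contaminates both channels;
* volume rises by TV over the inspiratory time and decays passively;
  flow is its derivative, so the per-breath flow integral equals TV by
  construction; the neural burst onset precedes the volume peak by
  `neural_lead_time` (default 0.3 s).

Breath timing is snapped to the 100 Hz ventilator grid so that timing
ground truth is exactly representable on the analysis grid. One sub-seed
per segment is derived from the trial seed, making segments individually
reproducible and whole trials bit-identical per configuration. The
generator also emits its *programmed* envelope/baseline pair: detection
geometry can be verified sample-exactly against it, whereas the raw-signal
route carries the irreducible smearing of the 250 ms RMS window
(about half a window at each burst edge) and the small per-breath area
noise of the stochastic carrier.

`simulate_cohort()` generates trial-level per-level medians directly
from the statistical model (lognormal between-patient scale, sdlog 0.8
for ETPdi; between-trial sdlog 0.4; 8 % multiplicative level noise;
slopes anchored at the PS-12 reference so the programmed normalised
slope is exact). Slope-recovery and covariate experiments run at this
summary scale — hundreds of cohort replicates at 2048 Hz would add
nothing but rendering time, since the group statistics only ever see the
level medians.

What the generator does *not* emulate: patient-ventilator asynchrony,
crosstalk from other respiratory muscles, realistic lung mechanics,
non-stationary heart rhythm, or electrode artifacts beyond the QRS
train. Passing tests therefore demonstrate the correctness of the
algorithms under the stated statistical structure, not clinical
performance on real recordings.

## Numerical choices and degenerate inputs

* Deterministic analysis path: the QRS gate fill is a pure function of
  the surrounding signal (pre-gate samples rescaled to a linearly
  interpolated pre/post RMS level), so gating is idempotent and the
  pipeline is bit-reproducible; no random numbers are drawn after
  simulation.
* Zero-phase filtering demeans and reflect-pads the signal (0.5 s) to
  suppress forward-backward edge transients.
* The moving baseline (rolling 33rd percentile over 7.5 s, then 1 s
  smoothing) is computed on a 10 Hz decimated grid and interpolated —
  indistinguishable for a trace this slow, an order of magnitude faster.
* Zero-variance NVC inputs give NVC = 0 with a `degenerate` flag
  (constant TV is physiologically meaningful passive breathing); fewer
  than 5 pairs give an *undefined* (NA) result, not zero.
* Fewer than 4 breaths per recording skips the relative quality
  criteria; fewer than 4 pairs skips Tukey exclusion — both signalled.
* Identical-lag matching ties break on flow-breath order; all-equal
  values collapse Tukey fences onto the value itself and exclude
  nothing.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(clinical_ps = 8, level_duration = 120, seed = 42)
trial <- simulate_trial(cfg)
res <- process_trial(trial$signals, trial$segments)
res$nvc                      # per-level NVC
trial$ground_truth$nvc       # generator's closed-form truth

co <- simulate_cohort(n_patients = 13, trials_per_patient = 2, seed = 1)
norm <- normalize_to_ps12(co, c("median_etpdi", "median_tv", "rr"))
fit_ps_slopes(norm)          # pp per cmH2O, clustered CIs
```

Typical problem sizes used throughout the test suite — 60-120 s levels,
500-pair NVC experiments, 100-replicate cohort studies — were chosen as
the smallest at which the statistical assertions are sharp (e.g. the
Fisher-z width of an R² estimate at n = 500 is a few percentage points).

## Known limitations

* ECG removal is gating-plus-fill, not template subtraction or adaptive
  filtering; heavy contamination between R waves would survive it.
* The morphology score uses a moment-matched Gaussian rather than a
  free nonlinear fit; extremely asymmetric but genuine breaths score
  lower than a fitted bell would.
* The marginal model supports one regressor (PS) plus intercept, which
  covers the analyses here; it is not a general GEE replacement.
* EDF input is not supported; recordings are exchanged as CSV (one
  time/value file per EMG channel, one multi-column ventilator file).
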