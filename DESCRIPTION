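Package: nvcoupling
Title: Neuro-Ventilatory Coupling Analysis of Diaphragm Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Serial analysis of diaphragm surface electromyography (sEMGdi)
    recorded during pressure-support ventilation. Converts raw sEMG and ECG
    channels into the diaphragm activity envelope (sEAdi) with ECG artifact
    gating, detects neural breaths between baseline crossings, computes the
    per-breath sEAdi time-product (ETPdi) with quality gating, detects
    flow-based breaths from ventilator volume tracings, matches neural to
    flow-based breaths, and quantifies neuro-ventilatory coupling (NVC) as
    the squared breath-by-breath correlation between ETPdi and tidal volume.
    Group-level tools normalise per-level medians to the pressure-support
    level of 12 cmH2O, decompose variance within and between trials, and
    estimate pressure-support response slopes with marginal (GEE-type)
    regression for repeated measurements. A synthetic-data module generates
    physiologically structured recordings with known ground truth so every
    stage can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    zoo,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
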