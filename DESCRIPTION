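Package: sprintnirs
Title: Muscle and Cerebral NIRS Analysis of Repeated Sprints to Exhaustion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Processing and inference pipeline for near-infrared spectroscopy
    (NIRS) recordings collected during repeated-sprint cycling tests to
    exhaustion. Provides zero-phase low-pass Butterworth filtering of oxy- and
    deoxyhemoglobin concentration signals, automatic sprint-phase segmentation
    referenced to muscle deoxyhemoglobin, per-sprint maximum-minimum delta
    extraction, normalization of delta profiles to percent of set duration,
    repeated-sprint performance summaries (percent decrement score, total work,
    30-s peak oxygen uptake), and linear mixed-model inference with
    likelihood-ratio tests and Tukey-adjusted least-squares-mean contrasts.
    Includes a seeded synthetic-session generator emulating the 10-s sprint /
    20-s recovery block structure with hypoxia-dependent amplitudes and known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    lmerTest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
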