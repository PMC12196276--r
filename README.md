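# cmcgait

Corticomuscular coherence, motor-preparation beta power, and gait analysis
for ankle-dorsiflexion studies.

## What it is for

Voluntary ankle dorsiflexion is a small movement whose cortical control
resembles the control of walking, which makes it a candidate bedside probe
of gait-relevant motor control. `cmcgait` is an R implementation of the
full analysis chain used in that line of research, for methodologists and
motor-control researchers who want to run, audit, or stress-test it:

* **Preprocessing** — zero-phase Butterworth filtering (mains notch,
  5–300 Hz EMG band, 0.5–45 Hz EEG band), full-wave EMG rectification,
  EOG-regression artifact removal, movement-onset detection from ankle
  goniometer traces, and −3…+3 s epoching.
* **Corticomuscular coherence (CMC)** — segment-averaged magnitude-squared
  coherence between Cz and tibialis anterior,

  `Coh_xy(f) = |P_xy(f)|² / (P_xx(f) · P_yy(f))`,

  with one Hann-tapered 3 s segment per trial (N = 10), the analytic
  confidence level `CL_α = 1 − (1−α)^(1/(N−1))`, a 14–20 Hz beta-band
  summary, and the median split into CMC-high / CMC-low groups.
* **Time–frequency analysis** — complex Morlet wavelet (7 cycles) beta-power
  time courses at Cz, baseline normalization against −3000…−2500 ms, and
  eleven 500 ms window features from −2500 to +3000 ms around movement
  onset.
* **Biomechanics** — dorsiflexion angle change and peak angular velocities
  per trial; post-toe-off dorsiflexion change, inversion angle at initial
  contact, and gait speed per gait cycle.
* **Group statistics** — Shapiro–Wilk-gated t / Mann–Whitney comparisons
  and pooled-SD Cohen's d, including closed-form versions that work from
  printed summary statistics.
* **Classification** — bootstrap augmentation, stratified 5-fold
  cross-validated RBF-SVM per window (faithful augment-then-split ordering
  and a leak-free alternative), reporting Accuracy, Precision, Recall and
  F1 per class.
* **Synthetic cohorts** — a seeded generator that reproduces the
  statistical structure of a 23-subject study (group coherences
  0.28 ± 0.02 vs 0.23 ± 0.02, −500…0 ms beta-power change −0.40 ± 0.24 vs
  1.03 ± 0.93 µV², the dorsiflexion and gait group distributions), so the
  whole chain is testable against planted ground truth.

The methods vignette (`vignettes/motor-preparation-cmc.Rmd`) documents the
models, every tunable parameter, the generator's calibration, and the
package's known limitations.

## Worked example

```r
library(cmcgait)

# effect size and t-test straight from printed group summaries
cohens_d_from_summary(34.26, 9.25, 12, 25.36, 9.43, 11)
#> [1] 0.953284
ttest_from_summary(1.20, 0.17, 12, 1.08, 0.16, 11)
#>           t          df           p
#>  1.73898497 21.00000000  0.09667759

# the N = 10 coherence significance threshold
confidence_level(n_segments = 10, alpha = 0.95)
#> [1] 0.2831288

# synthesize a 23-subject cohort and run the full pipeline
cfg <- pipeline_config(synth = synth_config(seed = 1), seed = 1,
                       bootstrap_sizes = 1000, out_dir = tempfile())
res <- run_pipeline(cfg, quiet = TRUE)

round(tapply(res$cmc_values, res$truth$group, mean), 3)
#>  high   low
#> 0.272 0.211

subset(res$classifier$primary, window == "-500~0 ms")
#>      window size accuracy precision_high recall_high   f1_high precision_low recall_low    f1_low
#> 5 -500~0 ms 1000    0.955              1   0.9132948 0.9546828     0.9144487          1 0.9553128
```

Reading the output: the estimated group-mean beta coherences land on the
planted 0.28 / 0.23 within the coherence estimator's noise (d = 0.95 and
t = 1.74, p = 0.097 reproduce the printed dorsiflexion effect size and the
null gait-speed comparison exactly); the bootstrap-augmented SVM on the
−500…0 ms beta-power feature classifies the measured median split with
0.955 accuracy and an F1 of 0.955 for the low-coherence class. `run_pipeline()`
also writes every stage artifact (ground truth, coherence groups, feature
table, biomechanics, statistics and classifier reports) plus an MD5
manifest into `out_dir`.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/cmcgait.R run --out myrun --seed 1
Rscript inst/cli/cmcgait.R report --out myrun
```

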