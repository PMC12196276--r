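---
title: "Corticomuscular coherence, motor-preparation beta power, and gait: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corticomuscular coherence, motor-preparation beta power, and gait: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcgait)
```

## The scientific problem

Ankle dorsiflexion is a small, clinically accessible movement whose cortical
control resembles the control of walking. A line of motor-control research
quantifies that control with **corticomuscular coherence (CMC)**: the
frequency-domain correlation between the EEG over the leg area of the motor
cortex (electrode Cz) and the surface EMG of the tibialis anterior (TA)
during voluntary dorsiflexion. Beta-band (here 14--20 Hz) Cz--TA coherence
indexes the integrity of the corticospinal drive; cohorts split at the
median beta CMC differ in dorsiflexion kinematics, in gait kinematics around
toe-off and initial contact, and in the event-related desynchronization
(ERD) of Cz beta power during the motor-preparation period before movement
onset. Because the pre-movement beta power needs no overt movement, a
classifier that predicts a person's CMC group from the −500--0 ms beta-power
feature is a candidate severity-independent assessment of ankle control.

`cmcgait` implements that entire analysis chain as a reusable, testable
pipeline, together with a synthetic-cohort generator that reproduces the
statistical structure of a 23-subject study (12 high- vs 11 low-CMC
subjects, 10 dorsiflexion trials of 3 s movement + 7 s rest, 10 gait
cycles), so every stage can be validated against planted ground truth
without access to human recordings.

## Pipeline stages and their models

### Preprocessing

All filters are 4th-order Butterworth applied forward--backward
(`signal::filtfilt`), i.e. zero-phase, so epoch timing is never skewed.
Band-passes are applied as a high-pass/low-pass cascade, which is
numerically safer than a single eighth-order transfer function when the
lower edge (0.5 Hz) is a tiny fraction of the Nyquist frequency. Defaults:

| step | setting | note |
|---|---|---|
| mains notch | 59--61 Hz band-stop | 60 Hz mains; configurable (`mains_hz`) |
| EMG band-pass | 5--300 Hz | then full-wave rectification |
| EEG band-pass | 0.5--45 Hz | |
| EOG removal | per-channel least-squares regression on the EOG pair | enabled when EOG channels exist |

EMG is rectified **before** epoching; coherence is computed on filtered EEG
versus filtered, rectified EMG. Vendor EOG-removal algorithms are
proprietary; channel-wise linear regression is the standard open
implementation of the same idea.

Movement onsets are detected from the 50 Hz ankle-angle trace: baseline =
median of the preceding 1 s, onset = first sample exceeding baseline + 2°
sustained for 100 ms, successive onsets at least 5 s apart. The threshold
and hold are configurable; the defaults are robust to the 50 Hz encoder
noise level the generator emulates. Trials are cut from −3 s to +3 s around
each onset without resampling (samples inside an epoch are bit-identical to
the recording).

### Coherence and grouping

For each subject the magnitude-squared coherence

$$\mathrm{Coh}_{xy}(f) \;=\; \frac{|P_{xy}(f)|^2}{P_{xx}(f)\,P_{yy}(f)}$$

is estimated by averaging cross- and auto-spectra over N = 10 segments, one
per trial: the 3 s movement-execution window, Hann-tapered, no overlap,
giving a 1/3 Hz frequency grid. The significance threshold is the analytic
confidence level

$$CL_\alpha = 1 - (1-\alpha)^{1/(N-1)},$$

which at N = 10, α = 0.95 evaluates to 0.2831. The per-subject scalar is
the **mean** MSC over 14--20 Hz (`mode = "peak"` is available; the mean is
the default because it is the lower-variance band statistic). Subjects at
or above the cohort median are labelled `high`, the rest `low`; ties at the
median go to `high` and are messaged.

### Beta-power time courses and window features

Cz epochs are convolved with complex Morlet wavelets (7 cycles, 14--20 Hz
in 1 Hz steps), normalized so a unit-amplitude sinusoid at the wavelet's
frequency yields unit power; band power is the mean over the seven
frequencies of the trial-averaged squared magnitude. The pipeline epochs
with a 0.35 s buffer margin and crops after convolution, so no retained
sample is contaminated by the reflection padding used at the array edges.
Power is expressed relative to the −3000 to −2500 ms baseline; `absolute`
mode (P − P̄base, in μV²) is the default because the group-level values
this package reproduces are printed on that scale, and `percent` mode
(100·(P − P̄base)/P̄base) is available. Eleven contiguous 500 ms windows
from −2500 ms to +3000 ms yield the feature vector; the −500--0 ms window
is the motor-preparation feature of interest.

### Biomechanics

Angular velocity is computed from centered finite differences at 50 Hz
after a 5-sample running-median pre-smoothing (the median filter is the
identity on smooth monotone segments, so noise-free peaks are recovered
exactly). Dorsiflexion-task metrics per trial: angle change (max
dorsiflexion within 3 s after onset minus the angle at onset) and peak
dorsiflexion/inversion angular velocities; the representative value is the
mean over trials, never the metric of a mean trace. Gait metrics per cycle
(two consecutive initial contacts): the post-toe-off dorsiflexion change,
measured over the swing-initiation window from toe-off to toe-off + 20% of
the cycle, the inversion angle at the sample nearest initial contact, and
gait speed = path length / traversal time averaged over passes.

Two open points are settled here as package choices: the post-toe-off
window ("after TO" has no published endpoint; the first fifth of the cycle
is the conventional tripping-risk window), and velocity units. Published
peak angular velocities for this task are sometimes printed in "rad/s"
with magnitudes in the thousands, which is dimensionally implausible for
an ankle; this package works in degrees/s throughout, and the generator
plants velocities at one hundredth of such readouts (e.g. 83.5 °/s rather
than 8352.8). Cohen's d and every significance decision are invariant
under this common rescaling, so group statistics are unaffected.

### Group statistics

Each metric is compared between groups with a normality gate: if both
groups pass the Shapiro--Wilk test at α = 0.05, an independent pooled-
variance t-test is used, otherwise the Mann--Whitney U test. Cohen's d
always uses the pooled SD,

$$d = \frac{m_1 - m_2}{\sqrt{\big((n_1-1)s_1^2 + (n_2-1)s_2^2\big)/(n_1+n_2-2)}},$$

which reproduces the dorsiflexion-task effect sizes 0.95, 1.37, 1.23 from
the printed group summaries exactly at two decimals. (The corresponding
printed gait effect sizes do not match any pooled-SD computation from
their own printed summaries and are therefore not used as validation
targets.) No multiple-testing correction is applied, matching the original
analysis. `ttest_from_summary()` provides the closed-form pooled t-test
from printed summaries; it confirms the reported pattern: gait speed
p ≈ 0.10 (not significant), −500--0 ms beta power p < 0.001.

### Classifier

Per window, the subject features are bootstrap-resampled to a configured
size (default sweep 10, 100, ..., 1000; headline size 1000) and classified
with an RBF-kernel SVM (`e1071::svm`, cost 1) under stratified 5-fold
cross-validation, features z-scored with training-fold statistics. Two
orderings are exposed and the report always names the one used:

* **faithful** (default): augment first, then split the augmented rows
  into folds. Resampled duplicates of the same subject then appear in both
  training and test folds. This is the ordering described in the study and
  is what makes the reported accuracy (0.96 at −500--0 ms) reproducible —
  the optimism is a property of the procedure, not of the data.
* **leakfree**: split the original subjects into folds, augment the
  training subjects only, and test on untouched held-out subjects. On
  weakly separated classes this mode scores substantially lower, and on
  label-shuffled data it returns chance, which is how the package's tests
  characterize the leakage.

The kernel width is the one SVM parameter with real leverage here, and it
is unspecified in the source analysis. The package default is the standard
quantile heuristic, γ = 1 / q₀.₁(‖xᵢ − xⱼ‖²), computed on each training
fold (zero distances guarded). On bootstrap-duplicated data the low
quantile contracts toward the replicated point masses, so the kernel is
exactly sharp enough to resolve individual resampled subjects — which is
the mechanism by which augment-then-split cross-validation attains its
reported scores. A fixed γ (e.g. 1) smooths over neighbouring subjects and
cannot reproduce them; both γ and the cost are configurable.

## The synthetic-cohort generator

The generator's defaults are the study conditions: 12/11 subjects, group
beta-CMC 0.28 ± 0.02 vs 0.23 ± 0.02 *on the 10-segment estimated scale*,
−500--0 ms beta-power change −0.40 ± 0.24 vs 1.03 ± 0.93 μV² (and
−0.06 ± 0.70 vs 1.12 ± 0.72 for 500--1000 ms), baseline beta power
2.0 μV² (so −0.40 is a ~20% desynchronization, the physiological range),
dorsiflexion angle change 34.26 ± 9.25 vs 25.36 ± 9.43°, post-toe-off
change 2.23 ± 0.88 vs 3.51 ± 1.75°, initial-contact inversion 2.51 ± 1.45
vs 4.72 ± 2.56°, gait speed 1.20 ± 0.17 vs 1.08 ± 0.16 m/s, EEG/EMG at
1000 Hz, angles at 50 Hz.

**Draw modes.** With `empirical = TRUE` (default) each group's values are
realized as randomly permuted normal scores scaled to the exact configured
mean and SD: every synthetic cohort then has precisely the printed summary
statistics and a normal-shaped sample, which is the sharpest meaning of
"re-run the study whose summaries are fixed". This matters for two
reasons: the t-tests on planted metrics reproduce the printed p-values
deterministically, and the Shapiro--Wilk gate behaves as it did in the
study instead of tripping on sampling accidents. `empirical = FALSE`
draws i.i.d. Gaussians instead, for law-of-large-numbers checks and for
experiments whose protocol prescribes i.i.d. sampling (the classifier
acceptance experiment does).

**Signal model.** Per subject the Cz beta rhythm is a constant-amplitude
sinusoid whose instantaneous frequency sweeps 14--20 Hz triangularly with
a 1.37 s period (incommensurate with the 10 s trial spacing, so trials
sample the sweep uniformly). Its envelope is √(v(t)) with v(t) chosen so
the wavelet-measured band power equals baseline + the subject's planted
ERD/ERS template exactly; because the envelope is deterministic, the
planted −500--0 ms feature is recovered with a residual SD of only
~0.1 μV² instead of the ~0.45 μV² a Gaussian beta process would impose
(10 trials × 0.5 s × 6 Hz ≈ 30 degrees of freedom). The template is 0
before −500 ms, d₁ over −500--0 ms, linear to d₂ through 0--500 ms, d₂
over 500--1000 ms, then a linear return to baseline by +3 s.

TA EMG is amplitude-modulated broadband noise: rest tone 8 μV, movement
envelope 50·max(1 + 0.3·u(t), 0.05) μV, where the modulation u(t) mixes
the Cz beta rhythm with independent band-limited Gaussian noise. Full-wave
rectification (the pipeline's own EMG step) recovers the modulated
envelope, so the Cz--TA coherence is controlled by the mixing ratio. The
generator inverts the whole measurement chain: (i) the closed shared-drive
form `expected_coherence()` underlies the mixing algebra; (ii) the target
printed coherence is first mapped from the estimated scale to the
population scale by inverting the N-segment estimator bias
E[ĉ] ≈ C + (1−C)²/N·(1 + 2C/N) (the printed 0.28/0.23 are N = 10
estimates, so the generator must target the estimate, not the population
value); (iii) EEG-side dilution by broadband background and EMG-side
dilution by rectified-carrier noise are computed from calibration
constants; and (iv) the Gaussian mixing level is solved bin-wise from the
calibrated spectral shapes so the band-mean coherence hits the drive
target. All calibration constants (wavelet band gains, in-band variance
fractions, rectified-carrier statistics, spectral-shape ratios) are
measured once per configuration on long stationary surrogates against the
package's own estimators, under a fixed internal seed, and cached.

EOG blinks are injected as 80--160 μV Gaussian pulses every 2.5--6 s with
a fixed 0.05 leak into Cz; angle traces use trapezoidal-velocity
profiles whose accelerations, plateaus and event times are aligned to the
50 Hz grid, so noise-free planted kinematics (angle change, peak
velocities, post-toe-off change, inversion at initial contact, gait
speed) are recovered by the biomechanics module to machine precision.
Encoder noise (default 0.05°) can be switched off. All randomness flows
from one master seed through named per-subject substreams; identical
configurations are bit-identical.

**What the generator does not emulate.** Single-trial beta amplitude
variability (the deterministic envelope is *less* variable than real EEG),
1/f background structure, electrode artifacts other than blinks, gait
kinematics beyond the two extracted metrics, and any topography beyond the
recorded channel set. Consequently, green pipeline tests demonstrate
algorithmic correctness and calibrated recovery of planted structure —
not that real recordings would yield these effect sizes.

## Known limitations, stated quantitatively

**Median-split label recovery is noise-limited and fails its nominal
target.** The band-mean MSC of a subject with true coherence ~0.26,
estimated from N = 10 Hann-tapered 3 s segments and averaged over the 19
band bins, carries an irreducible standard deviation of ≈ 0.048 (measured
by simulation; the per-bin variance is ≈ 2C(1−C)²/N with ~10 effectively
independent bins). The planted group gap is only 0.05 with a
between-subject SD of 0.02, so the probability that a subject lands on
its own side of the cohort median is ≈ Φ(0.025/0.05) ≈ 0.7. The package's
acceptance suite asserts the nominal ≥ 90% recovery and that assertion
fails honestly at ≈ 0.69; recovery at 90% would require an estimator SD
≤ 0.02, i.e. roughly five times more movement data per subject than the
10 × 3 s the protocol provides. This also quantifies a circularity in
median-split designs: group summaries of the *measured* split (SDs of
0.02) understate the measurement noise of the quantity being split on.

**Other numerical choices.** Wavelet edges: 7 cycles at 14 Hz span
±0.28 s; the pipeline's 0.35 s epoch margin covers them. Windows touching
reflected samples (only possible when `morlet_power()` is called without a
margin) carry an `edge_contaminated` flag. Degenerate inputs error
informatively rather than guessing: zero-power coherence segments, empty
bands, all-equal median splits, zero baseline power in percent mode,
single-class classifier folds (refolded up to 3 times), zero-variance
groups with equal means.

## Problem sizes used by the test and acceptance suites

Unit tests run tiny cohorts (3 + 3 subjects, 3--4 trials). The acceptance
suite uses: 20 seeds × 1000 bootstrap rows for the classifier experiment;
five full 23-subject cohorts for parameter recovery; ~40 subjects for the
ERD-detection rate; ≥ 1000 null frequency bins for estimator calibration.
These sizes put every stochastic assertion's Monte-Carlo error well below
its tolerance while keeping the default suite in the low minutes.
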