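---
title: "Comparing TMS-evoked potentials with the Divergence Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing TMS-evoked potentials with the Divergence Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tepdi)
```

## The problem

Transcranial magnetic stimulation combined with high-density EEG (TMS/hd-EEG)
probes cortical excitability and connectivity directly: a magnetic pulse
depolarizes a patch of cortex and the averaged, time-locked EEG response —
the TMS-evoked potential (TEP) — traces how the perturbation reverberates
through connected circuits. For the technique to be useful as a monitoring
tool, TEPs must be *sensitive* (they change when the perturbation changes)
and *repeatable* (they do not change when it does not). Deciding whether two
TEPs recorded in different sessions "differ" is therefore the core
statistical task: a pointwise test at every channel and time sample would
drown in multiple comparisons, while ad-hoc component picking requires prior
knowledge of where the response lives.

`tepdi` implements a non-parametric answer. Two epoched sessions (single
trials around each pulse) are compared by a trial-mixing permutation test
with max-statistic family-wise correction over time, and the outcome is
summarized by a single number, the **Divergence Index (DI)**: the percentage
of spatio-temporal samples — all retained channels by all post-stimulus time
samples — at which the two TEPs differ significantly. Labelled collections
of DIs (change vs no-change comparisons) are then classified by an ROC
analysis with a Youden-optimal threshold.

## The statistical procedure

For each pairwise comparison of sessions A and B:

1. **Trial rejection.** Trials with EOG peak-to-peak amplitude > 70 µV, or
   with mean power spectral density of channel F8 above 25 Hz exceeding
   0.9 µV²/Hz, are discarded (ocular and muscular contamination). Each
   rejected trial is attributed to the first failing rule.
2. **Baseline equalization.** The 250 ms pre-stimulus baselines of the two
   trial sets must be exchangeable before mixing. Each trial is summarized
   by the mean over channels of its mean absolute baseline voltage; a
   Wilcoxon rank-sum test compares the groups, and while P ≤ 0.05 the
   single trial farthest from the pooled median is removed (at most 5% of
   the pooled trials; beyond that the comparison aborts for inspection).
3. **Preprocessing.** Band-pass 2–80 Hz (zero-phase Butterworth),
   downsampling 1450 → 725 Hz, common-average reference. Because every step
   is linear, trials are preprocessed individually and averaging commutes
   with the chain; the evoked potential of a session is the mean of its
   preprocessed trials.
4. **Trial-mixing null.** The pooled single trials are re-partitioned at
   random into two groups of the original sizes `n_perm` times (default
   1000); the average of one re-formed group is a "mixed" TEP. Per channel
   and time sample, the mean of the mixed ensemble is the centralization
   profile δ(t). Per channel, each mixed TEP is centered by δ(t) and its
   maximum absolute value over the 250 ms post-stimulus window (182 samples
   at 725 Hz) is recorded; the (1−α)·100th percentile of those maxima is the
   family-wise threshold G for the whole window.
5. **Significance mask and DI.** A (channel, t) sample is flagged when
   either observed TEP lies strictly outside the boundaries δ(t) ± G. The
   DI is 100 × flagged / (channels × 182); sub-window DIs are reported for
   0–60, 60–120 and 120–250 ms (half-open windows, the last closed — they
   partition the 182 samples, so the total DI is their cell-count-weighted
   mean).
6. **ROC.** Over a labelled set of comparisons, every observed DI serves as
   a candidate threshold for the rule "change if DI > threshold".
   Sensitivity and specificity are tabulated, the area under the curve is
   computed by the trapezoidal rule (equal to the Mann–Whitney rank
   probability, ties counted half), and the operating threshold maximizes
   the Youden index (sensitivity + specificity − 1), ties broken toward the
   lowest threshold.

### Design choices worth knowing about

Several details of the procedure are underdetermined by its verbal
description; the package fixes them as follows and exposes each as a
configurable, logged parameter.

- **α** defaults to 0.05 and is recorded in every report; it is the
  family-wise false-positive probability *per channel* over the 250 ms
  window. The correction is over time only; the DI simply aggregates
  channels, so under the null the expected DI is roughly α × (mean flagged
  run length)/182, well below 1%.
- **δ(t) is the mean** of the mixed ensemble at each (channel, t); the mean
  is smoother than the median over a 500–1000-sample ensemble.
- **One mixed average per permutation.** Each re-partition contributes the
  average of one re-formed group (size n_A). Under exchangeability the two
  groups are equivalent, and using one per draw keeps the ensemble i.i.d.
  The observed partition is not forcibly included; the threshold uses the
  order statistic ⌈(1−α)·n_perm⌉, which is the standard slightly
  conservative convention.
- **G is per channel** (max over time within each channel), matching the
  per-channel significance boundaries drawn in the procedure's
  illustration; no correction is applied across channels.
- **EOG rule statistic** is peak-to-peak within the epoch (robust to DC
  offset); the threshold is strict (exactly 70 µV is kept). The F8 beta
  power is a Hann-tapered periodogram averaged over 25–80 Hz, computed on
  the epoch excluding 0–8 ms after the pulse (the amplifier guarantees
  artifact-free recording only from 8 ms).
- **The band-pass** is implemented as an order-3 high-pass (2 Hz) cascaded
  with an order-5 low-pass (80 Hz), both zero-phase (forward–backward). A
  single band-pass section with a 2 Hz edge at 1450 Hz is numerically
  ill-conditioned in transfer-function form — it breaks the linearity that
  step 3 relies on at the 10⁻³ level — while the cascade keeps round-off
  near machine precision and attenuates a 100 Hz tone by ~21 dB after the
  double pass.
- **Baseline equalization metric.** The removal loop needs a scalar
  "deviance" per trial; we use the distance of the per-trial summary from
  the pooled median. Note an intrinsic property of the rank-sum loop: a
  handful of extreme outlier trials (within the 5% cap) barely move a rank
  test, so the loop engages only for distribution-level baseline shifts;
  isolated artifacts are the rejection stage's job.
- **Ties at the ROC threshold** classify as "no change" (the rule is a
  strict inequality), and among thresholds with equal Youden index the
  lowest is chosen, which favors sensitivity.

## The synthetic session generator

No public recordings accompany the analysis, so the package ships a
generator (`session_config()`, `generate_session()`,
`make_comparison_pair()`) that emulates the statistical structure the
procedure assumes. It is first-class, tested code — the end-to-end
benchmarks run on it.

Each session is ~200 trials × (60 EEG + 1 EOG) channels × 726 samples at
1450 Hz (−250…+250 ms). The evoked response is a sum of K = 3 damped
sinusoids (10, 22, 33 Hz; decay constants 90, 50, 35 ms; onset latency
≥ 8 ms) with smooth bipolar spatial amplitude maps anchored at the
stimulated site (BA6 premotor, BA7 superior parietal, BA19 occipital; maps
are fixed per site, independent of the session seed). The stimulation
parameters act as in the recorded data they emulate:

- **Site** selects a different amplitude map → topography change.
- **Intensity** multiplies the response by `(I%/50)²` and shortens the
  onset latency slightly. The quadratic gain (steep growth in the 40–75%
  working range) is a calibration choice: it makes a +10-percentage-point
  step a clearly supra-noise amplitude change, matching the observation
  that such steps are reliably detected while the topography is preserved.
- **Angle** (0°/45°/90°) offsets the component phases and partially shifts
  the map centers → morphology change of intermediate size.
- **Day** ≠ 1 applies a small multiplicative per-channel perturbation of
  the maps (default sd 3%), emulating one-week test–retest drift
  (electrode repositioning, biological variability).

Trials add multiplicative amplitude jitter (sd 10%), latency jitter
(sd 1 ms), spatially correlated 1/f background (9 µV rms per channel, mixed
from 12 pink sources with a Gaussian spatial kernel), and white sensor
noise (2 µV). The EOG channel carries its own background plus stereotyped
~300 ms biphasic blinks (180 µV, per-trial probability 0.08, with frontal
leakage), and F8 receives band-limited >25 Hz muscle bursts (35 µV rms,
probability 0.05) — together these exercise both rejection rules at
realistic rates (~12% of trials rejected, comfortably above the 150-trial
floor at 200 trials).

All amplitudes were chosen once, as plausible values for eyes-open resting
EEG and medium-intensity TEPs, and calibrated so that the synthetic study
reproduces the qualitative DI regimes of the recorded data: site changes
≈ 10–17%, angle ≈ 3–15%, intensity ≈ 2–5%, no-change pairs ≪ 1%. What the
generator does **not** model: pulse and decay artifacts (recordings are
assumed artifact-free from 8 ms), volume-conducted lead fields, heartbeat
and line noise, non-stationary vigilance drift within a session, and any
source-space structure. Passing benchmarks on synthetic sessions therefore
validates the statistics and the pipeline mechanics, not the
neurophysiology of real TEPs.

## Numerical and reproducibility choices

- All randomness derives from one master seed per run (stage seeds are
  hashed from it); comparison records log α, the permutation count and the
  seed, and re-running a study reproduces its report byte for byte.
- Windows are half-open `[start, end)` in milliseconds, the last closed at
  250 ms; sample k (0-based) of the post-stimulus window sits at t = k/725 s.
  250 ms at 725 Hz spans ⌈0.250 × 725⌉ = 182 samples, counting the pulse
  sample as the first.
- Epoch validation allows half a sample of slack on the 250 ms pre/post
  spans so that the canonical symmetric 726-sample epoch at 1450 Hz (362
  samples on one side of the pulse sample) validates.
- Degenerate inputs are errors, not silent results: all trials rejected,
  fewer than 2 trials per group, fewer than `min_trials` after cleaning,
  empty masks, single-class ROC input, baseline equivalence unreachable
  within the 5% cap.
- Sessions are stored in a single-file container: one JSON header line
  (shape, dtype, units, sampling rate, onset index, channel labels, EOG
  index, stimulation metadata) followed by a little-endian float32 payload
  — self-describing, language-neutral and lossless within float32. Reports
  are UTF-8 TSV with a fixed column schema.

## Problem sizes used by the shipped benchmarks

The packaged tests and the reproduction script run scaled-down but
structurally faithful designs, chosen so the whole suite completes on a
single CPU in minutes: the end-to-end study uses 10 change + 10 no-change
comparisons (4 site / 3 intensity / 3 angle / 5 same-day / 5 one-week),
160 trials per session, 500 permutations, and a trial floor of 120 (the
full-scale design — 62 C + 30 NC, 200 trials, floor 150, 1000 permutations
— is available through `study_design(22, 20, 20, 10, 20)` or the CLI's
`--full-scale`). Family-wise error calibration uses 500 null simulations of
a single channel at α = 0.05. The exhaustive-enumeration check uses 3 + 3
trials, where all 20 partitions can be enumerated.

## Known limitations

- The DI weights amplitude differences heavily: two responses with equal
  shape and different gain are maximally divergent. That is a feature for
  excitability monitoring and a limitation for morphology-focused questions.
- The permutation null assumes exchangeable trials after baseline
  equalization; slow within-session drift violates this and is not modeled
  or corrected.
- No spatial-adjacency or cluster statistics: channels are corrected over
  time only, and the DI aggregates them without spatial structure.
- ROC confidence intervals are out of scope; the AUC is a point estimate.

## A worked example

```{r example, eval = FALSE}
cfg <- session_config(site = "BA19", intensity_pct = 50, n_trials = 160,
                      seed = 1)
pair <- make_comparison_pair(cfg, change = "site", magnitude = "BA6",
                             seeds = c(1, 2))
res <- compare_sessions(pair$a, pair$b, comparison_id = "BA19_vs_BA6",
                        n_perm = 500, min_trials = 120, seed = 3)
res
#> <comparison_result> BA19_vs_BA6 [C/site]: DI = 16.66% (0-60: 35.11, 60-120: 22.36, 120-250: 5.53)
#>   alpha 0.05, 500 permutations, seed 3, 139 + 144 trials
```

A full scaled study with ROC classification:

```{r study, eval = FALSE}
des <- study_design(n_site = 4, n_intensity = 3, n_angle = 3,
                    n_sameday = 5, n_oneweek = 5, seed = 1)
study <- run_study(des, outdir = "study", n_perm = 500, n_trials = 160,
                   min_trials = 120, seed = 1)
study$roc
```
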