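# tepdi — Divergence Index statistics for TMS-evoked EEG potentials

`tepdi` decides, non-parametrically, whether two TMS-evoked potentials
(TEPs) differ. TMS/hd-EEG delivers single magnetic pulses to a cortical
target while recording high-density EEG; the averaged time-locked response
is a direct readout of cortical excitability and connectivity. Using
TMS/hd-EEG as a monitoring tool — tracking plasticity, pathology or therapy
over repeated sessions — requires a principled answer to one question:
*did the response change, or is this just measurement variability?*

The package is for electrophysiologists and methods researchers working
with epoched TMS-EEG (or any evoked-potential) data who need a
multiple-comparison-safe change statistic and a decision threshold with
known sensitivity and specificity.

## The statistic

For two sessions of single trials, after artifact rejection and baseline
equalization, the pooled trials are randomly re-partitioned `n_perm` times
into groups of the original sizes and averaged, giving an ensemble of
"mixed" TEPs — the empirical null of "no difference". Per channel, with
δ(t) the ensemble mean at each time sample and

&nbsp;&nbsp;&nbsp;&nbsp;G = (1−α)·100th percentile of max₍t₎ |mixed(t) − δ(t)|

the significance boundaries for the whole 250 ms post-stimulus window are
δ(t) ± G (family-wise error α per channel, corrected over time by the
max-statistic). A (channel, t) sample is *divergent* when either observed
TEP falls strictly outside the boundaries, and the **Divergence Index** is

&nbsp;&nbsp;&nbsp;&nbsp;DI = 100 × #divergent cells / (channels × 182)

with 182 = ⌈0.250 s × 725 Hz⌉ post-stimulus samples per channel. Over a
labelled set of change (C) and no-change (NC) comparisons, an ROC analysis
with the rule "change if DI > threshold" selects the operating threshold at
the maximum of the Youden index (sensitivity + specificity − 1); the area
under the curve equals the probability of ranking a random C comparison
above a random NC one.

Because no recordings ship with the analysis, the package includes a
synthetic TMS-EEG generator (damped-sinusoid evoked model with
site/intensity/angle effects, 1/f background, blink and muscle artifacts,
between-day drift) that reproduces the statistical structure the pipeline
assumes; all shipped benchmarks run on it. See the methods vignette
(`vignettes/tep-divergence.Rmd`) for the model, the design decisions and
their rationale.

## A worked example

```r
library(tepdi)

cfg  <- session_config(site = "BA19", intensity_pct = 50, n_trials = 160,
                       seed = 1)
pair <- make_comparison_pair(cfg, change = "site", magnitude = "BA6",
                             seeds = c(1, 2))
res  <- compare_sessions(pair$a, pair$b, comparison_id = "BA19_vs_BA6",
                         n_perm = 500, min_trials = 120, seed = 3)
res
#> <comparison_result> BA19_vs_BA6 [C/site]: DI = 16.66% (0-60: 35.11, 60-120: 22.36, 120-250: 5.53)
#>   alpha 0.05, 500 permutations, seed 3, 139 + 144 trials
```

Reading: moving the stimulation target from occipital BA19 to premotor BA6
changed the evoked response at 16.66% of the 60 × 182 spatio-temporal
samples (α = 0.05 per channel, family-wise over time). The change is
strongest early (35.11% of cells in 0–60 ms) and persists late (5.53% in
120–250 ms). 139 and 144 artifact-free, baseline-equalized trials entered
the two averages. A repeat of the same session (change `"none"`) gives DI
well below 1%, and a study-level `run_study()` + `roc_curve()` turns a
labelled collection of such DIs into an operating threshold, sensitivity,
specificity, accuracy and AUC.

The same workflow is scriptable from a shell via `inst/cli/tepdi.R`
(subcommands `simulate`, `compare`, `roc`, `run-study`; flags `--alpha`,
`--n-perm`, `--seed`, `--min-trials`, `--eog-uv`, `--beta-power`).
`run-study` takes either `--full-scale` (62 C + 30 NC, 200 trials, 1000
permutations), the default scaled design, or `--design file.json`, a JSON
array of comparison objects with the `study_design()` columns — `id`,
`change` (`site`/`intensity`/`angle`/`none`), `magnitude` (new site, Δ
intensity points, or new angle), `base_site`, `intensity_pct`, `day_b`,
`seed_a`, `seed_b`.

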