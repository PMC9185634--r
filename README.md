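# ripsync

Thoraco-abdominal synchrony and fatigue biomarkers from wearable signals.

## What it does

During fatiguing repetitive work, chest-wall and abdominal-wall breathing
excursions drift out of phase as respiratory and postural muscle
coordination adapts. `ripsync` turns multi-channel wearable recordings —
two respiratory inductance plethysmography (RIP) bands, surface EMG of the
biceps brachii and upper trapezius, and a wrist triaxial accelerometer,
all at 1000 Hz — into quantitative fatigability markers for a protocol of
three 10-minute work trials (Baseline, Fatigue 1, Fatigue 2):

* **RIP synchrony.** Each trial's chest and abdomen channels are FIR
  band-passed to 0.15–0.45 Hz, decimated to 40 Hz, reduced to their first
  intrinsic mode function by masked-sift empirical mode decomposition,
  z-normalised and smoothed (10 s). The package then computes the rolling
  Pearson correlation r(n) and the instantaneous phase synchrony

  φ(n) = 1 − sin(|Δϕ(n)| / 2),  Δϕ wrapped to (−π, π],

  where Δϕ is the difference of the two channels' analytic-signal
  (Hilbert) phases. φ = 1 means perfectly in phase, φ = 0 antiphase.
* **EMG fatigue features.** 4th-order Butterworth band-pass (10–500 Hz),
  100-ms RMS envelope normalised to the maximal-voluntary-contraction
  reference (%MVC), and the Welch median frequency — amplitude rises and
  median frequency falls as a muscle fatigues.
* **Accelerometer kinematics.** Task cycles segmented from the
  antero-posterior axis via the analytic phase of the normalised signal;
  pitch = atan(−aₓ/√(a_y² + a_z²)) and roll = atan(a_y/a_z) summarised per
  trial.
* **Statistics.** Every metric is aggregated per trial decile
  (10 divisions of ~1 min), Yeo-Johnson + z transformed, and modelled with
  linear mixed models (fixed: trial + division, plus optional EMG
  covariates; random intercept per subject; Wald z per term), with
  residual diagnostics, pooled Pearson correlations, and repeated-measures
  ANOVA (Mauchly / Greenhouse-Geisser, Bonferroni pairwise) for the
  per-trial accelerometer metrics.

Because raw human recordings for such protocols are rarely deposited, the
package ships a first-class synthetic study generator
(`study_config()` / `gen_study()`) with per-subject ground truth, used by
the test suite for parameter-recovery and calibration checks.

## Worked example

Generate a small RIP-only study, run the synchrony pipeline, and fit the
trial/division mixed model:

```r
library(ripsync)

cfg <- study_config(n_subjects = 6, sampling_rate = 80, trial_length_s = 200,
                    rest_length_s = 0, channels = "rip", seed = 42)
study <- gen_study(cfg)

tbl <- dplyr::bind_rows(lapply(study$recordings, function(rec) {
  dm <- rip_decile_means(compute_rip_synchrony(rec))
  dm$subject_id <- rec$subject_id
  dm
})) |>
  tidyr::pivot_longer(c(rip_corr, rip_sync),
                      names_to = "metric", values_to = "value")

dplyr::group_by(tbl, metric, trial) |>
  dplyr::summarise(mean = mean(value), sd = sd(value), .groups = "drop")
#>   metric   trial      mean     sd
#> 1 rip_corr Baseline  0.762 0.116
#> 2 rip_corr Fatigue 1 0.698 0.0976
#> 3 rip_corr Fatigue 2 0.703 0.135
#> 4 rip_sync Baseline  0.666 0.0942
#> 5 rip_sync Fatigue 1 0.621 0.0702
#> 6 rip_sync Fatigue 2 0.620 0.0854
```

Both synchrony measures drop from Baseline to the two fatigue trials —
the generator's imposed chest–abdomen lag increase, recovered through the
whole signal chain. The mixed model quantifies it:

```r
fit <- fit_trial_division_model(tbl, "rip_sync")
tidy(fit)
#>   term             beta      z        p
#> 1 (Intercept)     0.189  0.589 0.556
#> 2 trialFatigue 1 -0.548 -3.72  0.000197
#> 3 trialFatigue 2 -0.551 -3.74  0.000184
#> 4 division2       0.200  0.743 0.458
#> # ... divisions 3-10

glance(fit)
#>   dependent random_intercept_variance residual_variance converged  nobs
#> 1 rip_sync                      0.360             0.650 TRUE        180
```

Both fatigue-trial coefficients are negative (transformed scale) with
p < 0.001; division terms are null, as generated. `autoplot(fit)`,
`plot_decile_profile(tbl, "rip_sync")` and `autoplot(sync)` give the
standard pictures. For full studies on disk, use
`run_simulate()` → `run_process()` → `run_analyze()` (or the
`inst/cli/ripsync.R` launcher) which write decile tables, model reports
and a reproducibility manifest.

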