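# mpeblock

Quantitative analysis of sensory nerve-block duration and intensity in
rodent thermal-latency assays, for preclinical anesthesiology and
diabetic-neuropathy research.

In a typical experiment, mice receive a sciatic nerve block with a local
anesthetic (e.g. plain bupivacaine hydrochloride, BH, or an extended-release
liposomal formulation, LB), and paw-withdrawal latency to a radiant heat
stimulus (plantar test) is followed for several hours. `mpeblock`
implements the full analysis chain for such studies:

- **%MPE scoring.** Each post-injection latency is normalized to the
  percent maximal possible effect,

  ```
  %MPE = 100 × (post − pre) / (cutoff − pre),
  ```

  where `pre` is the animal's trimmed baseline latency and `cutoff` is the
  assay ceiling (15 s plantar, 4 s tail-flick) at which the stimulus is
  removed to prevent tissue damage; readings at the ceiling are censored at
  100%. Raw scores are clamped to [0, 100].
- **Phenotyping filters.** Baseline repeats are summarized by a one-SD
  trimmed mean; animals whose baseline reaches the cut-off (neuropathy the
  assay cannot quantify) are excluded, as are animals whose fasting glucose
  contradicts their assigned condition (> 23 mmol/L diabetic, < 8 mmol/L
  non-diabetic, the gap flagged indeterminate).
- **Balanced incomplete block scheduling.** Each mouse is measured once per
  13.5-min window on a 1.5-min slot grid over 270 min (180 grid points per
  arm; a 6-mouse group occupies 120 of them), with a seeded rotation that
  keeps consecutive visits to the same animal at least two slots apart.
- **Block kinetics.** Per-window group means of %MPE are fitted with a
  third-order polynomial (R² reported); onset (global maximum) and partial
  release (interior local minimum) landmarks are extracted analytically.
  Block duration is the time from injection until the group %MPE falls
  below 15% without re-exceeding it; blocks still above 15% at the 270-min
  horizon are reported censored. Three crossing estimators are available
  (fitted cubic, piecewise-linear interval means, and the default
  monotone-smoothed precision-weighted means; see the methods vignette).
- **Discrimination statistics.** ROC curves built from %MPE scores
  discriminate condition or treatment; areas are computed by trapezoidal
  integration (equal to the tie-corrected Mann–Whitney statistic) with
  Hanley–McNeil or bootstrap standard errors, and two independent areas are
  contrasted with χ² = (A₁ − A₂)²/(SE₁² + SE₂²) on 1 df. Two-sample
  t-tests (pooled or Welch) are available from raw samples or from
  published summary statistics alone.
- **Synthetic studies.** A seeded generator produces cohorts and censored
  latency trajectories with realistic baselines, glucose, exclusion rates
  and single-release or dip-and-rebound (bimodal release) block profiles,
  so the whole pipeline is testable end-to-end without animal data.

## Worked example

```r
library(mpeblock)

study  <- generate_study(seed = 2)        # 24 mice, 4 arms, BIBD schedule
report <- run_pipeline(study$cohort, study$measurements)
print(report)
#> <study_report>
#>   included mice: 22 (excluded: 2)
#>   control.BH   n = 6, onset 6.8 min @ 57.9% MPE, duration 108.1 min (R^2 0.79)
#>   control.LB   n = 6, onset 6.8 min @ 84.0% MPE, duration 117.6 min (R^2 0.86)
#>   dm_pn.BH     n = 5, onset 6.8 min @ 58.6% MPE, duration 126.3 min (R^2 0.89)
#>   dm_pn.LB     n = 5, onset 6.8 min @ 80.2% MPE, duration censored above horizon (R^2 0.45)
#>   ROC condition_given_BH       AUC 0.650 (SE 0.087)
#>   ROC condition_given_LB       AUC 0.802 (SE 0.071)
#>   ROC treatment_given_control  AUC 0.525 (SE 0.092)
#>   ROC treatment_given_dm_pn    AUC 0.948 (SE 0.037)
#>   contrast treatment_models  chi2(1) = 1.84, p = 0.175
#>   contrast condition_models  chi2(1) = 18.02, p = 2.19e-05
```

Two neuropathic mice whose baseline reached the 15-s cut-off were excluded
before analysis. The three single-release arms have estimated durations of
108, 118 and 126 min (the generating profiles use 106, 118 and 117 min);
the liposomal-bupivacaine neuropathic arm shows a partial release followed
by re-deepening and is still above the 15% MPE threshold at 270 min, so its
duration is censored at the study horizon. The ROC contrasts say that %MPE
separates treatments far better in neuropathic animals (AUC 0.95 vs 0.53,
χ²(1) = 18.0) and separates conditions better under the liposomal
formulation.

Cohort contrasts work from summary statistics alone:

```r
t_test_from_summary(11.9, 3.4, 12, 6.4, 2.8, 12)   # plantar latency, dm vs control
#> <block_t_test> pooled: t = 4.326, df = 22, p = 0.0002723 (means 11.9 vs 6.4, n 12/12)
```

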