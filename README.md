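# aumix

Analysis of spontaneous positive facial expression from frame-level facial
action-unit (AU) **evidence** time series — the log10 posterior odds that an
AU is active, as reported by automated facial-expression software while
participants watch short amusing video clips.

The package is aimed at researchers studying affective responsiveness in
autism spectrum disorder (ASD) versus typical development (TD). It covers
the full analysis chain:

* **Features.** For each participant, video, and AU ∈ {AU12 lip-corner
  puller, AU6 cheek raiser}: the average evidence over frames with a
  detected face, and the area under the absolute evidence curve
  (AUC, evidence·seconds, trapezoid over maximal valid frame runs). Each is
  averaged over the three videos, giving four features per participant.
* **Subgroup discovery.** Finite Gaussian mixtures on the z-scored
  (average AU12, average AU6) of the ASD group, with component covariances
  factored as Σₖ = λₖ Dₖ Aₖ Dₖᵀ (volume / shape / orientation). All 14
  equal/variable constraint families (EII … VVV) are fitted for G = 1..9
  components and compared by BIC = 2ℓ − d·log n (larger is better). The
  two-component solution is labelled **over-responsive** (larger mean
  AU12 + AU6) vs **under-responsive**.
* **Statistics.** Rank-based covariate-adjusted group contrasts with effect
  size r = t/√(t² + df) and Fisher-z CIs; partial Spearman correlations
  (residualised ranks) between features and eight caregiver-reported scales
  (ABC, ABI, RBS-R, SRS-2), adjusted for age, sex and IQ.
* **Synthetic cohort.** A calibrated generator (three 13–20 s videos at 24
  frames/s, raised-cosine Duchenne/non-Duchenne smile bursts, block-wise
  face-tracking dropout, planted scale associations) reproduces the
  published group moments exactly in its latent calibration, so the whole
  pipeline is testable without clinical data.

The EM core for the 14 covariance families is implemented in the package
(compiled RcppArmadillo with a pure-R reference engine); the test suite
cross-checks it against an independent general-purpose mixture
implementation on shared initialisations.

## Worked example

```r
library(aumix)

cfg <- cohort_config(seed = 5)          # 41 TD + 35/89 latent ASD subgroups
cohort <- generate_cohort(cfg)
features <- extract_features(cohort$traces)

m <- merge(features, cohort$participants, by = "participant_id")
asd <- m[m$group == "ASD", ]
z <- normalize_features(asd, c("avg_au12", "avg_au6"))
sel <- model_select(z, seed = 7, n_restarts = 5)
print(sel)
#> BIC model selection over 126 cells (0 failed)
#> best: VVE with G = 2, BIC = -532.92

lab <- label_subgroups(sel$best, asd)
table(lab$subgroup)
#>  over under
#>    28    96

res <- group_difference(m$avg_au12, m$group,
                        data.frame(age = m$age_years, sex = m$sex),
                        ref = "TD")
round(res[c("r", "p", "ci_low", "ci_high")], 3)
#>        r     p ci_low ci_high
#> 1 -0.176 0.025 -0.321  -0.022
```

The selected model has two components of variable volume and shape with a
shared orientation; 28 of the 124 ASD participants form the over-responsive
subgroup (the generator planted 35). The ASD group shows lower average AU12
than TD (r ≈ −0.18, p < .05) after adjusting for age and sex, matching the
planted group moments (TD 0.64 vs ASD 0.37 in the calibration targets).

The same stages run as a numbered workflow writing into `results/`:

```sh
Rscript analysis/01_simulate_cohort.R 1
Rscript analysis/02_extract_features.R
Rscript analysis/03_cluster_subgroups.R 1
Rscript analysis/04_group_statistics.R
Rscript analysis/05_reproduce_printed_effects.R 1
```

or in one call via `run_pipeline(pipeline_config(out_dir = "run", seed = 1))`,
which writes `traces.csv`, `participants.csv`, `features.csv`,
`bic_grid.csv`, `mixture_fit.json`, `report.json` plus a manifest, and is
byte-identical on re-run with the same seed.

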