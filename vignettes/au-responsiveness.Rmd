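---
title: "Facial action-unit evidence features and model-based responsiveness subgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facial action-unit evidence features and model-based responsiveness subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automated facial-expression software reports, for every video frame, an
*evidence* value for each facial action unit (AU): the base-10 logarithm of
the posterior odds that the AU is active, measured relative to an emotional
baseline. Positive facial affect is carried chiefly by AU12 (lip-corner
puller) and AU6 (cheek raiser); a smile involving both is a *Duchenne*
smile, AU12 alone a non-Duchenne smile. When children and adults watch short
amusing video clips, these evidence series quantify spontaneous positive
expression, and group differences in them are of clinical interest in
autism-spectrum (ASD) research — in particular, whether the marked
heterogeneity of the ASD group hides distinct *over-responsive* and
*under-responsive* subgroups.

`aumix` implements that analysis end to end:

1. a **synthetic-cohort generator** emulating the data structure of a
   funny-videos task (three clips of 13–20 s at 24 frames/s, TD and ASD
   groups, caregiver-reported behavioural scales);
2. **feature extraction** — per video and AU, the average evidence over
   frames with a detected face and the area under the absolute evidence
   curve (AUC), each then averaged across the three videos;
3. **model-based clustering** of the ASD participants' (average AU12,
   average AU6) with finite Gaussian mixtures under the fourteen
   eigendecomposed covariance parameterisations, selected by BIC;
4. **rank-based statistics** — covariate-adjusted group contrasts with
   effect size *r*, and partial Spearman correlations between features and
   caregiver scales.

The `analysis/` scripts in the repository run these stages as a numbered
workflow; `run_pipeline()` orchestrates the same stages in one call.

## The mixture model

Each ASD participant contributes a point $x_i \in \mathbb{R}^2$ (z-scored
average AU12 and AU6). The density is a finite mixture

$$f(x_i; \Psi) = \sum_{k=1}^{G} \pi_k \, \phi(x_i; \mu_k, \Sigma_k),
\qquad \pi_k \ge 0, \; \sum_k \pi_k = 1,$$

with each covariance factored by its eigendecomposition

$$\Sigma_k = \lambda_k D_k A_k D_k^{\top},$$

where the scalar $\lambda_k$ sets the **volume** of the density ellipsoid,
the diagonal $A_k$ with $\det A_k = 1$ its **shape**, and the orthogonal
$D_k$ its **orientation**. Constraining each factor to be equal across
components, variable, or the identity yields the fourteen standard families
(`EII` … `VVV`; see `mixture_families()`). Parameters are estimated by EM;
model and component count are chosen by
$\mathrm{BIC} = 2\ell - d\log n$ (larger is better), scanning $G = 1..9$
for all fourteen families — a 126-cell grid.

### Numerical choices

* **M-steps.** Most families have closed-form constrained updates. The
  volume–shape coupled families (`VEI`, `VEV`, `VEE`) use the standard
  fixed-point alternation; the common-orientation families (`EVE`, `VVE`)
  alternate shape/volume updates with an orientation update performed by
  cyclic Givens-rotation sweeps, for which the optimal rotation angle in
  each coordinate plane is available in closed form (exact in the 2-D
  setting used here). Inner tolerance: `1e-7`.
* **Convergence.** Relative log-likelihood change below `1e-8`, at most 500
  iterations. The log-likelihood trajectory is recorded and is
  non-decreasing (asserted in the tests for every family).
* **Initialisation.** k-means++-style seeding of one-hot responsibilities,
  `n_restarts = 10` by default, under a user-supplied seed; `em_fit()` also
  accepts an explicit responsibility matrix, which the tests use to
  warm-start nested-family comparisons.
* **Degeneracy.** Covariance eigenvalues are floored at
  `reg_floor` (`1e-6`) times the mean marginal variance and the fit is
  flagged `regularized`; collapsing components (vanishing responsibility
  mass) abort the restart.
* **Engines.** The EM core is compiled (RcppArmadillo) with a pure-R
  reference implementation retained; the suite checks they agree to
  ~1e-8 and that both match an independent general-purpose mixture
  implementation on shared initialisations.
* **Ties.** Hard assignment takes the highest-responsibility component,
  exact ties towards the lower index (logged). Subgroup labelling calls the
  component whose members have the larger mean of
  `avg_au12 + avg_au6` *over-responsive*; exact ties break by `avg_au12`.

## Feature definitions

For one participant, video and AU, with evidence $e_t$ at frame times $t$
(24 frames/s) and a face-detected mask:

* **average evidence** — the arithmetic mean of $e_t$ over detected frames
  (valence-preserving, so negative evidence counts negatively);
* **AUC** — the trapezoidal integral of $|e_t|$ against time in seconds,
  computed piecewise over maximal runs of consecutive detected frames; gaps
  contribute no area. This captures signal strength regardless of valence.

Undetected frames carry no information: they are excluded from means and
contribute no area (no interpolation). Each feature is then the unweighted
mean over the participant's valid videos (a video is valid when all four
per-video features exist), with `n_valid_videos` recorded; participants
with no valid video are excluded and reported. Features are z-scored over
the ASD rows before clustering (`normalize_features()`); AUC features never
enter the mixture — clustering uses average AU12 and AU6 only, which keeps
the model 2-D and interpretable while AUC carries largely redundant
intensity information.

The AUC abscissa is seconds, not frames: with three videos of 13–20 s and
mean absolute evidence below 1, that convention matches the magnitude of
published AUC summaries (≈ 3–21 evidence·s), while a frame abscissa would
be 24× larger.

Probabilities are mapped to evidence by $\log_{10}(p/(1-p))$; degenerate
$p \in \{0, 1\}$ are clipped to $[10^{-6}, 1-10^{-6}]$ with a warning.

## Rank-based statistics

Group contrasts regress the rank-transformed feature (average ranks for
ties) on a group indicator plus covariates — numeric covariates are also
ranked; sex enters as an indicator. The effect size is
$r = t/\sqrt{t^2 + \mathrm{df}}$ from the group coefficient's $t$
statistic; the published analyses report $r$ without defining it, and this
standard conversion reproduces the printed subgroup-contrast magnitudes
from the group moments. Two-sided p-values come from the $t$ distribution;
95% CIs from the Fisher $z$ transform with
$SE = 1/\sqrt{n - 3 - q}$ ($q$ covariates). No multiple-comparison
correction is applied (matching the original analyses); the rendered report
marks $p < .05$ with an asterisk.

Partial Spearman correlations rank both variables and the numeric
covariates, residualise the two ranked variables on the covariates by least
squares, and correlate the residuals; with no covariates this reduces
*exactly* to Spearman's $\rho$. (A recursive partial-correlation formula
coincides with one-pass residualisation; residualisation is the documented
choice.) Missing values are handled by casewise deletion with dropped-row
counts reported — IQ is never measured for TD participants, so
IQ-adjusted analyses are only ever run within ASD.

## The synthetic cohort

No public data accompany the analysis, so the generator *is* the study
fixture. It emulates:

* **Design.** Three videos of 13, 17 and 20 s at 24 frames/s; groups of
  41 TD and 124 ASD participants, the latter split latently into 35
  over-responsive and 89 under-responsive (the published sizes).
* **Signal.** Evidence is zero-mean Gaussian baseline noise (SD 0.3) plus
  smooth raised-cosine smile bursts with duration
  $\mathcal{N}(3.5, 0.5^2)$ s truncated to $[1, 6]$ s (spontaneous smiles
  typically last 3–4 s), at group-specific Poisson rates. A burst is
  Duchenne with group-specific probability (TD 0.6, over 0.8, under 0.4);
  Duchenne bursts raise AU12 and AU6 with log-normal relative amplitudes
  correlated 0.8, non-Duchenne bursts raise AU12 only. Negative evidence is
  legitimate (log-odds); the under-responsive calibration indeed implies
  some negative average evidence.
* **Dropout.** `face_detected` is false in contiguous blocks (mean 0.5 s)
  totalling ~5% of frames — faces turn away in runs, not in i.i.d. frames.
  Masked frames still carry values but are provably ignored downstream.
* **Calibration.** Per-participant latent targets for (average AU12,
  average AU6) are drawn per group with *exact moment matching*: the
  within-group sample mean, SD and correlation of the latent targets equal
  the configured calibration moments (published group moments by default;
  within-group correlation 0.5, a quantity the published group summaries
  do not constrain).
  Burst amplitudes are then solved so each participant's signal-only
  average over detected frames equals the target. Exact matching removes
  between-replicate drift of nuisance moments — a standard
  variance-reduction device in simulation studies — so group moments
  reproduce the calibration targets up to within-participant noise; with
  i.i.d. latent draws the group-mean sampling error alone would exceed a
  2% calibration check. AUC features are *emergent* from the event model,
  not directly calibrated.
* **Scales.** Eight caregiver scales are generated on instrument-plausible
  integer ranges and treated as ordinal downstream. Two associations can be
  planted: a shift (default 0.5 SD) of ABI self-regulation impulsivity in
  the over-responsive subgroup, and a Gaussian-copula correlation (default
  −0.3) between ABC lethargy/social-withdrawal and the latent AU6 AUC
  within the under-responsive subgroup. All other scales are noise. TD
  participants receive `NA` for these ASD instruments, and `NA` IQ.

What the generator does **not** emulate: facial dynamics beyond smooth
bursts (no negative-valence AUs, no AU co-articulation), attention and
compliance differences between groups, instrument floor/ceiling pile-ups,
or any dependence of dropout on expression. Passing tests therefore
demonstrate that the *pipeline* recovers planted structure under the
published moments — not that the published findings themselves generalise.

## What the simulations can and cannot recover

Two structural limits are worth stating, because the test suite asserts
them honestly:

* **Subgroup recovery has a Bayes ceiling.** Under the published group
  moments the two ASD components overlap: a Monte Carlo of the
  Bayes-optimal classifier (true parameters known) yields an adjusted Rand
  index above 0.8 in only ~65–70% of cohort draws at $n = 35/89$. A fitted
  mixture cannot beat that ceiling, so demanding ARI > 0.8 in ≥90% of
  replicates fails *by construction*; the suite asserts it anyway and the
  failure is expected and documented. Component-count selection ($G = 2$)
  and the sign of the planted scale correlation are recovered reliably.
* **Rank contrasts cap the attainable effect size.** On ranks, the
  point-biserial $r$ of two *completely separated* groups of sizes 35/89
  is 0.779 ($\sqrt{3}/2 \approx 0.866$ for equal sizes). Resimulating the
  over/under average-AU6 contrast from published moments therefore lands
  near 0.66, not the published 0.78 — the published value corresponds to
  near-complete separation, which clustering-derived labels naturally
  exhibit on the very feature they were clustered on, but which independent
  Gaussian draws from the summary moments do not reproduce.

## Problem sizes used by the test suite

Simulation sizes are chosen to make the suite informative yet quick:
calibration consistency at $n = 2000$ per group; printed-effect
resimulation with 500 replicates per contrast; BIC-consistency Monte Carlo
at $n = 1000$ with 30 seeds per scenario over $G = 1..5$; end-to-end
subgroup recovery over 50 cohort replicates with 2 EM restarts per cell.
`scripts/acceptance.R` recomputes the three headline resimulated effect
sizes (500 replicates each) from scratch under a supplied seed.

## Reproducibility

Every stochastic stage takes a seed; a pipeline master seed fans out
deterministically (`derive_seed()`), identical configuration + seed is
byte-identical on re-run (numeric output at 17 significant digits), and the
run manifest records the configuration and its hash. External data in the
documented CSV dialect can bypass the generator via
`run_pipeline(config, traces =, participants =)` after
`validate_inputs()`.

## Known limitations

* The clustering space is fixed at the two average-evidence features; the
  mixture machinery is dimension-generic, but the coupled-orientation
  families are only validated in 2-D.
* Published Table values cannot be reproduced cell-for-cell without the
  original data; the package reproduces arithmetic facts, moment-level
  resimulations and structural properties only.
* The caregiver-scale generator plants at most the two documented
  associations; it is not a general copula simulator.
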