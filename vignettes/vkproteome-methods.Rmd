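---
title: "Methods: mixed-model association analysis of multiplexed plasma proteomics and vitamin K status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model association analysis of multiplexed plasma proteomics and vitamin K status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vkproteome)
```

## The problem

Multiplexed isobaric-label (iTRAQ 8-plex) proteomics quantifies relative
protein abundance for up to eight plasma samples per mass-spectrometry
experiment. A cohort of hundreds of children therefore spans dozens of
experiments, each with its own labelling, loading and instrument drift, and
each detecting a different subset of proteins (missing-by-experiment:
a protein is quantified for all samples of an experiment or for none).
`vkproteome` implements the statistical pipeline for relating such data to
a continuous plasma nutritional biomarker — here PIVKA-II
(protein induced by vitamin K absence-II, under-carboxylated prothrombin),
a sensitive marker of subclinical vitamin K deficiency — in a design
emulating 500 children across 72 experiments.

## Normalization

Raw reporter-ion intensities are log2-transformed and centered so that each
channel (each child's sample) has median zero within its experiment
(`log2_median_normalize()`). This removes per-channel loading and labelling
offsets and makes channels comparable. We read "median normalized within a
single experiment" as per-channel centering; a per-protein-within-experiment
mode is exposed (`center = "protein"`) for sensitivity analysis, since
either convention appears in multiplexed-proteomics practice. Normalization
is idempotent on already-centered data and invariant to rescaling any
channel's raw intensities.

Only proteins quantified in strictly more than `min_children` distinct
children (default 50, i.e. >10% of a 500-child cohort) enter the analyses.

## The mixed model

All inference rests on one model, fitted per protein
(`lmm_ri()`): a univariate linear mixed model with a random intercept per
iTRAQ experiment,

$$ y_{ij} = \beta_0 + \beta_1 x_{ij} + u_j + e_{ij},
   \qquad u_j \sim N(0,\sigma_u^2),\; e_{ij} \sim N(0,\sigma_e^2), $$

estimated by restricted maximum likelihood (REML). The random intercept
absorbs experiment-level batch effects and is what lets 72 separate
experiments be combined into one regression.

Two fixed directions are used, encoded explicitly so they can never be
swapped:

* **association** (`associate_all()`): $y$ = log2 PIVKA-II (children at or
  above the assay detection limit of 0.001 µg/L; below-detection children
  cannot enter a log outcome), $x$ = normalized log2 protein abundance;
* **group difference** (`group_diff_all()`): $y$ = normalized log2 protein
  abundance, $x$ = deficiency indicator (PIVKA-II strictly above 2 µg/L;
  children at or below the cutoff, including below-detection children, are
  the reference group). All 500 children are eligible here.

### Estimation

The REML criterion is profiled over the variance ratio
$\lambda = \sigma_u^2/\sigma_e^2$. For fixed $\lambda$ the covariance is
block compound-symmetric, so the GLS fixed effects, the profiled
$\hat\sigma_e^2$ and the restricted log-likelihood reduce to closed forms in
per-experiment sums; a bounded scalar optimizer then maximizes over
$\log\lambda \in [-14, 14]$ with tolerance $10^{-8}$, and the interior
optimum is compared against the $\lambda = 0$ boundary (and the interval
endpoints), so $\hat\sigma_u^2$ is never negative. With a single experiment,
or a boundary estimate $\hat\sigma_u^2 = 0$, the fit equals ordinary least
squares exactly. Proteins observed in only one experiment are fitted in that
OLS limit rather than skipped. Perfect fits ($\hat\sigma_e^2 = 0$) are
returned with zero standard errors; the Wald test then refuses to run
rather than reporting a spurious zero p-value. Constant predictors raise a
degenerate-design error; inside the per-protein loops such proteins are
skipped with a warning, never fatally.

The tests validate the optimizer two independent ways: against a dense-matrix
brute-force grid maximization of the restricted likelihood (small instances),
and against `lme4::lmer` (fixed effects, variance components, BLUPs and REML
log-likelihood agree to ~1e-5 or better).

### Inference conventions

* **Wald z**: p-values come from $z = \hat\beta_1/\mathrm{se}(\hat\beta_1)$
  against the standard normal, with no small-sample df correction. With up
  to 72 experiments and several hundred children per fit the normal
  reference is adequate; on driver-free null cohorts the realized type-I
  error at $\alpha = 0.05$ sits at its nominal level (see the error
  calibration test). This is a deliberate convention, not an oversight;
  Satterthwaite-type corrections are out of scope.
* **Effect scale**: slopes on the log2–log2 scale are reported as the
  percent change in the outcome per doubling of the predictor,
  $(2^\beta - 1) \times 100$, with 95% normal-quantile confidence bounds
  transformed through the same monotone map (`percent_change()`).
* **$R^2$**: the proportion of outcome variance explained by the fitted
  values, $\mathrm{Var}(\hat y)/\mathrm{Var}(y)$ clipped to $[0,1]$, where
  fitted values include the BLUP random intercepts by default
  (`fitted_r2(fit, include_ranef = FALSE)` gives the fixed-effects-only
  variant for sensitivity).

## Multiple testing

Each analysis family (association; group difference) gets its own Storey
q-values (`storey_qvalues()`), never pooled. The null proportion $\pi_0$
uses the conventional smoother: $\hat\pi_0(\lambda)$ on the grid
$\lambda = 0.05, 0.10, \dots, 0.95$, cubic smoothing spline (df = 3),
evaluated at the grid maximum, clipped to $(0, 1]$; fixed-$\lambda$ and
$\pi_0 = 1$ modes are available. With $\pi_0 = 1$ the q-values reduce
exactly to Benjamini–Hochberg adjusted p-values, which the tests assert
against `stats::p.adjust`. Discovery thresholds are strict: the primary
screen is $q < 0.10$, the relaxed network threshold $q < 0.20$.

## Correlation network

The network stage (`select_network_proteins()`, `averaged_correlation()`)
takes the union of proteins passing $q < 0.20$ in either family, ordered by
each protein's minimum q. For every pair, Pearson correlation is computed
within each experiment over the children observed for both proteins, and
per-experiment coefficients are averaged, unweighted, across experiments —
computing within experiments keeps batch effects from inflating
co-abundance estimates. Experiments contributing fewer than 3 complete
pairs are skipped for that pair (Pearson is undefined at fewer than 2
points and degenerates to ±1 at 2). Count-weighted and Fisher-z averaging
modes exist for sensitivity analysis; plain averaging is the default
because it is the study convention. For display, entries with
$|r| < 0.01$ (strict) are set to exactly 0; the diagonal is untouched.

Note that the per-experiment sample size is at most the plex size, so a
single per-experiment coefficient is noisy (sd ≈ 0.2 at 7 children and
ρ = 0.8, with the usual small-sample negative bias of Pearson's r);
stability comes from averaging over ~70 experiments, and any check on the
extreme (minimum) pairwise entry should itself be averaged over replicate
cohorts.

## The synthetic cohort generator

`generate_cohort()` draws full synthetic studies so every stage is testable
against known truth without any external data. What it emulates, and how
its defaults were set:

* **Design**: 500 children shuffled and allocated round-robin to 72
  experiments (each at most 8 channels; channel labels drawn at random
  within experiment; surplus channels stay empty).
* **Abundance**: log2 intensity = grand level + protein mean
  ($\sigma = 0.3$) + channel offset ($\sigma = 0.3$) + experiment-level
  batch effect ($\sigma_u^2 = 0.04$) + child-level biological signal
  ($\sigma_{bio}^2 = 0.09$); raw intensities $2^{(\cdot)}$ are emitted so
  the normalization stage is always exercised.
* **Missing-by-experiment detection**: each protein carries a detection
  probability drawn from a Beta distribution whose mean matches the target
  mean detected-per-experiment count (589 of 4705) and whose shape is
  solved (beta-binomial tail equation, `uniroot`) so that the expected
  number of proteins quantified in >50 children matches its target (978).
  The driver and block proteins are abundant, near-ubiquitously detected
  species (detection probability 0.95), like coagulation factors and
  hemoglobin subunits in plasma.
* **Outcome**: latent log2 PIVKA-II = $\alpha + \sum_k \beta_k x_{ik} + e_i$
  with five driver proteins (slopes 1.2, −0.8, 0.9, −0.7, 0.6, chosen so
  the strongest driver explains ≈30% of outcome variance, matching the
  magnitudes seen in this kind of screen) and residual variance solved so
  the marginal log2 sd is 0.79. The location is $\log_2(1.31)$. The sd is
  a deliberate compromise: matching the target interquartile range
  (0.83, 1.87) exactly implies ≈24% deficiency prevalence, while matching
  the ≈20% prevalence exactly implies an IQR ≈17% too narrow; sd 0.79
  keeps the median exact, the IQR within ≈5%, and the prevalence ≈21–22%.
* **Below-detection zero spike**: `round(26/500 · n)` children are
  recorded as assay-undetectable (value 0, flagged), drawn independently
  of the continuous latent. A continuous distribution with median
  1.31 µg/L has essentially no mass below 0.001 µg/L, so the undetectable
  group is modelled as a distinct spike — not as the smooth lower tail of
  the latent. This matters statistically: treating the 26 as the lowest
  latent values would make the continuous analysis a lower-tail truncation
  of the outcome, attenuating every slope by roughly
  $v/(R^2 v + 1 - R^2) \approx 0.85$ (truncated-normal variance factor
  $v \approx 0.80$ at 5.2% truncation) — a bias the zero-spike model does
  not induce.
* **Correlated block**: 5 proteins share a latent factor so their
  within-experiment biological correlation is exactly ρ = 0.8, emulating
  the hemoglobin-subunit / erythrocyte-enzyme cluster.
* **Reproducibility**: one master seed fans out to per-stage substreams
  (allocation, outcome, detection, intensities); identical configs and
  seeds give identical TSV output byte for byte.

What it does **not** emulate: reporter-ion ratio compression and
interference, peptide-to-protein rollup, covariate structure (age, lipids,
inflammation) beyond independent columns, assay measurement error in
PIVKA-II, and correlation between driver proteins. Passing tests therefore
show that the statistical machinery recovers truth under the stated
generative model, not that the biological findings of any particular cohort
are reproduced.

`resample_null()` permutes outcomes across children within experiment,
severing protein–outcome association while preserving batch structure. One
subtlety discovered in validation: when the outcome itself carries
experiment-level signal variance (drivers with batch effects), the
restriction also preserves the random between-experiment overlap between a
protein's batch effects and the outcome's, so a single restricted
permutation is an exact null only for the within-experiment association.
Error-calibration checks therefore use driver-free cohorts, where the
permutation null is exact.

## Problem sizes used by the checks

The test-suite and the acceptance script size their simulations as
follows, chosen to give stable Monte-Carlo estimates: design calibration
on 20 full-size cohorts (4705 proteins); driver recovery on 50 cohorts of
300 proteins with the full 500 × 72 child/experiment layout and dense
detection (240/experiment — a proportionally sparse reduction would let
the per-channel median itself add noise and attenuate slopes by 1–2%,
an artifact of reduction rather than of the full design); error
calibration on one 400-protein driver-free permuted cohort; FDR control
on 50 cohorts of 200 proteins with 10% true effects (slopes ±0.45);
REML-vs-oracle comparison on 100 instances of ≤40 observations and
≤6 groups against a 402-point profile grid.

## Known limitations

* Wald z inference carries mild small-sample anticonservatism for proteins
  spanning very few experiments; at this design's coverage filter
  (>50 children, hence ≥8 experiments) the effect is not measurable in the
  calibration checks, but users applying the package to much smaller
  designs should expect it.
* The univariate models are unadjusted by construction; confounding by
  age, lipids or inflammation is out of scope, as in the emulated
  analysis.
* $\pi_0$ smoothing is unstable for very small families (tens of
  p-values); the implementation floors $\hat\pi_0$ at $1/m$ with a warning
  rather than failing.
* Group analyses classify below-detection children as sufficient; if the
  undetectable group were enriched for extreme deficiency this would
  attenuate group contrasts — with PIVKA-II the undetectable children are
  the *least* deficient direction, so the convention follows the assay's
  meaning.
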