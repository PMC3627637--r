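---
title: "Methods: paired inspiratory-expiratory CT densitometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired inspiratory-expiratory CT densitometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedCT)
```

## The measurement model

All metrics are histogram-level summaries of Hounsfield-unit (HU) values
inside a supplied lung segmentation. Nothing in the package registers the
inspiratory to the expiratory scan: the two phases are treated as
independent samples of the same lung at different inflation, which is why
all paired measures compare *distributions* (percentages, means, band
fractions), never voxel-to-voxel differences. Parametric-response-mapping
style voxel matching is explicitly out of scope.

The threshold conventions are fixed once:

* the emphysema set is `HU < -950` (strict),
* the trapping band is `-950 <= HU < -856`,
* "non-emphysematous lung" is `HU >= -950`.

With strict lower bounds everywhere, the three sets partition the segmented
lung exactly, and every thresholded measure is invariant to how ties at the
cutoff would otherwise be broken. Source literature writes "< -950" and
"> -950" without resolving equality; the partition property is why equality
is assigned to the denser side here. HU values are used as stored — the
NIfTI scale slope/intercept is applied on read, but no scanner-specific
recalibration is attempted (none is implemented anywhere in the field's
standard pipelines either); values outside [-1024, 3071] trigger a warning
because they usually indicate a format problem.

Lung volumes are voxel count × voxel volume, with voxel volume the product
of the three spacing components (volumetric acquisitions; no slice-gap
model). Inspiratory volume is reported as TLC, expiratory as FRC, in liters.

### Severity classification

Emphysema is *absent* below 5% (former smokers) or 4% (current smokers) of
inspiratory lung under -950 HU, *severe* above 15% / 14%, otherwise
*intermediate*. The one-point offset compensates the higher lung density of
active smokers, which depresses the emphysema index. Both comparisons are
strict, so a value exactly on a cut-point is intermediate — the definitions
use strict inequalities on both sides, and this is the only assignment
consistent with both of them.

### The residual measure

The fourth gas-trapping measure is the per-subject residual from one
cohort-wide OLS regression of Exp₋₈₅₆ on Insp₋₉₅₀, fitted with an
intercept. The intercept is not optional: without it the residuals would
not have zero mean, and the defining property of the measure — zero mean
and exactly zero Pearson correlation with the emphysema index — is an
algebraic consequence of least squares with an intercept, not an empirical
finding. The fit is cohort-wide rather than per-stratum (a single fit is
what gives one consistent residual column that subgroup analyses can then
slice); missing pairs are excluded from the fit and flagged `NA`, never
imputed.

### Joint outcome models

Each model regresses one clinical outcome on the standardized emphysema
index plus one standardized gas-trapping measure (optional covariates can
be added; none are included by default, because the covariate sets behind
published adjusted models are study-specific and not part of this package's
contract). Standardization uses the sample (n−1) standard deviation; the
choice between n and n−1 rescales coefficients by a factor of order 1/n and
leaves fit, p-values and R² untouched. Coefficients therefore read as
outcome change per 1 SD of the raw predictor, which is what makes measures
with different natural units comparable. Missing data: pairwise-complete
for correlation tables, listwise for regressions. p-values are two-sided
with no multiplicity correction. GOLD staging implements the standard
spirometric rules (ratio < 0.7 gated, then 80/50/30% predicted), with
preserved-ratio-reduced-FEV₁ subjects reported as `unclassified`.

## What the phantom generator emulates

A phantom is an ellipsoidal "lung" whose voxels belong independently to one
of three compartments:

| compartment | insp. mean (HU) | insp. SD | expiratory shift |
|---|---|---|---|
| emphysema | -990 | 15 | +5 |
| trapped   | -880 | 20 | +10 |
| normal    | -870 | 25 | +150 |

Inspiratory HU are truncated-normal draws on [-1024, 100]; expiration keeps
a random 65% of the lung voxels (volume loss without geometry — the metrics
are histogram-level, so thinning is statistically equivalent to deformation
and keeps every expectation closed-form) and adds the compartment shift to
the retained voxels. The defaults encode the mechanism of interest:
emphysema stays almost entirely below -950 on both phases, trapped lung
stays lucent (inside the band) on expiration, and normal lung crosses -856
as it densifies. Consequently expiratory lucency alone cannot distinguish a
high-`f_emph` phantom from a high-`f_trap` phantom built to match its
Exp₋₈₅₆ — while the inspiratory index separates them by construction. The
acceptance script stages exactly this experiment (matched Exp₋₈₅₆ ≈ 38%,
Insp₋₉₅₀ differing by ~25 points).

Because compartment assignment and draws are i.i.d., every metric has a
closed-form expectation from truncated-normal tail probabilities
(`expected_phantom_metrics()`), and the sampling error of a measured metric
is known (`phantom_metric_se()`): binomial for the thresholded percents,
delta-method for E/I MLA and RVC. The delta-method SEs ignore the positive
inspiratory–expiratory covariance created by voxel thinning (expiratory HU
are shifted copies of retained inspiratory HU); ignoring a positive
covariance overstates the SE of a ratio and of a difference, so the 3-SE
agreement bands used in the tests are conservative.

What the phantom does *not* emulate: anatomy, airway trees, reconstruction
kernels, noise texture, scanner drift, segmentation error, or breath-hold
variability. Passing phantom tests therefore validates the *arithmetic* of
the metrics against a known generative law — it says nothing about
segmentation quality or acquisition protocol effects on real scans.

## What the cohort generator emulates

Subjects are drawn with a right-skewed (gamma) emphysema index of mean 6.2%
and SD 9.7%. The three gas-trapping measures load on the standardized
emphysema index plus one latent small-airway severity factor, with loadings
(0.83, 0.45), (0.51, 0.70) and (0.37, 0.55) for Exp₋₈₅₆, E/I MLA and
RVC₈₅₆₋₉₅₀, chosen so the emphysema correlations rank
Exp₋₈₅₆ > E/I MLA > RVC — the ordering that motivates paired acquisition in
the first place (the expiratory-only measure is the one most contaminated
by emphysema). Measures are then placed on their natural scales
(21.9 ± 19.9%, 0.87 ± 0.07, −0.37 ± 0.18) and clamped to their admissible
ranges, with clamp counts logged; the spike of Exp₋₈₅₆ values at 0 that
clamping produces is, incidentally, what real smoker cohorts look like.

Outcomes come in two kinds:

* **Joint-equation outcomes** (`fev1_l`, `sixmwd_ft`, `sgrq_total` by
  default) follow exactly linear Gaussian laws in the two standardized CT
  predictors. These are deliberately *not* clamped: the generator's purpose
  here is parameter recovery, and an exactly linear law is what makes
  "noiseless equations give R² = 1 and exact coefficients" a theorem rather
  than an approximation. The cost is that extreme synthetic tails can
  produce out-of-range values (a near-zero or negative FEV₁ in well under
  1% of subjects); a generator aiming at clinical realism would saturate,
  and a saturating generator could not certify a regression implementation.
* **Descriptive columns** (spirometry percents, FEV₁/FVC, FEF₂₅₋₇₅,
  FRC/TLC, MMRC, exacerbation frequency, demographics) follow single-loading
  laws and *are* clamped to instrument ranges; they exist to exercise
  correlation tables, stratification and GOLD staging, not recovery tests.

The default FEV₁ equation uses E/I MLA as the gas measure with
coefficients −0.31 and −0.30 L per SD; its noise SD (0.3636 L) is the
closed-form value for which the two-predictor model explains ≈ 68% of the
outcome variance given the 0.51 predictor correlation. The FEV₁ cohort mean
(2.2 L) is a realistic value for a mixed-severity smoker cohort; large COPD
cohorts report percent-predicted rather than absolute means, so liters had
to be chosen here. Duplicate-scan visits (18 subjects by default) add
Gaussian retest noise scaled per measure (factors 0.72, 1.05, 1.48 of the
measure SD), making the expiratory-only measure the most repeatable and RVC
the least — the pattern expected when a measure compounds the variability
of two acquisitions.

All randomness in both generators flows from the explicit `seed` field
through a private RNG stream (the caller's `.Random.seed` is untouched),
and identical specs give bit-identical volumes and tables.

## Numerical choices and degenerate inputs

* Truncated-normal mean/variance/CDF use the standard Mills-ratio closed
  forms; sampling is by inverse CDF, which is exact and vectorizable (no
  rejection step, no accuracy loss at the mild truncations used here).
* E/I MLA errors out when the inspiratory MLA is within 1 HU of zero — the
  ratio is numerically meaningless there, and real lungs are several
  hundred HU below zero.
* Relative lung volume errors out when no voxel is ≥ -950 HU (an
  "all-emphysema" input has no non-emphysematous denominator); RVC
  propagates that error labeled with the offending phase.
* An empty mask is an error for every density metric but yields 0 L (with a
  warning) for lung volume — a volume of nothing is zero, but the FRC/TLC
  ratio downstream still requires a positive TLC.
* Collinear model predictors are reported by name rather than silently
  dropped (R's `lm` would alias them).
* Spearman correlation is computed as Pearson on mid-ranks, which is the
  tie-correct definition and matches an explicit rank-then-correlate oracle
  to floating precision.

## Problem sizes

The test suite exercises the voxel-level oracles on volumes up to 32³ (200
random volumes in the orthogonality/oracle block), phantom agreement on a
4×4 grid of compartment fractions at 64³ (≈ 100k lung voxels per phantom,
all sixteen combinations within 3 conservative SEs of the closed form), and
cohort statistics at n = 5000–8517 — sizes at which the binomial SEs are a
few hundredths of a percentage point and coefficient SEs are ≈ 0.006 L, so
the recovery checks are sharp. The whole suite runs in well under a minute.

## Known limitations

* No deformable registration: measures needing voxel correspondence
  (parametric response mapping) are out of scope by design.
* Lung segmentation is an input, never computed; garbage masks give garbage
  metrics with no warning beyond the calibration range check.
* Airway-wall morphometry (Pi10 and relatives) is not implemented.
* The synthetic cohort's correlation structure is a two-factor
  approximation; it reproduces the first-order moments and the measure
  ordering, not the full joint distribution of a real cohort, so effect
  sizes estimated on synthetic data validate the estimator, not the
  biology.
* CT lung volumes depend on breath-hold compliance; the package reports
  what the mask contains and cannot detect a poorly coached expiration.
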