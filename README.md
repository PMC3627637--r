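# pairedCT

Quantitative densitometry of paired inspiratory–expiratory chest CT in R.

## The problem

In smokers with COPD, airflow obstruction lives mostly in the small airways
(< 2 mm), which are below CT resolution. Gas trapping on expiratory CT is the
standard imaging surrogate, but a lucent voxel on an expiratory scan can mean
two very different things: destroyed, emphysematous lung (which is lucent on
*both* phases) or intact lung that fails to empty because its small airways
are obstructed. Expiratory imaging alone cannot tell them apart; pairing the
expiratory scan with the inspiratory scan can.

`pairedCT` implements the voxel-level metric panel for that paired analysis,
the cohort-level statistics used to compare the measures against clinical
outcomes, and synthetic phantom/cohort generators with closed-form expected
values so the entire pipeline is testable without patient data.

## The measures

For lung voxels (from a supplied segmentation mask) with attenuation in
Hounsfield units:

- **Insp₋₉₅₀** — percent of inspiratory lung voxels with HU < −950: the
  density-mask **emphysema index**.
- **Exp₋₈₅₆** — percent of expiratory lung voxels with HU < −856: whole-lung
  **gas trapping** (emphysema + small-airway disease, conflated).
- **E/I MLA** — ratio of expiratory to inspiratory mean lung attenuation.
  Lungs that empty normally densify on expiration (ratio well below 1); gas
  trapping pushes the ratio toward 1.
- **RVC₈₅₆₋₉₅₀** — expiratory-minus-inspiratory change in the fraction of
  non-emphysematous lung (HU ≥ −950) occupying the −950…−856 HU band.
  Typically negative; trapped lung keeps it near zero.
- **Residuals** — per-subject residuals from the cohort-level OLS regression
  of Exp₋₈₅₆ on Insp₋₉₅₀: gas trapping with the emphysema contribution
  regressed out (zero mean and exactly uncorrelated with Insp₋₉₅₀ by
  construction).
- **TLC, FRC** — CT-derived lung volumes (voxel count × voxel volume) from
  the inspiratory and expiratory masks; their ratio FRC/TLC indexes
  hyperinflation.

Emphysema is classed as *absent* (Insp₋₉₅₀ < 5% in former, < 4% in current
smokers — the offset compensates the density inflation of active smoking) or
*severe* (> 15% / > 14%), with everything else *intermediate*. Joint linear
models of an outcome on the standardized emphysema index plus one
standardized gas-trapping measure report per-SD coefficients, p-values and
R², so competing gas-trapping measures can be compared on a common scale.
Thresholds use strict inequalities, so the emphysema set, the band and the
denser lung partition the segmented lung exactly.

## Worked example

```r
library(pairedCT)

# a synthetic paired scan: 25% emphysema, 25% air-trapped, rest normal lung
spec    <- phantom_spec(shape = c(48, 48, 48), f_emph = 0.25, f_trap = 0.25, seed = 7)
phantom <- generate_phantom_pair(spec)
compute_scan_pair_metrics(phantom$pair)
#> <density_metrics> Insp-950 24.83%  Exp-856 43.61%  E/I MLA 0.9127  RVC -0.5178
#>   TLC 0.014 L  FRC 0.009 L  FRC/TLC 0.650  emphysema: severe
phantom$truth
#> <phantom_truth> 42168 insp / 27409 exp lung voxels
#>   expected: Insp-950 24.94%, Exp-856 43.95%, E/I MLA 0.9127, RVC -0.5149
```

The measured emphysema index (24.83%) sits on the programmed compartment
fraction, and every metric matches the truncated-normal closed-form
expectation carried in the truth sidecar. (The tiny ellipsoid "lung" is a
toy, hence the 0.014 L TLC; FRC/TLC equals the programmed 0.65 expiratory
volume scale.)

```r
g   <- generate_cohort(cohort_spec(n = 2000, seed = 7))
fit <- fit_gas_trapping_residuals(g$cohort$exp_856, g$cohort$insp_950)
fit
#> <residual_fit> Exp-856 = 12.8501 + 1.5424 * Insp-950  (n = 2000, 0 excluded)
#>   residual SD 10.4389, mean 3.24e-16

joint_outcome_model(g$cohort, "fev1_l", "ei_mla")
#> <joint_model_result> fev1_l ~ z(insp_950) + z(ei_mla)  (n = 2000)
#>   beta emphysema -0.3277 (p = 3.99e-211), beta gas trapping -0.2956 (p = 4.83e-179), R^2 = 0.688
```

The residuals have mean zero by construction, and the joint model recovers
the cohort generator's coefficients (−0.31 and −0.30 L per SD, R² ≈ 0.68).

Batch analysis of real data is manifest-driven: a CSV mapping `subject_id`
to the four NIfTI paths plus smoking status, through `run_pipeline()` or the
installed command-line script:

```sh
pairedct cohort --input manifest.csv --clinical clinical.csv --out results/
pairedct simulate --type cohort --n 500 --seed 7 --out sim/
```

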