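Package: pairedCT
Title: Quantitative Densitometry of Paired Inspiratory-Expiratory Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-level emphysema and gas-trapping metrics from paired
    inspiratory and expiratory thoracic CT scans with lung segmentation
    masks: the density-mask emphysema index (percent of inspiratory lung
    below -950 HU), whole-lung expiratory gas trapping (percent below
    -856 HU), the expiratory-to-inspiratory ratio of mean lung attenuation,
    the relative volume change of the -856 to -950 HU band, and residuals
    of expiratory gas trapping regressed on emphysema. Also computes
    CT-derived lung volumes (TLC, FRC), classifies emphysema severity with
    smoking-status-specific cut-points, and provides the cohort-level
    statistical machinery (Pearson and Spearman correlations, standardized
    joint regression models with R-squared, GOLD staging, subgroup
    stratification, duplicate-scan reproducibility). Includes synthetic
    phantom and cohort generators with closed-form expected metrics so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
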