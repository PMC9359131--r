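Package: planscore
Title: Dosimetric Plan-Quality Scoring and DVH Analysis for Radiotherapy Plan Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing competing radiotherapy treatment-plan groups on
    a common patient cohort. Computes cumulative dose-volume histograms (DVH)
    and the derived point metrics (D2%, D50%, D98%, Dmean, VxGy) from voxel
    dose grids and binary structure masks, the ICRU-83 style target coverage,
    homogeneity and conformity indices, and a cohort-referenced relative-
    deviation quality score that ranks plan groups against the per-item best
    performer. Includes delivery-efficiency metrics (total monitor units,
    small-segment fraction), normality-gated two-sample comparison statistics
    with Bonferroni correction, organ-at-risk constraint checking, and a
    synthetic-cohort generator (blurred-step voxel phantoms, per-metric
    Gaussian cohorts with a shared patient effect, mixture segment MU lists)
    so the whole pipeline is exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'blur.R'
    'cohort.R'
    'score.R'
    'constraints.R'
    'io.R'
    'data-defaults.R'
    'dvh.R'
    'efficiency.R'
    'indices.R'
    'metrics.R'
    'phantom.R'
    'segments.R'
    'stats.R'
    'pipeline.R'
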