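---
title: "Cohort-referenced plan-quality scoring: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-referenced plan-quality scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planscore)
```

## The problem

Comparing competing radiotherapy plan groups — the same patient cohort
re-planned under several optimisation settings, such as fluence-map beamlet
widths from 2 to 10 mm — is awkward because the groups trade off dozens of
metrics at once: one setting covers the target slightly better, another
spares a parotid slightly more. `planscore` implements a relative-deviation
scoring system that collapses any configured set of metrics into one
comparable number per group, plus the DVH machinery, efficiency metrics and
comparison statistics around it. This vignette records the models, the
numerical conventions, and the choices made where the design was genuinely
open.

## The scoring model

Each scored item is one (structure, metric) pair with a declared direction
of merit and a weight. Writing $M_j$ for a group's value on item $j$ and
$C_j$ for the cohort-best value on that item (minimum across groups when
lower is better, maximum when higher), the item score and overall score are

$$S_j = \left| \frac{M_j - C_j}{C_j}\, P_j \right|, \qquad
  S_D = \sum_{j=1}^{k} S_j ,$$

with $P_j = 1$ by default. Properties the implementation guarantees and the
tests assert: every item has at least one group scoring exactly 0; scores
are non-negative and invariant under a change of dose units (both $M$ and
$C$ rescale); the overall score is exactly the PTV subtotal plus the OAR
subtotal; a zero reference value is an error (the relative deviation is
undefined), never a silent skip; ties leave every tied group at 0 and are
recorded.

Three choices here were open and are worth stating:

- **The reference is selected per item, not per group.** A single "best
  group overall" cannot simultaneously hold every per-item best value, and
  a per-group reference would force that group's subtotal to 0 by
  construction. With per-item references even the winning group accrues a
  small positive subtotal from the items where another group is better —
  which is what makes the score informative.
- **Group means are scored, not per-patient scores averaged.** With 20
  patients per group the natural alternatives differ; scoring the means is
  the convention that reproduces the published subtotals this package's
  acceptance checks target, and it keeps the score a property of the group.
- **Direction of merit per metric.** Coverage (TC) and conformity (CI) are
  higher-better; homogeneity (HI), all OAR dose metrics and the PTV
  near-max dose are lower-better. Full precision is kept internally;
   3-decimal rounding is applied only in display columns.

The default scored item set (`defaultMetricSpecs()`) is TC, CI, HI and
D2 per PTV plus one dose metric per OAR. The exact PTV item set behind
published PTV subtotals of this kind is generally not recoverable from
published summary tables (D50 values, for instance, are often not
printed), so the
PTV side is deliberately configuration-driven and no test asserts specific
PTV subtotal values; the OAR side is fully determined by the shipped table.

## DVH conventions

The cumulative DVH is built by counting: `cumVolume[i]` is the percentage
of masked voxels with dose at least `binEdges[i]`, on edges that are
multiples of the bin width (default **0.05 Gy**) spanning `[0, max + bin]`.
The curve is therefore non-increasing from exactly 100% to exactly 0%.

- **Dx% (dose at volume)** returns the largest bin edge at which at least
  x% of the volume is still covered. For counting-based curves this is the
  exact voxel quantile whenever the quantile coincides with an edge (a
  uniform 2 Gy structure gives D2% = D50% = D98% = 2 Gy exactly) and is
  within one bin width otherwise; tests quantify the binning error against
  a sorting oracle. Linear interpolation into the falling bin was rejected
  because it misplaces degenerate (flat) distributions by up to one bin.
- **VxGy (volume at dose)** linearly interpolates the cumulative curve.
- **Dmax is reported as D2%** (the near-max), following the common clinical
  convention that a single hottest voxel is not robust; the true voxel
  maximum is exposed separately (`dmaxVoxel`).
- **Volumes** are voxel counts times the voxel volume (product of
  spacings); masks are binary and partial-volume effects are ignored — a
  desk-scale simplification, acceptable because every consumer of these
  volumes (TC, CI) uses ratios of consistently computed quantities.
- **Floating-point guard.** All "dose ≥ threshold" tests (DVH counting,
  prescription-isodose membership) use a relative-plus-absolute guard of
  1e-9, so analytically exact ties — a uniform region at exactly the
  prescription, bin edges that are decimal multiples — count as covered
  despite binary representation error. The guard is far below any
  dosimetric resolution and invisible for continuous dose data.
- The homogeneity index is implemented in the ICRU-83 **difference form**
  $(D_{2\%} - D_{98\%})/D_{50\%}$. The ratio form
  $(D_{2\%}/D_{98\%})/D_{50\%}$ occasionally seen in print carries units of
  Gy$^{-1}$ and cannot reproduce the dimensionless 0.07–0.29 magnitudes
  clinical tables report; the difference form does.

## The synthetic cohort generator

No patient data ship with the package; three generators stand in, and their
defaults are the study conditions the packaged tables describe (five groups
BL02–BL10, 20 patients, the shipped per-cell means and SDs).

**Voxel phantom** (`buildPhantom`). A spherical target inside a voxel grid
receives the prescription dose on a low background, then the dose is
convolved with an isotropic Gaussian of width `blurSigma` (mm), implemented
as an exact separable discrete convolution (kernel support 4σ, replicate
edge padding, oracle-tested against dense convolution). The blur is the
phantom's single tunable and stands in for the penumbra broadening that
coarser beamlet widths produce; the default mapping is 1:1 (width in mm →
σ in mm). Sweeping σ reproduces the qualitative physics the analysis is
meant to detect: target coverage is non-increasing and abutting-OAR dose
non-decreasing in σ.

One consequence of the literal blurred-step construction deserves a
warning: since Gaussian tails reach everywhere, *no* voxel remains at
exactly the prescription once the blur support crosses the target boundary,
so coverage evaluated at the literal step dose collapses to 0 by σ ≈ 4 mm
on a 20 mm target (monotonically, but abruptly). Clinical plans do not
behave this way because they are normalised so the prescription isodose
sits below the target's hot plateau. The pipeline therefore also reports
coverage at a configurable fraction of the step dose (default 0.95), which
yields a smooth, informative sweep; both versions are asserted monotone in
the tests.

**Metric cohort** (`sampleMetricCohort`). Each (group, structure, metric)
cell is Normal(mean, sd) in the metric's units; each patient additionally
carries one shared offset, Normal(0, `patientEffectSd`), applied across all
of that patient's plans. The shared offset is what makes the design paired
— per-patient values correlate across groups — matching a cohort in which
the same patients are re-planned once per group. Values are truncated to
physically valid bounds (doses ≥ 0, percentages in [0, 100], CI in [0, 1])
by **resampling**, not clipping, so cell means are approximately preserved
and no probability mass piles up at the bounds. "Approximately" is doing
real work: for cells close to a bound (TC ≈ 98 with SD ≈ 1.2 against the
100% ceiling) the realised mean is the truncated-normal mean, about 0.2
percentage points below the configured one. The tests assert convergence to
the analytic truncated-normal moments, which coincide with the configured
ones away from the bounds.

**Segment MUs** (`sampleSegments`). Per-segment monitor units follow a
two-component uniform mixture — low component on [1, 4.5] MU drawn with
probability `smallWeight`, high component on [8, 25] MU — then all MUs are
rescaled so the plan total is exact. The packaged per-group defaults take
total MU and small-segment weight from the shipped efficiency table, and
set the segment count to `round(totalMu / mixture mean)` so the rescale
factor is near 1 and the realised small-segment fraction tracks the
configured weight (a rescale factor far from 1 would push high-component
segments across the 5 MU threshold and bias the fraction). The
small-segment threshold is **strictly** less than 5 MU, configurable.

What the generators deliberately do **not** emulate: fluence-map
optimisation and MLC sequencing (the phantom has no beams), inter-metric
correlation beyond the shared patient effect (a real plan's TC and CI are
correlated through geometry), non-Gaussian skew in OAR doses, and measured
delivery times (hardware-dependent). Passing tests therefore demonstrate
that the analysis machinery is correct and well-calibrated on data with the
declared statistical structure — not that any clinical conclusion
transfers to real plans.

## Comparison statistics

`compareGroups` gates on normality: Shapiro–Wilk at α = 0.05 on each sample
(on the paired differences when paired), then a t-test if accepted
(paired, or Welch two-sample), otherwise the rank-sum test (signed-rank
when paired; normal approximation, so ties are handled). Two-sided p-values
throughout; a degenerate paired comparison with all differences zero
returns statistic 0 and p = 1 by definition. Bonferroni correction is
`min(1, m·p)` with a default family size of **4** — the four comparisons of
each non-reference group against the reference group per metric, which is
the comparison layout the pipeline produces. The paired mode is the
default (the cohort design is paired); unpaired is available because
published analyses of this kind do not always state which was used. A
2000-replicate null simulation in the test suite verifies the gated
procedure keeps its nominal 5% type-I error (accepted band 3–7%).

Constraint checking (`evaluateConstraints`) treats every bound as an
inclusive upper bound; a constrained metric missing from a plan's table is
reported as "unevaluated" and blocks a pass. The shipped parotid bound
(V30 ≤ 5%) is kept verbatim from its clinical source table although
head-and-neck parotid V30 values typically sit near 50% — it is almost
certainly a misprint for ≤ 50%, and users should supply their own
constraint CSV if the literal value is not intended.

## The pipeline

`runPipeline()` chains the stages (generate/ingest → DVH metrics → scoring
→ constraints → efficiency → statistics → report) from one YAML-style
config, writing every table as CSV plus a JSON summary naming the winning
(lowest overall score) group; ties are reported as ties. All randomness
derives from the single run seed, and two runs with the same seed produce
byte-identical CSVs. Any stage error removes the partially written outputs
and is re-raised with the stage name. Full-precision values are written
alongside 3-decimal display columns so downstream consumers never inherit
reporting precision. The package's interface is its functions — the
pipeline is itself an exported function, so no shell wrapper is shipped.

## Problem sizes and runtime choices

The shipped tests run the DVH oracle suite on one hundred random grids up
to 20³ voxels, phantom sweeps on 40³ grids (2 mm voxels, 16 mm target),
cohort moment checks at n = 1000 patients, the null-calibration study at
2000 replicates, and segment mixtures at 10⁴ segments. These sizes give
oracle agreement to machine precision and statistical checks with
standard errors well inside the asserted bands, while keeping the whole
suite around ten seconds on one core. The phantom's default 48³ grid at
2 mm spacing holds a 20 mm-radius target with room for a 4σ = 40 mm blur
kernel at the largest width.

## Known limitations

- Binary masks: no partial-volume weighting, no contour rasterisation;
  masks are inputs (no DICOM-RT import, though grids and masks from any
  reader can be wrapped directly).
- The DVH engine does not resample between dose grids of different
  geometry; grid and mask must be aligned.
- The quality score inherits the instability of small references: items
  whose cohort-best value is near zero produce large relative deviations
  (and exactly zero is an error by design). Weights can damp this, but the
  score is best used with dose-scale metrics, as here.
- The generator's independence across metric cells understates the
  correlation structure of real plan cohorts; group-comparison p-values on
  synthetic data are calibrated per metric, not jointly.
- Fisher's LSD correction, sometimes named alongside Bonferroni in this
  literature, is not implemented; Bonferroni is the stated method.
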