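#' @import methods
NULL

#' DoseGrid: a 3-D absorbed-dose array with voxel geometry
#'
#' Container for a voxel dose distribution. Doses are absorbed dose in Gy,
#' one value per voxel; the geometry is a regular grid with per-axis spacing
#' in mm and a physical origin in mm.
#'
#' @slot dose 3-D numeric array of absorbed dose (Gy), all values >= 0.
#' @slot spacing numeric(3), voxel spacing in mm per axis, all > 0.
#' @slot origin numeric(3), physical position (mm) of the first voxel centre.
#' @export
setClass("DoseGrid",
  representation(dose = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(2, 2, 2), origin = c(0, 0, 0)))

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (length(dim(object@dose)) != 3L)
    msg <- c(msg, "dose must be a 3-D array")
  if (any(!is.finite(object@dose)) || any(object@dose < 0))
    msg <- c(msg, "all doses must be finite and >= 0")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have 3 components (mm)")
  if (length(msg)) msg else TRUE
})

#' StructureMask: a binary voxel mask aligned to a DoseGrid
#'
#' @slot name structure label (e.g. "PTVnx", "Brainstem").
#' @slot role one of "target" or "oar".
#' @slot voxels logical 3-D array, same shape as the dose grid it refers to;
#'   at least one voxel must be set.
#' @export
setClass("StructureMask",
  representation(name = "character", role = "character", voxels = "array"))

setValidity("StructureMask", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty label")
  if (!object@role %in% c("target", "oar"))
    msg <- c(msg, "role must be 'target' or 'oar'")
  if (length(dim(object@voxels)) != 3L || !is.logical(object@voxels))
    msg <- c(msg, "voxels must be a logical 3-D array")
  else if (!any(object@voxels))
    msg <- c(msg, "mask must contain at least one voxel")
  if (length(msg)) msg else TRUE
})

#' DVHCurve: a cumulative dose-volume histogram
#'
#' Cumulative DVH for one structure: \code{cumVolume[i]} is the percentage of
#' the structure volume receiving at least \code{binEdges[i]} Gy. The curve is
#' non-increasing, starts at 100% and ends at 0%.
#'
#' @slot structure structure label.
#' @slot binEdges ascending dose bin edges (Gy), starting at 0.
#' @slot cumVolume cumulative volume (%) at each edge, in [0, 100],
#'   non-increasing, first value 100 and last value 0.
#' @export
setClass("DVHCurve",
  representation(structure = "character", binEdges = "numeric",
                 cumVolume = "numeric"))

setValidity("DVHCurve", function(object) {
  msg <- character()
  v <- object@cumVolume; e <- object@binEdges
  if (length(e) != length(v) || length(e) < 2L)
    msg <- c(msg, "binEdges and cumVolume must have equal length >= 2")
  if (length(e) >= 2L && any(diff(e) <= 0))
    msg <- c(msg, "binEdges must be strictly ascending")
  if (length(v)) {
    if (any(v < -1e-9) || any(v > 100 + 1e-9))
      msg <- c(msg, "cumVolume must lie in [0, 100]")
    if (any(diff(v) > 1e-9))
      msg <- c(msg, "cumVolume must be non-increasing")
    if (abs(v[1L] - 100) > 1e-9 || abs(v[length(v)]) > 1e-9)
      msg <- c(msg, "cumVolume must start at 100% and end at 0%")
  }
  if (length(msg)) msg else TRUE
})

#' DoseStatistics: DVH point metrics for one structure
#'
#' @slot d2 near-maximum dose D2% (Gy): minimum dose to the hottest 2%.
#' @slot d98 near-minimum dose D98% (Gy).
#' @slot d50 median dose D50% (Gy).
#' @slot dmean arithmetic mean voxel dose (Gy).
#' @slot dmaxReport reported maximum dose (Gy); by convention equal to D2%
#'   (the near-max), the value clinical tables usually print as Dmax.
#' @slot dmaxVoxel true maximum voxel dose (Gy), exposed alongside the
#'   near-max convention.
#' @export
setClass("DoseStatistics",
  representation(d2 = "numeric", d98 = "numeric", d50 = "numeric",
                 dmean = "numeric", dmaxReport = "numeric",
                 dmaxVoxel = "numeric"))

setValidity("DoseStatistics", function(object) {
  msg <- character()
  tol <- 1e-9
  with_slots <- c(object@d2, object@d98, object@d50, object@dmean)
  if (any(!is.finite(with_slots)) || any(with_slots < -tol))
    msg <- c(msg, "dose statistics must be finite and >= 0")
  if (object@d2 < object@d50 - tol || object@d50 < object@d98 - tol)
    msg <- c(msg, "quantile ordering violated: need d2 >= d50 >= d98")
  if (length(msg)) msg else TRUE
})

#' PlanVolumes: coverage volumes for conformity analysis
#'
#' Absolute volumes (cc) entering the target-coverage and conformity-index
#' formulas: \code{tv} is the target volume, \code{tvPi} the target volume
#' inside the prescription isodose, and \code{vPi} the total
#' prescription-isodose volume.
#'
#' @slot tv target volume (cc), > 0.
#' @slot tvPi target volume covered by the prescription isodose (cc).
#' @slot vPi total prescription-isodose volume (cc).
#' @export
setClass("PlanVolumes",
  representation(tv = "numeric", tvPi = "numeric", vPi = "numeric"))

setValidity("PlanVolumes", function(object) {
  msg <- character()
  tol <- 1e-9 * (1 + object@tv)
  if (object@tv <= 0) msg <- c(msg, "tv must be > 0")
  if (object@vPi < 0) msg <- c(msg, "vPi must be >= 0")
  if (object@tvPi < -tol ||
      object@tvPi > min(object@tv, object@vPi) + tol)
    msg <- c(msg, "need 0 <= tvPi <= min(tv, vPi)")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: geometry of a synthetic blurred-step dose phantom
#'
#' Describes a desk-scale voxel phantom: a spherical target receiving the
#' prescription dose on a low-dose background, convolved with an isotropic
#' Gaussian whose width \code{blurSigma} emulates the penumbra broadening
#' caused by coarser fluence-map beamlet widths. A larger sigma spills more
#' dose into adjacent organs at risk and erodes target coverage, which is the
#' qualitative behaviour the downstream analysis is designed to detect.
#'
#' @slot gridShape integer(3), voxel counts per axis.
#' @slot spacing numeric(3), mm per voxel per axis.
#' @slot targetCenter numeric(3), target sphere centre in voxel coordinates.
#' @slot targetRadius target sphere radius in mm, > 0.
#' @slot oarSpecs list of OARs, each \code{list(name=, center=, radius=)}
#'   with centre in voxel coordinates and radius in mm.
#' @slot prescriptionDose prescription dose (Gy), > 0.
#' @slot baseDose background dose (Gy) outside the target before blurring.
#' @slot blurSigma isotropic Gaussian blur width (mm), >= 0.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
                 targetCenter = "numeric", targetRadius = "numeric",
                 oarSpecs = "list", prescriptionDose = "numeric",
                 baseDose = "numeric", blurSigma = "numeric"))

.sphereInsideGrid <- function(center, radius, shape, spacing) {
  # centre is in voxel coordinates (1-based); radius in mm
  lo <- (center - 1) * spacing - radius
  hi <- (center - 1) * spacing + radius
  all(lo >= -0.5 * spacing) && all(hi <= (shape - 0.5) * spacing)
}

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L))
    msg <- c(msg, "gridShape must be 3 integers >= 4")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (object@targetRadius <= 0) msg <- c(msg, "targetRadius must be > 0")
  if (object@blurSigma < 0) msg <- c(msg, "blurSigma must be >= 0")
  if (object@prescriptionDose <= 0)
    msg <- c(msg, "prescriptionDose must be > 0")
  if (object@baseDose < 0) msg <- c(msg, "baseDose must be >= 0")
  if (!length(msg) &&
      !.sphereInsideGrid(object@targetCenter, object@targetRadius,
                         object@gridShape, object@spacing))
    msg <- c(msg, "geometry error: target sphere does not fit inside grid")
  if (!length(msg)) for (o in object@oarSpecs) {
    if (!all(c("name", "center", "radius") %in% names(o)) || o$radius <= 0) {
      msg <- c(msg, "each oarSpec needs name, center and positive radius")
      break
    }
    if (!.sphereInsideGrid(o$center, o$radius, object@gridShape,
                           object@spacing)) {
      msg <- c(msg, sprintf("geometry error: OAR '%s' does not fit inside grid",
                            o$name))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' CohortSpec: generative model for a paired metric-level plan cohort
#'
#' Describes a cohort of patients each planned once per group (a paired
#' design): every (group, structure, metric) cell has a Normal(mean, sd)
#' law in the metric's own units, and each patient carries one shared
#' additive offset (sd \code{patientEffectSd}) applied across all of that
#' patient's plans, which induces the across-group correlation a re-planned
#' cohort exhibits. Values are truncated to physically valid bounds
#' (doses >= 0, percentages in [0, 100], conformity in [0, 1]) by resampling.
#'
#' @slot groupLabels plan-group labels, e.g. BL02..BL10.
#' @slot nPatients number of patients, >= 2.
#' @slot metricParams data.frame with columns group, structure, metric,
#'   category, mean, sd: one row per (group, structure, metric) cell.
#' @slot patientEffectSd sd of the shared per-patient additive offset, >= 0.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSpec",
  representation(groupLabels = "character", nPatients = "integer",
                 metricParams = "data.frame", patientEffectSd = "numeric",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  mp <- object@metricParams
  need <- c("group", "structure", "metric", "category", "mean", "sd")
  if (!all(need %in% names(mp)))
    msg <- c(msg, paste("metricParams must have columns:",
                        paste(need, collapse = ", ")))
  if (length(object@groupLabels) < 2L)
    msg <- c(msg, "need at least 2 group labels")
  if (object@nPatients < 2L) msg <- c(msg, "nPatients must be >= 2")
  if (object@patientEffectSd < 0)
    msg <- c(msg, "patientEffectSd must be >= 0")
  if (!length(msg)) {
    if (any(!is.finite(mp$sd)) || any(mp$sd < 0))
      msg <- c(msg, "all sd values must be finite and >= 0")
    cells <- unique(mp[, c("structure", "metric")])
    for (g in object@groupLabels) {
      got <- mp[mp$group == g, c("structure", "metric")]
      miss <- !paste(cells$structure, cells$metric) %in%
        paste(got$structure, got$metric)
      if (any(miss) || nrow(got) < nrow(cells)) {
        msg <- c(msg, sprintf(
          "configuration error: group '%s' is missing metricParams cells", g))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' SegmentSpec: mixture model for per-segment monitor units
#'
#' Segments of one IMRT plan are drawn from a two-component uniform mixture:
#' with probability \code{smallWeight} a segment comes from the low-MU
#' component (below the small-segment threshold), otherwise from the high-MU
#' component; all MUs are then rescaled so they sum to \code{totalMu}.
#'
#' @slot nSegments number of segments, >= 1.
#' @slot totalMu total plan monitor units, > 0.
#' @slot smallWeight probability of the low-MU component, in [0, 1].
#' @slot lowMuRange MU interval (min, max) of the low component; must lie
#'   entirely below the small-segment threshold (5 MU by convention).
#' @slot highMuRange MU interval (min, max) of the high component.
#' @slot seed integer RNG seed.
#' @export
setClass("SegmentSpec",
  representation(nSegments = "integer", totalMu = "numeric",
                 smallWeight = "numeric", lowMuRange = "numeric",
                 highMuRange = "numeric", seed = "integer"))

setValidity("SegmentSpec", function(object) {
  msg <- character()
  if (object@nSegments < 1L)
    msg <- c(msg, "validation error: nSegments must be >= 1")
  if (object@totalMu <= 0) msg <- c(msg, "totalMu must be > 0")
  if (object@smallWeight < 0 || object@smallWeight > 1)
    msg <- c(msg, "smallWeight must lie in [0, 1]")
  for (r in list(low = object@lowMuRange, high = object@highMuRange))
    if (length(r) != 2L || any(r <= 0) || r[2L] < r[1L])
      msg <- c(msg, "MU ranges must be positive (min, max) intervals")
  if (!length(msg) && object@lowMuRange[2L] >= 5)
    msg <- c(msg, "lowMuRange must lie entirely below the 5 MU threshold")
  if (length(msg)) msg else TRUE
})

#' ScoreBreakdown: quality-score decomposition for one plan group
#'
#' Holds the per-item relative-deviation scores of one group together with
#' the target (PTV) and organ-at-risk subtotals and the overall score, which
#' is their exact sum. Lower is better; a group scoring 0 holds the
#' cohort-best value on every scored item.
#'
#' @slot group plan-group label.
#' @slot items data.frame with one row per scored item: structure, metric,
#'   category, direction, weight, measured, reference, score,
#'   referenceGroups (comma-separated labels of the group(s) holding the
#'   cohort-best value).
#' @slot ptvSubtotal sum of item scores over target items.
#' @slot oarSubtotal sum of item scores over organ-at-risk items.
#' @slot overall total score: ptvSubtotal + oarSubtotal exactly.
#' @export
setClass("ScoreBreakdown",
  representation(group = "character", items = "data.frame",
                 ptvSubtotal = "numeric", oarSubtotal = "numeric",
                 overall = "numeric"))

setValidity("ScoreBreakdown", function(object) {
  msg <- character()
  if (any(object@items$score < 0)) msg <- c(msg, "item scores must be >= 0")
  if (abs(object@overall - (object@ptvSubtotal + object@oarSubtotal)) > 1e-12)
    msg <- c(msg, "overall must equal ptvSubtotal + oarSubtotal")
  if (abs(object@overall - sum(object@items$score)) > 1e-9)
    msg <- c(msg, "overall must equal the sum of all item scores")
  if (length(msg)) msg else TRUE
})

#' ComparisonResult: one two-sample dosimetric comparison
#'
#' @slot metric metric label the comparison refers to.
#' @slot groupA,groupB group labels compared.
#' @slot testUsed "t" or "rank_sum", chosen by the normality gate.
#' @slot statistic test statistic.
#' @slot pRaw two-sided raw p-value.
#' @slot pAdjusted multiplicity-adjusted p-value (NA until adjusted).
#' @slot significant TRUE if pAdjusted < 0.05.
#' @export
setClass("ComparisonResult",
  representation(metric = "character", groupA = "character",
                 groupB = "character", testUsed = "character",
                 statistic = "numeric", pRaw = "numeric",
                 pAdjusted = "numeric", significant = "logical"))

setValidity("ComparisonResult", function(object) {
  msg <- character()
  if (!object@testUsed %in% c("t", "rank_sum"))
    msg <- c(msg, "testUsed must be 't' or 'rank_sum'")
  if (object@pRaw < 0 || object@pRaw > 1)
    msg <- c(msg, "pRaw must lie in [0, 1]")
  if (!is.na(object@pAdjusted) &&
      (object@pAdjusted > 1 || object@pAdjusted < object@pRaw - 1e-12))
    msg <- c(msg, "need pRaw <= pAdjusted <= 1")
  if (length(msg)) msg else TRUE
})
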