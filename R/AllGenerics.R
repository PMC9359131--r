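#' @include AllClasses.R
NULL

# ---- constructors -----------------------------------------------------------

#' Construct a DoseGrid
#'
#' @param dose 3-D numeric array of absorbed dose (Gy).
#' @param spacing voxel spacing in mm per axis (length 3, recycled from 1).
#' @param origin physical origin in mm (length 3).
#' @return A validated \linkS4class{DoseGrid}.
#' @examples
#' g <- DoseGrid(array(2, c(4, 4, 4)), spacing = c(2, 2, 2))
#' @export
DoseGrid <- function(dose, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("DoseGrid", dose = dose, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a StructureMask
#'
#' @param name structure label.
#' @param voxels logical 3-D array aligned to the dose grid.
#' @param role "target" or "oar".
#' @return A validated \linkS4class{StructureMask}.
#' @export
StructureMask <- function(name, voxels, role = c("oar", "target")) {
  role <- match.arg(role)
  new("StructureMask", name = name, role = role, voxels = voxels)
}

#' Construct a DVHCurve
#'
#' @param structure structure label.
#' @param binEdges ascending dose edges (Gy).
#' @param cumVolume cumulative volume (%) at each edge.
#' @return A validated \linkS4class{DVHCurve}.
#' @export
DVHCurve <- function(structure, binEdges, cumVolume) {
  new("DVHCurve", structure = structure, binEdges = as.numeric(binEdges),
      cumVolume = as.numeric(cumVolume))
}

#' Construct a PhantomSpec
#'
#' @param gridShape voxel counts per axis (length 3).
#' @param spacing mm per voxel per axis (length 3, recycled from 1).
#' @param targetCenter target sphere centre, voxel coordinates (length 3).
#' @param targetRadius target sphere radius, mm.
#' @param oarSpecs list of \code{list(name=, center=, radius=)} OAR spheres.
#' @param prescriptionDose prescription dose, Gy.
#' @param baseDose background dose outside the target before blurring, Gy.
#' @param blurSigma isotropic Gaussian penumbra width, mm.
#' @return A validated \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(gridShape = c(48L, 48L, 48L), spacing = c(2, 2, 2),
                        targetCenter = (gridShape + 1) / 2,
                        targetRadius = 20, oarSpecs = list(),
                        prescriptionDose = 70, baseDose = 10,
                        blurSigma = 4) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), targetCenter = as.numeric(targetCenter),
      targetRadius = as.numeric(targetRadius), oarSpecs = oarSpecs,
      prescriptionDose = as.numeric(prescriptionDose),
      baseDose = as.numeric(baseDose), blurSigma = as.numeric(blurSigma))
}

#' Construct a CohortSpec
#'
#' @param metricParams data.frame (group, structure, metric, category,
#'   mean, sd); \code{\link{defaultCohortParams}} ships the packaged
#'   defaults.
#' @param groupLabels plan-group labels; default the groups present in
#'   \code{metricParams}.
#' @param nPatients number of patients (each planned once per group).
#' @param patientEffectSd sd (metric units) of the shared per-patient offset.
#' @param seed RNG seed.
#' @return A validated \linkS4class{CohortSpec}.
#' @export
CohortSpec <- function(metricParams = defaultCohortParams(),
                       groupLabels = unique(metricParams$group),
                       nPatients = 20L, patientEffectSd = 0, seed = 1L) {
  new("CohortSpec", groupLabels = as.character(groupLabels),
      nPatients = as.integer(nPatients),
      metricParams = as.data.frame(metricParams),
      patientEffectSd = as.numeric(patientEffectSd), seed = as.integer(seed))
}

#' Construct a SegmentSpec
#'
#' @param nSegments number of segments in the plan.
#' @param totalMu total plan monitor units.
#' @param smallWeight probability a segment is drawn from the low-MU
#'   component.
#' @param lowMuRange,highMuRange MU intervals (min, max) of the two mixture
#'   components; the low range must sit entirely below 5 MU.
#' @param seed RNG seed.
#' @return A validated \linkS4class{SegmentSpec}.
#' @export
SegmentSpec <- function(nSegments = 60L, totalMu = 800, smallWeight = 0.25,
                        lowMuRange = c(1, 4.5), highMuRange = c(8, 25),
                        seed = 1L) {
  new("SegmentSpec", nSegments = as.integer(nSegments),
      totalMu = as.numeric(totalMu), smallWeight = as.numeric(smallWeight),
      lowMuRange = as.numeric(lowMuRange),
      highMuRange = as.numeric(highMuRange), seed = as.integer(seed))
}

# ---- generics ---------------------------------------------------------------

#' @rdname DoseGrid-class
#' @param x object.
#' @export
setGeneric("doseArray", function(x) standardGeneric("doseArray"))
#' @rdname DoseGrid-class
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname StructureMask-class
#' @param x object.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname StructureMask-class
#' @export
setGeneric("structureName", function(x) standardGeneric("structureName"))
#' @rdname StructureMask-class
#' @export
setGeneric("structureRole", function(x) standardGeneric("structureRole"))
#' @rdname DVHCurve-class
#' @param x object.
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))
#' @rdname DVHCurve-class
#' @export
setGeneric("cumVolume", function(x) standardGeneric("cumVolume"))

#' Homogeneity index (ICRU-83 difference form)
#'
#' \eqn{HI = (D_{2\%} - D_{98\%}) / D_{50\%}}: 0 for a perfectly uniform
#' target dose, growing as the dose spread widens. Note that the ratio form
#' \eqn{(D_{2\%}/D_{98\%})/D_{50\%}} sometimes seen in print is
#' dimensionally inconsistent (it carries units of 1/Gy) and does not
#' reproduce the 0.07-0.29 magnitudes clinical tables report; this package
#' implements the standard difference form.
#'
#' @param x a \linkS4class{DoseStatistics}, or D2% (Gy) when using the
#'   numeric interface.
#' @param ... numeric interface: \code{d98}, \code{d50} (Gy).
#' @return dimensionless HI >= 0.
#' @export
setGeneric("homogeneityIndex", function(x, ...)
  standardGeneric("homogeneityIndex"))

#' Conformity index
#'
#' \eqn{CI = TV_{PI}^2 / (TV \times V_{PI})}: 1 for perfect conformity of
#' the prescription isodose to the target, smaller when the isodose either
#' misses target volume or spills outside it.
#'
#' @param x a \linkS4class{PlanVolumes}, or the target volume \code{tv} (cc)
#'   when using the numeric interface.
#' @param ... numeric interface: \code{tvPi}, \code{vPi} (cc).
#' @return CI in [0, 1]; 0 (with a warning) when no prescription isodose
#'   volume exists.
#' @export
setGeneric("conformityIndex", function(x, ...)
  standardGeneric("conformityIndex"))

#' Target coverage
#'
#' \eqn{TC(\%) = 100 \times TV_{PI} / TV}: the percentage of the target
#' enclosed by the prescription isodose.
#'
#' @param x a \linkS4class{PlanVolumes}.
#' @return coverage in [0, 100] (%).
#' @export
setGeneric("targetCoverage", function(x) standardGeneric("targetCoverage"))

#' @rdname ScoreBreakdown-class
#' @param x object.
#' @export
setGeneric("overallScore", function(x) standardGeneric("overallScore"))
#' @rdname ScoreBreakdown-class
#' @export
setGeneric("scoreItems", function(x) standardGeneric("scoreItems"))

# ---- accessors and show methods --------------------------------------------

#' @rdname DoseGrid-class
setMethod("doseArray", "DoseGrid", function(x) x@dose)
#' @rdname DoseGrid-class
setMethod("gridSpacing", "DoseGrid", function(x) x@spacing)
#' @rdname StructureMask-class
setMethod("maskArray", "StructureMask", function(x) x@voxels)
#' @rdname StructureMask-class
setMethod("structureName", "StructureMask", function(x) x@name)
#' @rdname StructureMask-class
setMethod("structureRole", "StructureMask", function(x) x@role)
#' @rdname DVHCurve-class
setMethod("binEdges", "DVHCurve", function(x) x@binEdges)
#' @rdname DVHCurve-class
setMethod("cumVolume", "DVHCurve", function(x) x@cumVolume)
#' @rdname ScoreBreakdown-class
setMethod("overallScore", "ScoreBreakdown", function(x) x@overall)
#' @rdname ScoreBreakdown-class
setMethod("scoreItems", "ScoreBreakdown", function(x) x@items)

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@dose)
  cat(sprintf("DoseGrid: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  dose range: %.3f - %.3f Gy\n",
              min(object@dose), max(object@dose)))
})

setMethod("show", "StructureMask", function(object) {
  cat(sprintf("StructureMask '%s' (%s): %d voxels set\n",
              object@name, object@role, sum(object@voxels)))
})

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("DVHCurve '%s': %d edges spanning 0 - %.2f Gy\n",
              object@structure, length(object@binEdges),
              max(object@binEdges)))
})

setMethod("show", "ScoreBreakdown", function(object) {
  cat(sprintf("ScoreBreakdown '%s': overall %.3f (PTV %.3f + OAR %.3f), %d items\n",
              object@group, object@overall, object@ptvSubtotal,
              object@oarSubtotal, nrow(object@items)))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult %s: %s vs %s, %s test, p = %.4g (adj %.4g)\n",
              object@metric, object@groupA, object@groupB, object@testUsed,
              object@pRaw, object@pAdjusted))
})

#' Structure volume in cc
#'
#' Volume of a binary mask: number of set voxels times the voxel volume
#' (product of spacings); partial-volume effects are ignored.
#'
#' @param mask a \linkS4class{StructureMask}.
#' @param grid the aligned \linkS4class{DoseGrid} supplying the geometry.
#' @return volume in cc.
#' @export
structureVolume <- function(mask, grid) {
  .checkAligned(grid, mask)
  sum(mask@voxels) * prod(grid@spacing) / 1000
}

.checkAligned <- function(grid, mask) {
  if (!identical(dim(grid@dose), dim(mask@voxels)))
    stop("alignment error: mask '", mask@name,
         "' does not match the dose grid shape")
  invisible(TRUE)
}
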