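#' @include AllGenerics.R
NULL

# Floating-point guard for ">= threshold" tests on doses: analytically exact
# ties (uniform region equal to the prescription, bin edges that are decimal
# multiples) must count as covered despite representation error.
.doseTol <- function(x) 1e-9 * (1 + abs(x))

#' Compute a cumulative dose-volume histogram
#'
#' \code{cumVolume[i]} is the percentage of masked voxels whose dose is at
#' least \code{binEdges[i]}. Edges are multiples of \code{binWidth} spanning
#' \code{[0, max dose + binWidth]}, so the curve always starts at 100% and
#' ends at 0%.
#'
#' @param grid a \linkS4class{DoseGrid}.
#' @param mask a \linkS4class{StructureMask} aligned to the grid.
#' @param binWidth dose bin width, Gy (default 0.05).
#' @return a \linkS4class{DVHCurve}.
#' @examples
#' g <- DoseGrid(array(2, c(4, 4, 4)))
#' m <- StructureMask("roi", array(TRUE, c(4, 4, 4)))
#' dvh <- computeDVH(g, m, binWidth = 0.1)
#' @export
computeDVH <- function(grid, mask, binWidth = 0.05) {
  validObject(grid); validObject(mask)
  .checkAligned(grid, mask)
  if (binWidth <= 0) stop("validation error: binWidth must be > 0")
  d <- grid@dose[mask@voxels]
  if (!length(d)) stop("validation error: empty mask")
  nEdge <- ceiling((max(d) + binWidth) / binWidth)
  edges <- (0:nEdge) * binWidth
  sd_ <- sort(d)
  n <- length(sd_)
  # voxels with dose >= edge (with fp guard) = n - #(dose < edge - tol)
  below <- findInterval(edges - .doseTol(edges), sd_, left.open = TRUE)
  cum <- 100 * (n - below) / n
  DVHCurve(mask@name, edges, cum)
}

.checkCurve <- function(dvh) {
  validObject(dvh)
  invisible(TRUE)
}

#' Dose at volume (Dx%)
#'
#' The largest dose received by at least \code{x}% of the structure volume:
#' D2% is the near-maximum, D98% the near-minimum, D50% the median dose.
#' The returned dose is the largest bin edge at which the cumulative volume
#' still meets \code{x}. For counting-based curves (right-continuous steps,
#' as \code{\link{computeDVH}} produces) this is the exact voxel quantile
#' whenever it falls on an edge and is within one bin width otherwise; for
#' smooth imported curves it is conservative by at most one bin width.
#'
#' @param dvh a \linkS4class{DVHCurve}.
#' @param x volume percentage in (0, 100].
#' @return dose in Gy.
#' @export
doseAtVolume <- function(dvh, x) {
  .checkCurve(dvh)
  if (any(x <= 0 | x > 100))
    stop("validation error: x must lie in (0, 100]")
  v <- dvh@cumVolume; e <- dvh@binEdges
  vapply(x, function(xx) e[max(which(v >= xx - 1e-12))], numeric(1))
}

#' Volume at dose (VxGy)
#'
#' The percentage of the structure volume receiving at least \code{d} Gy,
#' linearly interpolated on the cumulative DVH (e.g. the parotid V30 is
#' \code{volumeAtDose(dvh, 30)}).
#'
#' @param dvh a \linkS4class{DVHCurve}.
#' @param d dose in Gy, >= 0.
#' @return volume percentage in [0, 100].
#' @export
volumeAtDose <- function(dvh, d) {
  .checkCurve(dvh)
  if (any(d < 0)) stop("validation error: dose must be >= 0")
  stats::approx(dvh@binEdges, dvh@cumVolume, xout = d, rule = 2)$y
}

#' DVH point statistics for one structure
#'
#' Computes D2%, D98%, D50% (via \code{\link{doseAtVolume}} on the structure
#' DVH), the arithmetic mean voxel dose, and the reported maximum. Following
#' common clinical reporting, the reported Dmax is the near-maximum D2%
#' rather than the single hottest voxel; the true voxel maximum is exposed
#' in \code{dmaxVoxel}.
#'
#' @param grid a \linkS4class{DoseGrid}.
#' @param mask a \linkS4class{StructureMask}.
#' @param binWidth DVH bin width, Gy.
#' @return a \linkS4class{DoseStatistics}.
#' @export
doseStatistics <- function(grid, mask, binWidth = 0.05) {
  dvh <- computeDVH(grid, mask, binWidth)
  d <- grid@dose[mask@voxels]
  q <- doseAtVolume(dvh, c(2, 50, 98))
  new("DoseStatistics", d2 = q[1], d50 = q[2], d98 = q[3],
      dmean = mean(d), dmaxReport = q[1], dmaxVoxel = max(d))
}

#' Coverage volumes at the prescription isodose
#'
#' Computes the three volumes entering the target-coverage and conformity
#' formulas: the target volume TV, the target volume inside the prescription
#' isodose TV_PI (target voxels with dose >= prescription), and the total
#' prescription-isodose volume V_PI (all grid voxels with dose >=
#' prescription). Volumes are voxel counts times the voxel volume.
#'
#' @param grid a \linkS4class{DoseGrid}.
#' @param target the target \linkS4class{StructureMask}.
#' @param prescription prescription dose, Gy (> 0).
#' @return a \linkS4class{PlanVolumes} (cc).
#' @export
coverageVolumes <- function(grid, target, prescription) {
  validObject(grid); validObject(target)
  .checkAligned(grid, target)
  if (prescription <= 0)
    stop("validation error: prescription must be > 0")
  voxcc <- prod(grid@spacing) / 1000
  covered <- grid@dose >= prescription - .doseTol(prescription)
  new("PlanVolumes",
      tv = sum(target@voxels) * voxcc,
      tvPi = sum(target@voxels & covered) * voxcc,
      vPi = sum(covered) * voxcc)
}
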