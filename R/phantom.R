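#' @include AllGenerics.R blur.R
NULL

.sphereMask <- function(shape, spacing, center, radius) {
  # voxel centre coordinates in mm along each axis
  ax <- lapply(1:3, function(i) ((seq_len(shape[i]) - center[i]) * spacing[i])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  array(d2 <= radius^2, dim = shape)
}

#' Build a synthetic blurred-step dose phantom
#'
#' Constructs a deterministic voxel phantom from a \linkS4class{PhantomSpec}:
#' the dose is the prescription inside the spherical target and the base dose
#' outside, convolved with an isotropic Gaussian of width \code{blurSigma}
#' (mm). The blur is the phantom's single tunable: it stands in for the
#' penumbra broadening that coarser fluence-map beamlet widths produce, so
#' sweeping it reproduces the qualitative trade-off the analysis measures --
#' target coverage decreases and dose to adjacent organs at risk increases
#' as the blur widens.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return \code{list(grid = DoseGrid, masks = list of StructureMask)} with
#'   the target mask first, followed by one mask per configured OAR.
#' @examples
#' ph <- buildPhantom(PhantomSpec(blurSigma = 0))
#' range(doseArray(ph$grid)[maskArray(ph$masks$target)])  # all prescription
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  shape <- spec@gridShape
  target <- .sphereMask(shape, spec@spacing, spec@targetCenter,
                        spec@targetRadius)
  dose <- array(spec@baseDose, dim = shape)
  dose[target] <- spec@prescriptionDose
  if (spec@blurSigma > 0)
    dose <- .gaussianBlur3D(dose, spec@blurSigma / spec@spacing)
  masks <- list(target = StructureMask("target", target, role = "target"))
  for (o in spec@oarSpecs)
    masks[[o$name]] <- StructureMask(
      o$name, .sphereMask(shape, spec@spacing, o$center, o$radius),
      role = "oar")
  list(grid = DoseGrid(dose, spacing = spec@spacing), masks = masks)
}
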