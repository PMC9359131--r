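#' @include dvh.R
NULL

#' @rdname targetCoverage
#' @aliases targetCoverage,PlanVolumes-method
setMethod("targetCoverage", "PlanVolumes", function(x) {
  validObject(x)
  if (x@tv <= 0) stop("validation error: tv must be > 0")
  100 * x@tvPi / x@tv
})

#' @rdname homogeneityIndex
#' @aliases homogeneityIndex,DoseStatistics-method
setMethod("homogeneityIndex", "DoseStatistics", function(x, ...) {
  homogeneityIndex(x@d2, d98 = x@d98, d50 = x@d50)
})

#' @rdname homogeneityIndex
#' @param d98,d50 near-minimum and median dose (Gy), numeric interface.
#' @aliases homogeneityIndex,numeric-method
setMethod("homogeneityIndex", "numeric", function(x, d98, d50, ...) {
  if (d50 <= 0) stop("validation error: d50 must be > 0")
  (x - d98) / d50
})

#' @rdname conformityIndex
#' @aliases conformityIndex,PlanVolumes-method
setMethod("conformityIndex", "PlanVolumes", function(x, ...) {
  validObject(x)
  conformityIndex(x@tv, tvPi = x@tvPi, vPi = x@vPi)
})

#' @rdname conformityIndex
#' @param tvPi target volume inside the prescription isodose (cc).
#' @param vPi total prescription-isodose volume (cc).
#' @aliases conformityIndex,numeric-method
setMethod("conformityIndex", "numeric", function(x, tvPi, vPi, ...) {
  if (x <= 0) stop("validation error: tv must be > 0")
  if (vPi <= 0) {
    warning("no prescription isodose volume exists; CI defined as 0")
    return(0)
  }
  tvPi^2 / (x * vPi)
})
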