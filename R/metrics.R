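#' @include indices.R
NULL

#' Extract a metric table from a dose grid
#'
#' Bridges the voxel stage to the scoring stage: evaluates a configured set
#' of (structure, metric) pairs on one plan's dose grid and returns them as
#' long-format rows. Supported metric names: \code{TC}, \code{HI},
#' \code{CI}, \code{D2}, \code{D50}, \code{D98}, \code{Dmean}, \code{Dmax}
#' (reported as the near-max D2%), and \code{V<x>} for any threshold x in Gy
#' (e.g. \code{V30}).
#'
#' @param grid a \linkS4class{DoseGrid}.
#' @param structures named list of \linkS4class{StructureMask} objects.
#' @param prescriptions named numeric of prescription doses (Gy), one per
#'   target structure for which TC/CI are requested.
#' @param metricConfig data.frame with columns \code{structure, metric}.
#' @param binWidth DVH bin width, Gy.
#' @return data.frame with columns \code{structure, metric, value}.
#' @export
extractPlanMetrics <- function(grid, structures, prescriptions = numeric(),
                               metricConfig, binWidth = 0.05) {
  stopifnot(is.list(structures), is.data.frame(metricConfig))
  if (!all(c("structure", "metric") %in% names(metricConfig)))
    stop("configuration error: metricConfig needs columns structure, metric")
  dvhCache <- list(); statCache <- list()
  getDVH <- function(s) {
    if (is.null(dvhCache[[s]]))
      dvhCache[[s]] <<- computeDVH(grid, structures[[s]], binWidth)
    dvhCache[[s]]
  }
  getStats <- function(s) {
    if (is.null(statCache[[s]]))
      statCache[[s]] <<- doseStatistics(grid, structures[[s]], binWidth)
    statCache[[s]]
  }
  getRx <- function(s) {
    if (is.na(match(s, names(prescriptions))))
      stop("configuration error: no prescription dose for structure '", s, "'")
    prescriptions[[s]]
  }
  value <- numeric(nrow(metricConfig))
  for (i in seq_len(nrow(metricConfig))) {
    s <- metricConfig$structure[i]; m <- metricConfig$metric[i]
    if (is.null(structures[[s]]))
      stop("configuration error: unknown structure '", s, "'")
    value[i] <-
      if (m == "TC") targetCoverage(coverageVolumes(grid, structures[[s]],
                                                    getRx(s)))
      else if (m == "CI") conformityIndex(coverageVolumes(grid,
                                                          structures[[s]],
                                                          getRx(s)))
      else if (m == "HI") homogeneityIndex(getStats(s))
      else if (m == "D2") getStats(s)@d2
      else if (m == "D50") getStats(s)@d50
      else if (m == "D98") getStats(s)@d98
      else if (m == "Dmean") getStats(s)@dmean
      else if (m == "Dmax") getStats(s)@dmaxReport
      else if (grepl("^V[0-9]+(\\.[0-9]+)?$", m))
        volumeAtDose(getDVH(s), as.numeric(sub("^V", "", m)))
      else stop("configuration error: unknown metric '", m, "'")
  }
  data.frame(structure = metricConfig$structure,
             metric = metricConfig$metric, value = value,
             stringsAsFactors = FALSE)
}
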