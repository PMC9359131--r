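#' @include io.R
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "planscore")
  if (!nzchar(path)) stop("packaged default table not found: ", file)
  path
}

#' Packaged default cohort parameters
#'
#' Per-cell (group, structure, metric) means and standard deviations for a
#' five-group (beamlet widths 2-10 mm), 20-patient nasopharyngeal-carcinoma
#' planning cohort: PTV conformity/homogeneity/coverage/near-max indices,
#' organ-at-risk dose metrics, and per-plan monitor-unit and small-segment
#' summaries. These are the defaults the synthetic cohort generator draws
#' from; categories are \code{ptv}, \code{oar} and \code{efficiency}.
#'
#' @return data.frame with columns \code{group, structure, metric,
#'   category, mean, sd}.
#' @export
defaultCohortParams <- function() {
  utils::read.csv(.extdata("cohort_params.csv"), stringsAsFactors = FALSE)
}

#' Packaged default metric specs for scoring
#'
#' The default scored item set: per PTV the coverage (TC, higher better),
#' conformity (CI, higher better), homogeneity (HI, lower better) and
#' near-max dose (D2, lower better); per OAR the reported dose metric
#' (Dmax/V30/Dmean, all lower better). All weights are 1.
#'
#' @return validated metric-spec data.frame.
#' @export
defaultMetricSpecs <- function() {
  .validateMetricSpecs(
    utils::read.csv(.extdata("metric_specs.csv"), stringsAsFactors = FALSE))
}

#' Packaged default OAR dose constraints
#'
#' Upper bounds per organ at risk (near-max dose for most organs, mean dose
#' for the eyes, V30 for the parotids). Note: the shipped parotid bound
#' (V30 <= 5%) is kept verbatim from its clinical source table even though
#' head-and-neck parotid V30 values typically sit near 50%; it is almost
#' certainly a misprint for <= 50% and plans will generally fail it --
#' replace it via your own constraint CSV if that is not what you want.
#'
#' @return constraint data.frame (\code{structure, metric, bound, units}).
#' @export
defaultConstraints <- function() {
  readConstraintsCSV(.extdata("oar_constraints.csv"))
}

#' Packaged default per-group segment specs
#'
#' Builds one \linkS4class{SegmentSpec} per plan group from the packaged
#' total-MU and small-segment-weight defaults. The segment count is set to
#' \code{round(totalMu / mean mixture MU)} so the rescaling step that forces
#' the MU sum to \code{totalMu} has a factor near 1 and the realised
#' small-segment fraction tracks the configured mixture weight.
#'
#' @param seed base RNG seed; each group gets a distinct derived seed.
#' @param lowMuRange,highMuRange mixture component MU intervals.
#' @return named list of \linkS4class{SegmentSpec}, one per group.
#' @export
defaultSegmentSpecs <- function(seed = 1L, lowMuRange = c(1, 4.5),
                                highMuRange = c(8, 25)) {
  par <- utils::read.csv(.extdata("segment_params.csv"),
                         stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(par))) {
    w <- par$small_weight[i]
    meanMu <- w * mean(lowMuRange) + (1 - w) * mean(highMuRange)
    out[[par$group[i]]] <- SegmentSpec(
      nSegments = max(1L, as.integer(round(par$total_mu[i] / meanMu))),
      totalMu = par$total_mu[i], smallWeight = w,
      lowMuRange = lowMuRange, highMuRange = highMuRange,
      seed = as.integer(seed + 101L * i))
  }
  out
}

#' Group-mean metric table from the packaged defaults
#'
#' Convenience: the packaged cohort means as a group-level metric table
#' (one row per group, structure, metric with \code{value = mean}),
#' optionally restricted to one category. This is the table the worked
#' scoring examples operate on.
#'
#' @param category optional filter: "ptv", "oar" or "efficiency".
#' @return data.frame with columns \code{group, structure, metric, value}.
#' @export
defaultGroupMeans <- function(category = NULL) {
  mp <- defaultCohortParams()
  if (!is.null(category)) mp <- mp[mp$category %in% category, ]
  data.frame(group = mp$group, structure = mp$structure, metric = mp$metric,
             value = mp$mean, stringsAsFactors = FALSE)
}
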