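#' @include AllGenerics.R
NULL

# Run code under a local RNG seed without disturbing the caller's RNG state.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Physically valid bounds per metric: doses are >= 0; coverage and
# volume-percentage metrics live in [0, 100]; conformity in [0, 1].
.metricBounds <- function(metric) {
  if (metric %in% c("CI")) return(c(0, 1))
  if (metric == "TC" || grepl("^V[0-9]+(\\.[0-9]+)?$", metric) ||
      grepl("(Pct|pct|%)$", metric)) return(c(0, 100))
  c(0, Inf)
}

#' Sample a paired metric-level plan cohort
#'
#' Draws a long-format table of per-plan metric values under the cohort's
#' generative model: for each (group, structure, metric) cell the value is
#' \code{Normal(mean, sd)} plus a shared per-patient offset
#' (\code{Normal(0, patientEffectSd)}) that is identical across all of a
#' patient's plans, emulating a paired design in which the same patients are
#' re-planned once per group. Draws falling outside the metric's physically
#' valid bounds (doses >= 0, percentages in [0, 100], CI in [0, 1]) are
#' resampled rather than clipped, so cell means are approximately preserved.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return data.frame with columns \code{plan_id, group, structure, metric,
#'   value}; \code{plan_id} is \code{"P<patient>_<group>"} so the paired
#'   structure is recoverable.
#' @examples
#' tab <- sampleMetricCohort(CohortSpec(nPatients = 5, seed = 7L))
#' head(tab)
#' @export
sampleMetricCohort <- function(spec) {
  validObject(spec)
  mp <- spec@metricParams
  mp <- mp[order(mp$group, mp$structure, mp$metric), , drop = FALSE]
  n <- spec@nPatients
  .withSeed(spec@seed, {
    offsets <- stats::rnorm(n, 0, spec@patientEffectSd)
    out <- vector("list", nrow(mp))
    for (i in seq_len(nrow(mp))) {
      row <- mp[i, ]
      b <- .metricBounds(row$metric)
      v <- row$mean + offsets + stats::rnorm(n, 0, row$sd)
      bad <- which(v < b[1] | v > b[2])
      tries <- 0L
      while (length(bad) && tries < 100L) {
        v[bad] <- row$mean + offsets[bad] + stats::rnorm(length(bad), 0, row$sd)
        bad <- which(v < b[1] | v > b[2])
        tries <- tries + 1L
      }
      if (length(bad)) v[bad] <- pmin(pmax(v[bad], b[1]), b[2])
      out[[i]] <- data.frame(
        plan_id = sprintf("P%02d_%s", seq_len(n), row$group),
        group = row$group, structure = row$structure, metric = row$metric,
        value = v, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
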