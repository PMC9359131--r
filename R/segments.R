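#' @include cohort.R
NULL

#' Sample per-segment monitor units for one plan
#'
#' Draws \code{nSegments} segment MU values from the two-component uniform
#' mixture of the spec (low-MU component with probability
#' \code{smallWeight}), then rescales all MUs so their sum equals
#' \code{totalMu} exactly. Segments are assigned round-robin to
#' \code{nBeams} beams, mirroring a multi-beam IMRT plan.
#'
#' @param spec a \linkS4class{SegmentSpec}.
#' @param planId plan label for the output records.
#' @param nBeams number of beams segments are distributed over.
#' @return data.frame with columns \code{plan_id, beam, segment, mu}; one
#'   row per segment, \code{sum(mu) == totalMu} to within 1e-9 relative.
#' @examples
#' seg <- sampleSegments(SegmentSpec(nSegments = 50L, totalMu = 800, seed = 3L))
#' sum(seg$mu)
#' @export
sampleSegments <- function(spec, planId = "plan1", nBeams = 9L) {
  validObject(spec)
  n <- spec@nSegments
  .withSeed(spec@seed, {
    small <- stats::runif(n) < spec@smallWeight
    mu <- ifelse(small,
                 stats::runif(n, spec@lowMuRange[1], spec@lowMuRange[2]),
                 stats::runif(n, spec@highMuRange[1], spec@highMuRange[2]))
    mu <- mu * spec@totalMu / sum(mu)
    data.frame(
      plan_id = planId,
      beam = sprintf("B%d", ((seq_len(n) - 1L) %% nBeams) + 1L),
      segment = seq_len(n), mu = mu, stringsAsFactors = FALSE)
  })
}
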