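#' @include AllGenerics.R
NULL

.segmentMu <- function(segments) {
  mu <- if (is.data.frame(segments)) segments$mu else segments
  if (is.null(mu) || !length(mu))
    stop("validation error: no segments given")
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("validation error: segment MUs must be finite and >= 0")
  mu
}

#' Total plan monitor units
#'
#' @param segments a segment data.frame (with an \code{mu} column) or a
#'   numeric vector of per-segment MUs.
#' @return the exact MU sum.
#' @examples
#' totalMU(c(100.5, 2.3))
#' @export
totalMU <- function(segments) sum(.segmentMu(segments))

#' Small-segment fraction
#'
#' The percentage of a plan's segments whose monitor units fall strictly
#' below the threshold (5 MU by convention); small segments are a delivery
#' efficiency and accuracy concern. The boundary is exclusive: a segment of
#' exactly 5 MU is not small. Invariant under segment reordering.
#'
#' @param segments segment data.frame or numeric MU vector.
#' @param threshold small-segment MU threshold (> 0), default 5.
#' @param strict use strict "<" (default); set FALSE for "<=".
#' @return percentage in [0, 100].
#' @examples
#' smallSegmentFraction(c(3, 4.9, 5, 10))  # 50
#' @export
smallSegmentFraction <- function(segments, threshold = 5, strict = TRUE) {
  mu <- .segmentMu(segments)
  if (threshold <= 0) stop("validation error: threshold must be > 0")
  small <- if (strict) mu < threshold else mu <= threshold
  100 * mean(small)
}
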