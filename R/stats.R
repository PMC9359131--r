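#' @include AllGenerics.R
NULL

.isNormal <- function(x, alpha) {
  if (stats::sd(x) == 0) return(FALSE)   # degenerate: Shapiro undefined
  stats::shapiro.test(x)$p.value >= alpha
}

#' Normality-gated two-sample comparison
#'
#' Compares two samples of a dosimetric metric with the test the data
#' support: normality is assessed with the Shapiro-Wilk test at
#' \code{normalityAlpha} (on the paired differences when \code{paired}, on
#' each sample otherwise); if accepted a t-test is used (paired or
#' two-sample Welch), otherwise the rank-sum test (Wilcoxon signed-rank when
#' paired, Mann-Whitney otherwise). Two-sided p-values throughout. The
#' returned result carries the raw p; apply \code{\link{bonferroni}} for
#' multiplicity.
#'
#' @param a,b numeric samples (each n >= 3; equal lengths when paired).
#' @param paired treat the samples as paired (default TRUE: the same
#'   patients re-planned under each condition).
#' @param normalityAlpha significance level of the normality gate.
#' @param metric,groupA,groupB labels carried into the result.
#' @return a \linkS4class{ComparisonResult} (with \code{pAdjusted = NA}).
#' @examples
#' compareGroups(rnorm(20), rnorm(20, 1), paired = TRUE)
#' @export
compareGroups <- function(a, b, paired = TRUE, normalityAlpha = 0.05,
                          metric = "metric", groupA = "A", groupB = "B") {
  if (length(a) < 3L || length(b) < 3L)
    stop("insufficient-data error: each sample needs n >= 3")
  if (paired && length(a) != length(b))
    stop("validation error: paired samples must have equal length")
  if (paired && all(a == b)) {
    # degenerate no-difference case: statistic 0, p = 1 by definition
    return(new("ComparisonResult", metric = metric, groupA = groupA,
               groupB = groupB, testUsed = "t", statistic = 0,
               pRaw = 1, pAdjusted = NA_real_, significant = FALSE))
  }
  normal <- if (paired) .isNormal(a - b, normalityAlpha)
    else .isNormal(a, normalityAlpha) && .isNormal(b, normalityAlpha)
  if (normal) {
    ht <- stats::t.test(a, b, paired = paired)
    used <- "t"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, paired = paired, exact = FALSE,
                         correct = TRUE))
    used <- "rank_sum"
  }
  new("ComparisonResult", metric = metric, groupA = groupA, groupB = groupB,
      testUsed = used, statistic = unname(ht$statistic),
      pRaw = min(1, max(0, ht$p.value)), pAdjusted = NA_real_,
      significant = FALSE)
}

#' Bonferroni correction
#'
#' Adjusts a raw p-value for a family of \code{m} comparisons:
#' \code{min(1, m * p)}. Monotone in both arguments and never smaller than
#' the raw p.
#'
#' @param pRaw raw p-value(s) in [0, 1].
#' @param m family size (number of comparisons), >= 1.
#' @return adjusted p-value(s), capped at 1.
#' @examples
#' bonferroni(0.01, 4)  # 0.04
#' @export
bonferroni <- function(pRaw, m) {
  if (m < 1) stop("validation error: m must be >= 1")
  if (any(pRaw < 0 | pRaw > 1))
    stop("validation error: p-values must lie in [0, 1]")
  vapply(pRaw, function(p) stats::p.adjust(p, method = "bonferroni", n = m),
         numeric(1))
}

#' Adjust and flag a comparison result
#'
#' @param result a \linkS4class{ComparisonResult}.
#' @param m Bonferroni family size.
#' @param alpha significance level (default 0.05).
#' @return the result with \code{pAdjusted} and \code{significant} filled.
#' @export
adjustComparison <- function(result, m, alpha = 0.05) {
  result@pAdjusted <- bonferroni(result@pRaw, m)
  result@significant <- result@pAdjusted < alpha
  validObject(result)
  result
}
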