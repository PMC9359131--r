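#' @include AllGenerics.R
NULL

#' Select the cohort-best reference value for one scored item
#'
#' For a single (structure, metric) item measured in every plan group, the
#' reference value C is the best value achieved by any group: the minimum
#' when lower is better (OAR doses, HI, PTV near-max), the maximum when
#' higher is better (TC, CI). Every group attaining the reference is listed;
#' tied groups all score 0 on the item.
#'
#' @param values named numeric: one value per group (>= 2 groups, finite).
#' @param direction "lower_better" or "higher_better".
#' @return \code{list(reference = value, referenceGroups = labels)}.
#' @examples
#' selectReference(c(BL02 = 49.18, BL04 = 49.10, BL10 = 50.90), "lower_better")
#' @export
selectReference <- function(values,
                            direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  if (length(values) < 2L)
    stop("validation error: need values for at least 2 groups")
  if (any(!is.finite(values)))
    stop("validation error: all values must be finite")
  ref <- if (direction == "lower_better") min(values) else max(values)
  if (ref == 0)
    stop("scoring-undefined error: reference value is 0 ",
         "(relative deviation undefined)")
  list(reference = ref, referenceGroups = names(values)[values == ref])
}

#' Relative-deviation item score
#'
#' The quality score of one item is the absolute relative deviation of the
#' measured value M from the cohort-best reference C, weighted:
#' \eqn{S = |(M - C)/C \times P|}. It is 0 when the group holds the
#' reference, grows with deviation in either direction, and is invariant
#' under a common rescaling of M and C (a change of dose units does not
#' change the score).
#'
#' @param m measured value(s) M.
#' @param c reference value C (non-zero).
#' @param weight item weight P (> 0), 1 by default.
#' @return non-negative score(s), vectorized over \code{m}.
#' @examples
#' itemScore(50.90, 49.10)    # 0.0367 -> rounds to 0.037
#' itemScore(49.10, 49.10)    # exactly 0
#' @export
itemScore <- function(m, c, weight = 1) {
  if (c == 0)
    stop("scoring-undefined error: reference value is 0")
  if (weight <= 0) stop("validation error: weight must be > 0")
  abs((m - c) / c * weight)
}

#' Aggregate item scores into an overall plan score
#'
#' The overall quality score is the plain sum of the item scores; an empty
#' item set scores 0. Lower is better; 0 means the plan held the cohort-best
#' value on every scored item.
#'
#' @param items numeric vector of item scores (finite, >= 0).
#' @return the overall score.
#' @examples
#' aggregateScore(c(0.111, 0.125))  # 0.236
#' @export
aggregateScore <- function(items) {
  if (!length(items)) return(0)
  if (any(!is.finite(items)))
    stop("validation error: item scores must be finite")
  if (any(items < 0))
    stop("validation error: item scores must be >= 0")
  sum(items)
}

.validateMetricSpecs <- function(specs) {
  need <- c("structure", "metric", "category", "direction", "weight")
  if (!is.data.frame(specs) || !all(need %in% names(specs)))
    stop("configuration error: metric specs need columns ",
         paste(need, collapse = ", "))
  if (!all(specs$category %in% c("ptv", "oar")))
    stop("configuration error: category must be 'ptv' or 'oar'")
  if (!all(specs$direction %in% c("lower_better", "higher_better")))
    stop("configuration error: direction must be 'lower_better' or ",
         "'higher_better'")
  if (any(specs$weight <= 0))
    stop("configuration error: weights must be > 0")
  invisible(specs)
}

#' Score a plan cohort against its per-item best performer
#'
#' Runs the full scoring system over a long-format metric table: when the
#' table holds several plans (patients) per group, group means are computed
#' per (group, structure, metric) first and the means are scored. For each
#' configured item the cohort-best group mean is taken as the reference
#' (\code{\link{selectReference}}), each group's mean is scored with
#' \code{\link{itemScore}}, and per-group PTV and OAR subtotals plus the
#' overall score are accumulated with \code{\link{aggregateScore}}. Full
#' precision is kept internally; rounding is a reporting concern.
#'
#' @param table data.frame with columns \code{group, structure, metric,
#'   value} (and optionally \code{plan_id}).
#' @param specs metric-spec data.frame (\code{structure, metric, category,
#'   direction, weight}); see \code{\link{defaultMetricSpecs}}.
#' @return named list of \linkS4class{ScoreBreakdown}, one per group.
#' @examples
#' tab <- data.frame(group = rep(c("A", "B"), each = 1),
#'                   structure = "Brainstem", metric = "Dmax",
#'                   value = c(50.90, 49.10))
#' sp <- data.frame(structure = "Brainstem", metric = "Dmax",
#'                  category = "oar", direction = "lower_better", weight = 1)
#' sapply(scoreCohort(tab, sp), overallScore)
#' @export
scoreCohort <- function(table, specs) {
  .validateMetricSpecs(specs)
  if (!all(c("group", "structure", "metric", "value") %in% names(table)))
    stop("validation error: table needs columns group, structure, metric, value")
  groups <- unique(as.character(table$group))
  # group means per cell (single-plan tables pass through unchanged)
  agg <- stats::aggregate(value ~ group + structure + metric, data = table,
                          FUN = mean)
  key <- function(d) paste(d$structure, d$metric, sep = "\r")
  breakdowns <- list()
  for (g in groups) {
    rows <- vector("list", nrow(specs))
    for (j in seq_len(nrow(specs))) {
      sp <- specs[j, ]
      cell <- agg[agg$structure == sp$structure & agg$metric == sp$metric, ]
      vals <- stats::setNames(cell$value, cell$group)
      missing <- setdiff(groups, names(vals))
      if (length(missing) || !(g %in% names(vals)))
        stop(sprintf(
          "scoring error: missing cell (%s, %s, %s)",
          if (length(missing)) missing[1] else g, sp$structure, sp$metric))
      vals <- vals[groups]
      ref <- selectReference(vals, sp$direction)
      rows[[j]] <- data.frame(
        structure = sp$structure, metric = sp$metric,
        category = sp$category, direction = sp$direction,
        weight = sp$weight, measured = unname(vals[g]),
        reference = ref$reference,
        score = itemScore(unname(vals[g]), ref$reference, sp$weight),
        referenceGroups = paste(ref$referenceGroups, collapse = ","),
        stringsAsFactors = FALSE)
    }
    items <- do.call(rbind, rows)
    ptv <- aggregateScore(items$score[items$category == "ptv"])
    oar <- aggregateScore(items$score[items$category == "oar"])
    breakdowns[[g]] <- new("ScoreBreakdown", group = g, items = items,
                           ptvSubtotal = ptv, oarSubtotal = oar,
                           overall = ptv + oar)
  }
  breakdowns
}

#' Summarise a cohort score as one row per group
#'
#' @param breakdowns result of \code{\link{scoreCohort}}.
#' @param digits rounding for the display columns (default 3, matching the
#'   usual reporting precision); full-precision columns are retained.
#' @return data.frame with per-group subtotals, overall score, and rounded
#'   display columns, ordered best (lowest overall) first.
#' @export
scoreSummary <- function(breakdowns, digits = 3) {
  df <- do.call(rbind, lapply(breakdowns, function(b) data.frame(
    group = b@group, ptv_subtotal = b@ptvSubtotal,
    oar_subtotal = b@oarSubtotal, overall = b@overall,
    stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df$ptv_display <- round(df$ptv_subtotal, digits)
  df$oar_display <- round(df$oar_subtotal, digits)
  df$overall_display <- round(df$overall, digits)
  df[order(df$overall), , drop = FALSE]
}
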