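#' @include score.R
NULL

#' Evaluate organ-at-risk dose constraints
#'
#' Checks a metric table against a constraint table of upper bounds: a row
#' passes iff its value is less than or equal to the bound (inclusive). A
#' plan passes iff all of its constrained rows pass; a constrained metric
#' missing from the table is reported as "unevaluated" and prevents the plan
#' from passing.
#'
#' @param table data.frame with columns \code{structure, metric, value} and
#'   a plan identifier column (\code{plan_id} if present, else
#'   \code{group}).
#' @param constraints data.frame with columns \code{structure, metric,
#'   bound} (and optionally \code{units}); see
#'   \code{\link{defaultConstraints}}.
#' @return \code{list(rows = per-row report, plans = per-plan pass table)};
#'   row status is "pass", "fail" or "unevaluated".
#' @examples
#' tab <- data.frame(plan_id = "p1", structure = "Brainstem",
#'                   metric = "Dmax", value = 49.10)
#' con <- data.frame(structure = "Brainstem", metric = "Dmax", bound = 54)
#' evaluateConstraints(tab, con)$plans
#' @export
evaluateConstraints <- function(table, constraints) {
  if (!all(c("structure", "metric", "bound") %in% names(constraints)))
    stop("configuration error: constraints need columns structure, metric, bound")
  if (any(constraints$bound <= 0))
    stop("configuration error: bounds must be > 0")
  idcol <- if ("plan_id" %in% names(table)) "plan_id" else "group"
  plans <- unique(as.character(table[[idcol]]))
  rows <- list()
  for (p in plans) {
    sub <- table[table[[idcol]] == p, ]
    for (i in seq_len(nrow(constraints))) {
      cn <- constraints[i, ]
      hit <- sub[sub$structure == cn$structure & sub$metric == cn$metric, ]
      status <- if (!nrow(hit)) "unevaluated"
        else if (hit$value[1] <= cn$bound) "pass" else "fail"
      rows[[length(rows) + 1L]] <- data.frame(
        plan = p, structure = cn$structure, metric = cn$metric,
        value = if (nrow(hit)) hit$value[1] else NA_real_,
        bound = cn$bound, status = status, stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  planPass <- vapply(plans, function(p)
    all(rows$status[rows$plan == p] == "pass"), logical(1))
  list(rows = rows,
       plans = data.frame(plan = plans, pass = unname(planPass),
                          stringsAsFactors = FALSE))
}
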