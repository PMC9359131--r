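#' @include AllGenerics.R
NULL

.readCSVChecked <- function(path, required, what) {
  if (!file.exists(path)) stop("cannot read ", what, ": no file at ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " at ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  df
}

#' Read / write a long-format plan metric table
#'
#' CSV with header \code{plan_id,group,structure,metric,value} (the
#' \code{plan_id} column may be absent for group-level tables).
#'
#' @param path file path.
#' @return data.frame of metric records.
#' @export
readMetricsCSV <- function(path) {
  df <- .readCSVChecked(path, c("group", "structure", "metric", "value"),
                        "metric table")
  df
}

#' @rdname readMetricsCSV
#' @param table metric table to write.
#' @export
writeMetricsCSV <- function(table, path) {
  keep <- intersect(c("plan_id", "group", "structure", "metric", "value"),
                    names(table))
  utils::write.csv(table[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read / write segment monitor-unit records
#'
#' CSV with header \code{plan_id,beam,segment,mu}.
#'
#' @param path file path.
#' @return data.frame of segment records.
#' @export
readSegmentsCSV <- function(path) {
  df <- .readCSVChecked(path, c("plan_id", "beam", "segment", "mu"),
                        "segment table")
  if (any(df$mu < 0)) stop("validation error: segment MUs must be >= 0")
  if (anyDuplicated(df[, c("plan_id", "beam", "segment")]))
    stop("validation error: duplicate (plan, beam, segment) records")
  df
}

#' @rdname readSegmentsCSV
#' @param segments segment table to write.
#' @export
writeSegmentsCSV <- function(segments, path) {
  utils::write.csv(segments[, c("plan_id", "beam", "segment", "mu")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write cumulative DVH curves
#'
#' CSV with header \code{structure,dose_gy,cum_volume_pct}, one curve per
#' structure with ascending edges.
#'
#' @param curves list of \linkS4class{DVHCurve}.
#' @param path file path.
#' @export
writeDVHCSV <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv) data.frame(
    structure = cv@structure, dose_gy = cv@binEdges,
    cum_volume_pct = cv@cumVolume, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDVHCSV
#' @return \code{readDVHCSV}: named list of \linkS4class{DVHCurve}.
#' @export
readDVHCSV <- function(path) {
  df <- .readCSVChecked(path, c("structure", "dose_gy", "cum_volume_pct"),
                        "DVH table")
  out <- lapply(split(df, df$structure), function(d)
    DVHCurve(d$structure[1], d$dose_gy, d$cum_volume_pct))
  out[unique(df$structure)]
}

#' Read a constraint table
#'
#' CSV with header \code{structure,metric,bound,units}: upper dose/volume
#' bounds per (structure, metric).
#'
#' @param path file path.
#' @return data.frame of constraints.
#' @export
readConstraintsCSV <- function(path) {
  df <- .readCSVChecked(path, c("structure", "metric", "bound"),
                        "constraint table")
  if (any(df$bound <= 0)) stop("validation error: bounds must be > 0")
  if (anyDuplicated(df[, c("structure", "metric")]))
    stop("validation error: duplicate (structure, metric) constraint rows")
  df
}

#' Read a metric-spec table
#'
#' CSV with header \code{structure,metric,category,direction,weight}
#' defining which items are scored, their merit direction and weight.
#'
#' @param path file path.
#' @return validated metric-spec data.frame.
#' @export
readMetricSpecsCSV <- function(path) {
  .validateMetricSpecs(.readCSVChecked(
    path, c("structure", "metric", "category", "direction", "weight"),
    "metric-spec table"))
}

#' Read a pipeline run configuration
#'
#' YAML file describing one \code{\link{runPipeline}} run; see the package
#' vignette for the schema.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("cannot read run config at ", path)
  yaml::read_yaml(path)
}
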