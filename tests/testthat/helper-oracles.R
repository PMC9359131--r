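# Independent brute-force oracles used to cross-check the DVH engine and
# the scoring system, plus small fixture builders. Oracles deliberately use
# direct voxel counting / sorting / formula transcription, not the package's
# own code paths.

randomGrid <- function(shape = c(16L, 16L, 16L), maxDose = 75,
                       spacing = c(2, 2, 2)) {
  DoseGrid(array(runif(prod(shape), 0, maxDose), dim = shape),
           spacing = spacing)
}

fullMask <- function(grid, name = "roi", role = "oar") {
  StructureMask(name, array(TRUE, dim = dim(doseArray(grid))), role = role)
}

lineGrid <- function(doses, spacing = c(1, 1, 1)) {
  DoseGrid(array(doses, dim = c(length(doses), 1L, 1L)), spacing = spacing)
}

# cumulative-DVH oracle: direct voxel counting at each threshold
oracleCumVolume <- function(doses, thresholds) {
  vapply(thresholds, function(t) 100 * mean(doses >= t), numeric(1))
}

# Dx% oracle: the (100 - x)th percentile of the sorted voxel doses
oracleDoseAtVolume <- function(doses, x) {
  unname(stats::quantile(doses, probs = 1 - x / 100, type = 1))
}

# coverage-volumes oracle: raw voxel counting
oracleCoverage <- function(grid, mask, rx) {
  d <- doseArray(grid); m <- maskArray(mask)
  voxcc <- prod(gridSpacing(grid)) / 1000
  list(tv = sum(m) * voxcc, tvPi = sum(m & d >= rx) * voxcc,
       vPi = sum(d >= rx) * voxcc)
}

# direct transcription of the scoring formulas: per item, reference = best
# group value, score = |(M - C)/C * P|, subtotals by category
oracleScores <- function(table, specs) {
  groups <- unique(table$group)
  out <- stats::setNames(rep(0, length(groups)), groups)
  ptv <- out; oar <- out
  for (j in seq_len(nrow(specs))) {
    sp <- specs[j, ]
    sub <- table[table$structure == sp$structure &
                   table$metric == sp$metric, ]
    vals <- stats::setNames(sub$value, sub$group)[groups]
    ref <- if (sp$direction == "lower_better") min(vals) else max(vals)
    s <- abs((vals - ref) / ref * sp$weight)
    out <- out + s
    if (sp$category == "ptv") ptv <- ptv + s else oar <- oar + s
  }
  list(overall = out, ptv = ptv, oar = oar)
}

# analytic mean/sd of a Normal(mu, sigma) truncated to [lo, hi] -- the law
# the resampling cohort generator actually draws from
truncNormMoments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  pa <- dnorm(a); pb <- dnorm(b)
  m <- mu + sigma * (pa - pb) / Z
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  v <- sigma^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# tiny random cohort for scoring property tests
randomCohortTable <- function(nGroups = 3, nItems = 6, seed = 1) {
  set.seed(seed)
  groups <- paste0("G", seq_len(nGroups))
  items <- data.frame(
    structure = paste0("S", seq_len(nItems)),
    metric = sample(c("Dmax", "Dmean", "V30"), nItems, replace = TRUE),
    category = sample(c("ptv", "oar"), nItems, replace = TRUE),
    direction = sample(c("lower_better", "higher_better"), nItems,
                       replace = TRUE),
    weight = round(runif(nItems, 0.5, 2), 2), stringsAsFactors = FALSE)
  table <- do.call(rbind, lapply(groups, function(g) data.frame(
    group = g, structure = items$structure, metric = items$metric,
    value = runif(nItems, 10, 80), stringsAsFactors = FALSE)))
  list(table = table, specs = items)
}
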