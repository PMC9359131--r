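#' @include data-defaults.R metrics.R constraints.R efficiency.R stats.R segments.R phantom.R
NULL

.defaultWidths <- c(BL02 = 2, BL04 = 4, BL06 = 6, BL08 = 8, BL10 = 10)

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, written, code) {
  t0 <- Sys.time()
  res <- tryCatch(force(code), error = function(e) {
    unlink(written, force = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[planscore] stage %-12s %6.2f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full plan-comparison pipeline
#'
#' Orchestrates generate/ingest, metric extraction, quality scoring,
#' constraint checking, delivery-efficiency metrics and group-comparison
#' statistics, writing all result tables to an output directory plus a JSON
#' summary naming the winning (lowest overall score) plan group. In
#' \code{synthetic} mode the inputs are generated by the package's cohort,
#' phantom and segment models under the run seed, so two runs with the same
#' seed produce byte-identical CSV outputs; in \code{from_files} mode a
#' metric CSV (and optionally a segment CSV) is ingested instead. Any stage
#' error removes the partially written outputs and is re-raised with the
#' stage name.
#'
#' The config is a nested list (or path to a YAML file with the same
#' shape); every field has a default. Top-level fields: \code{mode}
#' ("synthetic" or "from_files"), \code{seed} (mandatory in synthetic
#' mode), \code{out_dir}, \code{rounding_digits}; blocks \code{cohort}
#' (\code{n_patients}, \code{patient_effect_sd}, \code{params_csv}),
#' \code{phantom} (\code{grid_shape}, \code{spacing}, \code{target_radius},
#' \code{prescription_dose}, \code{base_dose}, \code{widths}),
#' \code{comparison} (\code{paired}, \code{family_size}), \code{files}
#' (\code{metrics_csv}, \code{segments_csv}) and paths
#' \code{metric_specs_csv}, \code{constraints_csv}.
#'
#' @param config configuration list or path to a YAML config file.
#' @return invisibly, a list with the score summary, winner, file paths and
#'   the JSON summary structure.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  mode <- config$mode %||% "synthetic"
  if (!mode %in% c("synthetic", "from_files"))
    stop("config error: mode must be 'synthetic' or 'from_files'")
  if (mode == "synthetic" && is.null(config$seed))
    stop("config error: seed is mandatory in synthetic mode")
  seed <- as.integer(config$seed %||% 0L)
  outDir <- config$out_dir %||% "planscore_run"
  digits <- config$rounding_digits %||% 3
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  out <- function(f) file.path(outDir, f)
  note <- function(f) { written <<- c(written, f); f }

  specs <- if (!is.null(config$metric_specs_csv))
    readMetricSpecsCSV(config$metric_specs_csv) else defaultMetricSpecs()
  constraints <- if (!is.null(config$constraints_csv))
    readConstraintsCSV(config$constraints_csv) else defaultConstraints()
  message(sprintf("[planscore] seed %d, config hash %s", seed,
                  .configHash(config)))

  segments <- NULL
  if (mode == "synthetic") {
    cohortCfg <- config$cohort %||% list()
    params <- if (!is.null(cohortCfg$params_csv))
      utils::read.csv(cohortCfg$params_csv, stringsAsFactors = FALSE)
      else defaultCohortParams()
    cspec <- CohortSpec(
      metricParams = params,
      nPatients = as.integer(cohortCfg$n_patients %||% 20L),
      patientEffectSd = cohortCfg$patient_effect_sd %||% 1,
      seed = seed)
    metrics <- .stage("cohort", written, sampleMetricCohort(cspec))
    writeMetricsCSV(metrics, note(out("metrics.csv")))

    phantomCfg <- config$phantom %||% list()
    widths <- unlist(phantomCfg$widths %||% as.list(.defaultWidths))
    .stage("phantom", written, {
      curves <- list(); prows <- list()
      for (g in names(widths)) {
        ph <- buildPhantom(.phantomSpecFromConfig(phantomCfg, widths[[g]]))
        rxDose <- phantomCfg$prescription_dose %||% 70
        # clinical plans are normalised so the prescription isodose sits
        # below the target's hot plateau; report coverage at that isodose
        # fraction of the step alongside the literal-step coverage
        isoFrac <- phantomCfg$coverage_isodose_frac %||% 0.95
        for (m in ph$masks) {
          cv <- computeDVH(ph$grid, m)
          cv@structure <- paste(g, m@name, sep = ":")
          curves[[cv@structure]] <- cv
        }
        vols <- coverageVolumes(ph$grid, ph$masks$target, rxDose)
        vols95 <- coverageVolumes(ph$grid, ph$masks$target, isoFrac * rxDose)
        st <- doseStatistics(ph$grid, ph$masks$target)
        prows[[g]] <- data.frame(
          group = g, tc = targetCoverage(vols),
          tc_iso = targetCoverage(vols95), ci = conformityIndex(vols95),
          hi = homogeneityIndex(st), d2 = st@d2, stringsAsFactors = FALSE)
      }
      writeDVHCSV(curves, note(out("dvh_curves.csv")))
      utils::write.csv(do.call(rbind, prows), note(out("phantom_metrics.csv")),
                       row.names = FALSE)
    })

    segSpecs <- defaultSegmentSpecs(seed = seed)
    segments <- .stage("segments", written, {
      muTab <- metrics[metrics$structure == "Plan" & metrics$metric == "MU", ]
      segs <- list()
      for (g in names(segSpecs)) {
        plansG <- muTab[muTab$group == g, ]
        for (i in seq_len(nrow(plansG))) {
          sp <- segSpecs[[g]]
          sp@totalMu <- max(plansG$value[i], 1)
          sp@seed <- as.integer(seed + 101L * match(g, names(segSpecs)) + i)
          segs[[plansG$plan_id[i]]] <-
            sampleSegments(sp, planId = plansG$plan_id[i])
        }
      }
      do.call(rbind, segs)
    })
    writeSegmentsCSV(segments, note(out("segments.csv")))
  } else {
    files <- config$files %||% list()
    if (is.null(files$metrics_csv))
      stop("config error: from_files mode needs files$metrics_csv")
    metrics <- .stage("ingest", written, readMetricsCSV(files$metrics_csv))
    if (!is.null(files$segments_csv))
      segments <- readSegmentsCSV(files$segments_csv)
  }

  scorable <- metrics[paste(metrics$structure, metrics$metric) %in%
                        paste(specs$structure, specs$metric), ]
  breakdowns <- .stage("score", written, scoreCohort(scorable, specs))
  itemsDf <- do.call(rbind, lapply(breakdowns, function(b)
    cbind(group = b@group, b@items)))
  rownames(itemsDf) <- NULL
  utils::write.csv(itemsDf, note(out("score_items.csv")), row.names = FALSE)
  summ <- scoreSummary(breakdowns, digits = digits)
  utils::write.csv(summ, note(out("score_summary.csv")), row.names = FALSE)

  constrRep <- .stage("constraints", written, {
    groupMeans <- stats::aggregate(value ~ group + structure + metric,
                                   data = metrics, FUN = mean)
    evaluateConstraints(groupMeans, constraints)
  })
  utils::write.csv(constrRep$rows, note(out("constraints.csv")),
                   row.names = FALSE)

  if (!is.null(segments)) {
    eff <- .stage("efficiency", written, {
      perPlan <- do.call(rbind, lapply(split(segments, segments$plan_id),
        function(s) data.frame(
          plan_id = s$plan_id[1],
          group = sub("^.*_", "", s$plan_id[1]),
          total_mu = totalMU(s),
          small_segment_pct = smallSegmentFraction(s),
          stringsAsFactors = FALSE)))
      agg <- do.call(rbind, lapply(split(perPlan, perPlan$group),
        function(d) data.frame(
          group = d$group[1], mu_mean = mean(d$total_mu),
          mu_sd = stats::sd(d$total_mu),
          small_pct_mean = mean(d$small_segment_pct),
          small_pct_sd = stats::sd(d$small_segment_pct),
          stringsAsFactors = FALSE)))
      rownames(agg) <- NULL
      agg
    })
    utils::write.csv(eff, note(out("efficiency.csv")), row.names = FALSE)
  }

  winner <- summ$group[summ$overall == min(summ$overall)]
  cmpCfg <- config$comparison %||% list()
  comparisons <- NULL
  if ("plan_id" %in% names(metrics) &&
      min(table(metrics$group, paste(metrics$structure, metrics$metric))) >= 3) {
    comparisons <- .stage("compare", written,
      .compareToReference(scorable, reference = winner[1],
                          paired = cmpCfg$paired %||% TRUE,
                          m = cmpCfg$family_size %||% 4L))
    utils::write.csv(comparisons, note(out("comparisons.csv")),
                     row.names = FALSE)
  }

  summary <- list(
    seed = seed, mode = mode, config_hash = .configHash(config),
    winner = if (length(winner) > 1) list(tie = TRUE, groups = winner)
             else winner,
    groups = lapply(seq_len(nrow(summ)), function(i) list(
      group = summ$group[i],
      ptv_subtotal = summ$ptv_subtotal[i],
      oar_subtotal = summ$oar_subtotal[i],
      overall = summ$overall[i],
      overall_display = summ$overall_display[i])))
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), note(out("summary.json")))
  invisible(list(scoreSummary = summ, winner = winner,
                 breakdowns = breakdowns, comparisons = comparisons,
                 files = written, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.phantomSpecFromConfig <- function(cfg, widthMm) {
  shape <- as.integer(cfg$grid_shape %||% c(48L, 48L, 48L))
  spacing <- as.numeric(cfg$spacing %||% c(2, 2, 2))
  radius <- cfg$target_radius %||% 20
  center <- (shape + 1) / 2
  # one adjacent OAR just outside the target along the first axis
  oarRadius <- cfg$oar_radius %||% 8
  oarGap <- cfg$oar_gap %||% 2
  oarCenter <- center +
    c((radius + oarGap + oarRadius) / spacing[1], 0, 0)
  PhantomSpec(gridShape = shape, spacing = spacing, targetCenter = center,
              targetRadius = radius,
              oarSpecs = list(list(name = "adjacent_oar", center = oarCenter,
                                   radius = oarRadius)),
              prescriptionDose = cfg$prescription_dose %||% 70,
              baseDose = cfg$base_dose %||% 10,
              blurSigma = widthMm)
}

.compareToReference <- function(metrics, reference, paired = TRUE, m = 4L) {
  cells <- unique(metrics[, c("structure", "metric")])
  groups <- setdiff(unique(metrics$group), reference)
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    s <- cells$structure[i]; mt <- cells$metric[i]
    sub <- metrics[metrics$structure == s & metrics$metric == mt, ]
    sub <- sub[order(sub$plan_id), ]
    ref <- sub$value[sub$group == reference]
    for (g in groups) {
      cur <- sub$value[sub$group == g]
      if (paired && length(cur) != length(ref)) next
      res <- compareGroups(cur, ref, paired = paired,
                           metric = paste(s, mt, sep = ":"),
                           groupA = g, groupB = reference)
      res <- adjustComparison(res, m = m)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = s, metric = mt, group = g, reference = reference,
        test = res@testUsed, statistic = res@statistic, p_raw = res@pRaw,
        p_adjusted = res@pAdjusted, significant = res@significant,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
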