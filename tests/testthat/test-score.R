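# Cohort-referenced quality scoring: reference selection, item scores,
# aggregation, full-cohort scoring and constraint checking.

test_that("reference selection picks the cohort-best group per direction", {
  brainstem <- c(BL02 = 49.18, BL04 = 49.10, BL06 = 49.19, BL08 = 49.50,
                 BL10 = 50.90)
  ref <- selectReference(brainstem, "lower_better")
  expect_equal(ref$reference, 49.10)
  expect_equal(ref$referenceGroups, "BL04")

  tc <- c(BL02 = 98.25, BL04 = 98.31, BL06 = 97.82, BL08 = 97.49,
          BL10 = 96.96)
  ref <- selectReference(tc, "higher_better")
  expect_equal(ref$reference, 98.31)
  expect_equal(ref$referenceGroups, "BL04")

  tie <- selectReference(c(A = 5, B = 5, C = 7), "lower_better")
  expect_equal(tie$reference, 5)
  expect_equal(sort(tie$referenceGroups), c("A", "B"))
  expect_equal(itemScore(5, tie$reference), 0)

  expect_error(selectReference(c(A = 0, B = 2), "lower_better"),
               "scoring-undefined")
  expect_error(selectReference(c(A = 1), "lower_better"), "2 groups")
})

test_that("item scores reproduce the worked brainstem example", {
  expect_equal(round(itemScore(50.90, 49.10, 1), 3), 0.037)
  expect_equal(itemScore(49.10, 49.10, 1), 0)
  expect_equal(itemScore(60, 50, weight = 0.5), 0.1)
  expect_error(itemScore(1, 0), "scoring-undefined")
  expect_error(itemScore(1, 1, weight = 0), "weight")
})

test_that("item scores are non-negative and scale-invariant", {
  set.seed(77)
  for (rep in 1:20) {
    m <- runif(1, 1, 100); c <- runif(1, 1, 100); a <- runif(1, 0.1, 10)
    s <- itemScore(m, c)
    expect_gte(s, 0)
    expect_equal(itemScore(a * m, a * c), s, tolerance = 1e-12)
  }
})

test_that("aggregation is an exact sum with an empty-set zero", {
  expect_equal(aggregateScore(c(0.111, 0.125)), 0.236)
  expect_equal(aggregateScore(numeric()), 0)
  expect_error(aggregateScore(c(0.1, -0.2)), "validation")
})

test_that("scoring the packaged OAR group means reproduces the reference subtotal", {
  specs <- defaultMetricSpecs()
  oarSpecs <- specs[specs$category == "oar", ]
  br <- scoreCohort(defaultGroupMeans("oar"), oarSpecs)
  expect_equal(round(br$BL04@oarSubtotal, 3), 0.079)
  # the other groups' subtotals agree with their published 2-d.p.-rounded
  # counterparts to within the input rounding error
  printed <- c(BL02 = 0.125, BL06 = 0.270, BL08 = 0.457, BL10 = 0.441)
  for (g in names(printed))
    expect_lt(abs(br[[g]]@oarSubtotal - printed[[g]]), 0.003)
  # per-item: at least one group scores exactly 0
  items <- do.call(rbind, lapply(br, slot, "items"))
  for (s in unique(items$structure)) {
    sub <- items[items$structure == s, ]
    expect_true(any(sub$score == 0))
  }
})

test_that("a group holding every reference scores exactly zero overall", {
  table <- data.frame(
    group = rep(c("A", "B"), each = 2),
    structure = rep(c("PTV", "Brainstem"), 2),
    metric = rep(c("TC", "Dmax"), 2),
    value = c(99, 50, 98, 55), stringsAsFactors = FALSE)
  specs <- data.frame(structure = c("PTV", "Brainstem"),
                      metric = c("TC", "Dmax"), category = c("ptv", "oar"),
                      direction = c("higher_better", "lower_better"),
                      weight = 1, stringsAsFactors = FALSE)
  br <- scoreCohort(table, specs)
  expect_equal(overallScore(br$A), 0)
  expect_gt(overallScore(br$B), 0)
  expect_equal(br$A@ptvSubtotal + br$A@oarSubtotal, overallScore(br$A))
})

test_that("cohort scoring matches the formula-transcription oracle", {
  for (seed in 1:5) {
    rc <- randomCohortTable(nGroups = sample(3:5, 1),
                            nItems = sample(5:15, 1), seed = seed)
    br <- scoreCohort(rc$table, rc$specs)
    oracle <- oracleScores(rc$table, rc$specs)
    for (g in names(br)) {
      expect_equal(overallScore(br[[g]]), unname(oracle$overall[g]),
                   tolerance = 1e-12)
      expect_equal(br[[g]]@ptvSubtotal, unname(oracle$ptv[g]),
                   tolerance = 1e-12)
      expect_equal(br[[g]]@oarSubtotal, unname(oracle$oar[g]),
                   tolerance = 1e-12)
    }
  }
})

test_that("group means are scored when the table holds multiple patients", {
  set.seed(9)
  tab <- do.call(rbind, lapply(c("A", "B"), function(g) data.frame(
    plan_id = paste0("P", 1:4, "_", g), group = g, structure = "Brainstem",
    metric = "Dmax", value = rnorm(4, if (g == "A") 49 else 51, 0.5),
    stringsAsFactors = FALSE)))
  specs <- data.frame(structure = "Brainstem", metric = "Dmax",
                      category = "oar", direction = "lower_better",
                      weight = 1, stringsAsFactors = FALSE)
  br <- scoreCohort(tab, specs)
  mA <- mean(tab$value[tab$group == "A"]); mB <- mean(tab$value[tab$group == "B"])
  expect_equal(overallScore(br$B), abs((mB - mA) / mA), tolerance = 1e-12)
})

test_that("moving a group's value onto the reference weakly lowers its score", {
  rc <- randomCohortTable(nGroups = 4, nItems = 8, seed = 12)
  br <- scoreCohort(rc$table, rc$specs)
  g <- names(br)[2]
  it <- br[[g]]@items[which.max(br[[g]]@items$score), ]
  tab2 <- rc$table
  hit <- tab2$group == g & tab2$structure == it$structure &
    tab2$metric == it$metric
  tab2$value[hit] <- it$reference
  br2 <- scoreCohort(tab2, rc$specs)
  expect_equal(br2[[g]]@items$score[br2[[g]]@items$structure == it$structure &
                                      br2[[g]]@items$metric == it$metric], 0)
  expect_lte(overallScore(br2[[g]]), overallScore(br[[g]]) + 1e-12)
})

test_that("missing cells and zero references are reported, not skipped", {
  rc <- randomCohortTable(nGroups = 3, nItems = 3, seed = 3)
  tab <- rc$table[-1, ]
  expect_error(scoreCohort(tab, rc$specs), "scoring error: missing cell")
  tab0 <- rc$table
  tab0$value[tab0$structure == "S1"] <- 0
  sp1 <- rc$specs; sp1$direction <- "lower_better"
  expect_error(scoreCohort(tab0, sp1), "scoring-undefined")
})

test_that("constraint evaluation uses inclusive upper bounds", {
  con <- data.frame(structure = c("Brainstem", "SpinalCord"),
                    metric = "Dmax", bound = c(54, 45),
                    stringsAsFactors = FALSE)
  tab <- data.frame(plan_id = c("p1", "p1", "p2", "p2"),
                    structure = rep(c("Brainstem", "SpinalCord"), 2),
                    metric = "Dmax", value = c(49.10, 46.0, 54, 45),
                    stringsAsFactors = FALSE)
  rep <- evaluateConstraints(tab, con)
  r <- rep$rows
  expect_equal(r$status[r$plan == "p1" & r$structure == "Brainstem"], "pass")
  expect_equal(r$status[r$plan == "p1" & r$structure == "SpinalCord"], "fail")
  # boundary: exactly at the bound passes
  expect_true(all(r$status[r$plan == "p2"] == "pass"))
  expect_equal(rep$plans$pass, c(FALSE, TRUE))

  # missing constrained metric: unevaluated, plan cannot pass
  tab2 <- tab[tab$structure == "Brainstem" & tab$plan_id == "p1", ]
  rep2 <- evaluateConstraints(tab2, con)
  expect_true("unevaluated" %in% rep2$rows$status)
  expect_false(any(rep2$plans$pass))
})

test_that("packaged defaults load and are internally consistent", {
  specs <- defaultMetricSpecs()
  expect_equal(sum(specs$category == "oar"), 11L)
  expect_equal(sum(specs$category == "ptv"), 16L)
  con <- defaultConstraints()
  expect_equal(nrow(con), 11L)
  params <- defaultCohortParams()
  expect_true(all(paste(specs$structure, specs$metric) %in%
                    paste(params$structure, params$metric)))
})
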