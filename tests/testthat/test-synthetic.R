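# Synthetic-cohort generator: phantoms, metric cohorts, segment mixtures.

test_that("blur-free phantom is an exact step function with full coverage", {
  spec <- PhantomSpec(gridShape = c(32L, 32L, 32L), targetRadius = 14,
                      blurSigma = 0)
  ph <- buildPhantom(spec)
  d <- doseArray(ph$grid); t <- maskArray(ph$masks$target)
  expect_true(all(d[t] == spec@prescriptionDose))
  expect_true(all(d[!t] == spec@baseDose))
  vols <- coverageVolumes(ph$grid, ph$masks$target, spec@prescriptionDose)
  expect_equal(targetCoverage(vols), 100)
})

test_that("phantom construction is deterministic", {
  spec <- PhantomSpec(gridShape = c(24L, 24L, 24L), targetRadius = 10,
                      blurSigma = 3)
  expect_identical(doseArray(buildPhantom(spec)$grid),
                   doseArray(buildPhantom(spec)$grid))
})

test_that("phantom geometry and spacing are validated", {
  expect_error(PhantomSpec(gridShape = c(10L, 10L, 10L), targetRadius = 40),
               "geometry error")
  expect_error(PhantomSpec(spacing = c(0, 2, 2)), "spacing")
  expect_error(
    PhantomSpec(gridShape = c(32L, 32L, 32L), targetRadius = 5,
                oarSpecs = list(list(name = "oar", center = c(31, 16, 16),
                                     radius = 20))),
    "geometry error")
})

test_that("wider blur spills more dose into an abutting OAR and erodes coverage", {
  oar <- list(list(name = "oar", center = c(34, 20, 20), radius = 6))
  mkspec <- function(s) PhantomSpec(gridShape = c(40L, 40L, 40L),
                                    targetCenter = c(20, 20, 20),
                                    targetRadius = 16, oarSpecs = oar,
                                    blurSigma = s)
  oarMean <- function(ph) mean(doseArray(ph$grid)[maskArray(ph$masks$oar)])
  ph2 <- buildPhantom(mkspec(2)); ph6 <- buildPhantom(mkspec(6))
  expect_gt(oarMean(ph6), oarMean(ph2))

  sigmas <- c(1, 2, 4, 6, 8, 10)
  res <- lapply(sigmas, function(s) buildPhantom(mkspec(s)))
  tc <- vapply(res, function(ph)
    targetCoverage(coverageVolumes(ph$grid, ph$masks$target, 70)), numeric(1))
  tcIso <- vapply(res, function(ph)
    targetCoverage(coverageVolumes(ph$grid, ph$masks$target, 0.95 * 70)),
    numeric(1))
  om <- vapply(res, oarMean, numeric(1))
  expect_true(all(diff(tc) <= 1e-9))
  expect_true(all(diff(tcIso) <= 1e-9))
  expect_true(all(diff(om) >= -1e-9))
  # the relaxed-isodose sweep is informative, not degenerate (erosion depth
  # scales with sigma, which is substantial against a 16 mm target)
  expect_gt(tcIso[1], 50)
  expect_gt(tcIso[1] - tcIso[length(tcIso)], 5)
})

test_that("separable Gaussian blur matches a direct dense convolution", {
  set.seed(42)
  arr <- array(runif(5 * 4 * 3), dim = c(5, 4, 3))
  sigma <- c(0.8, 1.1, 0.6)
  ks <- lapply(sigma, planscore:::.gaussianKernel)
  # dense oracle with replicate padding
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  expected <- array(0, dim = dim(arr))
  for (x in 1:5) for (y in 1:4) for (z in 1:3) {
    acc <- 0
    r <- vapply(ks, function(k) (length(k) - 1L) %/% 2L, integer(1))
    for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3])
      acc <- acc + ks[[1]][dx + r[1] + 1] * ks[[2]][dy + r[2] + 1] *
        ks[[3]][dz + r[3] + 1] *
        arr[clamp(x + dx, 5L), clamp(y + dy, 4L), clamp(z + dz, 3L)]
    expected[x, y, z] <- acc
  }
  expect_equal(planscore:::.gaussianBlur3D(arr, sigma), expected,
               tolerance = 1e-12)
})

test_that("cohort sampling is seed-reproducible and validated", {
  spec <- CohortSpec(nPatients = 4L, seed = 11L)
  expect_identical(sampleMetricCohort(spec), sampleMetricCohort(spec))
  bad <- defaultCohortParams()
  bad <- bad[-which(bad$group == "BL04" & bad$structure == "Brainstem"), ]
  expect_error(CohortSpec(metricParams = bad), "configuration error")
})

test_that("cohort cell means converge to the configured values", {
  onecell <- do.call(rbind, lapply(c("A", "B"), function(g) data.frame(
    group = g, structure = "Parotids", metric = "V30", category = "oar",
    mean = 48.51, sd = 5.54, stringsAsFactors = FALSE)))
  tab <- sampleMetricCohort(CohortSpec(metricParams = onecell,
                                       nPatients = 2000L,
                                       patientEffectSd = 0, seed = 21L))
  m <- mean(tab$value[tab$group == "A"])
  expect_lt(abs(m - 48.51), 3 * 5.54 / sqrt(2000))
})

test_that("cohort moments match the truncated-normal law within 3 standard errors", {
  params <- defaultCohortParams()
  cells <- params[params$structure %in% c("Brainstem", "PTVnd", "Parotids") &
                    params$group %in% c("BL02", "BL04"), ]
  tab <- sampleMetricCohort(CohortSpec(metricParams = cells,
                                       groupLabels = c("BL02", "BL04"),
                                       nPatients = 1000L,
                                       patientEffectSd = 0, seed = 5L))
  for (i in seq_len(nrow(cells))) {
    v <- tab$value[tab$group == cells$group[i] &
                     tab$structure == cells$structure[i] &
                     tab$metric == cells$metric[i]]
    b <- planscore:::.metricBounds(cells$metric[i])
    mom <- truncNormMoments(cells$mean[i], cells$sd[i], b[1], b[2])
    expect_lt(abs(mean(v) - mom$mean), 3 * mom$sd / sqrt(1000))
    expect_lt(abs(sd(v) - mom$sd), 3 * mom$sd / sqrt(2 * 999) + 1e-12)
  }
  # away from the bounds the truncated and configured moments coincide
  mom <- truncNormMoments(49.10, 2.22, 0, Inf)
  expect_equal(mom$mean, 49.10, tolerance = 1e-12)
  expect_equal(mom$sd, 2.22, tolerance = 1e-12)
})

test_that("a shared patient effect induces across-group correlation", {
  onecell <- do.call(rbind, lapply(c("A", "B"), function(g) data.frame(
    group = g, structure = "S", metric = "Dmax", category = "oar",
    mean = 50, sd = 1, stringsAsFactors = FALSE)))
  tab <- sampleMetricCohort(CohortSpec(metricParams = onecell,
                                       nPatients = 500L,
                                       patientEffectSd = 5, seed = 31L))
  a <- tab$value[tab$group == "A"]; b <- tab$value[tab$group == "B"]
  expect_gt(cor(a, b), 0.5)
})

test_that("physically bounded metrics stay within their bounds", {
  onecell <- do.call(rbind, lapply(c("A", "B"), function(g) data.frame(
    group = g, structure = "PTV", metric = "TC", category = "ptv",
    mean = 98, sd = 4, stringsAsFactors = FALSE)))
  tab <- sampleMetricCohort(CohortSpec(metricParams = onecell,
                                       nPatients = 2000L,
                                       patientEffectSd = 0, seed = 41L))
  expect_true(all(tab$value <= 100 & tab$value >= 0))
})

test_that("segment MUs renormalise exactly and honour the mixture weight", {
  spec <- SegmentSpec(nSegments = 77L, totalMu = 843.03, seed = 13L)
  seg <- sampleSegments(spec)
  expect_equal(nrow(seg), 77L)
  expect_equal(sum(seg$mu), 843.03, tolerance = 1e-9)
  expect_identical(seg, sampleSegments(spec))

  # degenerate mixture: no low-MU component at all
  segHi <- sampleSegments(SegmentSpec(nSegments = 200L, totalMu = 200 * 19,
                                      smallWeight = 0,
                                      lowMuRange = c(1, 4),
                                      highMuRange = c(8, 30), seed = 3L))
  expect_equal(smallSegmentFraction(segHi), 0)

  segMix <- sampleSegments(SegmentSpec(nSegments = 10000L,
                                       totalMu = 10000 * 12.4,
                                       smallWeight = 0.4,
                                       lowMuRange = c(1, 4),
                                       highMuRange = c(8, 30), seed = 7L))
  expect_lt(abs(smallSegmentFraction(segMix) - 40), 2)
})

test_that("segment spec invariants are enforced", {
  expect_error(SegmentSpec(nSegments = 0L), "nSegments")
  expect_error(SegmentSpec(lowMuRange = c(1, 6)), "below the 5 MU")
  expect_error(SegmentSpec(smallWeight = 1.2), "smallWeight")
})
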