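# Desk-scale end-to-end runs: small grids and forests keep these fast
# while exercising every stage of the ensemble.

smallScenario <- function(seed = 5) {
  sc <- synthLandscape(nBands = 8, shape = c(70, 70),
                       informative = c("band01", "band02"),
                       coefficients = c(1.5, -1.0), seed = seed)
  occ <- samplePresences(sc$truth, n = 120, seed = seed + 1)
  pres <- suppressWarnings(thinToCells(occ, sc$stack, seed = seed + 2))
  list(sc = sc, pres = pres)
}

test_that("ensemble aggregates respect their invariants", {
  s <- smallScenario()
  res <- suppressWarnings(
    runEnsemble(s$sc$stack, s$pres, nIterations = 5, nTrees = 50,
                seed = 11))
  hm <- gridValues(hsiMean(res))
  ok <- !is.na(hm)
  expect_true(all(hm[ok] >= 0 & hm[ok] <= 1))

  probs <- lapply(res@iterations, function(it) gridValues(it$probability))
  lo <- Reduce(pmin, probs); hi <- Reduce(pmax, probs)
  expect_true(all(hm[ok] >= lo[ok] - 1e-12 & hm[ok] <= hi[ok] + 1e-12))

  sdv <- gridValues(hsiSD(res))
  expect_true(all(sdv[!is.na(sdv)] >= 0))
  # population SD recomputed directly at 20 probe cells
  probe <- withr::with_seed(1, sample(which(ok), 20))
  for (i in probe) {
    v <- vapply(probs, `[`, numeric(1), i)
    expect_equal(sdv[i], sqrt(mean((v - mean(v))^2)), tolerance = 1e-12)
  }

  mv <- gridValues(majorityMap(res))
  expect_true(all(mv[!is.na(mv)] %in% c(0, 1)))
  bins <- lapply(res@iterations, function(it) gridValues(it$binary))
  counts <- Reduce(`+`, bins)
  expect_identical(mv[ok], (counts[ok] > 5 / 2) * 1)  # 5 iterations

  expect_equal(sum(meanImportance(res)), 100, tolerance = 1e-6)
  expect_equal(nrow(iterationMetrics(res)), 5)
  m <- iterationMetrics(res)
  expect_true(all(m$auc_roc >= 0 & m$auc_roc <= 1))
  expect_true(all(m$n_pos >= 1 & m$n_neg >= 1))
})

test_that("pseudo-absences stay off water and presence cells in full runs", {
  s <- smallScenario(seed = 21)
  geom <- gridGeometry(s$sc$stack)
  pc <- occurrenceCells(s$pres, geom)[, "cell"]
  env <- standardizeEnvironment(s$sc$stack)
  cm <- clusterEnvironment(env, k = 10, seed = 3)
  el <- eligibleAbsenceCells(cm, pc)
  lay <- buildBlocks(geom, 10)
  counts <- table(lay$blockId[pc])
  for (i in 1:3) {
    absn <- suppressWarnings(samplePseudoabsences(
      el, lay, setNames(as.integer(counts), names(counts)), seed = i))
    ac <- occurrenceCells(absn, geom)[, "cell"]
    expect_length(intersect(ac, pc), 0)
    expect_false(any(is.na(s$sc$stack@bands[[1]][ac])))  # not on water
    expect_equal(length(absn), length(s$pres))           # global balance
  }
})

test_that("the ensemble is reproducible bit-for-bit under one seed", {
  s <- smallScenario(seed = 31)
  r1 <- suppressWarnings(runEnsemble(s$sc$stack, s$pres, nIterations = 3,
                                     nTrees = 40, seed = 17))
  r2 <- suppressWarnings(runEnsemble(s$sc$stack, s$pres, nIterations = 3,
                                     nTrees = 40, seed = 17))
  expect_identical(gridValues(hsiMean(r1)), gridValues(hsiMean(r2)))
  expect_identical(iterationMetrics(r1), iterationMetrics(r2))
  expect_identical(meanImportance(r1), meanImportance(r2))
  r3 <- suppressWarnings(runEnsemble(s$sc$stack, s$pres, nIterations = 3,
                                     nTrees = 40, seed = 18))
  expect_false(identical(iterationMetrics(r1), iterationMetrics(r3)))
})

test_that("the pipeline writes its outputs, manifest and area table", {
  out <- withr::local_tempdir()
  cfg <- list(synthetic = list(nBands = 6, shape = c(50, 50),
                               informative = c("band01", "band02"),
                               coefficients = c(1.5, -1.0),
                               nPresences = 80,
                               years = c("2022", "2023")),
              nIterations = 3, nTrees = 40, seed = 9)
  mf <- suppressWarnings(suppressMessages(runPipeline(cfg, outDir = out)))
  expect_true(file.exists(file.path(out, "2022_hsi_mean.asc")))
  expect_true(file.exists(file.path(out, "2023_majority_binary.asc")))
  expect_true(file.exists(file.path(out, "2022_metrics.csv")))
  expect_true(file.exists(file.path(out, "2023_importance.csv")))
  expect_true(file.exists(file.path(out, "change_2022_2023.asc")))
  expect_true(file.exists(file.path(out, "manifest.json")))

  # area summary holds first differences of its own area column
  area <- read.csv(file.path(out, "area_summary.csv"))
  expect_equal(area$annual_change_km2[2],
               diff(area$suitable_km2), tolerance = 1e-9)
  # change map equals the difference of the written HSI maps
  d <- gridValues(readRaster(file.path(out, "change_2022_2023.asc")))
  a <- gridValues(readRaster(file.path(out, "2022_hsi_mean.asc")))
  b <- gridValues(readRaster(file.path(out, "2023_hsi_mean.asc")))
  expect_equal(d, b - a, tolerance = 1e-9)

  # same master seed -> byte-identical metrics
  out2 <- withr::local_tempdir()
  suppressWarnings(suppressMessages(runPipeline(cfg, outDir = out2)))
  expect_identical(readLines(file.path(out2, "2023_metrics.csv")),
                   readLines(file.path(out, "2023_metrics.csv")))
  expect_identical(unname(tools::md5sum(file.path(out2,
                                                  "2023_hsi_mean.asc"))),
                   unname(tools::md5sum(file.path(out,
                                                  "2023_hsi_mean.asc"))))
})

test_that("the command-line wrapper simulates a scenario from a config", {
  script <- system.file("scripts", "sdm.R", package = "sdmscape")
  expect_true(nzchar(script))
  out <- withr::local_tempdir()
  cfgPath <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(synthetic = list(nBands = 4, shape = c(30, 30),
                                         nPresences = 40),
                        seed = 3, outDir = out), cfgPath)
  res <- system2("Rscript", c(script, "simulate", "--config", cfgPath),
                 stdout = TRUE, stderr = TRUE)
  expect_true(is.null(attr(res, "status")) || attr(res, "status") == 0L)
  expect_true(file.exists(file.path(out, "presences.csv")))
  expect_true(file.exists(file.path(out, "water.asc")))
  expect_true(file.exists(file.path(out, "stack", "bands.json")))
  st <- readStack(file.path(out, "stack"))
  expect_equal(nBands(st), 11)  # 4 continuous + 6 land cover + roads
})
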