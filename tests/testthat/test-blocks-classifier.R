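test_that("block tiling follows ceiling arithmetic with row-major ids", {
  g20 <- list(nrow = 20, ncol = 20, cellSize = 30, origin = c(0, 600))
  expect_equal(buildBlocks(g20, 10)$nBlocks, 4)
  g25 <- list(nrow = 25, ncol = 25, cellSize = 30, origin = c(0, 750))
  expect_equal(buildBlocks(g25, 10)$nBlocks, 9)  # 3 x 3 with truncation
  lay1 <- buildBlocks(g20, 1)
  expect_equal(lay1$nBlocks, 400)  # every cell its own block
  lay <- buildBlocks(g20, 10)
  expect_equal(lay$blockId[1, 1], 1)
  expect_equal(lay$blockId[1, 11], 2)
  expect_equal(lay$blockId[11, 1], 3)
})

test_that("block partitioning is seeded, sized and balanced over seeds", {
  lay <- buildBlocks(list(nrow = 40, ncol = 40, cellSize = 30,
                          origin = c(0, 1200)), 10)
  occ <- 1:10
  p <- partitionBlocks(lay, occ, 0.7, seed = 5)
  expect_equal(sum(p == "train"), 7)
  expect_equal(sum(p == "validation"), 3)
  expect_identical(p, partitionBlocks(lay, occ, 0.7, seed = 5))
  expect_error(partitionBlocks(lay, 1, 0.7, seed = 1), "occupied block")

  freq <- rowMeans(vapply(1:1000, function(s)
    partitionBlocks(lay, occ, 0.7, seed = s) == "train",
    logical(10)))
  expect_true(all(abs(freq - 0.7) < 0.05))
})

test_that("training tables carry band values, labels and partitions", {
  st <- makeStack(nBands = 4, nrow = 20, ncol = 20, seed = 3)
  geom <- gridGeometry(st)
  lay <- buildBlocks(geom, 10)
  pres <- occurrenceSet(x = c(15, 45, 315, 345, 400),
                        y = c(15, 45, 315, 345, 500))
  absn <- occurrenceSet(x = c(75, 105, 375, 435, 500),
                        y = c(75, 105, 375, 435, 560))
  part <- c("1" = "train", "4" = "validation")
  tab <- extractTrainingTable(st, pres, absn, lay, part)
  expect_equal(nrow(tab), 10)
  expect_equal(sum(tab$label), 5)
  expect_identical(intersect(colnames(tab), bandNames(st)), bandNames(st))
  # feature values equal direct cell lookup at random probes
  probes <- withr::with_seed(4, sample(10, 5))
  for (i in probes) {
    pts <- rbind(pres@coords, absn@coords)
    rc <- occurrenceCells(occurrenceSet(pts[i, 1], pts[i, 2]), geom)
    for (nm in bandNames(st))
      expect_equal(tab[i, nm], gridValues(getBand(st, nm))[rc[1, "row"],
                                                           rc[1, "col"]])
  }
  # a point on a masked cell is dropped with a warning
  stM <- applyWaterMask(st, rasterGrid({
    w <- matrix(0, 20, 20); w[20, 1] <- 1; w  # cell of the (15, 15) point
  }, geom$cellSize, geom$origin))
  expect_warning(tab2 <- extractTrainingTable(stM, pres, absn, lay, part),
                 "masked")
  expect_equal(nrow(tab2), 9)
})

test_that("the classifier separates, is seeded, and rejects bad input", {
  withr::with_seed(10, {
    x <- matrix(rnorm(400), 100, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- as.integer(x[, 2] > 0)  # perfectly separable on f2
  })
  fit <- fitClassifier(x, y, nTrees = 60, seed = 9)
  expect_equal(mean((predictProbability(fit, x) >= 0.5) == y), 1)
  expect_gt(fit$importance[["f2"]], max(fit$importance[c("f1", "f3",
                                                         "f4")]))
  fit2 <- fitClassifier(x, y, nTrees = 60, seed = 9)
  expect_identical(predictProbability(fit2, x), predictProbability(fit, x))
  fit3 <- fitClassifier(x, y, nTrees = 60, seed = 10)
  expect_false(identical(predictProbability(fit3, x),
                         predictProbability(fit, x)))
  expect_error(fitClassifier(x, rep(1, 100)), "single class")
  expect_error(fitClassifier(x[1, , drop = FALSE], 1), "2 training rows")
})

test_that("held-out AUC on pure-noise labels stays near chance", {
  aucs <- withr::with_seed(123, replicate(50, {
    x <- matrix(rnorm(200 * 5), 200, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- c(0, 1, rbinom(198, 1, 0.5))
    tr <- 1:120; te <- 121:200
    fit <- fitClassifier(x[tr, ], y[tr], nTrees = 40,
                         seed = sample.int(1e6, 1))
    aucROC(predictProbability(fit, x[te, ]), y[te])
  }))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
  expect_gt(mean(aucs > 0.3 & aucs < 0.7), 0.9)
})

test_that("surface prediction binarizes at the threshold and keeps masks", {
  st <- makeStack(nBands = 3, nrow = 8, ncol = 8, seed = 17)
  geom <- gridGeometry(st)
  water <- rasterGrid({
    w <- matrix(0, 8, 8); w[3, 4] <- 1; w
  }, geom$cellSize, geom$origin)
  stM <- applyWaterMask(st, water)
  withr::with_seed(18, {
    x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, bandNames(st)))
    y <- as.integer(x[, 1] + rnorm(100, 0, 0.4) > 0)
  })
  fit <- fitClassifier(x, y, nTrees = 40, seed = 2)
  surf <- predictSurface(fit, stM)
  p <- gridValues(surf$probability); b <- gridValues(surf$binary)
  expect_true(all(p[!is.na(p)] >= 0 & p[!is.na(p)] <= 1))
  expect_identical(b[!is.na(b)], as.numeric(p[!is.na(p)] >= 0.5))
  expect_true(is.na(p[3, 4]) && is.na(b[3, 4]))
  expect_error(predictSurface(fit, makeStack(nBands = 2)), "lacks band")
})

test_that("majority vote matches brute-force counting with ties to 0", {
  mk <- function(v) makeGrid(2, 2, matrix(v, 2, 2))
  six <- c(lapply(1:6, function(i) mk(1)), lapply(1:4, function(i) mk(0)))
  expect_true(all(gridValues(majorityVote(six)) == 1))
  tie <- c(lapply(1:5, function(i) mk(1)), lapply(1:5, function(i) mk(0)))
  expect_true(all(gridValues(majorityVote(tie)) == 0))

  withr::with_seed(55, for (i in 1:20) {
    grids <- lapply(1:10, function(j)
      makeGrid(4, 4, matrix(rbinom(16, 1, 0.5), 4, 4)))
    mv <- gridValues(majorityVote(grids))
    counts <- Reduce(`+`, lapply(grids, gridValues))
    expect_identical(mv, (counts >= 6) * 1)
  })
})

test_that("importance aggregation normalizes then averages to 100", {
  expect_equal(unname(aggregateImportance(list(c(a = 2, b = 1, c = 1)))),
               c(50, 25, 25))
  same <- list(c(a = 10, b = 30), c(a = 10, b = 30))
  expect_equal(aggregateImportance(same), c(a = 25, b = 75))
  withr::with_seed(66, for (i in 1:20) {
    vs <- lapply(1:10, function(j) setNames(runif(8), paste0("p", 1:8)))
    expect_equal(sum(aggregateImportance(vs)), 100, tolerance = 1e-9)
  })
  expect_error(aggregateImportance(list(c(a = 0, b = 0))), "non-positive")
})

test_that("predictor subsetting applies the relative-contribution cut", {
  imp <- c(A = 40, B = 10, C = 5, D = 3.6, E = 3.4, F = 2)
  expect_identical(subsetPredictors(imp, 3.5), c("A", "B", "C", "D"))
  expect_identical(subsetPredictors(imp, 0), names(sort(imp, TRUE)))
  expect_warning(none <- subsetPredictors(imp, 99), "no predictor")
  expect_length(none, 0)
  # a crafted vector with exactly seven predictors above 3.5 percent
  v <- c(r = 30, e = 15, n1 = 10, n2 = 9, s1 = 8, s2 = 6, re = 4,
         x1 = 3.4, x2 = 3, x3 = 2.6, x4 = 2.4, x5 = 2.2, x6 = 2,
         x7 = 1.8, x8 = 1.6)
  expect_length(subsetPredictors(v, 3.5), 7)
})
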