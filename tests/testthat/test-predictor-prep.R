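test_that("road buffering marks exactly the cells within the buffer", {
  # vertical road along x = 0 on 30 m cells: centers at |x| = 15 and 45
  # are inside a 50 m buffer, 75 is not
  geom <- list(nrow = 2, ncol = 4, cellSize = 30, origin = c(0, 60))
  road <- roadNetwork(list(cbind(c(0, 0), c(-1000, 1000))))
  g <- bufferRasterizeRoads(road, 50, geom)
  expect_equal(gridValues(g)[1, ], c(1, 1, 0, 0))  # centers 15,45,75,105

  tiny <- bufferRasterizeRoads(roadNetwork(list(cbind(c(15, 15),
                                                      c(-10, 100)))),
                               0.01, geom)
  expect_equal(sum(gridValues(tiny)), 2)  # only the x = 15 column centers
})

test_that("road rasterization agrees with brute-force segment distance", {
  geom <- list(nrow = 12, ncol = 10, cellSize = 30, origin = c(0, 360))
  line <- withr::with_seed(11, cbind(runif(5, 0, 300), runif(5, 0, 360)))
  g <- bufferRasterizeRoads(roadNetwork(list(line)), 45, geom)
  for (r in seq_len(12)) for (c in seq_len(10)) {
    px <- (c - 0.5) * 30; py <- 360 - (r - 0.5) * 30
    expect_equal(gridValues(g)[r, c],
                 as.numeric(bruteSegDist(px, py, line) <= 45))
  }
})

test_that("road buffer is symmetric for a symmetric layout", {
  geom <- list(nrow = 8, ncol = 8, cellSize = 30, origin = c(0, 240))
  mid <- roadNetwork(list(cbind(c(120, 120), c(-10, 250))))  # center line
  v <- gridValues(bufferRasterizeRoads(mid, 70, geom))
  expect_identical(v, v[, ncol(v):1])  # mirror in x
  expect_warning(z <- bufferRasterizeRoads(roadNetwork(list()), 50, geom),
                 "empty road network")
  expect_true(all(gridValues(z) == 0))
})

test_that("decibel conversion matches the closed form and masks <= 0", {
  g <- makeGrid(1, 4, matrix(c(1, 0.1, 0.5, -2), 1, 4))
  expect_warning(db <- toDecibel(g), "non-positive")
  expect_equal(gridValues(db)[1, 1:3],
               c(0, -10, 10 * log10(0.5)), tolerance = 1e-12)
  expect_true(is.na(gridValues(db)[1, 4]))
  # strictly monotone on positive values
  v <- withr::with_seed(2, sort(runif(20, 0.01, 5)))
  out <- gridValues(toDecibel(makeGrid(1, 20, matrix(v, 1, 20))))
  expect_true(all(diff(as.vector(out)) > 0))
})

test_that("vegetation indices match their closed forms", {
  st <- makeSpectralStack(nir = matrix(0.8), red = matrix(0.2),
                          green = matrix(0.4), re1 = matrix(0.5))
  val <- function(nm, ...) gridValues(computeIndex(nm, st, ...))[1, 1]
  expect_equal(val("NDVI"), 0.6)
  expect_equal(val("RVI"), 4)
  expect_equal(val("SAVI", L = 0.5), (0.6 / 1.5) * 1.5)
  expect_equal(val("GNDVI"), (0.8 - 0.4) / (0.8 + 0.4))
  expect_equal(val("NDRE"), (0.8 - 0.5) / (0.8 + 0.5))
  expect_equal(val("CCCI"), ((0.8 - 0.5) / (0.8 + 0.5)) / 0.6)
  expect_equal(val("TVI"), sqrt(0.6 + 0.5))
  expect_equal(val("TVI", tviForm = "additive"), 1.1)

  eq <- makeSpectralStack(nir = matrix(0.3), red = matrix(0.3))
  expect_equal(gridValues(computeIndex("NDVI", eq))[1, 1], 0)
  expect_equal(gridValues(computeIndex("RVI", eq))[1, 1], 1)
})

test_that("NDVI equals the GNDVI formula with Green replaced by Red", {
  nir <- withr::with_seed(5, matrix(runif(16, 0.2, 0.9), 4))
  red <- withr::with_seed(6, matrix(runif(16, 0.05, 0.5), 4))
  stA <- makeSpectralStack(nir = nir, red = red)
  stB <- makeSpectralStack(nir = nir, red = red, green = red)
  expect_equal(gridValues(computeIndex("NDVI", stA)),
               gridValues(computeIndex("GNDVI", stB)))
})

test_that("zero denominators are masked, missing bands error", {
  st <- makeSpectralStack(nir = matrix(c(0.5, 0)), red = matrix(c(-0.5, 0)))
  v <- gridValues(computeIndex("NDVI", st))
  expect_true(all(is.na(v)))  # both cells have NIR + Red == 0
  expect_error(computeIndex("GNDVI", st), "Green")
  expect_error(computeIndex("SAVI", st, L = 0), "L > 0")
})

test_that("one-hot land cover produces one band per non-water class", {
  classes <- c("Bare_Ground", "Bushland", "Forest", "Grassland", "Wetland",
               "Woodland")
  codes <- withr::with_seed(9, matrix(sample(6, 36, TRUE), 6, 6))
  codes[1, 1] <- NA
  g <- rasterGrid(codes, 30, c(0, 180))
  bands <- onehotLandcover(g, classes)
  expect_identical(names(bands), classes)
  sums <- Reduce(`+`, lapply(bands, gridValues))
  expect_true(all(sums[!is.na(sums)] == 1))  # per-cell band sum
  expect_true(is.na(sums[1, 1]))

  allGrass <- onehotLandcover(rasterGrid(matrix(4, 3, 3), 30, c(0, 90)),
                              classes)
  expect_true(all(gridValues(allGrass$Grassland) == 1))
  expect_true(all(gridValues(allGrass$Forest) == 0))

  # water carries no band and unknown codes error
  withWater <- onehotLandcover(rasterGrid(matrix(c(1, 7), 1, 2), 30,
                                          c(0, 30)),
                               c(classes, "Water"))
  expect_false("Water" %in% names(withWater))
  expect_equal(sum(vapply(withWater, function(b) gridValues(b)[1, 2],
                          numeric(1))), 0)
  expect_error(onehotLandcover(rasterGrid(matrix(9, 1, 1), 30, c(0, 30)),
                               classes), "class code")
})

test_that("stack assembly enforces geometry and name uniqueness", {
  one <- assembleStack(list(a = matrix(1, 2, 2)), cellSize = 30,
                       origin = c(0, 60))
  expect_equal(nBands(one), 1)
  expect_error(assembleStack(list(a = matrix(1, 2, 2),
                                  b = matrix(1, 3, 3)),
                             cellSize = 30, origin = c(0, 60)), "shape")
  expect_error(assembleStack(list(a = matrix(1, 2, 2),
                                  a = matrix(2, 2, 2)),
                             cellSize = 30, origin = c(0, 60)),
               "duplicate")
  # unified mask: an NA anywhere masks that cell in every band
  a <- matrix(1, 2, 2); a[1, 2] <- NA
  st <- assembleStack(list(a = a, b = matrix(2, 2, 2)), cellSize = 30,
                      origin = c(0, 60))
  expect_true(is.na(st@bands$b[1, 2]))
})

test_that("the full emulated predictor roster assembles to 52 bands", {
  nr <- 6; nc <- 6
  mk <- withr::with_seed(78, {
    nms <- c("Roads",
             "Aspect", "Elevation", "Slope", "TPI", "TWI",
             "AET", "PET", "TMMX", "TMMN", "P", "SOIL",
             "Sand_TS", "Sand_SS", "Clay_TS", "Clay_SS", "C_TS", "C_SS",
             "ECC_TS", "ECC_SS", "N_TS", "N_SS", "P_TS", "P_SS", "pH_TS",
             "pH_SS",
             "Bare_Ground", "Bushland", "Forest", "Grassland", "Wetland",
             "Woodland",
             "VH", "VV",
             "Blue", "Green", "Red", "RE1", "RE2", "RE3", "NIR", "RE4",
             "SWIR1", "SWIR2")
    setNames(lapply(nms, function(n) matrix(runif(nr * nc, 0.05, 0.9),
                                            nr, nc)), nms)
  })
  spectral <- assembleStack(mk[c("Blue", "Green", "Red", "RE1", "RE2",
                                 "RE3", "NIR", "RE4", "SWIR1", "SWIR2")],
                            cellSize = 30, origin = c(0, nr * 30))
  indices <- list(CCCI = computeIndex("CCCI", spectral),
                  GNDVI = computeIndex("GNDVI", spectral),
                  NDRE = computeIndex("NDRE", spectral),
                  NDVI = computeIndex("NDVI", spectral),
                  RVI = computeIndex("RVI", spectral),
                  SAVI_L05 = computeIndex("SAVI", spectral, L = 0.5),
                  SAVI_L1 = computeIndex("SAVI", spectral, L = 1),
                  TVI = computeIndex("TVI", spectral))
  full <- assembleStack(c(mk, indices), cellSize = 30,
                        origin = c(0, nr * 30))
  expect_equal(nBands(full), 52)
  expect_false(anyDuplicated(bandNames(full)) > 0)
})
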