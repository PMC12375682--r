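# Synthetic landscapes with the statistical structure the pipeline
# assumes: spatially autocorrelated continuous predictors, categorical
# land cover, a road polyline with sampling bias, a water mask, and a known
# logistic true-suitability surface for parameter-recovery experiments.

# banded Gaussian smoothing matrix, rows normalized so edges keep unit mass
.smoothMatrix <- function(n, sigma) {
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  s <- exp(-d^2 / (2 * sigma^2))
  s[d > ceiling(3 * sigma)] <- 0
  s / rowSums(s)
}

#' Spatially autocorrelated Gaussian random field
#'
#' White noise smoothed with a separable Gaussian kernel of the given
#' correlation length (in cells), then standardized to mean 0 and unit
#' population variance over all cells. `correlationLength = 0` is plain
#' standardized white noise. Deterministic per seed.
#'
#' @param shape integer `(nrow, ncol)`.
#' @param correlationLength Gaussian kernel scale in cells (>= 0).
#' @param seed integer seed.
#' @param cellSize,origin geometry of the returned grid.
#' @return a [RasterGrid-class].
#' @export
gaussianField <- function(shape, correlationLength = 8, seed = 1L,
                          cellSize = 30, origin = c(0, shape[1] * cellSize)) {
  stopifnot(correlationLength >= 0)
  w <- withr::with_seed(seed,
                        matrix(stats::rnorm(shape[1] * shape[2]),
                               shape[1], shape[2]))
  if (correlationLength > 0) {
    sr <- .smoothMatrix(shape[1], correlationLength)
    sc <- .smoothMatrix(shape[2], correlationLength)
    w <- sr %*% w %*% t(sc)
  }
  w <- (w - mean(w)) / sqrt(mean((w - mean(w))^2))
  rasterGrid(w, cellSize = cellSize, origin = origin)
}

.defaultLandcover <- c("Bare_Ground", "Bushland", "Forest", "Grassland",
                       "Wetland", "Woodland")

#' Generate a synthetic landscape
#'
#' Builds a predictor stack of `nBands` autocorrelated continuous bands,
#' one-hot land-cover bands (thresholded from an auxiliary field), and a
#' buffered-road binary band; a water mask; and the known true suitability
#' surface
#' \deqn{P(presence) = logistic(\beta_0 + \sum_j \beta_j z_j + \beta_r\,road)}
#' where the informative \eqn{z_j} are a named subset of the continuous
#' bands. Defaults mirror a desk-scale version of a savannah-park predictor
#' archive: a 200 x 200 grid of 30 m cells, 20 continuous bands of which 3
#' are informative (\eqn{\beta} = 1.5, -1.0, 0.8), a road effect of 1.0 and
#' 5 percent water.
#'
#' @param nBands number of continuous predictor bands.
#' @param shape grid `(nrow, ncol)`.
#' @param cellSize cell size in metres.
#' @param informative names of the informative continuous bands.
#' @param coefficients logistic coefficients, one per informative band.
#' @param roadCoefficient logistic coefficient of the road indicator.
#' @param intercept logistic intercept (baseline log-odds).
#' @param waterFraction fraction of cells masked as water.
#' @param landcoverClasses land-cover class names (one-hot expanded).
#' @param correlationLength autocorrelation scale in cells.
#' @param nRoads number of random road polylines crossing the extent.
#' @param roadBufferM road buffer distance in metres.
#' @param biasStrength default road sampling-bias multiplier stored in the
#'   truth object.
#' @param seed master seed.
#' @return list with `stack` ([PredictorStack-class]), `truth` (list:
#'   `suitability` grid, `informativeBands`, `coefficients`,
#'   `roadCoefficient`, `roadGrid`, `biasStrength`), `water`
#'   ([RasterGrid-class]) and `roads` ([RoadNetwork-class]).
#' @export
synthLandscape <- function(nBands = 20L, shape = c(200L, 200L),
                           cellSize = 30,
                           informative = c("band01", "band02", "band03"),
                           coefficients = c(1.5, -1.0, 0.8),
                           roadCoefficient = 1.0, intercept = -2.0,
                           waterFraction = 0.05,
                           landcoverClasses = .defaultLandcover,
                           correlationLength = 4, nRoads = 8L,
                           roadBufferM = 50,
                           biasStrength = 5, seed = 1L) {
  if (length(informative) != length(coefficients))
    stop("one coefficient per informative band required", call. = FALSE)
  bandNms <- sprintf("band%02d", seq_len(nBands))
  if (!all(informative %in% bandNms))
    stop("informative bands must be among the continuous bands",
         call. = FALSE)
  geom <- list(nrow = shape[1], ncol = shape[2], cellSize = cellSize,
               origin = c(0, shape[1] * cellSize))

  fields <- lapply(seq_len(nBands), function(j)
    gaussianField(shape, correlationLength, seed = seed + 100L + j,
                  cellSize = cellSize, origin = geom$origin))
  names(fields) <- bandNms

  if (length(landcoverClasses)) {
    lcField <- gaussianField(shape, correlationLength, seed = seed + 90L,
                             cellSize = cellSize, origin = geom$origin)
    qs <- stats::quantile(lcField@values,
                          probs = seq_len(length(landcoverClasses) - 1L) /
                            length(landcoverClasses))
    lcCodes <- matrix(findInterval(lcField@values, qs) + 1L, shape[1],
                      shape[2])
    lcGrid <- rasterGrid(lcCodes, cellSize, geom$origin)
    lcBands <- onehotLandcover(lcGrid, landcoverClasses)
  } else lcBands <- list()

  wField <- gaussianField(shape, correlationLength, seed = seed + 91L,
                          cellSize = cellSize, origin = geom$origin)
  wThr <- stats::quantile(wField@values, probs = waterFraction)
  water <- rasterGrid((wField@values <= wThr) * 1, cellSize, geom$origin)

  ext <- .extent(geom)
  roads <- withr::with_seed(seed + 92L, {
    oneRoad <- function(horizontal) {
      # piecewise polyline crossing the extent, random-walk cross-track
      nv <- 7L
      along <- if (horizontal) c(ext["xmin"], ext["xmax"])
               else c(ext["ymin"], ext["ymax"])
      across <- if (horizontal) c(ext["ymin"], ext["ymax"])
                else c(ext["xmin"], ext["xmax"])
      span <- across[2] - across[1]
      a <- seq(along[1], along[2], length.out = nv)
      b <- numeric(nv)
      b[1] <- stats::runif(1, across[1] + 0.1 * span, across[2] - 0.1 * span)
      for (i in 2:nv)
        b[i] <- min(max(b[i - 1] + stats::runif(1, -1, 1) * 0.15 * span,
                        across[1] + 0.05 * span),
                    across[2] - 0.05 * span)
      if (horizontal) cbind(a, b) else cbind(b, a)
    }
    horiz <- rep_len(c(TRUE, FALSE), nRoads)
    roadNetwork(lapply(horiz, oneRoad))
  })
  roadGrid <- bufferRasterizeRoads(roads, roadBufferM, geom)

  bands <- c(fields, lcBands, list(Roads = roadGrid))
  stack <- assembleStack(bands, cellSize = cellSize, origin = geom$origin)
  stack <- applyWaterMask(stack, water)

  lin <- matrix(intercept, shape[1], shape[2])
  for (j in seq_along(informative))
    lin <- lin + coefficients[j] * fields[[informative[j]]]@values
  lin <- lin + roadCoefficient * roadGrid@values
  suit <- stats::plogis(lin)
  suit[water@values == 1] <- NA_real_
  truth <- list(suitability = rasterGrid(suit, cellSize, geom$origin),
                informativeBands = informative,
                coefficients = coefficients,
                roadCoefficient = roadCoefficient,
                roadGrid = roadGrid, biasStrength = biasStrength)
  list(stack = stack, truth = truth, water = water, roads = roads)
}

#' Sample presence points from a known suitability surface
#'
#' Draws `n` distinct cells without replacement with probability
#' proportional to `suitability * (1 + bias * road)` — emulating field
#' campaigns whose access is largely restricted to the road network — and
#' places one point per drawn cell at the cell center plus sub-cell
#' jitter. Water (masked) cells are never sampled. Deterministic per seed.
#'
#' @param truth truth object from [synthLandscape()].
#' @param n number of presence points.
#' @param seed integer seed.
#' @param bias road bias multiplier (defaults to the truth's
#'   `biasStrength`).
#' @param jitter half-width of the within-cell jitter as a fraction of the
#'   cell size (0 places points exactly at centers).
#' @return an [OccurrenceSet-class].
#' @export
samplePresences <- function(truth, n = 400L, seed = 1L, bias = NULL,
                            jitter = 0.45) {
  suitGrid <- truth$suitability
  if (is.null(bias)) bias <- truth$biasStrength %||% 0
  stopifnot(bias >= 0, jitter >= 0, jitter < 0.5)
  geom <- gridGeometry(suitGrid)
  suit <- suitGrid@values
  road <- truth$roadGrid@values
  idx <- which(!is.na(suit))
  w <- suit[idx] * (1 + bias * road[idx])
  if (n > sum(w > 0))
    stop("n exceeds the number of sampleable cells", call. = FALSE)
  withr::with_seed(seed, {
    cells <- idx[sample.int(length(idx), n, prob = w)]
    ctr <- .cellCenter(.linearToRC(cells, geom), geom)
    dx <- stats::runif(n, -jitter, jitter) * geom$cellSize
    dy <- stats::runif(n, -jitter, jitter) * geom$cellSize
    occurrenceSet(ctr[, "x"] + dx, ctr[, "y"] + dy)
  })
}
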