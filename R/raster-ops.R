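#' Mask water cells out of a predictor stack
#'
#' Adds the water cells to every band's nodata mask, so that no value at a
#' water cell participates in any downstream statistic, clustering step or
#' model fit. The masked-cell count can only grow.
#'
#' @param stack a [PredictorStack-class].
#' @param water a [RasterGrid-class] on the same geometry; cells with a
#'   non-zero, non-`NA` value are water.
#' @return the masked [PredictorStack-class].
#' @export
applyWaterMask <- function(stack, water) {
  stopifnot(is(stack, "PredictorStack"), is(water, "RasterGrid"))
  .stopGeometry(stack, water, "stack and water mask")
  wet <- !is.na(water@values) & water@values != 0
  bands <- lapply(stack@bands, function(b) { b[wet] <- NA_real_; b })
  new("PredictorStack", bands = bands, cellSize = stack@cellSize,
      origin = stack@origin)
}

#' Bilinear resampling to a finer grid
#'
#' Resamples a coarse raster to a target geometry: each target cell-center
#' value is the bilinear interpolation of the four surrounding coarse
#' cell-center values (the standard treatment for climate layers that are
#' much coarser than the working resolution). A target cell is masked when
#' any of its four support cells is nodata, or when its center lies outside
#' the coarse cell-center lattice — interpolation never fabricates values
#' near missing data.
#'
#' @param coarse a [RasterGrid-class] with cell size >= the target's.
#' @param target target geometry: a [RasterGrid-class], a
#'   [PredictorStack-class] or a `list(nrow, ncol, cellSize, origin)`.
#' @return a [RasterGrid-class] on the target geometry.
#' @export
bilinearResample <- function(coarse, target) {
  stopifnot(is(coarse, "RasterGrid"))
  tg <- .asGeometry(target)
  cg <- gridGeometry(coarse)
  if (cg$cellSize < tg$cellSize - 1e-9)
    stop("coarse cell size must be >= target cell size", call. = FALSE)
  te <- .extent(tg); ce <- .extent(cg)
  if (te["xmin"] < ce["xmin"] - 1e-9 || te["xmax"] > ce["xmax"] + 1e-9 ||
      te["ymin"] < ce["ymin"] - 1e-9 || te["ymax"] > ce["ymax"] + 1e-9)
    stop("target extent outside coarse grid", call. = FALSE)

  ctr <- .allCenters(tg)
  # fractional position on the coarse cell-center lattice (0-based)
  gx <- (ctr[, "x"] - (cg$origin[1] + cg$cellSize / 2)) / cg$cellSize
  gy <- ((cg$origin[2] - cg$cellSize / 2) - ctr[, "y"]) / cg$cellSize
  c0 <- floor(gx); r0 <- floor(gy)
  fx <- gx - c0; fy <- gy - r0

  ok <- c0 >= 0 & c0 + 1 <= cg$ncol - 1 & r0 >= 0 & r0 + 1 <= cg$nrow - 1
  out <- rep(NA_real_, nrow(ctr))
  if (any(ok)) {
    cv <- coarse@values
    i00 <- (c0[ok]) * cg$nrow + r0[ok] + 1
    i10 <- i00 + 1                       # one row south
    i01 <- i00 + cg$nrow                 # one col east
    i11 <- i01 + 1
    v <- (1 - fy[ok]) * ((1 - fx[ok]) * cv[i00] + fx[ok] * cv[i01]) +
         fy[ok] * ((1 - fx[ok]) * cv[i10] + fx[ok] * cv[i11])
    out[ok] <- v  # NA support propagates through the arithmetic
  }
  rasterGrid(matrix(out, nrow = tg$nrow, ncol = tg$ncol),
             cellSize = tg$cellSize, origin = tg$origin)
}

#' Per-cell temporal median composite
#'
#' Cell-wise median across a sequence of co-registered grids (e.g. monthly
#' climate layers composited to one value per year). Masked values are
#' dropped per cell; a cell is masked only if it is masked in every input.
#' Even counts use the standard convention, the mean of the central pair.
#'
#' @param grids list of [RasterGrid-class] sharing one geometry.
#' @return a [RasterGrid-class].
#' @export
temporalMedian <- function(grids) {
  if (length(grids) < 1L) stop("need at least one grid", call. = FALSE)
  g1 <- grids[[1L]]
  for (g in grids) .stopGeometry(g1, g, "grids")
  m <- matrix(vapply(grids, function(g) as.vector(g@values),
                     numeric(length(g1@values))),
              nrow = length(g1@values), ncol = length(grids))
  if (length(grids) == 1L) med <- m[, 1L]
  else med <- apply(m, 1L, stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  rasterGrid(matrix(med, nrow(g1@values), ncol(g1@values)),
             cellSize = g1@cellSize, origin = g1@origin)
}
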