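#' @useDynLib sdmscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Single-band raster grid
#'
#' A rectangular single-band raster in a projected metric coordinate system.
#' Values are stored as a numeric matrix with row 1 the northernmost row;
#' nodata cells are `NA`. The georeferencing is the top-left corner of the
#' top-left cell (`origin`) plus a square cell size in metres.
#'
#' A map point \eqn{(x, y)} falls in column
#' \eqn{\lfloor (x - x_0)/c \rfloor + 1} and row
#' \eqn{\lfloor (y_0 - y)/c \rfloor + 1}: cells are half-open intervals
#' `[edge, edge + cellSize)`, so a point on a shared edge belongs to exactly
#' one cell.
#'
#' @slot values numeric matrix of cell values; `NA` marks nodata.
#' @slot cellSize positive cell edge length in metres.
#' @slot origin numeric of length 2, map coordinates `(x, y)` of the
#'   top-left corner of the grid.
#'
#' @seealso [rasterGrid()], [nodataMask()], [gridGeometry()]
#' @export
setClass("RasterGrid",
  representation(values = "matrix", cellSize = "numeric", origin = "numeric"))

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@values) && !is.logical(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (length(object@cellSize) != 1L || is.na(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L || anyNA(object@origin))
    msg <- c(msg, "origin must be numeric (x, y) of length 2")
  if (length(msg)) msg else TRUE
})

#' Multi-band predictor stack
#'
#' Named, co-registered predictor bands sharing a single geometry and a
#' single nodata mask. Band matrices are stored in insertion order; after
#' [applyWaterMask()] (or construction with `unifyMask = TRUE`, the default
#' of [assembleStack()]) the `NA` pattern of every band is identical, so a
#' cell is either available in all bands or in none.
#'
#' @slot bands named list of numeric matrices, all of identical dimension.
#' @slot cellSize shared cell size in metres.
#' @slot origin shared top-left corner `(x, y)`.
#'
#' @seealso [assembleStack()], [getBand()], [bandNames()]
#' @export
setClass("PredictorStack",
  representation(bands = "list", cellSize = "numeric", origin = "numeric"))

setValidity("PredictorStack", function(object) {
  msg <- character()
  if (length(object@bands) < 1L)
    msg <- c(msg, "stack must contain at least one band")
  nm <- names(object@bands)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    msg <- c(msg, "band names must be unique and non-empty")
  dims <- lapply(object@bands, dim)
  if (length(unique(dims)) > 1L)
    msg <- c(msg, "all bands must share one matrix dimension")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must be numeric (x, y) of length 2")
  if (length(msg)) msg else TRUE
})

#' Presence / pseudo-absence point set
#'
#' Point coordinates in map units with an optional integer id. Cell indices
#' under a given grid geometry are derived on demand by [occurrenceCells()].
#'
#' @slot coords two-column numeric matrix (`x`, `y`).
#' @slot id integer identifier per point (row number by default).
#'
#' @seealso [loadPoints()], [thinToCells()]
#' @export
setClass("OccurrenceSet",
  representation(coords = "matrix", id = "integer"))

setValidity("OccurrenceSet", function(object) {
  msg <- character()
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "coords must have two columns (x, y)")
  if (nrow(object@coords) && anyNA(object@coords))
    msg <- c(msg, "coords must not contain NA")
  if (length(object@id) != nrow(object@coords))
    msg <- c(msg, "id must have one entry per point")
  if (length(msg)) msg else TRUE
})

#' Road network polylines
#'
#' @slot polylines list of two-column coordinate matrices (map units,
#'   metres); each polyline has at least two vertices.
#' @export
setClass("RoadNetwork", representation(polylines = "list"))

setValidity("RoadNetwork", function(object) {
  for (p in object@polylines) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 2L)
      return("each polyline must be a 2-column matrix with >= 2 vertices")
  }
  TRUE
})

#' Ensemble habitat-suitability result
#'
#' Output of [runEnsemble()]: the per-iteration probability and binary maps,
#' validation metrics and raw importances, together with their aggregates —
#' the mean habitat suitability index (HSI) map, its population standard
#' deviation, the majority-vote binary map and the mean relative variable
#' importance (percent, summing to 100).
#'
#' When the ensemble is run with `predictSurfaces = FALSE` the map slots
#' hold empty grids and only point-level metrics and importances are filled.
#'
#' @slot hsiMean [RasterGrid-class] of mean presence probability in `[0, 1]`.
#' @slot hsiSD [RasterGrid-class] of population SD across iterations.
#' @slot majority [RasterGrid-class] binary majority-vote map.
#' @slot importance named numeric, mean relative importance in percent.
#' @slot metrics data.frame, one row per iteration (auc_roc, auc_pr,
#'   sensitivity, specificity, n_pos, n_neg).
#' @slot iterations list of per-iteration detail (probability/binary grids
#'   if surfaces were predicted, raw importances, partition seeds).
#' @slot config list echoing the full run configuration, seeds included.
#' @export
setClass("EnsembleResult",
  representation(hsiMean = "RasterGrid", hsiSD = "RasterGrid",
                 majority = "RasterGrid", importance = "numeric",
                 metrics = "data.frame", iterations = "list",
                 config = "list"))

#' Interannual HSI change map
#'
#' Per-cell difference `HSI(year_b) - HSI(year_a)` on the continuous
#' probability surfaces; masks of the two inputs are unioned.
#'
#' @slot delta [RasterGrid-class] of differences in `[-1, 1]`.
#' @slot yearA,yearB labels of the two epochs being compared.
#' @export
setClass("ChangeMap",
  representation(delta = "RasterGrid", yearA = "character",
                 yearB = "character"))
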