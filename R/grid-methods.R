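#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = northernmost row); `NA` is nodata.
#' @param cellSize cell edge length in metres.
#' @param origin map coordinates `(x, y)` of the grid's top-left corner.
#' @return a [RasterGrid-class].
#' @examples
#' g <- rasterGrid(matrix(1:9, 3, 3), cellSize = 30, origin = c(0, 90))
#' cellSize(g)
#' @export
rasterGrid <- function(values, cellSize = 30, origin = c(0, nrow(values) * cellSize)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin))
}

#' @rdname RasterGrid-class
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname RasterGrid-class
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)

#' @rdname RasterGrid-class
#' @export
setMethod("gridOrigin", "RasterGrid", function(x) x@origin)

#' @rdname RasterGrid-class
#' @export
setMethod("nodataMask", "RasterGrid", function(x) is.na(x@values))

#' @rdname RasterGrid-class
#' @export
setMethod("gridGeometry", "RasterGrid", function(x)
  list(nrow = nrow(x@values), ncol = ncol(x@values),
       cellSize = x@cellSize, origin = x@origin))

#' @rdname PredictorStack-class
#' @export
setMethod("gridGeometry", "PredictorStack", function(x)
  list(nrow = nrow(x@bands[[1L]]), ncol = ncol(x@bands[[1L]]),
       cellSize = x@cellSize, origin = x@origin))

#' @rdname PredictorStack-class
#' @export
setMethod("bandNames", "PredictorStack", function(x) names(x@bands))

#' @rdname PredictorStack-class
#' @export
setMethod("nBands", "PredictorStack", function(x) length(x@bands))

#' @rdname PredictorStack-class
#' @export
setMethod("getBand", "PredictorStack", function(x, name) {
  if (!name %in% names(x@bands))
    stop("no band named '", name, "' in stack", call. = FALSE)
  rasterGrid(x@bands[[name]], x@cellSize, x@origin)
})

#' @rdname PredictorStack-class
#' @export
setMethod("nodataMask", "PredictorStack", function(x) is.na(x@bands[[1L]]))

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid: %d x %d cells @ %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), object@cellSize,
              object@origin[1], object@origin[2]))
  ok <- !is.na(v)
  cat(sprintf("  %d/%d cells unmasked", sum(ok), length(v)))
  if (any(ok))
    cat(sprintf("; range [%.4g, %.4g]", min(v[ok]), max(v[ok])))
  cat("\n")
})

setMethod("show", "PredictorStack", function(object) {
  g <- gridGeometry(object)
  cat(sprintf("PredictorStack: %d bands, %d x %d cells @ %g m\n",
              length(object@bands), g$nrow, g$ncol, g$cellSize))
  nm <- names(object@bands)
  cat("  bands:", paste(utils::head(nm, 8), collapse = ", "),
      if (length(nm) > 8) sprintf("... (%d more)", length(nm) - 8) else "",
      "\n")
})

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: %d points\n", nrow(object@coords)))
})

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf("EnsembleResult: %d iterations\n", nrow(object@metrics)))
  if (nrow(object@metrics)) {
    m <- colMeans(object@metrics[, c("auc_roc", "auc_pr", "sensitivity",
                                     "specificity")])
    cat(sprintf("  mean AUC_ROC %.3f | AUC_PR %.3f | sens %.3f | spec %.3f\n",
                m[1], m[2], m[3], m[4]))
  }
  top <- utils::head(sort(object@importance, decreasing = TRUE), 5)
  cat("  top importance (%):",
      paste(sprintf("%s %.1f", names(top), top), collapse = ", "), "\n")
})

setMethod("show", "ChangeMap", function(object) {
  d <- object@delta@values
  cat(sprintf("ChangeMap %s -> %s: mean delta %.4f\n", object@yearA,
              object@yearB, mean(d, na.rm = TRUE)))
})

#' @rdname EnsembleResult-class
#' @export
setMethod("hsiMean", "EnsembleResult", function(x) x@hsiMean)

#' @rdname EnsembleResult-class
#' @export
setMethod("hsiSD", "EnsembleResult", function(x) x@hsiSD)

#' @rdname EnsembleResult-class
#' @export
setMethod("majorityMap", "EnsembleResult", function(x) x@majority)

#' @rdname EnsembleResult-class
#' @export
setMethod("meanImportance", "EnsembleResult", function(x) x@importance)

#' @rdname EnsembleResult-class
#' @export
setMethod("iterationMetrics", "EnsembleResult", function(x) x@metrics)
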