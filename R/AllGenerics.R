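#' @rdname RasterGrid-class
#' @param object,x an object.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname RasterGrid-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname RasterGrid-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname RasterGrid-class
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))

#' @rdname RasterGrid-class
#' @export
setGeneric("gridGeometry", function(x) standardGeneric("gridGeometry"))

#' @rdname PredictorStack-class
#' @param x a [PredictorStack-class].
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))

#' @rdname PredictorStack-class
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' @rdname PredictorStack-class
#' @param name band name.
#' @export
setGeneric("getBand", function(x, name) standardGeneric("getBand"))

#' @rdname EnsembleResult-class
#' @param x an [EnsembleResult-class].
#' @export
setGeneric("hsiMean", function(x) standardGeneric("hsiMean"))

#' @rdname EnsembleResult-class
#' @export
setGeneric("hsiSD", function(x) standardGeneric("hsiSD"))

#' @rdname EnsembleResult-class
#' @export
setGeneric("majorityMap", function(x) standardGeneric("majorityMap"))

#' @rdname EnsembleResult-class
#' @export
setGeneric("meanImportance", function(x) standardGeneric("meanImportance"))

#' @rdname EnsembleResult-class
#' @export
setGeneric("iterationMetrics", function(x) standardGeneric("iterationMetrics"))
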