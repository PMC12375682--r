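#' Construct a road network
#'
#' @param polylines list of two-column coordinate matrices in map metres.
#' @return a [RoadNetwork-class].
#' @export
roadNetwork <- function(polylines) {
  polylines <- lapply(polylines, function(p) {
    p <- as.matrix(p); storage.mode(p) <- "double"
    colnames(p) <- c("x", "y"); p
  })
  new("RoadNetwork", polylines = polylines)
}

#' Read roads from GeoJSON
#'
#' Accepts `LineString` and `MultiLineString` features (or bare geometries)
#' in a projected metric CRS.
#'
#' @param path GeoJSON file.
#' @return a [RoadNetwork-class].
#' @export
readRoadsGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path)
  geoms <- switch(gj$type %||% "",
    FeatureCollection = lapply(gj$features, `[[`, "geometry"),
    Feature = list(gj$geometry),
    LineString = , MultiLineString = list(gj),
    stop("unsupported GeoJSON type for roads: ", gj$type, call. = FALSE))
  lines <- list()
  for (g in geoms) {
    cc <- g$coordinates
    if (g$type == "LineString") cc <- list(cc)
    else if (g$type != "MultiLineString")
      stop("road geometry must be LineString/MultiLineString", call. = FALSE)
    for (line in cc)
      lines[[length(lines) + 1L]] <-
        do.call(rbind, lapply(line, function(pt) as.numeric(pt[1:2])))
  }
  roadNetwork(lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# min distance from points (px, py) to one segment, vectorized over points
.pointSegDist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

#' Buffer and rasterize a road network
#'
#' Marks a cell as road-influenced (value 1) when the Euclidean distance
#' from its center to the nearest road segment is at most `bufferM` — the
#' "roads" predictor of the suitability model, e.g. a 50 m buffer on a 30 m
#' grid.
#'
#' @param roads a [RoadNetwork-class].
#' @param bufferM buffer distance in metres (> 0).
#' @param geometry target grid geometry.
#' @return binary [RasterGrid-class] (0/1).
#' @export
bufferRasterizeRoads <- function(roads, bufferM, geometry) {
  stopifnot(is(roads, "RoadNetwork"), bufferM > 0)
  geom <- .asGeometry(geometry)
  n <- geom$nrow * geom$ncol
  if (length(roads@polylines) == 0L) {
    warning("empty road network: returning all-zero grid")
    return(rasterGrid(matrix(0, geom$nrow, geom$ncol), geom$cellSize,
                      geom$origin))
  }
  ctr <- .allCenters(geom)
  dmin <- rep(Inf, n)
  for (line in roads@polylines) {
    for (s in seq_len(nrow(line) - 1L)) {
      d <- .pointSegDist(ctr[, "x"], ctr[, "y"], line[s, 1], line[s, 2],
                         line[s + 1L, 1], line[s + 1L, 2])
      dmin <- pmin(dmin, d)
    }
  }
  rasterGrid(matrix(as.numeric(dmin <= bufferM), geom$nrow, geom$ncol),
             geom$cellSize, geom$origin)
}

#' Convert linear-power backscatter to decibels
#'
#' Radar backscatter processed in natural (linear power) units is converted
#' back to decibels, \eqn{\sigma^0_{dB} = 10 \log_{10}(\sigma^0)}, before
#' entering the model. Non-positive unmasked values have no decibel
#' representation and are masked with a warning.
#'
#' @param linear a [RasterGrid-class] of linear-power values.
#' @return a [RasterGrid-class] in dB.
#' @export
toDecibel <- function(linear) {
  stopifnot(is(linear, "RasterGrid"))
  v <- linear@values
  bad <- !is.na(v) & v <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive cell(s) masked in dB conversion")
    v[bad] <- NA_real_
  }
  rasterGrid(10 * log10(v), linear@cellSize, linear@origin)
}

.indexNames <- c("CCCI", "GNDVI", "NDRE", "NDVI", "RVI", "SAVI", "TVI")

.normDiff <- function(a, b) {
  den <- a + b
  out <- (a - b) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Compute a vegetation index band
#'
#' Computes one of the standard multispectral vegetation indices from the
#' reflectance bands of a predictor stack (band names `NIR`, `Red`,
#' `Green`, and a red-edge band, `RE1` by default):
#' \describe{
#'   \item{NDVI}{\eqn{(NIR - Red)/(NIR + Red)}}
#'   \item{GNDVI}{\eqn{(NIR - Green)/(NIR + Green)}}
#'   \item{NDRE}{\eqn{(NIR - RE)/(NIR + RE)}}
#'   \item{RVI}{\eqn{NIR/Red}}
#'   \item{SAVI}{\eqn{(NIR - Red)/(NIR + Red + L)\,(1 + L)} with soil
#'     adjustment factor `L` (0.5 and 1.0 are the usual predictor pair)}
#'   \item{CCCI}{\eqn{NDRE/NDVI}, the canopy chlorophyll content index}
#'   \item{TVI}{\eqn{\sqrt{NDVI + 0.5}} (`tviForm = "sqrt"`, the standard
#'     transformed vegetation index); `tviForm = "additive"` gives the
#'     literal \eqn{NDVI + 0.5}}
#' }
#' Cells with a zero denominator are masked rather than clipped, so no
#' infinities reach the classifier.
#'
#' @param name index name, one of `r paste(.indexNames, collapse = ", ")`.
#' @param stack a [PredictorStack-class] holding the required bands.
#' @param L soil adjustment factor for SAVI (> 0).
#' @param redEdgeBand band used as the red edge (default `"RE1"`).
#' @param tviForm `"sqrt"` or `"additive"` (see above).
#' @return a [RasterGrid-class].
#' @export
computeIndex <- function(name, stack, L = 0.5, redEdgeBand = "RE1",
                         tviForm = c("sqrt", "additive")) {
  name <- match.arg(name, .indexNames)
  tviForm <- match.arg(tviForm)
  need <- switch(name,
    NDVI = , RVI = , SAVI = , TVI = c("NIR", "Red"),
    GNDVI = c("NIR", "Green"),
    NDRE = c("NIR", redEdgeBand),
    CCCI = c("NIR", "Red", redEdgeBand))
  miss <- setdiff(need, bandNames(stack))
  if (length(miss))
    stop("missing band(s) for ", name, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  b <- function(nm) stack@bands[[nm]]
  v <- switch(name,
    NDVI = .normDiff(b("NIR"), b("Red")),
    GNDVI = .normDiff(b("NIR"), b("Green")),
    NDRE = .normDiff(b("NIR"), b(redEdgeBand)),
    RVI = {
      den <- b("Red"); out <- b("NIR") / den
      out[!is.na(den) & den == 0] <- NA_real_; out
    },
    SAVI = {
      if (L <= 0) stop("SAVI requires L > 0", call. = FALSE)
      den <- b("NIR") + b("Red") + L
      out <- (b("NIR") - b("Red")) / den * (1 + L)
      out[!is.na(den) & den == 0] <- NA_real_; out
    },
    CCCI = {
      ndre <- .normDiff(b("NIR"), b(redEdgeBand))
      ndvi <- .normDiff(b("NIR"), b("Red"))
      out <- ndre / ndvi
      out[!is.na(ndvi) & ndvi == 0] <- NA_real_; out
    },
    TVI = {
      ndvi <- .normDiff(b("NIR"), b("Red"))
      if (tviForm == "sqrt") {
        arg <- ndvi + 0.5
        arg[!is.na(arg) & arg < 0] <- NA_real_
        sqrt(arg)
      } else ndvi + 0.5
    })
  v[!is.finite(v)] <- NA_real_
  rasterGrid(v, stack@cellSize, stack@origin)
}

#' One-hot expand a categorical land-cover grid
#'
#' Turns a categorical land-cover classification into one binary predictor
#' band per non-water class. Water carries no band of its own — water cells
#' are handled by the water mask — so at an unmasked cell the bands sum to 1
#' exactly when the cell's class is non-water.
#'
#' @param classesGrid [RasterGrid-class] of integer class codes indexing
#'   `classNames`.
#' @param classNames character vector mapping code `i` to its class name;
#'   a name equal to `"water"` (case-insensitive) is skipped.
#' @return named list of binary [RasterGrid-class] bands.
#' @export
onehotLandcover <- function(classesGrid, classNames) {
  stopifnot(is(classesGrid, "RasterGrid"))
  v <- classesGrid@values
  codes <- sort(unique(as.vector(v[!is.na(v)])))
  if (length(codes) && (any(codes < 1) || any(codes > length(classNames)) ||
                        any(codes != floor(codes))))
    stop("unknown land-cover class code(s): ",
         paste(setdiff(codes, seq_along(classNames)), collapse = ", "),
         call. = FALSE)
  keep <- which(tolower(classNames) != "water")
  out <- lapply(keep, function(i) {
    band <- ifelse(is.na(v), NA_real_, as.numeric(v == i))
    rasterGrid(band, classesGrid@cellSize, classesGrid@origin)
  })
  names(out) <- classNames[keep]
  out
}

#' Assemble named bands into a predictor stack
#'
#' Collects co-registered bands (insertion order preserved) into a
#' [PredictorStack-class]. With `unifyMask = TRUE` (default) the nodata
#' masks are unioned across bands so every band shares one mask — the state
#' the modelling steps assume.
#'
#' @param namedBands named list of [RasterGrid-class] objects or matrices.
#' @param cellSize,origin geometry, required when bands are bare matrices.
#' @param unifyMask union nodata masks across bands.
#' @return a [PredictorStack-class].
#' @export
assembleStack <- function(namedBands, cellSize = NULL, origin = NULL,
                          unifyMask = TRUE) {
  if (length(namedBands) < 1L) stop("no bands supplied", call. = FALSE)
  nm <- names(namedBands)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("all bands must be named", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate band names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  isGrid <- vapply(namedBands, function(b) is(b, "RasterGrid"), TRUE)
  if (any(isGrid)) {
    ref <- namedBands[[which(isGrid)[1L]]]
    cellSize <- cellSize %||% ref@cellSize
    origin <- origin %||% ref@origin
    for (b in namedBands[isGrid]) {
      if (!.sameGeometry(b, list(nrow = nrow(ref@values),
                                 ncol = ncol(ref@values),
                                 cellSize = cellSize, origin = origin)))
        stop("bands do not share one geometry", call. = FALSE)
    }
  }
  if (is.null(cellSize) || is.null(origin))
    stop("cellSize and origin required when bands are bare matrices",
         call. = FALSE)
  mats <- lapply(namedBands, function(b) {
    m <- if (is(b, "RasterGrid")) b@values else as.matrix(b)
    storage.mode(m) <- "double"; m
  })
  dims <- unique(lapply(mats, dim))
  if (length(dims) > 1L) stop("bands differ in shape", call. = FALSE)
  if (unifyMask && length(mats) > 1L) {
    na <- Reduce(`|`, lapply(mats, is.na))
    mats <- lapply(mats, function(m) { m[na] <- NA_real_; m })
  }
  new("PredictorStack", bands = mats, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin))
}
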