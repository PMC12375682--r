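# Raster I/O uses the ESRI ASCII grid format (.asc): a plain-text,
# georeferenced single-band raster. A multi-band stack is a directory of
# one .asc per band plus a bands.json manifest preserving band order.

.ascHeader <- function(geom, nodata) {
  paste0(
    "ncols ", geom$ncol, "\n",
    "nrows ", geom$nrow, "\n",
    "xllcorner ", sprintf("%.10g", geom$origin[1]), "\n",
    "yllcorner ", sprintf("%.10g", geom$origin[2] - geom$nrow * geom$cellSize), "\n",
    "cellsize ", sprintf("%.10g", geom$cellSize), "\n",
    "NODATA_value ", sprintf("%.10g", nodata), "\n")
}

#' Read a georeferenced raster (ESRI ASCII grid)
#'
#' Reads a single-band `.asc` raster. Cells equal to the file's
#' `NODATA_value` are returned as `NA`.
#'
#' @param path path to an `.asc` file.
#' @return a [RasterGrid-class].
#' @seealso [writeRaster()], [readStack()]
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  names(vals) <- keys
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% keys) || anyNA(vals[need]))
    stop("not a georeferenced ASCII grid (missing header): ", path,
         call. = FALSE)
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  cs <- vals[["cellsize"]]
  if ("xllcorner" %in% keys) {
    x0 <- vals[["xllcorner"]]; yll <- vals[["yllcorner"]]
  } else if ("xllcenter" %in% keys) {
    x0 <- vals[["xllcenter"]] - cs / 2; yll <- vals[["yllcenter"]] - cs / 2
  } else stop("missing georeferencing (xllcorner/xllcenter): ", path,
              call. = FALSE)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  nskip <- max(which(keys %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                                 "xllcenter", "yllcenter", "cellsize",
                                 "nodata_value")))
  vv <- scan(path, what = double(), skip = nskip, quiet = TRUE)
  if (length(vv) != nr * nc)
    stop("raster body has ", length(vv), " values, expected ", nr * nc,
         call. = FALSE)
  m <- matrix(vv, nrow = nr, ncol = nc, byrow = TRUE)  # rows north -> south
  m[m == nodata] <- NA_real_
  rasterGrid(m, cellSize = cs, origin = c(x0, yll + nr * cs))
}

#' Write a raster or predictor stack
#'
#' A [RasterGrid-class] is written as a single ESRI ASCII grid; a
#' [PredictorStack-class] is written as a directory containing one `.asc`
#' per band and a `bands.json` manifest recording band order and geometry.
#' `readRaster(writeRaster(g, path))` reproduces values, mask and geometry.
#'
#' @param x a [RasterGrid-class] or [PredictorStack-class].
#' @param path output file (grid) or directory (stack).
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(x, path, nodata = -9999) {
  if (is(x, "PredictorStack")) return(writeStack(x, path, nodata))
  stopifnot(is(x, "RasterGrid"))
  v <- x@values
  if (any(v[!is.na(v)] == nodata)) nodata <- -3.4e38
  v[is.na(v)] <- nodata
  geom <- gridGeometry(x)
  con <- file(path, "w")
  on.exit(close(con))
  cat(.ascHeader(geom, nodata), file = con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = " ")), con)
  invisible(path)
}

#' @rdname writeRaster
#' @param stack a [PredictorStack-class].
#' @export
writeStack <- function(stack, path, nodata = -9999) {
  stopifnot(is(stack, "PredictorStack"))
  if (nBands(stack) < 1L) stop("empty stack", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nm <- bandNames(stack)
  files <- sprintf("band_%03d.asc", seq_along(nm))
  for (i in seq_along(nm))
    writeRaster(getBand(stack, nm[i]), file.path(path, files[i]), nodata)
  manifest <- list(bands = as.list(nm), files = as.list(files),
                   cellSize = stack@cellSize, origin = stack@origin)
  jsonlite::write_json(manifest, file.path(path, "bands.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname readRaster
#' @export
readStack <- function(path) {
  mf <- file.path(path, "bands.json")
  if (!file.exists(mf)) stop("no bands.json manifest in ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  grids <- lapply(file.path(path, manifest$files), readRaster)
  names(grids) <- manifest$bands
  assembleStack(grids, unifyMask = FALSE)
}
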