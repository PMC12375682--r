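#' Construct an occurrence set
#'
#' @param x,y point coordinates in map metres (or a 2-column matrix as `x`).
#' @param id optional integer ids (defaults to row numbers).
#' @return an [OccurrenceSet-class].
#' @export
occurrenceSet <- function(x, y = NULL, id = NULL) {
  coords <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  if (is.null(id)) id <- seq_len(nrow(coords))
  new("OccurrenceSet", coords = coords, id = as.integer(id))
}

#' @describeIn occurrenceSet number of points.
#' @param object an [OccurrenceSet-class].
#' @export
setMethod("length", "OccurrenceSet", function(x) nrow(x@coords))

#' @export
as.data.frame.OccurrenceSet <- function(x, ...) {
  data.frame(id = x@id, x = x@coords[, "x"], y = x@coords[, "y"])
}

#' Load presence points from CSV or GeoJSON
#'
#' CSV files need `x` and `y` columns (an `id` column is honoured);
#' GeoJSON must contain Point features. When a grid `geometry` is given,
#' points outside its extent are dropped with a warning reporting the count.
#'
#' @param path file path (`.csv`, `.json` or `.geojson`).
#' @param geometry optional working-extent geometry used to drop outside
#'   points.
#' @return an [OccurrenceSet-class].
#' @export
loadPoints <- function(path, geometry = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    feats <- switch(gj$type %||% "",
      FeatureCollection = gj$features,
      Feature = list(gj),
      Point = list(list(geometry = gj)),
      stop("unsupported GeoJSON type for points: ", gj$type, call. = FALSE))
    coords <- do.call(rbind, lapply(feats, function(f) {
      g <- f$geometry %||% f
      if (g$type != "Point") stop("expected Point features", call. = FALSE)
      as.numeric(unlist(g$coordinates)[1:2])
    }))
    occ <- occurrenceSet(coords[, 1], coords[, 2])
  } else {
    df <- utils::read.csv(path)
    if (!all(c("x", "y") %in% names(df)))
      stop("CSV must have x and y columns", call. = FALSE)
    occ <- occurrenceSet(df$x, df$y, id = df$id %||% NULL)
  }
  if (!is.null(geometry)) {
    rc <- .pointToCell(occ@coords[, "x"], occ@coords[, "y"], geometry)
    out <- is.na(rc[, "row"])
    if (any(out)) {
      warning(sum(out), " point(s) outside the working extent dropped")
      occ <- occurrenceSet(occ@coords[!out, , drop = FALSE],
                           id = occ@id[!out])
    }
  }
  occ
}

#' Write points to CSV
#'
#' @param occ an [OccurrenceSet-class].
#' @param path output path.
#' @param label optional constant label column (1 for presences, 0 for
#'   pseudo-absences).
#' @export
writePointsCSV <- function(occ, path, label = NULL) {
  df <- as.data.frame(occ)
  if (!is.null(label)) df$label <- label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cell indices of occurrence points
#'
#' @param occ an [OccurrenceSet-class].
#' @param geometry grid geometry.
#' @return integer matrix with columns `row`, `col`, `cell` (column-major
#'   linear index); `NA` for points outside the extent.
#' @export
occurrenceCells <- function(occ, geometry) {
  geom <- .asGeometry(geometry)
  rc <- .pointToCell(occ@coords[, "x"], occ@coords[, "y"], geom)
  cbind(rc, cell = .cellLinear(rc, geom))
}

#' Thin occurrences to one point per grid cell
#'
#' Reduces spatial sampling-bias aggregation by keeping exactly one point
#' per occupied cell, selected uniformly at random; the selection is
#' deterministic for a fixed seed. Thinning a thinned set returns it
#' unchanged.
#'
#' @param occ an [OccurrenceSet-class]; points outside the extent are
#'   dropped with a warning.
#' @param geometry grid geometry defining the cells.
#' @param seed integer seed for the per-cell random choice.
#' @return the thinned [OccurrenceSet-class], one point per occupied cell.
#' @export
thinToCells <- function(occ, geometry, seed = 1L) {
  if (length(occ) == 0L) {
    warning("empty occurrence set: nothing to thin")
    return(occ)
  }
  cells <- occurrenceCells(occ, geometry)
  out <- is.na(cells[, "cell"])
  if (any(out)) {
    warning(sum(out), " point(s) outside the extent dropped before thinning")
    occ <- occurrenceSet(occ@coords[!out, , drop = FALSE], id = occ@id[!out])
    cells <- cells[!out, , drop = FALSE]
  }
  idxByCell <- split(seq_len(length(occ)), cells[, "cell"])
  keep <- withr::with_seed(seed, vapply(idxByCell, function(ii) {
    if (length(ii) == 1L) ii else ii[sample.int(length(ii), 1L)]
  }, integer(1)))
  keep <- sort(unname(keep))
  occurrenceSet(occ@coords[keep, , drop = FALSE], id = occ@id[keep])
}
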