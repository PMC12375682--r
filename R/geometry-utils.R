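# Internal geometry helpers. Linear cell indices use R's column-major
# matrix convention: idx = (col - 1) * nrow + row.

.asGeometry <- function(x) {
  if (is.list(x) && all(c("nrow", "ncol", "cellSize", "origin") %in% names(x)))
    return(x)
  if (is(x, "RasterGrid") || is(x, "PredictorStack")) return(gridGeometry(x))
  stop("cannot interpret geometry argument", call. = FALSE)
}

.sameGeometry <- function(a, b, tol = 1e-9) {
  a <- .asGeometry(a); b <- .asGeometry(b)
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$cellSize - b$cellSize) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

.stopGeometry <- function(a, b, what = "inputs") {
  if (!.sameGeometry(a, b))
    stop(what, " do not share the same grid geometry", call. = FALSE)
  invisible(TRUE)
}

# point -> (row, col), 1-based; NA outside the extent. Cells are half-open
# [edge, edge + cell): row 1 is the northernmost row.
.pointToCell <- function(x, y, geom) {
  geom <- .asGeometry(geom)
  col <- floor((x - geom$origin[1]) / geom$cellSize) + 1
  row <- floor((geom$origin[2] - y) / geom$cellSize) + 1
  bad <- row < 1 | row > geom$nrow | col < 1 | col > geom$ncol
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

.cellLinear <- function(rc, geom) {
  geom <- .asGeometry(geom)
  (rc[, "col"] - 1L) * geom$nrow + rc[, "row"]
}

.linearToRC <- function(idx, geom) {
  geom <- .asGeometry(geom)
  idx <- as.integer(idx)
  cbind(row = ((idx - 1L) %% geom$nrow) + 1L,
        col = ((idx - 1L) %/% geom$nrow) + 1L)
}

# centers of cells given (row, col)
.cellCenter <- function(rc, geom) {
  geom <- .asGeometry(geom)
  cbind(x = geom$origin[1] + (rc[, "col"] - 0.5) * geom$cellSize,
        y = geom$origin[2] - (rc[, "row"] - 0.5) * geom$cellSize)
}

# all cell-center coordinates as vectors aligned with column-major order
.allCenters <- function(geom) {
  geom <- .asGeometry(geom)
  rows <- rep(seq_len(geom$nrow), times = geom$ncol)
  cols <- rep(seq_len(geom$ncol), each = geom$nrow)
  .cellCenter(cbind(row = rows, col = cols), geom)
}

.extent <- function(geom) {
  geom <- .asGeometry(geom)
  c(xmin = geom$origin[1],
    xmax = geom$origin[1] + geom$ncol * geom$cellSize,
    ymin = geom$origin[2] - geom$nrow * geom$cellSize,
    ymax = geom$origin[2])
}
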