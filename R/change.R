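#' Interannual HSI change map
#'
#' Per-cell difference of two continuous habitat-suitability surfaces,
#' `HSI(b) - HSI(a)`; positive values mean suitability increased from epoch
#' `a` to epoch `b`. Masks are unioned, and the operation is antisymmetric
#' in its arguments.
#'
#' @param hsiA,hsiB [RasterGrid-class] HSI surfaces on one geometry.
#' @param yearA,yearB epoch labels.
#' @return a [ChangeMap-class].
#' @export
hsiChange <- function(hsiA, hsiB, yearA = "a", yearB = "b") {
  stopifnot(is(hsiA, "RasterGrid"), is(hsiB, "RasterGrid"))
  .stopGeometry(hsiA, hsiB, "HSI maps")
  delta <- hsiB@values - hsiA@values
  new("ChangeMap",
      delta = rasterGrid(delta, hsiA@cellSize, hsiA@origin),
      yearA = as.character(yearA), yearB = as.character(yearB))
}

#' Suitable habitat area in square kilometres
#'
#' @param binary binary [RasterGrid-class] (values 0/1, `NA` masked).
#' @return area of unmasked 1-cells in km².
#' @export
suitableAreaKm2 <- function(binary) {
  stopifnot(is(binary, "RasterGrid"))
  v <- binary@values[!is.na(binary@values)]
  if (length(v) && !all(v %in% c(0, 1)))
    stop("grid is not binary", call. = FALSE)
  sum(v == 1) * (binary@cellSize / 1000)^2
}

#' Annual suitable-area accounting
#'
#' Builds the per-year area table: suitable area (km²), annual change as
#' the first difference from the previous year, and the percentage of the
#' configured total study area. The annual changes telescope to
#' `suitable[last] - suitable[first]`, and the headline maximum percentage
#' is reported rounded to a whole percent.
#'
#' @param byYear either a named numeric vector of suitable areas in km²
#'   (names are years) or a named list of binary [RasterGrid-class] maps.
#' @param totalKm2 total study-area size in km².
#' @return data.frame (`year`, `suitable_km2`, `annual_change_km2`,
#'   `percent_of_total`) ordered by year, with attributes `max_percent`
#'   (rounded whole percent) and `max_year`.
#' @export
areaSummary <- function(byYear, totalKm2) {
  if (missing(totalKm2) || is.null(totalKm2) || !is.finite(totalKm2))
    stop("totalKm2 is required", call. = FALSE)
  if (is.list(byYear))
    areas <- vapply(byYear, suitableAreaKm2, numeric(1))
  else areas <- byYear
  if (is.null(names(areas)) || any(!nzchar(names(areas))))
    stop("byYear must be named by year", call. = FALSE)
  ord <- order(as.numeric(names(areas)))
  areas <- areas[ord]
  change <- c(NA_real_, diff(areas))
  pct <- 100 * areas / totalKm2
  out <- data.frame(year = names(areas), suitable_km2 = unname(areas),
                    annual_change_km2 = unname(change),
                    percent_of_total = unname(pct))
  imax <- which.max(out$percent_of_total)
  attr(out, "max_percent") <- round(out$percent_of_total[imax])
  attr(out, "max_year") <- out$year[imax]
  out
}
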