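# Pseudo-absence generation by environmental profiling: cluster the
# standardized environmental space with k-means, treat clusters free of
# presences as "environmentally distinct", and draw balanced background
# points from them.

#' Standardize the environmental space of a stack
#'
#' Builds the cell-by-band table used for environmental profiling: one row
#' per unmasked cell, each band z-scored (population SD) over those cells.
#' Constant bands carry no environmental signal and are dropped with a
#' warning.
#'
#' @param stack a [PredictorStack-class].
#' @return an `EnvironmentTable`: list with `values` (rows x bands matrix
#'   of z-scores), `cellIndex` (column-major linear cell index per row),
#'   `bandNames`, `means`, `sds`.
#' @export
standardizeEnvironment <- function(stack) {
  stopifnot(is(stack, "PredictorStack"))
  ok <- !is.na(stack@bands[[1L]])
  idx <- which(ok)
  if (length(idx) < 2L) stop("fewer than 2 unmasked cells", call. = FALSE)
  m <- vapply(stack@bands, function(b) b[idx], numeric(length(idx)))
  mu <- colMeans(m)
  sds <- sqrt(colMeans(sweep(m, 2L, mu)^2))  # population SD
  const <- sds < 1e-12
  if (any(const)) {
    warning("dropping constant band(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
    mu <- mu[!const]; sds <- sds[!const]
  }
  if (ncol(m) == 0L) stop("no non-constant bands", call. = FALSE)
  z <- sweep(sweep(m, 2L, mu), 2L, sds, `/`)
  structure(list(values = z, cellIndex = idx, bandNames = colnames(z),
                 means = mu, sds = sds),
            class = "EnvironmentTable")
}

# k-means++ seeding: first center uniform, then each next center with
# probability proportional to squared distance to the nearest chosen center.
.kmeansppCenters <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[j + 1L, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j + 1L, ])^2))
  }
  centers
}

#' Cluster the environmental space with k-means
#'
#' Lloyd k-means on the standardized environment table, k-means++ seeding,
#' best of `nInit` restarts by total within-cluster sum of squares, run to
#' convergence (up to 100 Lloyd iterations). Deterministic for a fixed
#' seed.
#'
#' @param table an `EnvironmentTable` from [standardizeEnvironment()].
#' @param k number of clusters (2 <= k <= rows).
#' @param seed integer seed.
#' @param nInit number of restarts.
#' @return a `ClusterModel`: list with `k`, `centroids`, `labels` (per
#'   row of `table`), `cellIndex`, `wcss`.
#' @export
clusterEnvironment <- function(table, k = 10L, seed = 1L, nInit = 5L) {
  stopifnot(inherits(table, "EnvironmentTable"))
  x <- table$values
  if (k > nrow(x)) stop("k exceeds number of cells", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  best <- NULL
  withr::with_seed(seed, for (r in seq_len(nInit)) {
    centers <- .kmeansppCenters(x, k)
    centers <- centers[!duplicated(centers), , drop = FALSE]
    km <- suppressWarnings(stats::kmeans(x, centers = centers,
                                         iter.max = 100L,
                                         algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  })
  structure(list(k = nrow(best$centers), centroids = best$centers,
                 labels = as.integer(best$cluster),
                 cellIndex = table$cellIndex,
                 wcss = best$tot.withinss),
            class = "ClusterModel")
}

#' Cells eligible to receive pseudo-absences
#'
#' Applies the two-step profiling rule: presence cells are excluded
#' outright, and background candidates are restricted to environmentally
#' distinct clusters — clusters containing no presence cell. If every
#' cluster holds at least one presence, the rule relaxes to clusters whose
#' presence fraction is below the global presence fraction.
#'
#' @param model a `ClusterModel` from [clusterEnvironment()].
#' @param presenceCells integer linear indices of presence cells.
#' @return integer vector of eligible linear cell indices.
#' @export
eligibleAbsenceCells <- function(model, presenceCells) {
  stopifnot(inherits(model, "ClusterModel"))
  presenceCells <- unique(presenceCells)
  isPres <- model$cellIndex %in% presenceCells
  presByCluster <- tapply(isPres, model$labels, sum)
  sizeByCluster <- tapply(isPres, model$labels, length)
  clusters <- as.integer(names(presByCluster))
  empty <- clusters[presByCluster == 0]
  if (length(empty)) {
    keep <- model$labels %in% empty
  } else {
    globalFrac <- sum(isPres) / length(isPres)
    lowFrac <- clusters[presByCluster / sizeByCluster < globalFrac]
    keep <- model$labels %in% lowFrac
  }
  eligible <- model$cellIndex[keep & !isPres]
  if (length(eligible) == 0L)
    stop("no eligible pseudo-absence cells; increase k or relax the rule",
         call. = FALSE)
  eligible
}

#' Sample balanced pseudo-absences per spatial block
#'
#' Draws, for each block holding `p` presence points, `p` pseudo-absence
#' cells uniformly without replacement from the eligible cells of the same
#' block, so presences and pseudo-absences are balanced both per block and
#' globally. A block whose eligible pool is too small takes its shortfall
#' from the global eligible pool (warning); pseudo-absence points sit at
#' cell centers.
#'
#' @param eligible integer linear indices from [eligibleAbsenceCells()].
#' @param layout a `BlockLayout` from [buildBlocks()].
#' @param presenceCountsPerBlock named integer vector, presences per block
#'   id.
#' @param seed integer seed.
#' @return an [OccurrenceSet-class] of pseudo-absence points.
#' @export
samplePseudoabsences <- function(eligible, layout, presenceCountsPerBlock,
                                 seed = 1L) {
  stopifnot(inherits(layout, "BlockLayout"))
  counts <- presenceCountsPerBlock[presenceCountsPerBlock > 0]
  total <- sum(counts)
  if (length(eligible) < total)
    stop("eligible pseudo-absence cells (", length(eligible),
         ") fewer than presences (", total, ")", call. = FALSE)
  blockOfEligible <- layout$blockId[eligible]
  chosen <- integer(0)
  shortfall <- 0L
  withr::with_seed(seed, {
    for (b in names(counts)) {
      p <- counts[[b]]
      pool <- eligible[blockOfEligible == as.integer(b)]
      pool <- setdiff(pool, chosen)
      take <- min(p, length(pool))
      if (take > 0)
        chosen <- c(chosen, pool[sample.int(length(pool), take)])
      shortfall <- shortfall + (p - take)
    }
    if (shortfall > 0L) {
      warning(shortfall, " pseudo-absence(s) drawn from the global pool ",
              "(block-local eligible cells exhausted)")
      pool <- setdiff(eligible, chosen)
      chosen <- c(chosen, pool[sample.int(length(pool), shortfall)])
    }
  })
  geom <- list(nrow = nrow(layout$blockId), ncol = ncol(layout$blockId),
               cellSize = layout$cellSize, origin = layout$origin)
  ctr <- .cellCenter(.linearToRC(chosen, geom), geom)
  occurrenceSet(ctr[, "x"], ctr[, "y"])
}
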