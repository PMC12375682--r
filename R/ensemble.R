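#' Extract the point-level training table
#'
#' One row per presence / pseudo-absence point carrying all band values at
#' the point's cell, the 0/1 label, the spatial block id and the block's
#' train/validation partition. Points falling on masked cells are dropped
#' with a warning; points in blocks absent from the partition map (possible
#' only via the global shortfall pool) default to the training partition.
#'
#' @param stack a [PredictorStack-class].
#' @param presences,pseudoabsences [OccurrenceSet-class] objects.
#' @param layout a `BlockLayout`.
#' @param partition named vector from [partitionBlocks()].
#' @return data.frame with band columns plus `label`, `block`, `partition`.
#' @export
extractTrainingTable <- function(stack, presences, pseudoabsences, layout,
                                 partition) {
  geom <- gridGeometry(stack)
  pts <- rbind(presences@coords, pseudoabsences@coords)
  label <- c(rep(1L, length(presences)), rep(0L, length(pseudoabsences)))
  rc <- .pointToCell(pts[, "x"], pts[, "y"], geom)
  cell <- .cellLinear(rc, geom)
  masked <- is.na(cell) | is.na(stack@bands[[1L]][cell])
  if (any(masked)) {
    warning(sum(masked), " point(s) on masked cells dropped")
    pts <- pts[!masked, , drop = FALSE]
    label <- label[!masked]; cell <- cell[!masked]
  }
  if (length(cell) == 0L) stop("no usable points", call. = FALSE)
  feats <- vapply(stack@bands, function(b) b[cell], numeric(length(cell)))
  if (length(cell) == 1L)
    feats <- matrix(feats, 1L, dimnames = list(NULL, bandNames(stack)))
  block <- layout$blockId[cell]
  part <- unname(partition[as.character(block)])
  part[is.na(part)] <- "train"
  out <- as.data.frame(feats)
  out$label <- label
  out$block <- block
  out$partition <- part
  out
}

#' Majority vote across binary ensemble maps
#'
#' A cell is suitable (1) when strictly more than half of its unmasked
#' votes are 1; an exact tie is conservatively called unsuitable (0).
#' Cells unmasked in no input stay masked.
#'
#' @param binaryGrids list of binary [RasterGrid-class] maps on one
#'   geometry.
#' @return binary [RasterGrid-class].
#' @export
majorityVote <- function(binaryGrids) {
  if (length(binaryGrids) < 1L) stop("no grids to vote over", call. = FALSE)
  g1 <- binaryGrids[[1L]]
  for (g in binaryGrids) .stopGeometry(g1, g, "binary grids")
  ones <- Reduce(`+`, lapply(binaryGrids, function(g) {
    v <- g@values; v[is.na(v)] <- 0; v
  }))
  votes <- Reduce(`+`, lapply(binaryGrids,
                              function(g) (!is.na(g@values)) * 1))
  out <- matrix(NA_real_, nrow(ones), ncol(ones))
  has <- votes > 0
  out[has] <- as.numeric(ones[has] > votes[has] / 2)
  rasterGrid(out, g1@cellSize, g1@origin)
}

#' Aggregate raw importances to mean relative contribution
#'
#' Normalizes each iteration's raw importance vector to percentages summing
#' to 100, then averages across iterations; the result again sums to 100.
#'
#' @param importanceList list of equal-length named non-negative vectors.
#' @return named numeric vector of mean relative importance (percent).
#' @export
aggregateImportance <- function(importanceList) {
  if (length(importanceList) < 1L) stop("no importances", call. = FALSE)
  mats <- vapply(importanceList, function(v) {
    s <- sum(v)
    if (!is.finite(s) || s <= 0)
      stop("importance vector with non-positive sum", call. = FALSE)
    100 * v / s
  }, numeric(length(importanceList[[1L]])))
  out <- rowMeans(mats)
  names(out) <- names(importanceList[[1L]])
  out
}

#' Select the most impactful predictors
#'
#' Keeps predictors whose mean relative contribution exceeds the threshold
#' (3.5 percent by default), sorted by decreasing importance — the rule
#' used to narrow a full model down to its strongest drivers for a subset
#' rerun.
#'
#' @param meanImportancePercent named numeric from [aggregateImportance()].
#' @param threshold percent cut-off.
#' @return character vector of predictor names, descending importance.
#' @export
subsetPredictors <- function(meanImportancePercent, threshold = 3.5) {
  keep <- meanImportancePercent[meanImportancePercent > threshold]
  if (length(keep) == 0L) {
    warning("no predictor exceeds the importance threshold of ", threshold)
    return(character(0))
  }
  names(sort(keep, decreasing = TRUE))
}

#' Run the spatial-block cross-validated ensemble
#'
#' The full presence-only modelling loop. Environmental profiling (z-score
#' standardization, k-means clustering, eligibility) is run once per stack;
#' then for each of `nIterations` iterations \eqn{i}, with iteration seed
#' `seed + i`: the presence-bearing blocks are split 70/30 into train and
#' validation, balanced pseudo-absences are drawn per block, the bagged-tree
#' classifier is fitted on the training rows, validation metrics (AUC-ROC,
#' AUC-PR, sensitivity, specificity) are computed on the validation rows,
#' and (optionally) the probability and binary surfaces are predicted.
#' The iterations are aggregated into the mean habitat suitability index
#' (HSI) map, its population SD, a majority-vote binary map and the mean
#' relative importance per predictor.
#'
#' @param stack a [PredictorStack-class].
#' @param presences thinned presence [OccurrenceSet-class].
#' @param nIterations ensemble size (default 10).
#' @param trainFraction train share of occupied blocks (default 0.7).
#' @param nTrees trees per forest (default 500).
#' @param blockSizeCells spatial block edge in cells (default 10).
#' @param k number of k-means clusters for profiling (default 10).
#' @param seed master seed; iteration \eqn{i} uses `seed + i`.
#' @param threshold binarization cut (default 0.5).
#' @param predictSurfaces predict full maps per iteration (set `FALSE` to
#'   compute only point-level metrics and importances, e.g. in large
#'   simulation studies).
#' @param mtry,minNode forwarded to [fitClassifier()].
#' @return an [EnsembleResult-class].
#' @export
runEnsemble <- function(stack, presences, nIterations = 10L,
                        trainFraction = 0.7, nTrees = 500L,
                        blockSizeCells = 10L, k = 10L, seed = 1L,
                        threshold = 0.5, predictSurfaces = TRUE,
                        mtry = NULL, minNode = 1L) {
  stopifnot(is(stack, "PredictorStack"), is(presences, "OccurrenceSet"))
  geom <- gridGeometry(stack)

  occCells <- occurrenceCells(presences, geom)[, "cell"]
  bad <- is.na(occCells) | is.na(stack@bands[[1L]][occCells])
  if (any(bad)) {
    warning(sum(bad), " presence point(s) outside the extent or on masked ",
            "cells dropped")
    presences <- occurrenceSet(presences@coords[!bad, , drop = FALSE],
                               id = presences@id[!bad])
    occCells <- occCells[!bad]
  }
  if (length(presences) < 2L) stop("too few usable presences", call. = FALSE)

  env <- standardizeEnvironment(stack)
  model <- clusterEnvironment(env, k = k, seed = seed)
  eligible <- eligibleAbsenceCells(model, occCells)

  layout <- buildBlocks(geom, blockSizeCells)
  presBlocks <- layout$blockId[occCells]
  presCounts <- table(presBlocks)
  occupied <- as.integer(names(presCounts))

  iterations <- vector("list", nIterations)
  metrics <- vector("list", nIterations)
  probGrids <- list(); binGrids <- list()
  impList <- vector("list", nIterations)

  for (i in seq_len(nIterations)) {
    seedI <- seed + i
    part <- partitionBlocks(layout, occupied, trainFraction, seed = seedI)
    absences <- samplePseudoabsences(eligible, layout,
                                     stats::setNames(as.integer(presCounts),
                                                     names(presCounts)),
                                     seed = seedI)
    tab <- extractTrainingTable(stack, presences, absences, layout, part)
    featCols <- bandNames(stack)
    trainRows <- tab$partition == "train"
    valRows <- tab$partition == "validation"
    fit <- fitClassifier(tab[trainRows, featCols, drop = FALSE],
                         tab$label[trainRows], nTrees = nTrees, mtry = mtry,
                         minNode = minNode, seed = seedI)
    valProb <- predictProbability(fit, tab[valRows, featCols, drop = FALSE])
    valLab <- tab$label[valRows]
    if (length(unique(valLab)) == 2L) {
      ss <- sensSpec(as.numeric(valProb >= threshold), valLab)
      metrics[[i]] <- data.frame(
        iteration = i,
        auc_roc = aucROC(valProb, valLab),
        auc_pr = aucPR(valProb, valLab),
        sensitivity = ss[["sensitivity"]],
        specificity = ss[["specificity"]],
        n_pos = sum(valLab == 1L), n_neg = sum(valLab == 0L))
    } else {
      # can happen on tiny landscapes when shortfall pseudo-absences all
      # land in training blocks
      warning("iteration ", i, ": validation partition holds a single ",
              "class; metrics set to NA")
      metrics[[i]] <- data.frame(
        iteration = i, auc_roc = NA_real_, auc_pr = NA_real_,
        sensitivity = NA_real_, specificity = NA_real_,
        n_pos = sum(valLab == 1L), n_neg = sum(valLab == 0L))
    }
    impList[[i]] <- fit$importance
    it <- list(seed = seedI, partition = part,
               importance = fit$importance)
    if (predictSurfaces) {
      surf <- predictSurface(fit, stack, threshold = threshold)
      probGrids[[i]] <- surf$probability
      binGrids[[i]] <- surf$binary
      it$probability <- surf$probability
      it$binary <- surf$binary
    }
    iterations[[i]] <- it
  }

  metrics <- do.call(rbind, metrics)
  importance <- aggregateImportance(impList)

  emptyGrid <- rasterGrid(matrix(numeric(0), 0L, 0L), geom$cellSize,
                          geom$origin)
  if (predictSurfaces) {
    probMat <- vapply(probGrids, function(g) as.vector(g@values),
                      numeric(geom$nrow * geom$ncol))
    mu <- rowMeans(probMat)
    sdv <- sqrt(rowMeans(probMat^2) - mu^2)
    sdv[which(sdv < 0 | is.nan(sdv))] <- 0
    sdv[which(is.na(mu))] <- NA_real_
    hsiMean <- rasterGrid(matrix(mu, geom$nrow, geom$ncol), geom$cellSize,
                          geom$origin)
    hsiSD <- rasterGrid(matrix(sdv, geom$nrow, geom$ncol), geom$cellSize,
                        geom$origin)
    majority <- majorityVote(binGrids)
  } else {
    hsiMean <- hsiSD <- majority <- emptyGrid
  }

  new("EnsembleResult", hsiMean = hsiMean, hsiSD = hsiSD,
      majority = majority, importance = importance, metrics = metrics,
      iterations = iterations,
      config = list(nIterations = nIterations,
                    trainFraction = trainFraction, nTrees = nTrees,
                    blockSizeCells = blockSizeCells, k = k, seed = seed,
                    iterationSeeds = seed + seq_len(nIterations),
                    threshold = threshold,
                    predictSurfaces = predictSurfaces))
}
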