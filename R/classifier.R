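#' Fit the bagged-tree (random forest) classifier
#'
#' Grows a seeded ensemble of CART classification trees, each on a
#' bootstrap resample of the training rows with a fresh random subset of
#' `mtry` candidate features at every split (Gini impurity). The fit is
#' fully reproducible for a fixed seed and exposes class-1 probabilities
#' (the mean leaf class fraction across trees) and per-predictor
#' mean-decrease-in-impurity importances.
#'
#' @param features numeric matrix or data.frame of predictors.
#' @param labels 0/1 vector; both classes must be present.
#' @param nTrees number of trees (default 500).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param minNode minimum node size to attempt a split.
#' @param seed integer seed.
#' @return a `FittedClassifier`: list with `forest`, `importance` (named,
#'   non-negative), `featureNames`, `nTrees`, `seed`.
#' @export
fitClassifier <- function(features, labels, nTrees = 500L, mtry = NULL,
                          minNode = 1L, seed = 1L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as.integer(labels)
  if (nrow(x) < 2L) stop("need at least 2 training rows", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training data contain a single class", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (anyNA(x)) stop("training features contain NA", call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- .rf_fit_cpp(x, y, as.integer(nTrees), as.integer(mtry),
                     as.integer(minNode), as.integer(seed))
  imp <- as.numeric(fit$importance)
  names(imp) <- colnames(x)
  structure(list(forest = fit$trees, importance = imp,
                 featureNames = colnames(x), nTrees = as.integer(nTrees),
                 seed = as.integer(seed)),
            class = "FittedClassifier")
}

#' Predict class-1 probability for new rows
#'
#' @param model a `FittedClassifier`.
#' @param features matrix/data.frame with the training columns (matched by
#'   name when named).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predictProbability <- function(model, features) {
  stopifnot(inherits(model, "FittedClassifier"))
  x <- as.matrix(features)
  if (!is.null(colnames(x)) && !is.null(model$featureNames)) {
    miss <- setdiff(model$featureNames, colnames(x))
    if (length(miss))
      stop("missing feature column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    x <- x[, model$featureNames, drop = FALSE]
  }
  storage.mode(x) <- "double"
  .rf_predict_cpp(model$forest, x)
}

#' Predict probability and binary suitability surfaces
#'
#' Applies a fitted classifier to every unmasked cell of a predictor stack,
#' returning the continuous presence-probability surface and its binary
#' classification (probability >= 0.5). Masked cells stay masked in both.
#'
#' @param model a `FittedClassifier`.
#' @param stack a [PredictorStack-class] carrying the training bands.
#' @param threshold binarization cut (default 0.5).
#' @return list with `probability` and `binary` [RasterGrid-class] maps.
#' @export
predictSurface <- function(model, stack, threshold = 0.5) {
  stopifnot(inherits(model, "FittedClassifier"), is(stack, "PredictorStack"))
  miss <- setdiff(model$featureNames, bandNames(stack))
  if (length(miss))
    stop("stack lacks band(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ok <- !is.na(stack@bands[[1L]])
  idx <- which(ok)
  x <- vapply(model$featureNames, function(nm) stack@bands[[nm]][idx],
              numeric(length(idx)))
  if (length(idx) == 1L) x <- matrix(x, nrow = 1L,
                                     dimnames = list(NULL,
                                                     model$featureNames))
  p <- predictProbability(model, x)
  g <- gridGeometry(stack)
  prob <- matrix(NA_real_, g$nrow, g$ncol)
  prob[idx] <- p
  bin <- matrix(NA_real_, g$nrow, g$ncol)
  bin[idx] <- as.numeric(p >= threshold)
  list(probability = rasterGrid(prob, g$cellSize, g$origin),
       binary = rasterGrid(bin, g$cellSize, g$origin))
}
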