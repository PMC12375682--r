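# Small in-code fixtures shared across test files.

# grid of given shape with values 1..n (column-major), 30 m cells
makeGrid <- function(nrow = 4, ncol = 4, values = NULL, cellSize = 30) {
  if (is.null(values)) values <- matrix(seq_len(nrow * ncol), nrow, ncol)
  rasterGrid(values, cellSize = cellSize,
             origin = c(0, nrow * cellSize))
}

# stack of nBands random bands on one geometry (seeded)
makeStack <- function(nBands = 3, nrow = 6, ncol = 6, seed = 1,
                      cellSize = 30) {
  bands <- withr::with_seed(seed, lapply(seq_len(nBands), function(i)
    matrix(rnorm(nrow * ncol), nrow, ncol)))
  names(bands) <- sprintf("b%02d", seq_len(nBands))
  assembleStack(bands, cellSize = cellSize,
                origin = c(0, nrow * cellSize))
}

# reflectance stack with named spectral bands (values in [0, 1])
makeSpectralStack <- function(nir, red, green = NULL, re1 = NULL) {
  b <- list(NIR = as.matrix(nir), Red = as.matrix(red))
  if (!is.null(green)) b$Green <- as.matrix(green)
  if (!is.null(re1)) b$RE1 <- as.matrix(re1)
  assembleStack(b, cellSize = 30, origin = c(0, nrow(b$NIR) * 30))
}

# brute-force distance from a point to a polyline (oracle)
bruteSegDist <- function(px, py, line) {
  dmin <- Inf
  for (s in seq_len(nrow(line) - 1)) {
    x1 <- line[s, 1]; y1 <- line[s, 2]
    x2 <- line[s + 1, 1]; y2 <- line[s + 1, 2]
    dx <- x2 - x1; dy <- y2 - y1
    l2 <- dx^2 + dy^2
    t <- if (l2 == 0) 0 else max(0, min(1, ((px - x1) * dx + (py - y1) * dy) / l2))
    dmin <- min(dmin, sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2))
  }
  dmin
}

# exhaustive pair-counting AUC oracle (ties count 1/2)
bruteAucROC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# stepwise precision-recall integration oracle
bruteAucPR <- function(scores, labels) {
  nPos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prevR <- 0
  for (t in thr) {
    tp <- sum(labels == 1 & scores >= t)
    fp <- sum(labels == 0 & scores >= t)
    prec <- tp / (tp + fp); rec <- tp / nPos
    ap <- ap + (rec - prevR) * prec
    prevR <- rec
  }
  ap
}
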