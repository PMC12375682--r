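#' Tile a grid into square spatial blocks
#'
#' Square blocks of `blockSizeCells` x `blockSizeCells` cells tiling the
#' extent (edge blocks truncated), with deterministic row-major block ids.
#' Spatial blocks — rather than individual points — are the unit of the
#' train/validation split, which curbs the optimistic bias that spatial
#' autocorrelation causes in random point-level splits.
#'
#' @param geometry grid geometry.
#' @param blockSizeCells block edge length in cells (>= 1).
#' @return a `BlockLayout`: list with `blockId` (integer matrix over the
#'   grid), `nBlocks`, `blockSizeCells`, `cellSize`, `origin`.
#' @export
buildBlocks <- function(geometry, blockSizeCells = 10L) {
  geom <- .asGeometry(geometry)
  stopifnot(blockSizeCells >= 1L)
  br <- (seq_len(geom$nrow) - 1L) %/% blockSizeCells
  bc <- (seq_len(geom$ncol) - 1L) %/% blockSizeCells
  nbc <- max(bc) + 1L
  blockId <- outer(br, bc, function(r, c) r * nbc + c + 1L)
  structure(list(blockId = blockId, nBlocks = max(blockId),
                 blockSizeCells = as.integer(blockSizeCells),
                 cellSize = geom$cellSize, origin = geom$origin),
            class = "BlockLayout")
}

#' Assign data-bearing blocks to train / validation partitions
#'
#' Randomly assigns the occupied blocks so that `round(trainFraction * n)`
#' of them train the model and the rest validate it (the 70/30 block split
#' of the cross-validation scheme). Both partitions must end up with at
#' least one presence-bearing block; if a draw violates this the seed is
#' incremented and the draw repeated (up to 100 tries).
#'
#' @param layout a `BlockLayout`.
#' @param occupiedBlocks integer ids of blocks containing presence points.
#' @param trainFraction fraction of occupied blocks to train on, in (0, 1).
#' @param seed integer seed.
#' @return named character vector: `"train"` / `"validation"` per occupied
#'   block id (names are the block ids).
#' @export
partitionBlocks <- function(layout, occupiedBlocks, trainFraction = 0.7,
                            seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  occupiedBlocks <- sort(unique(as.integer(occupiedBlocks)))
  n <- length(occupiedBlocks)
  nTrain <- round(trainFraction * n)
  if (n < 2L || nTrain < 1L || nTrain >= n)
    stop("cannot split ", n, " occupied block(s) into non-empty train and ",
         "validation partitions", call. = FALSE)
  for (try in 0:99) {
    tr <- withr::with_seed(seed + try,
                           sample(occupiedBlocks, nTrain))
    part <- ifelse(occupiedBlocks %in% tr, "train", "validation")
    names(part) <- occupiedBlocks
    if (any(part == "train") && any(part == "validation")) return(part)
  }
  stop("no valid partition found in 100 attempts", call. = FALSE)
}
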