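#' Read a pipeline run configuration
#'
#' YAML or JSON, one file per reproducible run. See [runPipeline()] for the
#' recognised fields.
#'
#' @param path path to a `.yml`/`.yaml` or `.json` config file.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

.pipelineDefaults <- list(
  nIterations = 10L, trainFraction = 0.7, k = 10L, blockSizeCells = 10L,
  nTrees = 500L, importanceThreshold = 3.5, threshold = 0.5, seed = 1L,
  predictSurfaces = TRUE, totalKm2 = NULL)

#' Run the end-to-end habitat-suitability pipeline
#'
#' Orchestrates predictor loading (or synthetic generation), occurrence
#' thinning, environmental pseudo-absence profiling, the spatial-block
#' cross-validated ensemble, validation, and — for multi-year runs —
#' interannual change maps and the suitable-area table. All outputs are
#' written under `outDir` and listed, with MD5 content hashes, in a
#' `manifest.json` that also echoes the full configuration and every seed,
#' so that a re-run with the same master seed is verifiable by hash
#' comparison.
#'
#' Recognised config fields (defaults in parentheses): `nIterations` (10),
#' `trainFraction` (0.7), `k` (10), `blockSizeCells` (10), `nTrees` (500),
#' `importanceThreshold` (3.5), `threshold` (0.5), `seed` (1),
#' `predictSurfaces` (TRUE), `totalKm2` (unmasked area of the first year);
#' either `synthetic` (a list of [synthLandscape()] arguments plus
#' `nPresences` and optional `years` labels) or the input paths `stackDir`
#' (one per year, named by year), `pointsPath`, `waterPath`.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @param outDir output directory (overrides `config$outDir`).
#' @param seed master seed (overrides `config$seed`).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, outDir = NULL, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  cfg <- utils::modifyList(.pipelineDefaults, config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outDir)) cfg$outDir <- outDir
  if (is.null(cfg$outDir)) stop("config needs an output directory (outDir)",
                                call. = FALSE)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

  # ---- stage: inputs ----
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    years <- as.character(syn$years %||% "year1")
    nPres <- syn$nPresences %||% 400L
    syn$years <- NULL; syn$nPresences <- NULL
    inputs <- lapply(seq_along(years), function(i) {
      sc <- do.call(synthLandscape,
                    c(syn, list(seed = cfg$seed + 1000L * i)))
      occ <- samplePresences(sc$truth, n = nPres,
                             seed = cfg$seed + 1000L * i + 1L)
      message("[simulate] year ", years[i], ": ", nBands(sc$stack),
              " bands, ", length(occ), " presences")
      list(stack = sc$stack, occ = occ)
    })
    names(inputs) <- years
  } else {
    if (is.null(cfg$stackDir) || is.null(cfg$pointsPath))
      stop("config needs stackDir and pointsPath (or a synthetic block)",
           call. = FALSE)
    stackDirs <- cfg$stackDir
    years <- names(stackDirs) %||% as.character(seq_along(stackDirs))
    inputs <- lapply(seq_along(stackDirs), function(i) {
      stack <- readStack(stackDirs[[i]])
      if (!is.null(cfg$waterPath))
        stack <- applyWaterMask(stack, readRaster(cfg$waterPath))
      occ <- loadPoints(cfg$pointsPath, geometry = stack)
      message("[prepare] year ", years[i], ": ", nBands(stack), " bands, ",
              length(occ), " presences")
      list(stack = stack, occ = occ)
    })
    names(inputs) <- years
  }

  files <- character(0)
  results <- list()
  for (y in names(inputs)) {
    stack <- inputs[[y]]$stack
    # ---- stage: thinning ----
    thinned <- thinToCells(inputs[[y]]$occ, stack, seed = cfg$seed)
    message("[thin] year ", y, ": ", length(inputs[[y]]$occ), " -> ",
            length(thinned), " presences")
    # ---- stage: ensemble ----
    res <- runEnsemble(stack, thinned, nIterations = cfg$nIterations,
                       trainFraction = cfg$trainFraction,
                       nTrees = cfg$nTrees,
                       blockSizeCells = cfg$blockSizeCells, k = cfg$k,
                       seed = cfg$seed, threshold = cfg$threshold,
                       predictSurfaces = cfg$predictSurfaces)
    sm <- summarizeIterations(iterationMetrics(res))
    message(sprintf("[model] year %s: mean AUC_ROC %.3f, AUC_PR %.3f", y,
                    sm["mean", "auc_roc"], sm["mean", "auc_pr"]))
    results[[y]] <- res

    pre <- file.path(cfg$outDir, paste0(y, "_"))
    if (cfg$predictSurfaces) {
      writeRaster(hsiMean(res), paste0(pre, "hsi_mean.asc"))
      writeRaster(hsiSD(res), paste0(pre, "hsi_sd.asc"))
      writeRaster(majorityMap(res), paste0(pre, "majority_binary.asc"))
      files <- c(files, paste0(pre, c("hsi_mean.asc", "hsi_sd.asc",
                                      "majority_binary.asc")))
    }
    met <- iterationMetrics(res)
    met <- rbind(met,
                 cbind(data.frame(iteration = c(NA, NA)),
                       summarizeIterations(met),
                       data.frame(n_pos = NA, n_neg = NA)))
    utils::write.csv(met, paste0(pre, "metrics.csv"), row.names = FALSE)
    imp <- meanImportance(res)
    utils::write.csv(data.frame(predictor = names(imp),
                                mean_importance_percent = unname(imp)),
                     paste0(pre, "importance.csv"), row.names = FALSE)
    files <- c(files, paste0(pre, c("metrics.csv", "importance.csv")))
  }

  # ---- stage: change detection ----
  if (length(results) >= 2L && cfg$predictSurfaces) {
    yrs <- names(results)
    for (i in seq_len(length(yrs) - 1L)) {
      cm <- hsiChange(hsiMean(results[[yrs[i]]]),
                      hsiMean(results[[yrs[i + 1L]]]),
                      yearA = yrs[i], yearB = yrs[i + 1L])
      f <- file.path(cfg$outDir,
                     sprintf("change_%s_%s.asc", yrs[i], yrs[i + 1L]))
      writeRaster(cm@delta, f)
      files <- c(files, f)
    }
    areas <- vapply(results, function(r) suitableAreaKm2(majorityMap(r)),
                    numeric(1))
    total <- cfg$totalKm2 %||% {
      g <- inputs[[1L]]$stack
      sum(!is.na(g@bands[[1L]])) * (g@cellSize / 1000)^2
    }
    area <- areaSummary(areas, totalKm2 = total)
    f <- file.path(cfg$outDir, "area_summary.csv")
    utils::write.csv(area, f, row.names = FALSE)
    files <- c(files, f)
    message(sprintf("[change] max %s%% of total area suitable (year %s)",
                    attr(area, "max_percent"), attr(area, "max_year")))
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "outDir")],
    iterationSeeds = cfg$seed + seq_len(cfg$nIterations),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$results <- results
  invisible(manifest)
}
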