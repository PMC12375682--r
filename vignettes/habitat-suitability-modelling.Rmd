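---
title: "Presence-only habitat suitability modelling with sdmscape"
author: "sdmscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-only habitat suitability modelling with sdmscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmscape)
```

## The problem

Invasive-plant management needs maps of where a species *could* establish,
not only where it has been seen. Field records for invasives are almost
always presence-only, spatially biased towards accessible terrain (in
protected savannah parks, essentially the road network), and small relative
to the landscape. `sdmscape` implements a complete presence-only species
distribution modelling (SDM) pipeline for this situation, working on
multi-band raster predictor stacks at a fixed metric resolution
(conventionally 30 m):

1. **Predictor preparation** — water masking, bilinear resampling of coarse
   climate grids, temporal median composites, radar backscatter conversion
   to decibels, vegetation indices, one-hot land-cover bands, and a buffered
   binary road layer.
2. **Occurrence thinning** — one randomly selected record per grid cell, to
   blunt aggregation bias.
3. **Pseudo-absence profiling** — absences invented where the environment is
   unlike any environment that holds a presence (k-means profiling).
4. **A spatial-block cross-validated ensemble** of bagged decision-tree
   (random forest) classifiers, aggregated into a habitat suitability index
   (HSI) map, its uncertainty, a majority-vote binary map, and relative
   variable importances.
5. **Validation** with threshold-independent metrics (AUC-ROC, AUC-PR) plus
   sensitivity and specificity.
6. **Change analysis** — interannual HSI difference maps and a suitable-area
   table in km² with first differences and percent-of-park statistics.

A synthetic-landscape generator with a *known* true suitability surface
makes every stage testable without any satellite archive.

## The model

Let $x_i \in \mathbb{R}^p$ be the predictor vector of cell $i$ (all bands of
the stack). Presence points $\{s_j\}$ are thinned to one per cell. The
pipeline then repeats, for iterations $t = 1, \dots, 10$:

1. Square spatial blocks (default $10 \times 10$ cells, i.e. 300 m at 30 m
   resolution) tile the extent; the presence-bearing blocks are split
   70 / 30 into training and validation. Blocks, not points, are the
   sampling unit, because spatial autocorrelation makes point-level splits
   optimistically biased.
2. For each presence-bearing block with $p_b$ presences, $p_b$
   pseudo-absence cells are drawn uniformly from the *eligible* cells of
   that block, giving a balanced sample both per block and globally.
   Eligibility comes from k-means profiling: all bands are z-scored over
   unmasked cells, Lloyd k-means (k-means++ seeding, best of 5 restarts,
   $k = 10$) partitions the environmental space, and clusters containing no
   presence cell are "environmentally distinct". If every cluster holds a
   presence, the rule relaxes to clusters whose presence fraction is below
   the global fraction. Presence cells themselves are never eligible.
3. A bagged CART ensemble (default 500 trees, Gini splits, `mtry`
   $= \lfloor\sqrt{p}\rfloor$, bootstrap resampling) is fitted to the
   training rows; class-1 probability is the mean leaf class fraction over
   trees.
4. The validation rows give AUC-ROC (rank form, ties one half), AUC-PR
   (average precision with stepwise interpolation), sensitivity and
   specificity at the 0.5 cut.

Aggregation over the ten iterations: $\mathrm{HSI}(i)$ is the mean predicted
probability, its spread is the population SD (the ten runs are the whole
ensemble, not a sample), the binary map takes a strict majority of the ten
binary outputs (ties conservatively to absence), and importances are
normalised to percent within each iteration before averaging, so the mean
contribution sums to 100. Predictors above a 3.5 % mean contribution form
the subset used for reduced reruns.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `nIterations` | 10 | ensemble size / CV repeats |
| `trainFraction` | 0.7 | train share of presence-bearing blocks |
| `blockSizeCells` | 10 | spatial block edge (cells); 300 m at 30 m |
| `k` | 10 | k-means clusters for environmental profiling |
| `nTrees` | 500 | trees per forest |
| `threshold` | 0.5 | probability cut for the binary maps |
| `importanceThreshold` | 3.5 | percent cut for predictor subsetting |

The block size must exceed the presence clustering scale while leaving
enough blocks (≥ 20 on a 200 × 200 grid) for a meaningful 70/30 split.
$k = 10$ balances profile resolution against empty-cluster risk at desk
scale. All of these are run-configuration fields; every run records its
master seed and the derived per-iteration seeds (`seed + i`) in the output
manifest.

## The synthetic world

`synthLandscape()` emulates the statistical structure of a savannah-park
predictor archive on a 200 × 200 grid of 30 m cells: 20 spatially
autocorrelated continuous bands (Gaussian random fields, kernel scale 4
cells ≈ 120 m), six land-cover classes thresholded from an auxiliary field
and one-hot expanded, a buffered road network (eight random polylines
crossing the extent, 50 m buffer), and a 5 % water mask applied to every
band. True suitability is
$\mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j z_j + \beta_r\,\mathrm{road})$
with three informative bands ($\beta = 1.5, -1.0, 0.8$), a road effect of
1.0 and intercept $\beta_0 = -2$. Presences (default 400) are drawn without
replacement with probability proportional to
$\mathrm{suitability} \times (1 + 5 \cdot \mathrm{road})$, mimicking
road-restricted field campaigns, and jittered inside their cells.

Choices the generator makes where the emulated world is open:

* **Road network density.** Eight crossing polylines over the 6 × 6 km
  window (a road roughly every 700–800 m) reflect a park managed for
  vehicle-based tourism; a single road would make the "access along roads"
  sampling bias a negligible feature of the data.
* **Autocorrelation scale** of 4 cells (≈ 120 m): long enough that block
  cross-validation is meaningfully different from random splits, short
  enough that predictors vary within 300 m blocks (fields much smoother
  than the blocks would make every within-block contrast degenerate).
* **Intercept** $\beta_0 = -2$: a baseline presence odds of
  $\approx 0.12$, so that suitable habitat is the exception rather than
  the rule and presences concentrate where the informative bands say they
  should.

These three values were calibrated once, jointly, so that the generator
actually exhibits the properties the pipeline is meant to demonstrate
(recoverable drivers and a discriminable presence/background contrast
under spatial-block validation); they are not re-tuned per run.

What the generator does **not** emulate: radiative-transfer-realistic
reflectances, temporally correlated weather, anisotropic terrain structure,
mixed pixels, or geolocation error. A green test on synthetic data
establishes that the pipeline's statistical machinery behaves as specified
under its own assumptions — not that any real landscape satisfies those
assumptions.

## Numerical conventions

* **Grid convention**: row 1 is the northernmost row; a point $(x, y)$ maps
  to `col = floor((x − x0)/c) + 1`, `row = floor((y0 − y)/c) + 1`; cells are
  half-open, so shared edges belong to exactly one cell.
* **Nodata**: masked cells are `NA` and excluded from every statistic;
  stacks unify masks across bands. Bilinear resampling masks a target cell
  if *any* of its four support cells is nodata — interpolation must not
  fabricate values near water.
* **Median composites**: even counts take the mean of the central pair.
* **Vegetation indices**: cells with a zero denominator are masked, not
  clipped. TVI is implemented as $\sqrt{\mathrm{NDVI} + 0.5}$ (the standard
  transformed vegetation index); the literal additive form
  $\mathrm{NDVI} + 0.5$ is available via `tviForm = "additive"` because the
  two appear interchangeably in applied work.
* **Ties**: majority votes over an even ensemble break ties to absence
  (conservative); AUC-ROC counts score ties as one half; AUC-PR groups tied
  scores at one threshold, making average precision well defined.
* **Determinism**: every stochastic step (thinning, k-means restarts, block
  partitioning, pseudo-absence draws, bootstrap and `mtry` sampling in the
  C++ forest) is driven by explicit integer seeds derived from the master
  seed, so a full run reproduces bit-for-bit.
* **Degenerate inputs**: empty road networks rasterise to all-zero with a
  warning; constant bands are dropped before clustering; a validation
  partition that loses one class (possible on tiny toy landscapes) yields
  `NA` metrics with a warning rather than an error.

## Design decisions taken where the design was open

* **File formats.** Rasters are read and written as plain-text ESRI ASCII
  grids (with a JSON manifest for multi-band stacks) rather than GeoTIFF:
  the format is standard, human-readable and dependency-free. Roads and
  points use GeoJSON/CSV in a projected metric CRS. No reprojection is
  attempted.
* **Classifier.** The bagged-tree ensemble is implemented natively (Rcpp)
  with the canonical random-forest construction — bootstrap, per-node
  feature subsetting, Gini impurity, mean-decrease-in-impurity importance —
  rather than depending on an external learner, which keeps the seeded
  reproducibility contract fully under the package's control.
* **Profiling granularity.** Environmental clustering runs once per
  predictor stack and is shared by all ten iterations; only the partition
  and sampling seeds vary per iteration. The profiling describes the
  landscape, not a particular data split.
* **70/30 unit.** The split counts presence-bearing blocks, not points;
  per-block class balance then keeps the point-level split close to 70/30.
* **Change maps** difference the continuous HSI surfaces (the binary maps
  feed only the area table), and the headline percentage is rounded to a
  whole percent.

## Known limitations

* Pseudo-absence quality degrades when presences occupy every environmental
  cluster *and* the landscape is environmentally homogeneous within blocks;
  the fallback rule then samples background that may resemble presences,
  and validation AUC drops accordingly. This is a property of profiling
  methods generally, reproduced faithfully here: on the default synthetic
  world the per-block balance rule bounds block-CV AUC-ROC near 0.8,
  because balanced background points must share the presence blocks' local
  environment. The bound is a property of the data-generating contrast,
  not of the learner.
* Profiling transfers importance to categorical bands: eligible clusters
  are selected partly on per-cluster presence-count noise, which makes the
  land-cover composition of pseudo-absences differ systematically from the
  presences'. One or two land-cover bands can therefore rank above a
  genuinely informative band with a modest coefficient. When interpreting
  importances from profiled pseudo-absences, treat categorical bands with
  caution.
* Mean-decrease-in-impurity importances are diluted across correlated or
  numerous noise predictors; ranking, not magnitude, is the meaningful
  output.
* The pipeline assumes a single shared geometry; reprojection, cloud
  masking and atmospheric correction are upstream concerns out of scope.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
sc <- synthLandscape(seed = 1)                     # default stated world
occ <- samplePresences(sc$truth, n = 400, seed = 2)
pres <- thinToCells(occ, sc$stack, seed = 3)
res <- runEnsemble(sc$stack, pres, seed = 1)
summarizeIterations(iterationMetrics(res))
head(sort(meanImportance(res), decreasing = TRUE))
suitableAreaKm2(majorityMap(res))
```

The same run, end to end with outputs on disk, is one call:

```{r pipeline, eval = FALSE}
cfg <- list(synthetic = list(nPresences = 400, years = c("2022", "2023")),
            nIterations = 10, seed = 1)
runPipeline(cfg, outDir = "runs/demo")
```
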