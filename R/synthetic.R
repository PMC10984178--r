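# Synthetic landscape generator. Produces covariate rasters, forest and
# village geometry, core habitat nodes and occurrence points with the
# statistical structure the downstream analysis assumes, plus the known
# ground-truth suitability surface used for parameter-recovery tests.

#' Spatially autocorrelated Gaussian random field
#'
#' Spectral synthesis: white noise is filtered in the Fourier domain with
#' a power-law amplitude |f|^(-roughness/2), giving a seedable,
#' fast, stationary autocorrelated field. \code{roughness = 0} returns
#' plain white noise; larger values give smoother fields.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param roughness spectral exponent (>= 0, dimensionless).
#' @param seed integer RNG seed.
#' @return A \linkS4class{GridRaster} standardized to mean 0, sd 1.
#' @export
gaussianField <- function(grid, roughness = 3, seed = 1) {
  if (grid@nRows < 1 || grid@nCols < 1) stop("non-positive grid")
  set.seed(seed)
  nr <- grid@nRows; nc <- grid@nCols
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (roughness > 0) {
    fr <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1) / nr
    fc <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1) / nc
    f <- sqrt(outer(fr^2, fc^2, `+`))
    filt <- ifelse(f > 0, f^(-roughness / 2), 0)
    field <- Re(stats::fft(stats::fft(noise) * filt, inverse = TRUE)) /
      (nr * nc)
  } else {
    field <- noise
  }
  field <- (field - mean(field)) / stats::sd(field)
  gridRaster(field, grid, "field")
}

#' Synthetic elevation surface
#'
#' An autocorrelated field rescaled to a configured elevation range,
#' standing in for a resampled DEM.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param roughness spectral exponent of the field (default 3).
#' @param range elevation range in metres (default 0 to 1200).
#' @param seed RNG seed.
#' @return A \linkS4class{GridRaster} named "elevation" (metres).
#' @export
makeElevation <- function(grid, roughness = 3, range = c(0, 1200), seed = 1) {
  f <- gaussianField(grid, roughness, seed)@values
  v <- (f - min(f)) / (max(f) - min(f)) * diff(range) + range[1]
  gridRaster(v, grid, "elevation")
}

#' Terrain ruggedness index
#'
#' Per cell, the square root of the summed squared elevation differences
#' to its eight neighbours (Riley's TRI); edge cells use the neighbours
#' that exist. Nodata propagates: a cell is nodata if its own elevation
#' is, and nodata neighbours are skipped.
#'
#' @param elevation elevation \linkS4class{GridRaster} (metres).
#' @return A \linkS4class{GridRaster} named "tri".
#' @export
deriveTri <- function(elevation) {
  z <- elevation@values
  if (all(is.na(z))) stop("all-nodata elevation input")
  nr <- nrow(z); nc <- ncol(z)
  acc <- matrix(0, nr, nc)
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- z
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
      d2 <- (z - nb)^2
      d2[is.na(d2)] <- 0
      acc <- acc + d2
    }
  }
  out <- sqrt(acc)
  out[is.na(z)] <- NA_real_
  gridRaster(out, elevation@grid, "tri")
}

#' Pooled mean NDVI over noisy epochs
#'
#' Generates \code{nEpochs} NDVI layers (a forest-elevated base plus an
#' autocorrelated component and per-epoch white noise, clamped to
#' [-1, 1]) and returns their per-cell mean, mirroring multi-year
#' seasonal NDVI pooling.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param forestMask 0/1 \linkS4class{GridRaster}.
#' @param nEpochs number of epochs pooled (default 45).
#' @param seed RNG seed.
#' @param base non-forest baseline NDVI (default 0.25).
#' @param forestBoost NDVI lift inside forest (default 0.35).
#' @param epochSd per-epoch white-noise sd (default 0.05).
#' @param keepEpochs when TRUE, attach the individual epoch matrices as
#'   attribute \code{"epochs"} for auditing.
#' @return Mean-NDVI \linkS4class{GridRaster} named "ndvi".
#' @export
makeNdvi <- function(grid, forestMask, nEpochs = 45, seed = 1, base = 0.25,
                     forestBoost = 0.35, epochSd = 0.05,
                     keepEpochs = FALSE) {
  if (nEpochs < 1) stop("nEpochs must be >= 1")
  checkCoRegistered(forestMask, gridRaster(0, grid))
  spatial <- 0.08 * gaussianField(grid, 3, seed)@values
  fixed <- base + forestBoost * forestMask@values + spatial
  set.seed(seed + 1L)
  epochs <- vector("list", nEpochs)
  acc <- matrix(0, grid@nRows, grid@nCols)
  for (e in seq_len(nEpochs)) {
    ep <- fixed + matrix(stats::rnorm(grid@nRows * grid@nCols, 0, epochSd),
                         grid@nRows, grid@nCols)
    ep <- pmax(pmin(ep, 1), -1)  # ep first so matrix dims survive
    epochs[[e]] <- ep
    acc <- acc + ep
  }
  out <- gridRaster(acc / nEpochs, grid, "ndvi")
  if (keepEpochs) attr(out@values, "epochs") <- epochs
  out
}

#' Synthetic protected areas and distance-to-PA surface
#'
#' Places \code{nPa} rectangular protected-area polygons and computes the
#' Euclidean distance from every cell centre to the nearest one (zero
#' inside).
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param nPa number of protected areas (>= 1).
#' @param seed RNG seed.
#' @param sideRange range of rectangle side lengths in km.
#' @return List with \code{polygons} (list of \code{simplePolygon}) and
#'   \code{dist} (a \linkS4class{GridRaster} named "dist_pa", km).
#' @export
makeProtectedAreas <- function(grid, nPa = 5, seed = 1,
                               sideRange = c(10, 30)) {
  if (nPa < 1) stop("nPa must be >= 1")
  set.seed(seed)
  ext <- gridExtent(grid)
  polys <- vector("list", nPa)
  for (i in seq_len(nPa)) {
    w <- stats::runif(1, sideRange[1], sideRange[2])
    h <- stats::runif(1, sideRange[1], sideRange[2])
    x0 <- stats::runif(1, ext["xmin"], max(ext["xmin"], ext["xmax"] - w))
    y0 <- stats::runif(1, ext["ymin"], max(ext["ymin"], ext["ymax"] - h))
    polys[[i]] <- rectPolygon(x0, min(x0 + w, ext["xmax"]),
                              y0, min(y0 + h, ext["ymax"]),
                              id = i, name = paste0("PA", i))
  }
  ctr <- cellCenters(grid)
  d <- rep(Inf, nrow(ctr))
  for (p in polys) d <- pmin(d, distanceToPolygon(p, ctr[, "x"], ctr[, "y"]))
  list(
    polygons = polys,
    dist = gridRaster(matrix(d, grid@nRows, grid@nCols), grid, "dist_pa")
  )
}

#' Synthetic forest mask
#'
#' Thresholds an autocorrelated field so that a configured fraction of
#' the landscape is forest (default roughly a third, typical of a
#' forested Indian state).
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param cover forest fraction in (0, 1) (default 0.35).
#' @param roughness field smoothness (default 4).
#' @param seed RNG seed.
#' @return 0/1 \linkS4class{GridRaster} named "forest".
#' @export
makeForestMask <- function(grid, cover = 0.35, roughness = 4, seed = 1) {
  f <- gaussianField(grid, roughness, seed)@values
  thr <- stats::quantile(f, 1 - cover)
  gridRaster((f >= thr) * 1, grid, "forest")
}

#' Synthetic village polygons
#'
#' Compact square villages centred on non-forest cells, with areas drawn
#' around a 2.92-km2 mean so that village-centroid geocoding error stays
#' below about 1 km.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param forestMask 0/1 \linkS4class{GridRaster}.
#' @param nVillages number of villages.
#' @param seed RNG seed.
#' @param meanArea mean village area in km2 (default 2.92).
#' @return List of \code{simplePolygon}s.
#' @export
makeVillages <- function(grid, forestMask, nVillages = 50, seed = 1,
                         meanArea = 2.92) {
  set.seed(seed)
  open <- which(forestMask@values == 0)
  if (!length(open)) stop("no non-forest cells for villages")
  cells <- sample(open, min(nVillages, length(open)))
  ctr <- cellCenters(grid, cells)
  areas <- pmax(0.5, stats::rgamma(length(cells), shape = 4,
                                   scale = meanArea / 4))
  lapply(seq_along(cells), function(i) {
    s <- sqrt(areas[i]) / 2
    rectPolygon(ctr[i, "x"] - s, ctr[i, "x"] + s,
                ctr[i, "y"] - s, ctr[i, "y"] + s,
                id = i, name = paste0("village", i))
  })
}

#' Synthetic core habitat nodes
#'
#' Rectangular habitat patches of at least \code{minArea} km2 (default
#' 100 km2, an annual home range) placed with limited overlap, to act as
#' terminals in the connectivity analyses.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param nNodes number of nodes.
#' @param minArea minimum patch area (km2).
#' @param seed RNG seed.
#' @param maxArea maximum patch area (km2).
#' @return List of \code{simplePolygon}s with ids 1..nNodes.
#' @export
makeCoreNodes <- function(grid, nNodes = 6, minArea = 100, seed = 1,
                          maxArea = 900) {
  set.seed(seed)
  ext <- gridExtent(grid)
  polys <- list()
  tries <- 0L
  while (length(polys) < nNodes && tries < 2000L) {
    tries <- tries + 1L
    area <- stats::runif(1, minArea, maxArea)
    aspect <- stats::runif(1, 0.6, 1.6)
    w <- sqrt(area * aspect); h <- area / w
    if (w >= diff(ext[c("xmin", "xmax")]) ||
        h >= diff(ext[c("ymin", "ymax")])) next
    x0 <- stats::runif(1, ext["xmin"], ext["xmax"] - w)
    y0 <- stats::runif(1, ext["ymin"], ext["ymax"] - h)
    cand <- rectPolygon(x0, x0 + w, y0, y0 + h,
                        id = length(polys) + 1L,
                        name = paste0("Node", length(polys) + 1L))
    ok <- all(vapply(polys, function(p) polygonDistance(p, cand) > 2,
                     logical(1)))
    if (ok) polys[[length(polys) + 1L]] <- cand
  }
  if (length(polys) < nNodes)
    stop("could not place ", nNodes, " non-overlapping core nodes")
  polys
}

#' Ground-truth suitability from a linear logit model
#'
#' logistic(intercept + sum coefficient x standardized covariate); the
#' surface the ensemble is asked to recover in validation runs.
#'
#' @param covariates a \linkS4class{CovariateStack}.
#' @param truth list with \code{intercept} (logit units) and
#'   \code{coefficients}, a named vector on the logit scale per
#'   standardized covariate.
#' @return \linkS4class{GridRaster} named "true_suitability", strictly in
#'   (0, 1).
#' @export
makeTrueSuitability <- function(covariates, truth) {
  if (!all(names(truth$coefficients) %in% names(covariates)))
    stop("truth coefficients name covariates missing from the stack")
  g <- gridOf(covariates)
  eta <- matrix(truth$intercept, g@nRows, g@nCols)
  for (nm in names(truth$coefficients)) {
    v <- covariates[[nm]]@values
    vs <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    eta <- eta + truth$coefficients[[nm]] * vs
  }
  gridRaster(stats::plogis(eta), g, "true_suitability")
}

#' Sample presence points from a suitability surface
#'
#' Cells are drawn with probability proportional to suitability times an
#' effort weight \code{exp(effortBias x accessibility)}; accessibility is
#' a standardized negative distance-to-village surface, mimicking the
#' reporting bias of opportunistic and newspaper records. With
#' \code{effortBias = 0} sampling is proportional to suitability alone.
#' Points are jittered uniformly within their cell.
#'
#' @param trueSuitability \linkS4class{GridRaster} in (0, 1).
#' @param nPoints number of presences.
#' @param effortBias bias strength >= 0 (default 0).
#' @param accessibility optional \linkS4class{GridRaster}; larger =
#'   better surveyed. Required when \code{effortBias > 0}.
#' @param seed RNG seed.
#' @return data.frame with x, y, source = "direct", label = 1.
#' @export
samplePresences <- function(trueSuitability, nPoints, effortBias = 0,
                            accessibility = NULL, seed = 1) {
  g <- trueSuitability@grid
  s <- as.vector(trueSuitability@values)
  ok <- which(!is.na(s))
  if (nPoints > length(ok) * 1e4)
    stop("nPoints far exceeds available cells")
  w <- s[ok]
  if (effortBias > 0) {
    if (is.null(accessibility))
      stop("effortBias > 0 requires an accessibility raster")
    a <- as.vector(accessibility@values)[ok]
    a <- (a - mean(a, na.rm = TRUE)) / stats::sd(a, na.rm = TRUE)
    w <- w * exp(effortBias * a)
  }
  set.seed(seed)
  cells <- ok[sample.int(length(ok), nPoints, replace = TRUE, prob = w)]
  ctr <- cellCenters(g, cells)
  jit <- matrix(stats::runif(2 * nPoints, -0.5, 0.5), ncol = 2) * g@cellSize
  data.frame(
    x = ctr[, "x"] + jit[, 1], y = ctr[, "y"] + jit[, 2],
    source = "direct", label = 1L, stringsAsFactors = FALSE
  )
}

#' Sample conflict points at the forest-village interface
#'
#' Conflict locations sit outside the forest mask, within a configured
#' Chebyshev distance of forest cells and inside or near villages --
#' emulating crop-raid and settlement-damage reports clustered where
#' settlements meet forest.
#'
#' @param forestMask 0/1 \linkS4class{GridRaster}.
#' @param villages list of village \code{simplePolygon}s.
#' @param nPoints number of conflicts.
#' @param seed RNG seed.
#' @param interfaceKm maximum distance (km) from forest and from a
#'   village for an eligible cell (default 3).
#' @return data.frame with x, y, source = "conflict", label = 1.
#' @export
sampleConflicts <- function(forestMask, villages, nPoints, seed = 1,
                            interfaceKm = 3) {
  g <- forestMask@grid
  k <- max(1L, as.integer(round(interfaceKm / g@cellSize)))
  nearForest <- .dilate(forestMask@values == 1, k)
  villageMask <- rasterizePolygons(villages, g)@values == 1
  nearVillage <- .dilate(villageMask, k)
  eligible <- which(forestMask@values == 0 & nearForest & nearVillage)
  if (!length(eligible))
    stop("no eligible forest-village interface cells")
  set.seed(seed)
  cells <- eligible[sample.int(length(eligible), nPoints, replace = TRUE)]
  ctr <- cellCenters(g, cells)
  jit <- matrix(stats::runif(2 * nPoints, -0.45, 0.45), ncol = 2) *
    g@cellSize
  data.frame(
    x = ctr[, "x"] + jit[, 1], y = ctr[, "y"] + jit[, 2],
    source = "conflict", label = 1L, stringsAsFactors = FALSE
  )
}

# binary dilation by k cells (Chebyshev), matrix of logicals
.dilate <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -k:k) {
    for (dc in -k:k) {
      if (dr == 0 && dc == 0) next
      sr <- max(1, 1 + dr):min(nr, nr + dr)
      tr <- max(1, 1 - dr):min(nr, nr - dr)
      sc <- max(1, 1 + dc):min(nc, nc + dc)
      tc <- max(1, 1 - dc):min(nc, nc - dc)
      out[tr, tc] <- out[tr, tc] | m[sr, sc]
    }
  }
  out
}

#' Simulate a full landscape bundle
#'
#' Generates co-registered covariates (bio12, elevation, tri, ndvi,
#' dist_pa), forest mask, protected areas, villages, core habitat nodes
#' and the ground-truth suitability surface under one seed. The default
#' truth makes NDVI the strongest (positive) driver, ruggedness positive,
#' distance to protected areas negative, with weaker elevation and
#' precipitation effects -- the qualitative structure a large forest
#' herbivore's habitat model is expected to recover.
#'
#' @param nRows,nCols grid dimensions (default 300 x 300 at 1 km).
#' @param seed RNG seed.
#' @param nPa,nNodes,nVillages feature counts.
#' @param truth optional truth override (list with intercept and named
#'   coefficients).
#' @param ndviEpochs epochs pooled for NDVI (default 45).
#' @return A list of class \code{"landscapeBundle"}: \code{covariates}
#'   (CovariateStack), \code{forestMask}, \code{trueSuitability},
#'   \code{paPolygons}, \code{coreNodes}, \code{villages}, \code{truth},
#'   \code{grid}.
#' @export
simulateLandscape <- function(nRows = 300, nCols = 300, seed = 1,
                              nPa = 5, nNodes = 6, nVillages = 60,
                              truth = NULL, ndviEpochs = 45) {
  grid <- gridSpec(nRows, nCols)
  if (is.null(truth)) {
    # Defaults emulate a landscape where good habitat is scarce (mean
    # suitability ~0.16, under a tenth highly suitable) and NDVI is the
    # dominant positive driver, ruggedness positive, distance to
    # protected areas negative -- the structure a large forest
    # herbivore's habitat model is expected to recover.
    truth <- list(
      intercept = -3.5,
      coefficients = c(ndvi = 2.5, tri = 1.2, elevation = -0.7,
                       dist_pa = -1.5, bio12 = 0.5)
    )
  }
  elev <- makeElevation(grid, seed = seed)
  tri <- deriveTri(elev)
  forest <- makeForestMask(grid, seed = seed + 1L)
  ndvi <- makeNdvi(grid, forest, nEpochs = ndviEpochs, seed = seed + 2L)
  pa <- makeProtectedAreas(grid, nPa = nPa, seed = seed + 3L)
  bio12raw <- gaussianField(grid, 3.5, seed + 4L)@values
  bio12 <- gridRaster(960 + (bio12raw - min(bio12raw)) /
                        diff(range(bio12raw)) * 910, grid, "bio12")
  covs <- stackCovariates(list(
    bio12 = bio12, elevation = elev, tri = tri, ndvi = ndvi,
    dist_pa = pa$dist
  ))
  suit <- makeTrueSuitability(covs, truth)
  villages <- makeVillages(grid, forest, nVillages, seed = seed + 5L)
  nodes <- makeCoreNodes(grid, nNodes = nNodes, seed = seed + 6L)
  structure(
    list(
      grid = grid, covariates = covs, forestMask = forest,
      trueSuitability = suit, paPolygons = pa$polygons,
      coreNodes = nodes, villages = villages, truth = truth
    ),
    class = "landscapeBundle"
  )
}

#' @exportS3Method base::print
print.landscapeBundle <- function(x, ...) {
  cat(sprintf(
    "landscapeBundle: %d x %d @ %g km | %d covariates | %d PAs, %d core nodes, %d villages\n",
    x$grid@nRows, x$grid@nCols, x$grid@cellSize,
    length(x$covariates@layers), length(x$paPolygons),
    length(x$coreNodes), length(x$villages)
  ))
  invisible(x)
}
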