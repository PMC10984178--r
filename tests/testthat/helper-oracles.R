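# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the code paths they check: shortest paths
# by Bellman-Ford relaxation, effective resistance by a dense
# pseudo-inverse, variograms and histograms by direct loops.

# Bellman-Ford single-source shortest path over an undirected edge list.
bfShortestPath <- function(edges, w, n, from) {
  d <- rep(Inf, n)
  d[from] <- 0
  for (pass in seq_len(n)) {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      if (d[i] + w[k] < d[j]) { d[j] <- d[i] + w[k]; changed <- TRUE }
      if (d[j] + w[k] < d[i]) { d[i] <- d[j] + w[k]; changed <- TRUE }
    }
    if (!changed) break
  }
  d
}

# Effective resistance via dense Laplacian pseudo-inverse.
denseEffectiveResistance <- function(edges, cond, n, a, b) {
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    L[i, j] <- L[i, j] - cond[k]; L[j, i] <- L[j, i] - cond[k]
    L[i, i] <- L[i, i] + cond[k]; L[j, j] <- L[j, j] + cond[k]
  }
  Lp <- MASS::ginv(L)
  Lp[a, a] + Lp[b, b] - 2 * Lp[a, b]
}

# Empirical semivariogram of a matrix field at integer lags (row
# direction), by direct differencing.
bruteVariogram <- function(m, lags) {
  vapply(lags, function(h) {
    d <- m[seq_len(nrow(m) - h), ] - m[seq_len(nrow(m) - h) + h, ]
    mean(d^2) / 2
  }, numeric(1))
}

# Random connected graph on n vertices: a spanning path plus extra edges.
randomConnectedGraph <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  edges <- cbind(1:(n - 1), 2:n)
  more <- cbind(sample(n, extra, TRUE), sample(n, extra, TRUE))
  more <- more[more[, 1] != more[, 2], , drop = FALSE]
  edges <- rbind(edges, more)
  cond <- stats::runif(nrow(edges), 0.2, 3)
  list(edges = edges, cond = cond, n = n)
}

# Small random resistance raster.
randomResistance <- function(nr, nc, seed) {
  set.seed(seed)
  gridRaster(matrix(stats::runif(nr * nc, 1, 100), nr, nc),
             gridSpec(nr, nc))
}

# An arbitrary weighted graph wrapped as a RasterGraph on a fake 1 x n
# grid, so the circuit solver can be exercised on hand-built networks.
graphAsRasterGraph <- function(edges, cost, n) {
  new("RasterGraph",
    grid = gridSpec(1, n), cellIndex = seq_len(n),
    vertexOf = seq_len(n), edges = cbind(i = edges[, 1], j = edges[, 2]),
    dist = rep(1, nrow(edges)), cost = cost
  )
}

# A small landscape bundle reused by several tests (cheap settings),
# cached per seed within a test run.
.landscapeCache <- new.env(parent = emptyenv())
tinyLandscape <- function(seed = 42) {
  key <- as.character(seed)
  if (is.null(.landscapeCache[[key]])) {
    .landscapeCache[[key]] <- simulateLandscape(
      nRows = 80, nCols = 80, seed = seed, nNodes = 3,
      nVillages = 20, ndviEpochs = 4
    )
  }
  .landscapeCache[[key]]
}
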