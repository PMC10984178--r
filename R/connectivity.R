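# Connectivity between core habitat nodes on a resistance raster:
# least-cost paths and corridors (movement-cost view) and a circuit
# solver for effective resistance, current density and current-flow
# centrality (random-walk view). The raster is an 8-neighbour weighted
# graph; node polygons are contracted to supernodes (infinite internal
# conductance) in all circuit solves.

#' Convert a suitability surface to movement resistance
#'
#' Resistance is the reciprocal of suitability (conductance proportional
#' to suitability), scaled and capped so values lie in [1, 100]:
#' resistance = 100 / max(suitability, 1).
#'
#' @param surface suitability \linkS4class{GridRaster} in [0, 100].
#' @return Resistance \linkS4class{GridRaster}; nodata propagates.
#' @examples
#' g <- gridSpec(2, 2)
#' r <- suitabilityToResistance(gridRaster(c(100, 50, 1, 0.2), g))
#' rasterValues(r)  # 1, 2, 100, 100
#' @export
suitabilityToResistance <- function(surface) {
  v <- surface@values
  if (any(v < 0 | v > 100, na.rm = TRUE))
    stop("suitability must lie in [0, 100]")
  gridRaster(100 / pmax(v, 1), surface@grid, "resistance")
}

#' Build the weighted graph of a resistance raster
#'
#' Vertices are valid cells, edges join 8-neighbours (none across
#' nodata). Edge cost = centre distance (cell size; sqrt(2) x cell size
#' on diagonals) x mean endpoint resistance.
#'
#' @param resistance \linkS4class{GridRaster} with values >= some
#'   positive floor.
#' @return A \linkS4class{RasterGraph}.
#' @export
rasterGraph <- function(resistance) {
  g <- resistance@grid
  res <- resistance@values
  if (any(res <= 0, na.rm = TRUE)) stop("resistance must be positive")
  nr <- g@nRows; nc <- g@nCols
  vertexOf <- rep(NA_integer_, nr * nc)
  valid <- which(!is.na(as.vector(res)))
  vertexOf[valid] <- seq_along(valid)
  V <- matrix(vertexOf, nr, nc)
  cs <- g@cellSize
  offs <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)),
               c(1L, -1L, sqrt(2)))
  ei <- list(); ej <- list(); ed <- list(); ec <- list()
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1]; dc <- offs[[k]][2]; dmul <- offs[[k]][3]
    if (dr >= nr || abs(dc) >= nc) next
    r1 <- 1:(nr - dr); r2 <- (1 + dr):nr
    if (dc >= 0) { c1 <- 1:(nc - dc); c2 <- (1 + dc):nc }
    else { c1 <- (1 - dc):nc; c2 <- 1:(nc + dc) }
    a <- V[r1, c1]; b <- V[r2, c2]
    ra <- res[r1, c1]; rb <- res[r2, c2]
    ok <- !is.na(a) & !is.na(b)
    ei[[k]] <- a[ok]; ej[[k]] <- b[ok]
    ed[[k]] <- rep(dmul * cs, sum(ok))
    ec[[k]] <- dmul * cs * (ra[ok] + rb[ok]) / 2
  }
  new("RasterGraph",
    grid = g, cellIndex = as.integer(valid),
    vertexOf = as.integer(vertexOf),
    edges = cbind(i = unlist(ei), j = unlist(ej)),
    dist = unlist(ed), cost = unlist(ec)
  )
}

# igraph view of a RasterGraph (plus optional supernodes: a list of
# vertex-id vectors; supernode s becomes vertex nV + s, tied to its
# members with zero-cost edges)
.asIgraph <- function(rg, supernodes = list()) {
  nV <- length(rg@cellIndex)
  edges <- rg@edges
  w <- rg@cost
  for (s in seq_along(supernodes)) {
    mem <- supernodes[[s]]
    edges <- rbind(edges, cbind(mem, rep(nV + s, length(mem))))
    w <- c(w, rep(0, length(mem)))
  }
  ig <- igraph::make_graph(t(edges), n = nV + length(supernodes),
                           directed = FALSE)
  igraph::E(ig)$weight <- w
  ig
}

# vertex ids (in the RasterGraph) covered by a polygon
.polyVertices <- function(rg, poly) {
  cells <- cellsInPolygon(poly, rg@grid)
  v <- rg@vertexOf[cells]
  v <- v[!is.na(v)]
  if (!length(v))
    stop("node polygon '", poly$name, "' covers no valid cell")
  v
}

#' Cost-weighted distance from a source polygon
#'
#' Multi-source least accumulated cost over the raster graph; source
#' cells have cost zero.
#'
#' @param rg a \linkS4class{RasterGraph}.
#' @param source a \code{simplePolygon}, or an integer vector of source
#'   vertex ids.
#' @return A \linkS4class{GridRaster} of CWD (Inf where disconnected).
#' @export
costDistance <- function(rg, source) {
  verts <- if (is.list(source)) .polyVertices(rg, source) else
    as.integer(source)
  d <- .cwdVertices(rg, verts)
  v <- rep(NA_real_, rg@grid@nRows * rg@grid@nCols)
  v[rg@cellIndex] <- d
  gridRaster(matrix(v, rg@grid@nRows, rg@grid@nCols), rg@grid, "cwd")
}

.cwdVertices <- function(rg, verts) {
  ig <- .asIgraph(rg, supernodes = list(verts))
  d <- igraph::distances(ig, v = length(rg@cellIndex) + 1L,
                         algorithm = "dijkstra")[1, ]
  d[seq_len(length(rg@cellIndex))]
}

#' Least-cost path between two node polygons
#'
#' The minimum-accumulated-cost route over the raster graph, backtraced
#' between the polygons' contracted supernodes. Ties between equal-cost
#' routes are broken deterministically by the graph construction order.
#'
#' @param rg a \linkS4class{RasterGraph}.
#' @param nodeA,nodeB \code{simplePolygon}s (or vertex-id vectors).
#' @return List: \code{cells} (linear cell indices along the path),
#'   \code{coords} (cell-centre polyline), \code{lcp_km} (geometric
#'   length), \code{cwd} (accumulated cost).
#' @export
leastCostPath <- function(rg, nodeA, nodeB) {
  vA <- if (is.list(nodeA)) .polyVertices(rg, nodeA) else as.integer(nodeA)
  vB <- if (is.list(nodeB)) .polyVertices(rg, nodeB) else as.integer(nodeB)
  nV <- length(rg@cellIndex)
  ig <- .asIgraph(rg, supernodes = list(vA, vB))
  sp <- igraph::shortest_paths(ig, from = nV + 1L, to = nV + 2L,
                               output = "both")
  vp <- as.integer(sp$vpath[[1]])
  if (!length(vp)) stop("node polygons are not connected in the graph")
  cwd <- sum(igraph::E(ig)$weight[as.integer(sp$epath[[1]])])
  vp <- vp[vp <= nV]  # strip supernodes
  cells <- rg@cellIndex[vp]
  coords <- cellCenters(rg@grid, cells)
  lcp <- if (nrow(coords) > 1)
    sum(sqrt(diff(coords[, "x"])^2 + diff(coords[, "y"])^2)) else 0
  list(cells = cells, coords = coords, lcp_km = lcp, cwd = cwd)
}

#' Ratio of Euclidean to least-cost-path length
#'
#' Tortuosity index in (0, 1]: 1 means the optimal route is straight,
#' small values mean long detours relative to how close the nodes are.
#'
#' @param euclidKm straight-line (edge-to-edge) distance.
#' @param lcpKm least-cost-path length.
#' @export
linkageRatio <- function(euclidKm, lcpKm) {
  if (lcpKm <= 0) stop("lcp length must be positive")
  euclidKm / lcpKm
}

#' Candidate node pairs for linkage
#'
#' In \code{"adjacency"} mode a pair is retained when its two
#' cost-allocation regions (each cell assigned to its CWD-nearest node)
#' share an 8-neighbour boundary -- the usual way corridor tools avoid
#' redundant long-range links. \code{"all"} keeps every pair.
#'
#' @param cwdList list of per-node CWD \linkS4class{GridRaster}s (same
#'   order as the node ids).
#' @param mode "adjacency" or "all".
#' @return Two-column matrix of node index pairs (i < j).
#' @export
candidateLinks <- function(cwdList, mode = c("adjacency", "all")) {
  mode <- match.arg(mode)
  n <- length(cwdList)
  if (n < 2) stop("need at least 2 nodes")
  allPairs <- t(utils::combn(n, 2))
  if (mode == "all") return(allPairs)
  stk <- vapply(cwdList, function(r) as.vector(r@values),
                numeric(length(cwdList[[1]]@values)))
  ok <- rowSums(is.na(stk) | stk == Inf) == 0
  alloc <- rep(NA_integer_, nrow(stk))
  alloc[ok] <- max.col(-stk[ok, , drop = FALSE], ties.method = "first")
  g <- cwdList[[1]]@grid
  A <- matrix(alloc, g@nRows, g@nCols)
  touch <- matrix(FALSE, n, n)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- off[1]; dc <- off[2]
    if (dr >= g@nRows || abs(dc) >= g@nCols) next
    r1 <- 1:(g@nRows - dr); r2 <- (1 + dr):g@nRows
    if (dc >= 0) { c1 <- 1:(g@nCols - dc); c2 <- (1 + dc):g@nCols }
    else { c1 <- (1 - dc):g@nCols; c2 <- 1:(g@nCols + dc) }
    a <- A[r1, c1]; b <- A[r2, c2]
    keep <- !is.na(a) & !is.na(b) & a != b
    if (any(keep)) {
      pr <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
      touch[unique(pr, MARGIN = 1)] <- TRUE
    }
  }
  allPairs[touch[allPairs], , drop = FALSE]
}

#' Corridor (cost-sum) surface for one link
#'
#' Per cell, \code{cwd_a + cwd_b - cwd_of_lcp}: zero on the optimal
#' path, growing with the extra cost of detouring through the cell.
#' Cells beyond the truncation are masked (by Euclidean distance from
#' the path polyline, default 50 km, or in cost units), and the
#' remaining values are cut into three equal-interval movement classes
#' (1 high, 2 moderate, 3 least movement-prone -- class 1 is the
#' cheapest band).
#'
#' @param cwdA,cwdB CWD \linkS4class{GridRaster}s of the two nodes.
#' @param lcpCost accumulated cost of the least-cost path.
#' @param path optional \code{leastCostPath} result (needed for
#'   Euclidean truncation).
#' @param truncation threshold value (default 50).
#' @param truncationMode "euclid_km" (distance from the path) or
#'   "cost" (corridor value).
#' @return List: \code{surface} (GridRaster, NA outside the corridor),
#'   \code{classes} (GridRaster in 1..3), \code{breaks}.
#' @export
corridorSurface <- function(cwdA, cwdB, lcpCost, path = NULL,
                            truncation = 50,
                            truncationMode = c("euclid_km", "cost")) {
  truncationMode <- match.arg(truncationMode)
  checkCoRegistered(cwdA, cwdB)
  g <- cwdA@grid
  v <- cwdA@values + cwdB@values - lcpCost
  v[v < 0] <- 0  # guard tiny negative rounding on the path
  if (truncationMode == "euclid_km") {
    if (is.null(path)) stop("euclid_km truncation needs the path")
    ctr <- cellCenters(g)
    pd <- rep(Inf, nrow(ctr))
    px <- path$coords[, "x"]; py <- path$coords[, "y"]
    for (k in seq_along(px))
      pd <- pmin(pd, (ctr[, "x"] - px[k])^2 + (ctr[, "y"] - py[k])^2)
    v[matrix(sqrt(pd) > truncation, g@nRows, g@nCols)] <- NA_real_
  } else {
    v[v > truncation] <- NA_real_
  }
  rng <- range(v, na.rm = TRUE)
  brk <- rng[1] + diff(rng) * c(1, 2) / 3
  cls <- 1 + (v > brk[1]) + (v > brk[2])
  list(
    surface = gridRaster(v, g, "corridor"),
    classes = gridRaster(cls, g, "movement_class"),
    breaks = brk
  )
}

# ---- circuit solver ----

# Solve node potentials with unit current injected at supernode A and
# extracted at supernode B, contracting the vertex groups. edges is a
# 2-col matrix, cond the edge conductances, nV the vertex count.
# Returns potentials per original vertex (groups share one value),
# plus the contracted-map bookkeeping.
.solveCircuit <- function(edges, cond, nV, groupA, groupB) {
  if (length(intersect(groupA, groupB)))
    stop("terminal groups overlap")
  map <- seq_len(nV)
  map[groupA] <- nV + 1L
  map[groupB] <- nV + 2L
  keep <- sort(unique(map))
  relab <- match(map, keep)
  a <- relab[map == nV + 1L][1]
  b <- relab[map == nV + 2L][1]
  m <- length(keep)
  ei <- relab[edges[, 1]]; ej <- relab[edges[, 2]]
  ok <- ei != ej
  ei <- ei[ok]; ej <- ej[ok]; cc <- cond[ok]
  W <- Matrix::sparseMatrix(
    i = c(ei, ej), j = c(ej, ei), x = c(cc, cc), dims = c(m, m)
  )
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  free <- setdiff(seq_len(m), b)
  rhs <- rep(0, m); rhs[a] <- 1
  sol <- Matrix::solve(L[free, free, drop = FALSE], rhs[free])
  pot <- rep(0, m)
  pot[free] <- as.numeric(sol)
  list(
    potential = pot[relab],      # per original vertex
    potA = pot[a], potB = pot[b],
    relab = relab, a = a, b = b,
    edgeCurrent = cc * (pot[ei] - pot[ej]),
    edgesKept = cbind(ei, ej), ok = ok
  )
}

#' Effective resistance between two node polygons
#'
#' The landscape is treated as a resistor network (edge conductance =
#' 1 / edge cost); each node polygon is contracted to a supernode and
#' one ampere is passed between the two. The potential difference is the
#' effective resistance; it can only decrease as parallel pathways are
#' added, and never exceeds the accumulated cost of the least-cost path.
#'
#' @param rg a \linkS4class{RasterGraph}.
#' @param nodeA,nodeB \code{simplePolygon}s or vertex-id vectors.
#' @return Effective resistance (Inf for a disconnected pair).
#' @export
effectiveResistance <- function(rg, nodeA, nodeB) {
  vA <- if (is.list(nodeA)) .polyVertices(rg, nodeA) else as.integer(nodeA)
  vB <- if (is.list(nodeB)) .polyVertices(rg, nodeB) else as.integer(nodeB)
  if (!.isConnectedPair(rg, vA, vB)) return(Inf)
  sol <- .solveCircuit(rg@edges, 1 / rg@cost, length(rg@cellIndex),
                       vA, vB)
  sol$potA - sol$potB
}

.isConnectedPair <- function(rg, vA, vB) {
  ig <- .asIgraph(rg)
  comp <- igraph::components(ig)$membership
  comp[vA[1]] == comp[vB[1]]
}

#' Current density and pinch points for one link
#'
#' Per-cell current from the pair solve: half the summed absolute
#' currents of incident edges (terminals add their injected ampere).
#' Pinch points are the cells above a high quantile of within-corridor
#' current -- narrow sections with no nearby alternative routes.
#'
#' @param rg a \linkS4class{RasterGraph}.
#' @param nodeA,nodeB \code{simplePolygon}s or vertex-id vectors.
#' @param corridorMask optional \linkS4class{GridRaster}; non-NA cells
#'   define the corridor to which the report is restricted.
#' @param pinchQuantile quantile defining pinch points (default 0.995).
#' @return List: \code{current} (GridRaster, NA on node cells),
#'   \code{pinchPoints} (data.frame cell, x, y, current),
#'   \code{maxKirchhoffImbalance} (solver residual, amperes).
#' @export
currentDensity <- function(rg, nodeA, nodeB, corridorMask = NULL,
                           pinchQuantile = 0.995) {
  vA <- if (is.list(nodeA)) .polyVertices(rg, nodeA) else as.integer(nodeA)
  vB <- if (is.list(nodeB)) .polyVertices(rg, nodeB) else as.integer(nodeB)
  nV <- length(rg@cellIndex)
  sol <- .solveCircuit(rg@edges, 1 / rg@cost, nV, vA, vB)
  absI <- abs(sol$edgeCurrent)
  m <- max(sol$relab)
  inc <- numeric(m)
  for (cl in 1:2) {
    s <- tapply(absI, sol$edgesKept[, cl], sum)
    inc[as.integer(names(s))] <- inc[as.integer(names(s))] + s
  }
  inj <- numeric(m); inj[sol$a] <- 1; inj[sol$b] <- 1
  nodeCur <- (inc + inj) / 2
  # net-current residual at non-terminal contracted vertices
  net <- numeric(m)
  for (cl in 1:2) {
    sgn <- if (cl == 1) 1 else -1
    s <- tapply(sol$edgeCurrent, sol$edgesKept[, cl], sum)
    net[as.integer(names(s))] <- net[as.integer(names(s))] + sgn * s
  }
  residual <- max(abs(net[-c(sol$a, sol$b)]))
  cur <- nodeCur[sol$relab]
  cur[c(vA, vB)] <- NA_real_  # per-cell current is undefined inside terminals
  v <- rep(NA_real_, rg@grid@nRows * rg@grid@nCols)
  v[rg@cellIndex] <- cur
  if (!is.null(corridorMask))
    v[is.na(as.vector(corridorMask@values))] <- NA_real_
  out <- gridRaster(matrix(v, rg@grid@nRows, rg@grid@nCols), rg@grid,
                    "current")
  thr <- stats::quantile(v, pinchQuantile, na.rm = TRUE)
  pp <- which(!is.na(v) & v >= thr)
  ctr <- cellCenters(rg@grid, pp)
  list(
    current = out,
    pinchPoints = data.frame(cell = pp, x = ctr[, "x"], y = ctr[, "y"],
                             current = v[pp]),
    maxKirchhoffImbalance = residual
  )
}

#' Current-flow centrality on the reduced node/link graph
#'
#' The reduced graph has the habitat nodes as vertices and the retained
#' links as edges with resistance equal to the link's accumulated cost.
#' For every unordered node pair one ampere is passed through the
#' network; a link's centrality is the sum of the absolute currents it
#' carries over all pair solves, a node's the summed current through it
#' (terminals count their injected ampere). Pairs in different
#' components contribute nothing.
#'
#' @param nodeIds integer vertex ids of the reduced graph.
#' @param links data.frame with from_node, to_node and cwd columns.
#' @return List: \code{nodeScores} (named by node id),
#'   \code{linkScores} (aligned with \code{links} rows).
#' @export
networkCentrality <- function(nodeIds, links) {
  n <- length(nodeIds)
  idx <- function(v) match(v, nodeIds)
  ei <- idx(links$from_node); ej <- idx(links$to_node)
  cond <- 1 / links$cwd
  W <- matrix(0, n, n)
  for (k in seq_along(ei)) {
    W[ei[k], ej[k]] <- W[ei[k], ej[k]] + cond[k]
    W[ej[k], ei[k]] <- W[ej[k], ei[k]] + cond[k]
  }
  L <- diag(rowSums(W)) - W
  # pseudo-inverse via eigen decomposition (small dense graph)
  eg <- eigen(L, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  Linv <- eg$vectors[, pos, drop = FALSE] %*%
    diag(1 / eg$values[pos], sum(pos)) %*%
    t(eg$vectors[, pos, drop = FALSE])
  comp <- .componentsOf(ei, ej, n)
  nodeScores <- numeric(n)
  linkScores <- numeric(nrow(links))
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      if (comp[s] != comp[t]) next
      pot <- Linv[, s] - Linv[, t]
      I <- cond * (pot[ei] - pot[ej])
      linkScores <- linkScores + abs(I)
      through <- numeric(n)
      for (k in seq_along(ei)) {
        through[ei[k]] <- through[ei[k]] + abs(I[k])
        through[ej[k]] <- through[ej[k]] + abs(I[k])
      }
      inj <- numeric(n); inj[c(s, t)] <- 1
      nodeScores <- nodeScores + (through + inj) / 2
    }
  }
  list(
    nodeScores = stats::setNames(nodeScores, nodeIds),
    linkScores = linkScores
  )
}

.componentsOf <- function(ei, ej, n) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_along(ei)) {
      m <- min(comp[ei[k]], comp[ej[k]])
      if (comp[ei[k]] != m || comp[ej[k]] != m) {
        comp[comp == comp[ei[k]] | comp == comp[ej[k]]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Three-class equal-interval centrality ranks
#'
#' Breaks at anchor + k (max - anchor) / 3 for k = 1, 2, where the
#' anchor is the minimum score (\code{"min"}) or zero (\code{"zero"}).
#' Scores in the top band rank "high", the middle "moderate", the
#' bottom "least". Equal scores are a degenerate single-class case,
#' flagged and ranked "moderate".
#'
#' @param scores numeric centrality scores.
#' @param anchor "min" or "zero".
#' @return List: \code{classes} (character vector), \code{breaks},
#'   \code{degenerate}.
#' @export
classifyCentrality <- function(scores, anchor = c("min", "zero")) {
  anchor <- match.arg(anchor)
  a <- if (anchor == "min") min(scores) else 0
  mx <- max(scores)
  if (mx - a < 1e-12) {
    return(list(classes = rep("moderate", length(scores)),
                breaks = c(NA_real_, NA_real_), degenerate = TRUE))
  }
  brk <- a + (mx - a) * c(1, 2) / 3
  cls <- c("least", "moderate", "high")[1 + (scores > brk[1]) +
                                          (scores > brk[2])]
  list(classes = cls, breaks = brk, degenerate = FALSE)
}

#' Path length outside the forest mask
#'
#' Each polyline segment is subdivided finely and the length of the
#' pieces whose midpoints fall on non-forest cells is accumulated.
#'
#' @param coords two-column polyline coordinate matrix (km).
#' @param forestMask 0/1 \linkS4class{GridRaster}.
#' @param nSub subdivisions per segment (default 20).
#' @return Length outside forest in km.
#' @export
lengthOutsideForest <- function(coords, forestMask, nSub = 20) {
  if (nrow(coords) < 2) return(0)
  total <- 0
  for (k in seq_len(nrow(coords) - 1)) {
    x0 <- coords[k, 1]; y0 <- coords[k, 2]
    x1 <- coords[k + 1, 1]; y1 <- coords[k + 1, 2]
    L <- sqrt((x1 - x0)^2 + (y1 - y0)^2) / nSub
    tm <- (seq_len(nSub) - 0.5) / nSub
    fx <- x0 + tm * (x1 - x0); fy <- y0 + tm * (y1 - y0)
    f <- valuesAtXY(forestMask, fx, fy)
    total <- total + L * sum(f != 1, na.rm = TRUE) + L * sum(is.na(f))
  }
  unname(total)
}

#' Full node/link connectivity analysis
#'
#' Runs the whole connectivity chain on a resistance surface and a set
#' of core habitat node polygons: per-node cost-weighted distances,
#' candidate links by cost-allocation adjacency (or all pairs),
#' least-cost paths, Euclidean distances and tortuosity ratios,
#' raster-level effective resistance, reduced-graph current-flow
#' centrality with equal-interval ranks, and (optionally) path length
#' outside forest.
#'
#' @param resistance \linkS4class{GridRaster} of movement resistance.
#' @param nodes list of \code{simplePolygon} core nodes with unique ids.
#' @param forestMask optional 0/1 \linkS4class{GridRaster}.
#' @param linkMode "adjacency" or "all".
#' @param centralityAnchor "min" or "zero".
#' @param computeEffectiveResistance set FALSE to skip the circuit
#'   solves (cheap LCP-only run).
#' @param minNodeSeparationKm links with smaller Euclidean separation
#'   are dropped when > 0 (default 0: keep all).
#' @param minNodeAreaKm2 minimum node polygon area (default 100).
#' @return List of class \code{"connectivityAnalysis"}: \code{nodes}
#'   and \code{links} data.frames mirroring the published table
#'   layouts, \code{paths} (per-link \code{leastCostPath} results),
#'   \code{cwd} (per-node CWD rasters), \code{graph}.
#' @export
analyzeConnectivity <- function(resistance, nodes, forestMask = NULL,
                                linkMode = c("adjacency", "all"),
                                centralityAnchor = "min",
                                computeEffectiveResistance = TRUE,
                                minNodeSeparationKm = 0,
                                minNodeAreaKm2 = 100) {
  linkMode <- match.arg(linkMode)
  areas <- vapply(nodes, polygonArea, numeric(1))
  if (any(areas < minNodeAreaKm2))
    stop("node polygons below the minimum core area (",
         minNodeAreaKm2, " km2): ",
         paste(vapply(nodes[areas < minNodeAreaKm2], `[[`, character(1),
                      "name"), collapse = ", "))
  rg <- rasterGraph(resistance)
  ids <- vapply(nodes, `[[`, integer(1), "id")
  cwd <- lapply(nodes, function(p) costDistance(rg, p))
  pairs <- candidateLinks(cwd, linkMode)
  if (minNodeSeparationKm > 0) {
    sep <- apply(pairs, 1, function(p)
      polygonDistance(nodes[[p[1]]], nodes[[p[2]]]))
    pairs <- pairs[sep >= minNodeSeparationKm, , drop = FALSE]
  }
  paths <- list()
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    pth <- leastCostPath(rg, nodes[[i]], nodes[[j]])
    euc <- polygonDistance(nodes[[i]], nodes[[j]])
    er <- if (computeEffectiveResistance)
      effectiveResistance(rg, nodes[[i]], nodes[[j]]) else NA_real_
    ofk <- if (!is.null(forestMask))
      lengthOutsideForest(pth$coords, forestMask) else NA_real_
    paths[[k]] <- pth
    rows[[k]] <- data.frame(
      from_node = min(ids[i], ids[j]), to_node = max(ids[i], ids[j]),
      euclid_km = unname(euc), lcp_km = pth$lcp_km,
      ratio = if (pth$lcp_km > 0) unname(euc) / pth$lcp_km else 1,
      cwd = pth$cwd, effective_resistance = unname(er),
      outside_forest_km = unname(ofk)
    )
  }
  links <- do.call(rbind, rows)
  rownames(links) <- NULL
  cen <- networkCentrality(ids, links)
  links$centrality_score <- cen$linkScores
  linkCls <- classifyCentrality(links$centrality_score, centralityAnchor)
  links$centrality_class <- linkCls$classes
  nodeCls <- classifyCentrality(as.numeric(cen$nodeScores),
                                centralityAnchor)
  nodesDf <- data.frame(
    node_id = ids,
    name = vapply(nodes, `[[`, character(1), "name"),
    centrality_score = as.numeric(cen$nodeScores),
    centrality_rank = nodeCls$classes,
    area_km2 = areas
  )
  links <- links[, c("from_node", "to_node", "euclid_km", "lcp_km",
                     "ratio", "cwd", "effective_resistance",
                     "centrality_score", "centrality_class",
                     "outside_forest_km")]
  structure(
    list(nodes = nodesDf, links = links, paths = paths, cwd = cwd,
         graph = rg, nodeBreaks = nodeCls$breaks,
         linkBreaks = linkCls$breaks),
    class = "connectivityAnalysis"
  )
}

#' @exportS3Method base::print
print.connectivityAnalysis <- function(x, ...) {
  cat(sprintf(
    "connectivityAnalysis: %d nodes, %d links | mean LCP %.1f km | mean node centrality %.2f\n",
    nrow(x$nodes), nrow(x$links), mean(x$links$lcp_km),
    mean(x$nodes$centrality_score)
  ))
  invisible(x)
}
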