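test_that("resistance is capped inverse suitability in [1, 100]", {
  g <- gridSpec(2, 3)
  s <- gridRaster(matrix(c(100, 50, 1, 0.2, 0, NA), 2, 3), g)
  r <- rasterValues(suitabilityToResistance(s))
  expect_equal(as.vector(r), c(1, 2, 100, 100, 100, NA))
  expect_error(suitabilityToResistance(gridRaster(matrix(120, 2, 3), g)),
               "\\[0, 100\\]")
})

test_that("raster graph uses mean-resistance edge costs and sqrt(2) diagonals", {
  g <- gridSpec(2, 2)
  # values: [1,1]=1 [2,1]=2 [1,2]=3 [2,2]=4 (column-major, row 1 south)
  rg <- rasterGraph(gridRaster(matrix(c(1, 2, 3, 4), 2, 2), g))
  key <- paste(pmin(rg@edges[, 1], rg@edges[, 2]),
               pmax(rg@edges[, 1], rg@edges[, 2]))
  cost <- setNames(rg@cost, key)
  expect_equal(unname(cost["1 3"]), (1 + 3) / 2)        # east
  expect_equal(unname(cost["1 2"]), (1 + 2) / 2)        # north
  expect_equal(unname(cost["1 4"]), sqrt(2) * (1 + 4) / 2)  # diagonal
  expect_equal(nrow(rg@edges), 6)
  # no edges across nodata
  rg2 <- rasterGraph(gridRaster(matrix(c(1, NA, 3, 4), 2, 2), g))
  expect_false(any(rg2@edges == rg2@vertexOf[2], na.rm = TRUE))
})

test_that("cost distance matches closed forms and a Bellman-Ford oracle", {
  g <- gridSpec(1, 6)
  rg <- rasterGraph(gridRaster(matrix(1, 1, 6), g))
  d <- rasterValues(costDistance(rg, 1L))
  expect_equal(as.vector(d), 0:5)  # cardinal neighbours k cells away
  # one diagonal step, resistances 1 and 3
  g2 <- gridSpec(2, 2)
  rg2 <- rasterGraph(gridRaster(matrix(c(1, 5, 5, 3), 2, 2), g2))
  d2 <- rasterValues(costDistance(rg2, 1L))
  expect_equal(d2[2, 2], sqrt(2) * 1 * (1 + 3) / 2)
  # random 8 x 8 rasters against Bellman-Ford
  for (s in 1:10) {
    rg3 <- rasterGraph(randomResistance(8, 8, s))
    from <- ((s * 7) %% 64) + 1L
    mine <- rasterValues(costDistance(rg3, as.integer(from)))
    oracle <- bfShortestPath(rg3@edges, rg3@cost, 64, from)
    expect_equal(as.vector(mine), oracle, tolerance = 1e-9)
  }
})

test_that("least-cost paths go straight in uniform terrain and find wall gaps", {
  g <- gridSpec(20, 20)
  rg <- rasterGraph(gridRaster(matrix(1, 20, 20), g))
  a <- 10L + 4L * 20L   # row 10, col 5
  b <- 10L + 14L * 20L  # row 10, col 15
  va <- rg@vertexOf[a]; vb <- rg@vertexOf[b]
  pth <- leastCostPath(rg, va, vb)
  expect_equal(pth$lcp_km, 10)
  expect_equal(pth$cwd, 10)
  ctr <- cellCenters(g, c(a, b))
  euc <- sqrt(diff(ctr[, "x"])^2 + diff(ctr[, "y"])^2)
  expect_gt(linkageRatio(euc, pth$lcp_km), 0.99)
  # wall of high resistance with one gap
  m <- matrix(1, 20, 20); m[, 10] <- 1000; m[7, 10] <- 1
  rgw <- rasterGraph(gridRaster(m, g))
  pw <- leastCostPath(rgw, rgw@vertexOf[10 + 2 * 20], rgw@vertexOf[10 + 17 * 20])
  gap <- 7 + 9 * 20
  expect_true(gap %in% pw$cells)
  # cost of a 10 x 10 random LCP equals the shortest-path oracle
  rgr <- rasterGraph(randomResistance(10, 10, 77))
  pr <- leastCostPath(rgr, 1L, 100L)
  oracle <- bfShortestPath(rgr@edges, rgr@cost, 100, 1)[100]
  expect_equal(pr$cwd, oracle, tolerance = 1e-9)
})

test_that("polygon distances match geometry and a boundary-sampling oracle", {
  a <- rectPolygon(0, 1, 0, 1)
  b <- rectPolygon(8, 9, 0, 1)
  expect_equal(polygonDistance(a, b), 7)
  touching <- rectPolygon(1, 2, 0, 1)
  expect_equal(polygonDistance(a, touching), 0)
  overlapping <- rectPolygon(0.5, 3, 0.5, 3)
  expect_equal(polygonDistance(a, overlapping), 0)
  set.seed(14)
  for (k in 1:5) {
    p1 <- rectPolygon(runif(1, 0, 5), runif(1, 6, 10), runif(1, 0, 4),
                      runif(1, 5, 9))
    p2 <- rectPolygon(runif(1, 12, 15), runif(1, 16, 20), runif(1, 0, 4),
                      runif(1, 5, 9))
    t <- seq(0, 1, length.out = 500)
    ringPts <- function(p) {
      ring <- rbind(p$coords, p$coords[1, ])
      do.call(rbind, lapply(seq_len(nrow(ring) - 1), function(e)
        cbind(ring[e, 1] + t * (ring[e + 1, 1] - ring[e, 1]),
              ring[e, 2] + t * (ring[e + 1, 2] - ring[e, 2]))))
    }
    A <- ringPts(p1); B <- ringPts(p2)
    oracle <- min(sqrt(outer(A[, 1], B[, 1], "-")^2 +
                       outer(A[, 2], B[, 2], "-")^2))
    expect_equal(polygonDistance(p1, p2), oracle, tolerance = 1e-3)
  }
})

test_that("tortuosity ratios reproduce the published link arithmetic", {
  expect_equal(round(linkageRatio(11.78, 13.55), 2), 0.87)
  expect_equal(round(linkageRatio(25.30, 120.09), 2), 0.21)
  expect_equal(linkageRatio(10, 10), 1)
})

test_that("candidate links keep allocation-adjacent pairs only", {
  g <- gridSpec(10, 40)
  rg <- rasterGraph(gridRaster(matrix(1, 10, 40), g))
  nodes <- list(rectPolygon(1, 3, 4, 6, id = 1),
                rectPolygon(19, 21, 4, 6, id = 2),
                rectPolygon(37, 39, 4, 6, id = 3))
  cwd <- lapply(nodes, function(p) costDistance(rg, p))
  adj <- candidateLinks(cwd, "adjacency")
  expect_equal(adj, rbind(c(1L, 2L), c(2L, 3L)))
  all4 <- candidateLinks(c(cwd, cwd[1]), "all")
  expect_equal(nrow(all4), 6)
})

test_that("corridor surfaces are zero on the path and match the cost identity", {
  res <- randomResistance(15, 15, 5)
  rg <- rasterGraph(res)
  a <- rectPolygon(0, 2, 0, 2, id = 1)
  b <- rectPolygon(13, 15, 13, 15, id = 2)
  cwdA <- costDistance(rg, a); cwdB <- costDistance(rg, b)
  pth <- leastCostPath(rg, a, b)
  cor <- corridorSurface(cwdA, cwdB, pth$cwd, pth, truncation = 1000)
  v <- rasterValues(cor$surface)
  expect_true(all(v[pth$cells] < 1e-9))
  # identity: value = cwdA + cwdB - min(cwdA + cwdB)
  tot <- rasterValues(cwdA) + rasterValues(cwdB)
  expect_equal(pth$cwd, min(tot), tolerance = 1e-9)
  expect_equal(v, tot - min(tot), tolerance = 1e-9)
  expect_true(all(rasterValues(cor$classes) %in% 1:3))
  # cost-unit truncation masks expensive cells
  cor2 <- corridorSurface(cwdA, cwdB, pth$cwd, pth, truncation = 30,
                          truncationMode = "cost")
  expect_true(all(rasterValues(cor2$surface) <= 30, na.rm = TRUE))
})

test_that("effective resistance obeys series and parallel laws exactly", {
  chain <- graphAsRasterGraph(cbind(1:3, 2:4), rep(1, 3), 4)
  expect_equal(effectiveResistance(chain, 1L, 4L), 3, tolerance = 1e-12)
  # two disjoint 2-unit chains between the terminals
  par <- graphAsRasterGraph(
    rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4)), rep(1, 4), 4
  )
  expect_equal(effectiveResistance(par, 1L, 4L), 1, tolerance = 1e-12)
  disconnected <- graphAsRasterGraph(cbind(1, 2), 1, 4)
  expect_equal(effectiveResistance(disconnected, 1L, 4L), Inf)
})

test_that("effective resistance matches the dense pseudo-inverse oracle", {
  skip_if_not_installed("MASS")
  for (s in 1:8) {
    gr <- randomConnectedGraph(10 + 5 * s, seed = s)
    rg <- graphAsRasterGraph(gr$edges, 1 / gr$cond, gr$n)
    mine <- effectiveResistance(rg, 1L, as.integer(gr$n))
    oracle <- denseEffectiveResistance(gr$edges, gr$cond, gr$n, 1, gr$n)
    expect_lt(abs(mine - oracle) / oracle, 1e-8)
  }
})

test_that("adding an edge never increases effective resistance", {
  set.seed(6)
  gr <- randomConnectedGraph(30, seed = 19)
  base <- effectiveResistance(
    graphAsRasterGraph(gr$edges, 1 / gr$cond, gr$n), 1L, 30L
  )
  for (k in 1:5) {
    extra <- sample(30, 2)
    aug <- graphAsRasterGraph(rbind(gr$edges, extra),
                              c(1 / gr$cond, runif(1, 0.1, 2)), gr$n)
    expect_lte(effectiveResistance(aug, 1L, 30L), base + 1e-12)
  }
})

test_that("pair solves conserve current and find the hourglass waist", {
  res <- randomResistance(10, 10, 23)
  rg <- rasterGraph(res)
  cd <- currentDensity(rg, 5L, 96L)
  expect_lt(cd$maxKirchhoffImbalance, 1e-8)
  # hourglass: two permeable basins joined by a single-cell waist
  m <- matrix(NA_real_, 11, 15)
  m[, 1:6] <- 1; m[, 10:15] <- 1; m[6, 7:9] <- 1
  rgh <- rasterGraph(gridRaster(m, gridSpec(11, 15)))
  left <- rgh@vertexOf[cellFromXY(gridSpec(11, 15), rep(0.5, 11),
                                  seq(0.5, 10.5))]
  right <- rgh@vertexOf[cellFromXY(gridSpec(11, 15), rep(14.5, 11),
                                   seq(0.5, 10.5))]
  cdh <- currentDensity(rgh, left, right)
  cur <- rasterValues(cdh$current)
  waist <- cur[6, 7:9]
  expect_equal(unname(waist), rep(1, 3), tolerance = 1e-8)
  expect_true(max(cur, na.rm = TRUE) <= 1 + 1e-8)
  expect_true(all(cur[-6, 7:9] %in% NA))
})

test_that("two equal parallel corridors split the current 50/50", {
  m <- matrix(NA_real_, 3, 4)
  m[1, ] <- 1; m[3, ] <- 1  # two disjoint horizontal chains
  rg <- rasterGraph(gridRaster(m, gridSpec(3, 4)))
  A <- rg@vertexOf[c(1, 3)]          # left ends of both chains
  B <- rg@vertexOf[c(1, 3) + 3 * 3]  # right ends
  cd <- currentDensity(rg, A, B)
  mid <- rasterValues(cd$current)[c(1, 3), 2:3]
  expect_equal(unname(as.vector(mid)), rep(0.5, 4), tolerance = 1e-10)
})

test_that("reduced-graph centrality matches the hand-solved path graph", {
  links <- data.frame(from_node = c(1, 2), to_node = c(2, 3), cwd = c(1, 1))
  cen <- networkCentrality(1:3, links)
  expect_equal(unname(cen$nodeScores), c(2, 3, 2), tolerance = 1e-10)
  expect_equal(cen$linkScores, c(2, 2), tolerance = 1e-10)
  # symmetric 4-cycle: all links equal
  cyc <- data.frame(from_node = c(1, 2, 3, 4), to_node = c(2, 3, 4, 1),
                    cwd = rep(2, 4))
  cc <- networkCentrality(1:4, cyc)
  expect_equal(max(cc$linkScores) - min(cc$linkScores), 0,
               tolerance = 1e-10)
  expect_equal(max(cc$nodeScores) - min(cc$nodeScores), 0,
               tolerance = 1e-10)
  # star: hub strictly maximal
  star <- data.frame(from_node = c(1, 1, 1), to_node = 2:4,
                     cwd = rep(1, 3))
  cs <- networkCentrality(1:4, star)
  expect_true(cs$nodeScores["1"] > max(cs$nodeScores[-1]))
})

test_that("equal-interval centrality breaks reproduce the published thresholds", {
  tabs <- loadPaperTables()
  cls <- classifyCentrality(tabs$nodes$centrality_score, anchor = "min")
  expect_equal(cls$breaks, c(37.69, 57.38), tolerance = 1e-6)
  expect_equal(sum(cls$classes == "high"), 1)  # only the top-scoring node
  same <- classifyCentrality(rep(4.2, 6))
  expect_true(same$degenerate)
  expect_true(all(same$classes == "moderate"))
  set.seed(2)
  sc <- runif(50, 3, 30)
  out <- classifyCentrality(sc, "zero")
  brk <- max(sc) * c(1, 2) / 3
  oracle <- cut(sc, c(-Inf, brk, Inf), labels = c("least", "moderate", "high"))
  expect_equal(out$classes, as.character(oracle))
})

test_that("path length outside forest matches fine integration on stripes", {
  g <- gridSpec(10, 10)
  stripe <- matrix(rep(c(1, 0), each = 10, length.out = 100), 10, 10)
  forest <- gridRaster(stripe, g)
  path <- cbind(x = c(0.5, 9.5), y = c(5.5, 5.5))
  mine <- lengthOutsideForest(path, forest, nSub = 1000)
  t <- seq(0, 1, length.out = 200001)
  xs <- 0.5 + t * 9
  outside <- mean(stripe[6, pmin(10, floor(xs) + 1)] == 0) * 9
  expect_equal(mine, outside, tolerance = 0.02)
  allForest <- gridRaster(matrix(1, 10, 10), g)
  expect_equal(lengthOutsideForest(path, allForest), 0)
  noForest <- gridRaster(matrix(0, 10, 10), g)
  expect_equal(lengthOutsideForest(path, noForest), 9, tolerance = 1e-9)
})

test_that("the full connectivity analysis satisfies the link invariants", {
  L <- tinyLandscape()
  suit <- gridRaster(100 * rasterValues(L$trueSuitability), L$grid)
  res <- suitabilityToResistance(suit)
  ca <- analyzeConnectivity(res, L$coreNodes, forestMask = L$forestMask,
                            minNodeAreaKm2 = 50)
  expect_gte(nrow(ca$links), 2)
  expect_true(all(ca$links$euclid_km <= ca$links$lcp_km + 1e-9))
  expect_true(all(ca$links$ratio > 0 & ca$links$ratio <= 1))
  expect_true(all(ca$links$effective_resistance <= ca$links$cwd + 1e-9))
  expect_true(all(ca$links$outside_forest_km <= ca$links$lcp_km + 1e-9))
  expect_true(all(ca$nodes$centrality_rank %in%
                    c("least", "moderate", "high")))
  expect_error(
    analyzeConnectivity(res, L$coreNodes, minNodeAreaKm2 = 1e6),
    "minimum core area"
  )
})
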