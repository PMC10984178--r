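# Lightweight polygon utilities. Polygons are simple (single-ring,
# non-holed) and represented as a list with elements:
#   coords : n x 2 matrix of ring vertices (km, not closed),
#   id     : integer identifier, name : character label.
# This covers the geometry the pipeline needs (protected areas, core
# habitat nodes, villages): containment tests, areas, minimum distances
# and rasterization.

#' Create a simple polygon
#'
#' @param coords n x 2 matrix of ring vertices in km (open ring; the
#'   closing edge is implied).
#' @param id integer identifier.
#' @param name label.
#' @return A list of class \code{"simplePolygon"}.
#' @export
simplePolygon <- function(coords, id = 1L, name = paste0("poly", id)) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) < 3L)
    stop("polygon needs an n x 2 coordinate matrix with n >= 3")
  colnames(coords) <- c("x", "y")
  structure(list(coords = coords, id = as.integer(id), name = name),
            class = "simplePolygon")
}

#' Axis-aligned rectangular polygon
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds in km.
#' @param id,name identifier and label.
#' @export
rectPolygon <- function(xmin, xmax, ymin, ymax, id = 1L,
                        name = paste0("poly", id)) {
  simplePolygon(
    cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)),
    id = id, name = name
  )
}

#' Polygon area (shoelace formula)
#'
#' @param poly a \code{simplePolygon}.
#' @return Area in km^2.
#' @export
polygonArea <- function(poly) {
  p <- poly$coords
  n <- nrow(p)
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param poly a \code{simplePolygon}.
#' @param x,y point coordinates.
#' @return Logical vector; boundary points count as inside.
#' @export
pointInPolygon <- function(poly, x, y) {
  p <- poly$coords
  n <- nrow(p)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1]; yi <- p[i, 2]; xj <- p[j, 1]; yj <- p[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  # boundary tolerance: a point on an edge is inside
  onEdge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    d <- .pointSegDist(x, y, p[j, 1], p[j, 2], p[i, 1], p[i, 2])
    onEdge <- onEdge | d < 1e-9
    j <- i
  }
  inside | onEdge
}

# distance from points (x, y) to segment (x1,y1)-(x2,y2), vectorized in points
.pointSegDist <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((x - x1)^2 + (y - y1)^2))
  t <- pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / L2))
  sqrt((x - x1 - t * dx)^2 + (y - y1 - t * dy)^2)
}

# minimum distance between two segments
.segSegDist <- function(a1, a2, b1, b2) {
  min(
    .pointSegDist(a1[1], a1[2], b1[1], b1[2], b2[1], b2[2]),
    .pointSegDist(a2[1], a2[2], b1[1], b1[2], b2[1], b2[2]),
    .pointSegDist(b1[1], b1[2], a1[1], a1[2], a2[1], a2[2]),
    .pointSegDist(b2[1], b2[2], a1[1], a1[2], a2[1], a2[2])
  )
}

#' Minimum edge-to-edge distance between two polygons
#'
#' Zero when the polygons touch or overlap.
#'
#' @param a,b \code{simplePolygon} objects.
#' @return Distance in km.
#' @export
polygonDistance <- function(a, b) {
  pa <- a$coords; pb <- b$coords
  if (any(pointInPolygon(a, pb[, 1], pb[, 2])) ||
      any(pointInPolygon(b, pa[, 1], pa[, 2]))) return(0)
  na <- nrow(pa); nb <- nrow(pb)
  ia <- cbind(seq_len(na), c(2:na, 1L))
  ib <- cbind(seq_len(nb), c(2:nb, 1L))
  best <- Inf
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d <- .segSegDist(
        pa[ia[i, 1], ], pa[ia[i, 2], ],
        pb[ib[j, 1], ], pb[ib[j, 2], ]
      )
      if (d < best) best <- d
    }
  }
  best
}

#' Distance from points to a polygon (0 inside)
#'
#' @param poly a \code{simplePolygon}.
#' @param x,y point coordinates (km).
#' @return Distances in km, 0 for interior points.
#' @export
distanceToPolygon <- function(poly, x, y) {
  p <- poly$coords
  n <- nrow(p)
  d <- rep(Inf, length(x))
  j <- n
  for (i in seq_len(n)) {
    d <- pmin(d, .pointSegDist(x, y, p[j, 1], p[j, 2], p[i, 1], p[i, 2]))
    j <- i
  }
  d[pointInPolygon(poly, x, y)] <- 0
  d
}

#' Linear indices of cells whose centres fall in a polygon
#'
#' @param poly a \code{simplePolygon}.
#' @param grid a \linkS4class{GridSpec}.
#' @return Integer vector of linear cell indices.
#' @export
cellsInPolygon <- function(poly, grid) {
  bb <- apply(poly$coords, 2, range)
  colRange <- pmax(1L, pmin(grid@nCols, ceiling(
    (bb[, "x"] - grid@originX) / grid@cellSize + c(0, 1)
  )))
  rowRange <- pmax(1L, pmin(grid@nRows, ceiling(
    (bb[, "y"] - grid@originY) / grid@cellSize + c(0, 1)
  )))
  rows <- rowRange[1]:rowRange[2]
  cols <- colRange[1]:colRange[2]
  cells <- as.integer(outer(rows, (cols - 1L) * grid@nRows, `+`))
  ctr <- cellCenters(grid, cells)
  cells[pointInPolygon(poly, ctr[, "x"], ctr[, "y"])]
}

#' Rasterize a set of polygons to a 0/1 mask
#'
#' @param polys list of \code{simplePolygon} objects.
#' @param grid a \linkS4class{GridSpec}.
#' @param name layer name.
#' @return A \linkS4class{GridRaster} with 1 inside any polygon, else 0.
#' @export
rasterizePolygons <- function(polys, grid, name = "mask") {
  v <- matrix(0, grid@nRows, grid@nCols)
  for (p in polys) v[cellsInPolygon(p, grid)] <- 1
  gridRaster(v, grid, name)
}
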