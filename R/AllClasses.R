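#' @import methods
NULL

#' Grid geometry of an analysis raster
#'
#' A \code{GridSpec} describes the common geometry every raster in an
#' analysis shares: number of rows and columns, the square cell size in
#' kilometres, the projected coordinates of the lower-left corner, and a
#' free-text CRS label. All coordinates in the package are projected
#' kilometres; row 1 is the southernmost row, so y increases with row
#' index and x with column index.
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot cellSize positive cell edge length in km.
#' @slot originX,originY projected coordinates (km) of the lower-left
#'   corner of the grid.
#' @slot crsLabel character label of the projected CRS.
#' @export
setClass("GridSpec",
  representation(
    nRows = "integer", nCols = "integer", cellSize = "numeric",
    originX = "numeric", originY = "numeric", crsLabel = "character"
  ),
  prototype(crsLabel = "local-km")
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || object@nRows < 1L)
    msg <- c(msg, "nRows must be a single positive integer")
  if (length(object@nCols) != 1L || object@nCols < 1L)
    msg <- c(msg, "nCols must be a single positive integer")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param nRows,nCols grid dimensions.
#' @param cellSize cell edge length in km (default 1, the analysis
#'   resolution).
#' @param originX,originY lower-left corner in projected km.
#' @param crsLabel CRS label.
#' @return A \linkS4class{GridSpec}.
#' @examples
#' gridSpec(10, 10)
#' @export
gridSpec <- function(nRows, nCols, cellSize = 1, originX = 0, originY = 0,
                     crsLabel = "local-km") {
  new("GridSpec",
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    cellSize = as.numeric(cellSize),
    originX = as.numeric(originX), originY = as.numeric(originY),
    crsLabel = as.character(crsLabel)
  )
}

#' Single-band raster on a GridSpec
#'
#' Values are stored as a numeric matrix indexed \code{[row, col]} with
#' row 1 at the south edge; missing data are \code{NA}. A nodata cell in
#' any covariate is treated as nodata in every derived surface.
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot values numeric matrix matching the grid dimensions.
#' @slot name layer name.
#' @export
setClass("GridRaster",
  representation(grid = "GridSpec", values = "matrix", name = "character"),
  prototype(name = "layer")
)

setValidity("GridRaster", function(object) {
  d <- dim(object@values)
  if (d[1] != object@grid@nRows || d[2] != object@grid@nCols)
    return("values matrix does not match grid dimensions")
  TRUE
})

#' Construct a GridRaster
#'
#' @param values numeric matrix (row 1 = south) or single value recycled.
#' @param grid a \linkS4class{GridSpec}.
#' @param name layer name.
#' @return A \linkS4class{GridRaster}.
#' @examples
#' r <- gridRaster(matrix(1:100, 10, 10), gridSpec(10, 10), "demo")
#' @export
gridRaster <- function(values, grid, name = "layer") {
  if (!is.matrix(values))
    values <- matrix(as.numeric(values), grid@nRows, grid@nCols)
  storage.mode(values) <- "double"
  new("GridRaster", grid = grid, values = values, name = name)
}

#' Stack of co-registered covariate rasters
#'
#' All layers must share one identical \linkS4class{GridSpec}; this is the
#' container handed to the suitability models (typically bio12, elevation,
#' tri, ndvi and dist_pa layers).
#'
#' @slot grid the shared \linkS4class{GridSpec}.
#' @slot layers named list of \linkS4class{GridRaster} objects.
#' @export
setClass("CovariateStack",
  representation(grid = "GridSpec", layers = "list")
)

setValidity("CovariateStack", function(object) {
  if (!length(object@layers)) return("stack has no layers")
  if (is.null(names(object@layers)) || any(!nzchar(names(object@layers))))
    return("all layers must be named")
  for (ly in object@layers) {
    if (!is(ly, "GridRaster")) return("layers must be GridRaster objects")
    if (!sameGrid(ly@grid, object@grid))
      return("all layers must share the stack GridSpec")
  }
  TRUE
})

#' Stack covariate rasters
#'
#' @param ... named \linkS4class{GridRaster} layers, or a single named list.
#' @return A \linkS4class{CovariateStack}.
#' @export
stackCovariates <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !is(layers[[1]], "GridRaster"))
    layers <- layers[[1]]
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- vapply(layers, function(l) l@name, character(1))
  new("CovariateStack", grid = layers[[1]]@grid, layers = layers)
}

#' Weighted-graph view of a resistance raster
#'
#' Vertices are the valid (non-nodata) cells; edges join 8-neighbours.
#' Edge cost is the cell-centre distance (cell size, or sqrt(2) times it
#' on diagonals) multiplied by the mean resistance of the two endpoint
#' cells; edge conductance is its reciprocal. No edges cross nodata.
#'
#' @slot grid the \linkS4class{GridSpec}.
#' @slot cellIndex integer vector: linear cell index of each vertex.
#' @slot vertexOf integer vector of length nRows*nCols mapping cells to
#'   vertex ids (NA for nodata cells).
#' @slot edges two-column integer matrix of vertex pairs (i < j).
#' @slot dist numeric geometric length (km) of each edge.
#' @slot cost numeric cost of each edge (km x resistance units).
#' @export
setClass("RasterGraph",
  representation(
    grid = "GridSpec", cellIndex = "integer", vertexOf = "integer",
    edges = "matrix", dist = "numeric", cost = "numeric"
  )
)

setValidity("RasterGraph", function(object) {
  if (nrow(object@edges) != length(object@cost) ||
      nrow(object@edges) != length(object@dist))
    return("edges, dist and cost lengths differ")
  if (any(object@cost <= 0)) return("edge costs must be positive")
  TRUE
})

# ---- accessors ----

#' @rdname gridSpec
#' @param x an object with a grid.
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))

#' @rdname gridSpec
#' @export
setMethod("gridOf", "GridRaster", function(x) x@grid)

#' @rdname gridSpec
#' @export
setMethod("gridOf", "CovariateStack", function(x) x@grid)

#' @rdname gridSpec
#' @export
setMethod("gridOf", "RasterGraph", function(x) x@grid)

#' Raster values
#'
#' @param x a \linkS4class{GridRaster}.
#' @return The numeric value matrix (row 1 = south).
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @rdname rasterValues
#' @export
setMethod("rasterValues", "GridRaster", function(x) x@values)

#' Layer names of a stack
#'
#' @param x a \linkS4class{CovariateStack}.
#' @export
setMethod("names", "CovariateStack", function(x) names(x@layers))

#' Extract a layer from a stack
#'
#' @param x a \linkS4class{CovariateStack}.
#' @param i layer name or index.
#' @export
setMethod("[[", "CovariateStack", function(x, i) x@layers[[i]])

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d cells of %g km, origin (%g, %g), crs '%s'\n",
    object@nRows, object@nCols, object@cellSize,
    object@originX, object@originY, object@crsLabel
  ))
})

setMethod("show", "GridRaster", function(object) {
  v <- object@values
  cat(sprintf(
    "GridRaster '%s': %d x %d @ %g km | range [%s, %s] | %d nodata\n",
    object@name, object@grid@nRows, object@grid@nCols, object@grid@cellSize,
    format(suppressWarnings(min(v, na.rm = TRUE)), digits = 4),
    format(suppressWarnings(max(v, na.rm = TRUE)), digits = 4),
    sum(is.na(v))
  ))
})

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf(
    "CovariateStack: %d layers (%s) on %d x %d @ %g km\n",
    length(object@layers), paste(names(object@layers), collapse = ", "),
    object@grid@nRows, object@grid@nCols, object@grid@cellSize
  ))
})

setMethod("show", "RasterGraph", function(object) {
  cat(sprintf(
    "RasterGraph: %d vertices, %d edges on %d x %d grid\n",
    length(object@cellIndex), nrow(object@edges),
    object@grid@nRows, object@grid@nCols
  ))
})

# ---- grid geometry helpers ----

#' Compare two grid specs for exact agreement
#'
#' @param a,b \linkS4class{GridSpec} objects.
#' @return TRUE when dimensions, cell size and origin agree.
#' @export
sameGrid <- function(a, b) {
  a@nRows == b@nRows && a@nCols == b@nCols &&
    isTRUE(all.equal(a@cellSize, b@cellSize)) &&
    isTRUE(all.equal(a@originX, b@originX)) &&
    isTRUE(all.equal(a@originY, b@originY))
}

#' Stop unless rasters are co-registered
#'
#' @param ... \linkS4class{GridRaster} (or stack) objects.
#' @export
checkCoRegistered <- function(...) {
  objs <- list(...)
  g <- gridOf(objs[[1]])
  for (o in objs[-1]) {
    if (!sameGrid(g, gridOf(o)))
      stop("rasters are not co-registered: GridSpec mismatch", call. = FALSE)
  }
  invisible(TRUE)
}

#' Cell-centre coordinates
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param cells linear cell indices (column-major, row 1 = south); default
#'   all cells.
#' @return Two-column matrix of x, y in km.
#' @export
cellCenters <- function(grid, cells = seq_len(grid@nRows * grid@nCols)) {
  row <- (cells - 1L) %% grid@nRows + 1L
  col <- (cells - 1L) %/% grid@nRows + 1L
  cbind(
    x = grid@originX + (col - 0.5) * grid@cellSize,
    y = grid@originY + (row - 0.5) * grid@cellSize
  )
}

#' Cell index containing each point
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param x,y point coordinates in km.
#' @return Linear cell indices; NA for points outside the grid.
#' @export
cellFromXY <- function(grid, x, y) {
  col <- ceiling((x - grid@originX) / grid@cellSize)
  row <- ceiling((y - grid@originY) / grid@cellSize)
  # points exactly on the origin edge belong to the first row/col
  col[col == 0L & x >= grid@originX - 1e-9] <- 1L
  row[row == 0L & y >= grid@originY - 1e-9] <- 1L
  bad <- col < 1L | col > grid@nCols | row < 1L | row > grid@nRows
  idx <- row + (col - 1L) * grid@nRows
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Raster values at point locations
#'
#' @param raster a \linkS4class{GridRaster}.
#' @param x,y coordinates in km.
#' @return Values at the containing cells (NA outside the grid).
#' @export
valuesAtXY <- function(raster, x, y) {
  idx <- cellFromXY(raster@grid, x, y)
  out <- rep(NA_real_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- raster@values[idx[ok]]
  out
}

#' Grid extent
#'
#' @param grid a \linkS4class{GridSpec}.
#' @return Named vector xmin, xmax, ymin, ymax (km).
#' @export
gridExtent <- function(grid) {
  c(
    xmin = grid@originX,
    xmax = grid@originX + grid@nCols * grid@cellSize,
    ymin = grid@originY,
    ymax = grid@originY + grid@nRows * grid@cellSize
  )
}
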