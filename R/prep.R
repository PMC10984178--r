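# Occurrence preparation: conflict-point relocation into forest, spatial
# rarefaction on a fixed-origin grid, pseudo-absence sampling and
# covariate collinearity screening.

#' Shift conflict points into the forest
#'
#' Each conflict point is relocated to a uniformly sampled forest cell
#' whose centre lies between \code{dMin} and \code{dMax} km away
#' (default 5 to 10 km, a daily-movement scale), reflecting the
#' assumption that a conflict-causing animal came from nearby forest.
#' Points with no forest cell in that annulus are dropped and counted.
#'
#' @param points data.frame with x, y (km); extra columns are preserved.
#' @param forestMask 0/1 \linkS4class{GridRaster}.
#' @param dMin,dMax displacement bounds in km.
#' @param seed RNG seed.
#' @return data.frame of shifted points (source/label preserved) with
#'   attribute \code{"nDropped"}; shifted points lie at forest cell
#'   centres.
#' @export
shiftConflicts <- function(points, forestMask, dMin = 5, dMax = 10,
                           seed = 1) {
  if (dMin > dMax) stop("dMin must not exceed dMax")
  g <- forestMask@grid
  forest <- forestMask@values == 1
  if (!any(forest)) stop("empty forest mask")
  set.seed(seed)
  keep <- logical(nrow(points))
  newx <- newy <- numeric(nrow(points))
  rmax <- ceiling(dMax / g@cellSize) + 1L
  for (i in seq_len(nrow(points))) {
    px <- points$x[i]; py <- points$y[i]
    c0 <- cellFromXY(g, px, py)
    if (is.na(c0)) next
    r0 <- (c0 - 1L) %% g@nRows + 1L
    col0 <- (c0 - 1L) %/% g@nRows + 1L
    rows <- max(1L, r0 - rmax):min(g@nRows, r0 + rmax)
    cols <- max(1L, col0 - rmax):min(g@nCols, col0 + rmax)
    cand <- as.integer(outer(rows, (cols - 1L) * g@nRows, `+`))
    cand <- cand[forest[cand]]
    if (!length(cand)) next
    ctr <- cellCenters(g, cand)
    d <- sqrt((ctr[, "x"] - px)^2 + (ctr[, "y"] - py)^2)
    cand <- cand[d >= dMin & d <= dMax]
    if (!length(cand)) next
    pick <- cand[sample.int(length(cand), 1L)]
    pc <- cellCenters(g, pick)
    keep[i] <- TRUE
    newx[i] <- pc[, "x"]; newy[i] <- pc[, "y"]
  }
  out <- points[keep, , drop = FALSE]
  out$x <- newx[keep]; out$y <- newy[keep]
  rownames(out) <- NULL
  attr(out, "nDropped") <- sum(!keep)
  attr(out, "keptIndex") <- which(keep)
  out
}

#' Spatially rarefy points on a fixed-origin grid
#'
#' At most one point is retained per \code{resolution}-km grid cell
#' (cells anchored at the given origin, by default the analysis raster
#' origin); the survivor in each occupied cell is chosen at random under
#' the seed. Thinning on the analysis resolution removes pseudo-
#' replicated records and damps reporting-effort clusters.
#'
#' @param points data.frame with x, y.
#' @param resolution cell size in km (default 1).
#' @param origin c(x, y) grid anchor (default c(0, 0)).
#' @param seed RNG seed.
#' @return Subset of \code{points}, one row per occupied cell.
#' @export
rarefyPoints <- function(points, resolution = 1, origin = c(0, 0),
                         seed = 1) {
  if (resolution <= 0) stop("resolution must be positive")
  if (!nrow(points)) return(points)
  cx <- floor((points$x - origin[1]) / resolution)
  cy <- floor((points$y - origin[2]) / resolution)
  key <- paste(cx, cy)
  set.seed(seed)
  ord <- sample.int(nrow(points))  # random survivor per cell
  keep <- ord[!duplicated(key[ord])]
  out <- points[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Draw pseudo-absence background points
#'
#' \code{round(ratio x n_presences)} points at uniformly sampled distinct
#' cell centres of the analysis grid, each at least
#' \code{exclusionRadius} km from every presence; labelled 0. The
#' default ratio of 2 doubles the presence count, the default exclusion
#' is one cell.
#'
#' @param presences data.frame with x, y (presences, label 1).
#' @param grid a \linkS4class{GridSpec} defining the extent and cells.
#' @param ratio pseudo-absences per presence (default 2).
#' @param exclusionRadius minimum distance to any presence in km
#'   (default: one cell size).
#' @param seed RNG seed.
#' @return data.frame with x, y, source = "background", label = 0.
#' @export
makePseudoAbsences <- function(presences, grid, ratio = 2,
                               exclusionRadius = grid@cellSize, seed = 1) {
  if (ratio <= 0) stop("ratio must be positive")
  n <- round(ratio * nrow(presences))
  ctrAll <- cellCenters(grid)
  # distance to nearest presence via cell bucketing of presences
  pcell <- cellFromXY(grid, presences$x, presences$y)
  pcell <- pcell[!is.na(pcell)]
  reach <- ceiling(exclusionRadius / grid@cellSize)
  blocked <- logical(grid@nRows * grid@nCols)
  pr <- (pcell - 1L) %% grid@nRows + 1L
  pc <- (pcell - 1L) %/% grid@nRows + 1L
  for (dr in -reach:reach) {
    for (dc in -reach:reach) {
      rr <- pr + dr; cc <- pc + dc
      ok <- rr >= 1L & rr <= grid@nRows & cc >= 1L & cc <= grid@nCols
      cand <- rr[ok] + (cc[ok] - 1L) * grid@nRows
      ctr <- cellCenters(grid, cand)
      d <- sqrt((ctr[, "x"] - presences$x[ok])^2 +
                (ctr[, "y"] - presences$y[ok])^2)
      blocked[cand[d < exclusionRadius]] <- TRUE
    }
  }
  avail <- which(!blocked)
  if (length(avail) < n)
    stop("extent too small: ", length(avail),
         " cells available for ", n, " pseudo-absences")
  set.seed(seed)
  cells <- avail[sample.int(length(avail), n)]
  ctr <- cellCenters(grid, cells)
  data.frame(
    x = ctr[, "x"], y = ctr[, "y"],
    source = "background", label = 0L, stringsAsFactors = FALSE
  )
}

#' Screen covariates for collinearity
#'
#' Two passes over the stack's valid-cell values: (1) while any retained
#' pair has |Pearson r| >= \code{rThreshold}, drop from the worst pair
#' the variable with the higher mean |r| against all others; (2) while
#' any variance inflation factor is >= \code{vifThreshold}, drop the
#' highest. Constant layers are flagged and dropped up front. VIF is
#' 1/(1-R^2) from an ordinary least-squares fit of each variable on the
#' others.
#'
#' @param covariates a \linkS4class{CovariateStack} or numeric matrix /
#'   data.frame of variable columns.
#' @param candidates variable names to screen (default: all).
#' @param rThreshold pairwise correlation threshold (default 0.6).
#' @param vifThreshold VIF threshold (default 10).
#' @return List of class \code{"screeningReport"}: \code{pairwiseR}
#'   (full correlation matrix), \code{vif} (final VIFs of retained
#'   variables), \code{retained}, \code{dropped} (data.frame with
#'   reasons), \code{steps} (character log).
#' @export
screenVariables <- function(covariates, candidates = NULL,
                            rThreshold = 0.6, vifThreshold = 10) {
  X <- if (is(covariates, "CovariateStack")) {
    vapply(covariates@layers, function(l) as.vector(l@values),
           numeric(covariates@grid@nRows * covariates@grid@nCols))
  } else {
    as.matrix(covariates)
  }
  if (is.null(candidates)) candidates <- colnames(X)
  if (length(candidates) < 2) stop("need at least 2 candidate variables")
  X <- X[stats::complete.cases(X), candidates, drop = FALSE]
  steps <- character()
  dropped <- data.frame(variable = character(), reason = character(),
                        stringsAsFactors = FALSE)
  constant <- candidates[apply(X, 2, stats::sd) == 0]
  for (v in constant) {
    dropped <- rbind(dropped, data.frame(variable = v, reason = "constant"))
    steps <- c(steps, paste0("dropped ", v, ": constant layer"))
  }
  retained <- setdiff(candidates, constant)
  R <- stats::cor(X[, retained, drop = FALSE])
  fullR <- R
  while (length(retained) > 1) {
    Rr <- abs(stats::cor(X[, retained, drop = FALSE]))
    diag(Rr) <- 0
    if (max(Rr) < rThreshold) break
    worst <- which(Rr == max(Rr), arr.ind = TRUE)[1, ]
    pair <- retained[worst]
    meanAbs <- rowMeans(Rr[pair, , drop = FALSE])
    drop <- pair[which.max(meanAbs)]
    dropped <- rbind(dropped, data.frame(
      variable = drop,
      reason = sprintf("pairwise |r| = %.3f with %s", max(Rr),
                       setdiff(pair, drop))
    ))
    steps <- c(steps, paste0("dropped ", drop, ": |r| >= ", rThreshold))
    retained <- setdiff(retained, drop)
  }
  vifOf <- function(vars) {
    vapply(vars, function(v) {
      fit <- stats::lm.fit(
        cbind(1, X[, setdiff(vars, v), drop = FALSE]), X[, v]
      )
      r2 <- 1 - sum(fit$residuals^2) / sum((X[, v] - mean(X[, v]))^2)
      1 / (1 - min(r2, 1 - 1e-12))
    }, numeric(1))
  }
  while (length(retained) > 1) {
    v <- vifOf(retained)
    if (max(v) < vifThreshold) break
    drop <- names(which.max(v))
    dropped <- rbind(dropped, data.frame(
      variable = drop, reason = sprintf("VIF = %.2f", max(v))
    ))
    steps <- c(steps, paste0("dropped ", drop, ": VIF >= ", vifThreshold))
    retained <- setdiff(retained, drop)
  }
  finalVif <- if (length(retained) > 1) vifOf(retained) else
    stats::setNames(rep(1, length(retained)), retained)
  structure(
    list(pairwiseR = fullR, vif = finalVif, retained = retained,
         dropped = dropped, steps = steps),
    class = "screeningReport"
  )
}

#' @exportS3Method base::print
print.screeningReport <- function(x, ...) {
  cat("Covariate screening:", length(x$retained), "retained (",
      paste(x$retained, collapse = ", "), ")\n")
  if (nrow(x$dropped)) {
    cat("Dropped:\n")
    for (i in seq_len(nrow(x$dropped)))
      cat("  -", x$dropped$variable[i], ":", x$dropped$reason[i], "\n")
  }
  cat("Final VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Extract model data at occurrence points
#'
#' @param points data.frame with x, y, label.
#' @param covariates a \linkS4class{CovariateStack}.
#' @param vars covariate names to extract (default all).
#' @return data.frame of label plus covariate columns; rows falling on
#'   nodata cells are removed.
#' @export
extractModelData <- function(points, covariates, vars = names(covariates)) {
  out <- data.frame(label = points$label)
  for (v in vars)
    out[[v]] <- valuesAtXY(covariates[[v]], points$x, points$y)
  out <- out[stats::complete.cases(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}
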