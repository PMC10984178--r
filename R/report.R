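# Aggregation of node/link tables into network-level summary statistics
# and class-count reports; pure functions of their input tables, usable
# both on fresh analysis output and on the packaged published tables.

#' Network summary statistics
#'
#' Means, sample standard deviations (n - 1 convention; the SD of a
#' single row is reported as 0 and flagged), ranges and recomputed
#' equal-interval centrality breaks for a node/link table pair laid out
#' like the packaged published tables.
#'
#' @param nodes data.frame with node_id, centrality_score, area_km2.
#' @param links data.frame with euclid_km, lcp_km, centrality_score.
#' @param anchor anchoring mode for the recomputed breaks ("min" or
#'   "zero").
#' @return List of class \code{"networkSummary"}.
#' @export
summarizeNetwork <- function(nodes, links, anchor = "min") {
  if (!nrow(nodes) || !nrow(links)) stop("empty node or link table")
  sdOr0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  nodeBrk <- classifyCentrality(nodes$centrality_score, anchor)
  linkBrk <- classifyCentrality(links$centrality_score, anchor)
  structure(list(
    n_nodes = nrow(nodes), n_links = nrow(links),
    mean_lcp_km = mean(links$lcp_km), sd_lcp_km = sdOr0(links$lcp_km),
    min_lcp_km = min(links$lcp_km), max_lcp_km = max(links$lcp_km),
    mean_euclid_km = mean(links$euclid_km),
    sd_euclid_km = sdOr0(links$euclid_km),
    min_euclid_km = min(links$euclid_km),
    max_euclid_km = max(links$euclid_km),
    mean_node_centrality = mean(nodes$centrality_score),
    sd_node_centrality = sdOr0(nodes$centrality_score),
    min_node_centrality = min(nodes$centrality_score),
    max_node_centrality = max(nodes$centrality_score),
    mean_link_centrality = mean(links$centrality_score),
    sd_link_centrality = sdOr0(links$centrality_score),
    mean_node_area_km2 = mean(nodes$area_km2),
    node_breaks = nodeBrk$breaks, link_breaks = linkBrk$breaks,
    sd_flagged = nrow(links) < 2 || nrow(nodes) < 2
  ), class = "networkSummary")
}

#' @exportS3Method base::print
print.networkSummary <- function(x, ...) {
  cat(sprintf("Network: %d nodes, %d links\n", x$n_nodes, x$n_links))
  cat(sprintf("  LCP length        %.2f +/- %.2f km (%.2f - %.2f)\n",
              x$mean_lcp_km, x$sd_lcp_km, x$min_lcp_km, x$max_lcp_km))
  cat(sprintf("  Euclidean dist    %.2f +/- %.2f km\n",
              x$mean_euclid_km, x$sd_euclid_km))
  cat(sprintf("  Node centrality   %.2f +/- %.2f (%.2f - %.2f), breaks %.2f / %.2f\n",
              x$mean_node_centrality, x$sd_node_centrality,
              x$min_node_centrality, x$max_node_centrality,
              x$node_breaks[1], x$node_breaks[2]))
  cat(sprintf("  Link centrality   %.2f +/- %.2f, breaks %.2f / %.2f\n",
              x$mean_link_centrality, x$sd_link_centrality,
              x$link_breaks[1], x$link_breaks[2]))
  invisible(x)
}

#' Centrality class counts
#'
#' Counts per class from the table's class column; optionally
#' recomputes classes from the scores under a chosen anchoring mode and
#' reports every row where the recomputed class disagrees with the
#' printed one.
#'
#' @param links data.frame with centrality_score and centrality_class.
#' @param recompute also recompute classes from the scores.
#' @param anchor anchoring mode for recomputation.
#' @return List: \code{counts} (named high/moderate/least),
#'   \code{recomputed} and \code{discrepancies} when requested.
#' @export
classCountReport <- function(links, recompute = FALSE, anchor = "min") {
  lv <- c("least", "moderate", "high")
  counts <- vapply(lv, function(l) sum(links$centrality_class == l),
                   numeric(1))
  out <- list(counts = counts)
  if (recompute) {
    rc <- classifyCentrality(links$centrality_score, anchor)
    disagree <- which(rc$classes != links$centrality_class)
    out$recomputed <- vapply(lv, function(l) sum(rc$classes == l),
                             numeric(1))
    out$discrepancies <- data.frame(
      row = disagree,
      score = links$centrality_score[disagree],
      printed = links$centrality_class[disagree],
      recomputed = rc$classes[disagree]
    )
    out$breaks <- rc$breaks
  }
  out
}

#' Forest-exposure bands of the corridors
#'
#' Per link, the forest fraction of the least-cost path,
#' 1 - outside_forest_km / lcp_km, banded into [0, 0.3), [0.3, 0.75]
#' and (0.75, 1].
#'
#' @param links data.frame with lcp_km and outside_forest_km.
#' @param thresholds band edges (default 0.3 and 0.75).
#' @return List: \code{perLink} (data.frame with fraction and band),
#'   \code{counts} (per band).
#' @export
forestExposureReport <- function(links, thresholds = c(0.3, 0.75)) {
  frac <- pmin(1, pmax(0, 1 - links$outside_forest_km / links$lcp_km))
  band <- 1 + (frac >= thresholds[1]) + (frac > thresholds[2])
  labels <- c(
    sprintf("below %g", thresholds[1]),
    sprintf("%g to %g", thresholds[1], thresholds[2]),
    sprintf("above %g", thresholds[2])
  )
  list(
    perLink = data.frame(
      from_node = links$from_node, to_node = links$to_node,
      forest_fraction = frac, band = band
    ),
    counts = stats::setNames(
      vapply(1:3, function(b) sum(band == b), numeric(1)), labels
    )
  )
}
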