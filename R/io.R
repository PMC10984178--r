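# Readers and writers. Rasters travel as ESRI ASCII grid (.asc), a plain
# text single-band format with an embedded georeference; vectors as
# GeoJSON; tables as RFC 4180 CSV with "." decimal. All stochastic
# operations elsewhere in the package take an explicit seed; the I/O layer
# is deterministic.

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster a \linkS4class{GridRaster}.
#' @param path output file path (.asc).
#' @param nodata sentinel written for NA cells (default -9999).
#' @export
writeRasterAsc <- function(raster, path, nodata = -9999) {
  g <- raster@grid
  hdr <- c(
    sprintf("ncols %d", g@nCols),
    sprintf("nrows %d", g@nRows),
    sprintf("xllcorner %.10g", g@originX),
    sprintf("yllcorner %.10g", g@originY),
    sprintf("cellsize %.10g", g@cellSize),
    sprintf("NODATA_value %.10g", nodata)
  )
  v <- raster@values
  v[is.na(v)] <- nodata
  # rows are written north to south
  lines <- apply(v[g@nRows:1, , drop = FALSE], 1, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path file path.
#' @param name layer name (default: file base name).
#' @return A \linkS4class{GridRaster}; the nodata sentinel becomes NA.
#' @export
readRasterAsc <- function(path, name = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not a single-band georeferenced ASCII grid (missing header keys): ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("raster body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  m[m == nodata] <- NA_real_
  grid <- gridSpec(nr, nc, hdr$cellsize, hdr$xllcorner, hdr$yllcorner)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gridRaster(m, grid, name)
}

#' Write polygons or points as GeoJSON
#'
#' @param obj a list of \code{simplePolygon}s, or a data.frame of points
#'   with x and y columns (extra columns become properties).
#' @param path output path.
#' @export
writeGeoJSON <- function(obj, path) {
  if (is.data.frame(obj)) {
    feats <- lapply(seq_len(nrow(obj)), function(i) {
      props <- as.list(obj[i, setdiff(names(obj), c("x", "y")), drop = FALSE])
      list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(obj$x[i], obj$y[i])),
        properties = props
      )
    })
  } else {
    feats <- lapply(obj, function(p) {
      ring <- rbind(p$coords, p$coords[1, , drop = FALSE])
      list(
        type = "Feature",
        geometry = list(
          type = "Polygon",
          coordinates = list(lapply(seq_len(nrow(ring)), function(k)
            as.numeric(ring[k, ])))
        ),
        properties = list(id = p$id, name = p$name)
      )
    })
  }
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read GeoJSON polygons or points
#'
#' @param path GeoJSON file.
#' @return A list of \code{simplePolygon}s, or a data.frame for point
#'   collections.
#' @export
readGeoJSON <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  types <- vapply(feats, function(f) f$geometry$type, character(1))
  if (all(types == "Point")) {
    rows <- lapply(feats, function(f) {
      co <- unlist(f$geometry$coordinates)
      c(list(x = co[1], y = co[2]), f$properties)
    })
    return(do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE)))
  }
  lapply(seq_along(feats), function(i) {
    f <- feats[[i]]
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    id <- if (!is.null(f$properties$id)) f$properties$id else i
    nm <- if (!is.null(f$properties$name)) f$properties$name
          else paste0("poly", id)
    simplePolygon(ring, id = id, name = nm)
  })
}

#' Write a table as CSV
#'
#' @param tbl data.frame.
#' @param path output path.
#' @export
writeTableCsv <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV table
#'
#' @param path file path.
#' @export
readTableCsv <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# ---- configuration ----

#' Default run configuration
#'
#' All documented analysis parameters with their defaults: 1-km
#' rarefaction, conflict shift between 5 and 10 km, pseudo-absence ratio
#' 2, correlation threshold 0.6, VIF threshold 10, 10 replicate 80/20
#' evaluation splits, AUC selection threshold 0.79, resistance from
#' inverse suitability, 50-km corridor truncation, 100-km2 minimum core
#' node area and 0.995 pinch-point quantile.
#'
#' @return Nested named list of parameters.
#' @export
defaultConfig <- function() {
  list(
    prep = list(
      rarefaction_km = 1,
      conflict_shift_min_km = 5,
      conflict_shift_max_km = 10,
      pseudo_absence_ratio = 2,
      pseudo_absence_exclusion_km = 1,
      r_threshold = 0.6,
      vif_threshold = 10
    ),
    sdm = list(
      n_replicates = 10,
      train_fraction = 0.8,
      auc_threshold = 0.79,
      n_threshold_steps = 201,
      n_suitability_classes = 5
    ),
    connectivity = list(
      corridor_threshold_km = 50,
      min_node_area_km2 = 100,
      min_node_separation_km = 0,
      pinch_point_quantile = 0.995,
      centrality_anchor = "min",
      link_mode = "adjacency"
    )
  )
}

#' Load a run configuration from YAML or JSON
#'
#' Unknown keys are an error: every documented parameter has an explicit
#' default and silent typos must not masquerade as defaults.
#'
#' @param path YAML (.yml/.yaml) or JSON file with any subset of the
#'   \code{\link{defaultConfig}} keys.
#' @return Full configuration with file values overriding defaults.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- defaultConfig()
  for (sect in names(user)) {
    if (!sect %in% names(cfg))
      stop("unknown config section: ", sect)
    for (key in names(user[[sect]])) {
      if (!key %in% names(cfg[[sect]]))
        stop("unknown config key: ", sect, ".", key)
      cfg[[sect]][[key]] <- user[[sect]][[key]]
    }
  }
  cfg
}

#' Write a configuration
#'
#' @param cfg configuration list.
#' @param path output path (.yml or .json by extension).
#' @export
writeConfig <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

# ---- packaged published tables ----

# column sums of the packaged tables, used as a corruption check
.paperTableChecksums <- list(
  nodes = c(centrality_score = 761.16, area_km2 = 12281.17),
  links = c(
    euclid_km = 5552.96, lcp_km = 7307.76, ratio = 43.93,
    effective_resistance = 1069.73, centrality_score = 590.18,
    outside_forest_km = 3514.56
  )
)

#' Load the packaged published core-node and movement-pathway tables
#'
#' The package ships, as CSV fixtures, the printed tables of a published
#' Asian elephant connectivity study for Odisha, India: 19 core habitat
#' nodes (name, current-flow centrality score and rank, area) and the 58
#' movement pathways between them (Euclidean distance, least-cost-path
#' length, their ratio, effective resistance, centrality score and class,
#' and the path length outside forest). Thousand separators in the
#' printed areas are normalized on load, and column checksums guard
#' against fixture corruption.
#'
#' @return A list with data.frames \code{nodes} and \code{links}.
#' @examples
#' tabs <- loadPaperTables()
#' nrow(tabs$links)  # 58
#' @export
loadPaperTables <- function() {
  nodesPath <- system.file("extdata", "core_nodes_table.csv",
                           package = "corridorscape", mustWork = TRUE)
  linksPath <- system.file("extdata", "movement_links_table.csv",
                           package = "corridorscape", mustWork = TRUE)
  nodes <- utils::read.csv(nodesPath, stringsAsFactors = FALSE)
  links <- utils::read.csv(linksPath, stringsAsFactors = FALSE)
  nodes$area_km2 <- as.numeric(gsub(",", "", nodes$area_km2))
  if (nrow(nodes) != 19L || nrow(links) != 58L)
    stop("packaged tables corrupted: expected 19 node and 58 link rows")
  if (!all(nodes$node_id %in% 1:19) || any(links$from_node >= links$to_node))
    stop("packaged tables corrupted: bad node ids")
  cs <- .paperTableChecksums
  for (cl in names(cs$nodes)) {
    if (abs(sum(nodes[[cl]]) - cs$nodes[[cl]]) > 1e-6)
      stop("packaged node table corrupted: checksum mismatch in ", cl)
  }
  for (cl in names(cs$links)) {
    if (abs(sum(links[[cl]]) - cs$links[[cl]]) > 1e-6)
      stop("packaged link table corrupted: checksum mismatch in ", cl)
  }
  list(nodes = nodes, links = links)
}
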