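# Plain-text interchange formats: rasters as Arc/Info ASCII grids
# (GDAL-readable, "AAIGrid"), vector layers as GeoJSON, tables as CSV with
# fixed 6-significant-digit floats so re-runs diff byte-identically, and
# scenarios/configs as YAML.

#' Write a raster as an Arc/Info ASCII grid
#'
#' Single-band integer grid with explicit nodata value; georeferencing
#' (lower-left corner + cell size) is carried in the header. The epoch
#' year, dataset id, CRS tag and (for transition rasters) the transition
#' code table are written to a JSON sidecar `<path>.aux.json`.
#'
#' @param r An [epoch_raster()] or [transition_raster()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata_code Integer written for `NA` cells (default -9999).
#' @export
write_ascii_grid <- function(r, path, nodata_code = -9999L) {
  v <- r$values
  v[is.na(v)] <- nodata_code
  header <- c(sprintf("ncols %d", ncol(v)),
              sprintf("nrows %d", nrow(v)),
              sprintf("xllcorner %.10g", r$xmin),
              sprintf("yllcorner %.10g", r$ymin),
              sprintf("cellsize %.10g", r$cell_size),
              sprintf("NODATA_value %d", nodata_code))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  aux <- list(crs = r$crs, dataset_id = r$dataset_id)
  if (inherits(r, "epoch_raster")) {
    aux$type <- "epoch"; aux$year <- r$year; aux$harmonized <- r$harmonized
  } else {
    aux$type <- "transition"; aux$period <- r$period
    aux$code_table <- as.list(transition_codes())
  }
  jsonlite::write_json(aux, paste0(path, ".aux.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a raster from an Arc/Info ASCII grid
#'
#' Reconstructs an [epoch_raster()] or [transition_raster()] from a grid
#' written by [write_ascii_grid()] (metadata taken from the `.aux.json`
#' sidecar when present; a bare grid is read as an unharmonized epoch).
#'
#' @param path Path to the `.asc` file.
#' @return An [epoch_raster()] or [transition_raster()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == h["nrows"], ncol(v) == h["ncols"])
  v[v == h["nodata_value"]] <- NA
  aux_path <- paste0(path, ".aux.json")
  aux <- if (file.exists(aux_path)) jsonlite::read_json(aux_path)
    else list(type = "epoch", year = 0, dataset_id = "unknown",
              crs = "local_equal_area", harmonized = FALSE)
  if (identical(aux$type, "transition")) {
    transition_raster(v, unlist(aux$period), aux$dataset_id,
                      xmin = h[["xllcorner"]], ymin = h[["yllcorner"]],
                      cell_size = h[["cellsize"]], crs = aux$crs)
  } else {
    epoch_raster(v, aux$year, aux$dataset_id,
                 xmin = h[["xllcorner"]], ymin = h[["yllcorner"]],
                 cell_size = h[["cellsize"]], crs = aux$crs,
                 harmonized = isTRUE(aux$harmonized))
  }
}

#' Write a polygon layer as GeoJSON
#'
#' One `Feature` per polygon, attributes as properties; rings are closed
#' on output.
#'
#' @param layer A [polygon_layer()].
#' @param path Output `.geojson` path.
#' @export
write_geojson <- function(layer, path) {
  features <- lapply(seq_len(length(layer)), function(i) {
    ring <- layer$geometry[[i]]
    if (!all(ring[1, ] == ring[nrow(ring), ]))
      ring <- rbind(ring, ring[1, ])
    props <- as.list(layer$table[i, , drop = FALSE])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(apply(ring, 1, as.list,
                                                  simplify = FALSE))))
  })
  obj <- list(type = "FeatureCollection",
              layer_type = layer$layer_type, features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a polygon layer from GeoJSON
#'
#' Reads FeatureCollections of single-ring polygons as written by
#' [write_geojson()].
#'
#' @param path Path to the `.geojson` file.
#' @return A [polygon_layer()].
#' @export
read_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  geometry <- lapply(obj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    if (nrow(ring) > 3 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    ring
  })
  tabs <- lapply(obj$features, function(f)
    as.data.frame(lapply(f$properties, function(x)
      if (is.null(x)) NA else x), stringsAsFactors = FALSE))
  table <- do.call(rbind, tabs)
  polygon_layer(table, geometry,
                layer_type = if (!is.null(obj$layer_type)) obj$layer_type
                else "generic")
}

#' Write an output table as reproducible CSV
#'
#' Numeric columns are serialized with 6 significant digits so identical
#' runs produce byte-identical files.
#'
#' @param tab A data.frame.
#' @param path Output `.csv` path.
#' @export
write_output_csv <- function(tab, path) {
  out <- tab
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], format = "g", digits = 6)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write / read a synthetic scenario as YAML
#'
#' @param scenario A [synthetic_scenario()].
#' @param path YAML file path.
#' @export
write_scenario_yaml <- function(scenario, path) {
  s <- unclass(scenario)
  # named atomic vectors serialize as sequences; maps keep the names
  for (nm in c("class_proportions", "pa_category_probs", "taxon_probs",
               "red_list_probs"))
    s[[nm]] <- as.list(s[[nm]])
  s$transition_matrix <- list(
    classes = rownames(scenario$transition_matrix),
    rows = apply(scenario$transition_matrix, 1, as.numeric,
                 simplify = FALSE))
  yaml::write_yaml(s, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @return `read_scenario_yaml()` returns a validated
#'   [synthetic_scenario()].
#' @export
read_scenario_yaml <- function(path) {
  s <- yaml::read_yaml(path)
  tm <- do.call(rbind, lapply(s$transition_matrix$rows, as.numeric))
  dimnames(tm) <- list(s$transition_matrix$classes,
                       s$transition_matrix$classes)
  args <- s
  args$transition_matrix <- tm
  for (nm in c("class_proportions", "pa_category_probs", "taxon_probs",
               "red_list_probs"))
    args[[nm]] <- unlist(args[[nm]])
  args$grid_shape <- as.integer(unlist(args$grid_shape))
  args$habitat_size_probs <- as.numeric(unlist(args$habitat_size_probs))
  args$pa_year_range <- as.numeric(unlist(args$pa_year_range))
  args$epoch_years <- as.integer(unlist(args$epoch_years))
  args$dataset_styles <- as.character(unlist(args$dataset_styles))
  do.call(synthetic_scenario, args)
}
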