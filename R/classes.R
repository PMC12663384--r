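# Core containers: epoch rasters, transition rasters, polygon layers, zones.
# Rasters are integer matrices (row 1 = top of the map) carrying a local
# equal-area or geographic geotransform; NA encodes nodata internally.

#' Harmonized land-cover classes
#'
#' The common classification scheme into which every product legend is
#' mapped: the four analysis classes (cultivated land/cropland, grassland &
#' shrubland, non-forested wetland, forestland) plus `OTHER` for land covers
#' outside the analysis (water, ice, bare, tundra, impervious). Nodata is
#' represented by `NA` in raster values, not by a class code.
#'
#' @return Named integer vector of class codes.
#' @export
#' @examples
#' harmonized_classes()
harmonized_classes <- function() {
  c(CULTIVATED = 1L, GRASS_SHRUB = 2L, NONFOREST_WETLAND = 3L,
    FOREST = 4L, OTHER = 5L)
}

#' Natural land-cover classes
#'
#' The three natural classes whose conversion to cultivated land is the
#' object of the analysis.
#'
#' @return Named integer vector (subset of [harmonized_classes()]).
#' @export
natural_classes <- function() {
  harmonized_classes()[c("GRASS_SHRUB", "NONFOREST_WETLAND", "FOREST")]
}

#' Transition classes between two epochs
#'
#' Per-pixel transition taxonomy: conversion of each natural class to
#' cultivated land (`CONV_GRASS`, `CONV_WETLAND`, `CONV_FOREST`), reversion
#' of cultivated land to any natural class (`REVERSION`), no class change
#' (`STABLE`), and any other change (`OTHER_CHANGE`).
#'
#' @return Named integer vector of transition codes.
#' @export
transition_codes <- function() {
  c(CONV_GRASS = 1L, CONV_WETLAND = 2L, CONV_FOREST = 3L,
    REVERSION = 4L, STABLE = 5L, OTHER_CHANGE = 6L)
}

#' Conversion (natural-to-cultivated) transition codes
#'
#' @param include_forest If `FALSE`, only the two non-forest conversion
#'   codes are returned.
#' @return Named integer vector (subset of [transition_codes()]).
#' @export
conversion_codes <- function(include_forest = TRUE) {
  codes <- transition_codes()[c("CONV_GRASS", "CONV_WETLAND", "CONV_FOREST")]
  if (!include_forest) codes <- codes[c("CONV_GRASS", "CONV_WETLAND")]
  codes
}

#' IUCN protected-area management categories used in the analysis
#'
#' Categories I (Strict Nature Reserve and Wilderness Area; subcategories
#' Ia/Ib collapsed) through VI (Sustainable use of natural resources).
#'
#' @return Character vector `c("I","II","III","IV","V","VI")`.
#' @export
iucn_categories <- function() c("I", "II", "III", "IV", "V", "VI")

#' Construct an epoch raster
#'
#' A georeferenced categorical land-cover grid for one dataset and year.
#' Values are integer class codes; `NA` marks nodata. The geotransform is a
#' lower-left origin plus square cell size; `crs` is either
#' `"local_equal_area"` (cell size in metres, constant cell area) or
#' `"geographic"` (cell size in decimal degrees, cell area varies with
#' latitude).
#'
#' @param values Integer matrix of class codes (row 1 = northernmost row).
#' @param year Calendar year of the epoch.
#' @param dataset_id Dataset identifier, e.g. `"globeland30"` or
#'   `"synthetic"`.
#' @param xmin,ymin Coordinates of the lower-left corner of the grid.
#' @param cell_size Cell side length (metres or degrees, per `crs`).
#' @param crs Coordinate reference tag: `"local_equal_area"` or
#'   `"geographic"`.
#' @param harmonized Logical; `TRUE` when values are harmonized class codes.
#' @return An object of class `epoch_raster`.
#' @export
epoch_raster <- function(values, year, dataset_id = "synthetic",
                         xmin = 0, ymin = 0, cell_size = 100,
                         crs = c("local_equal_area", "geographic"),
                         harmonized = TRUE) {
  crs <- match.arg(crs)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (cell_size <= 0) stop("`cell_size` must be positive")
  storage.mode(values) <- "integer"
  structure(
    list(values = values, year = as.integer(year), dataset_id = dataset_id,
         xmin = xmin, ymin = ymin, cell_size = cell_size, crs = crs,
         harmonized = isTRUE(harmonized)),
    class = "epoch_raster")
}

#' @export
print.epoch_raster <- function(x, ...) {
  cat(sprintf("<epoch_raster> %s, year %d: %d x %d cells, cell %s %s, %s%s\n",
              x$dataset_id, x$year, nrow(x$values), ncol(x$values),
              format(x$cell_size),
              if (x$crs == "geographic") "deg" else "m", x$crs,
              if (x$harmonized) ", harmonized" else ""))
  invisible(x)
}

#' Construct a transition raster
#'
#' Per-pixel transition class between two epochs (see [transition_codes()]);
#' `NA` wherever either epoch was nodata.
#'
#' @param values Integer matrix of transition codes.
#' @param period Length-2 integer vector `(year_start, year_end)`.
#' @param dataset_id Dataset identifier.
#' @param xmin,ymin,cell_size,crs Geotransform, as in [epoch_raster()].
#' @return An object of class `transition_raster`.
#' @export
transition_raster <- function(values, period, dataset_id,
                              xmin = 0, ymin = 0, cell_size = 100,
                              crs = "local_equal_area") {
  storage.mode(values) <- "integer"
  structure(
    list(values = values, period = as.integer(period),
         dataset_id = dataset_id, xmin = xmin, ymin = ymin,
         cell_size = cell_size, crs = crs),
    class = "transition_raster")
}

#' @export
print.transition_raster <- function(x, ...) {
  cat(sprintf("<transition_raster> %s, %d-%d: %d x %d cells\n",
              x$dataset_id, x$period[1], x$period[2],
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

period_label <- function(period) sprintf("%d-%d", period[1], period[2])

#' Construct a polygon layer
#'
#' A lightweight vector layer: an attribute table plus a list of polygon
#' rings (closed or open `n x 2` coordinate matrices, one exterior ring per
#' feature). Used for protected areas, Key Biodiversity Areas, species
#' ranges, and zone boundaries.
#'
#' @param table A data.frame of feature attributes (one row per polygon).
#' @param geometry A list of numeric `n x 2` matrices (x, y vertex
#'   coordinates; rings need not repeat the first vertex).
#' @param layer_type Free-text tag, e.g. `"pa"`, `"kba"`, `"species_range"`.
#' @return An object of class `polygon_layer`.
#' @export
polygon_layer <- function(table, geometry, layer_type = "generic") {
  if (nrow(table) != length(geometry))
    stop("attribute table and geometry list lengths differ")
  ok <- vapply(geometry, function(g) is.matrix(g) && ncol(g) == 2 &&
                 nrow(g) >= 3, logical(1))
  if (length(geometry) && !all(ok))
    stop("each geometry must be an n x 2 matrix with n >= 3")
  structure(list(table = table, geometry = geometry,
                 layer_type = layer_type),
            class = "polygon_layer")
}

#' @export
print.polygon_layer <- function(x, ...) {
  cat(sprintf("<polygon_layer> %s: %d feature(s), attributes: %s\n",
              x$layer_type, nrow(x$table),
              paste(names(x$table), collapse = ", ")))
  invisible(x)
}

#' Number of features in a polygon layer
#' @param x A `polygon_layer`.
#' @param ... Unused.
#' @export
length.polygon_layer <- function(x, ...) length(x$geometry)

#' Subset a polygon layer by feature index
#' @param x A `polygon_layer`.
#' @param i Feature indices (logical or integer).
#' @export
subset_layer <- function(x, i) {
  polygon_layer(x$table[i, , drop = FALSE], x$geometry[i], x$layer_type)
}

#' Construct a zone layer
#'
#' A label raster assigning every cell to one zone ("country"); zones are
#' mutually exclusive by construction. `NA` labels mark cells outside all
#' zones (reported downstream under a reserved `"unassigned"` zone).
#'
#' @param labels Integer matrix of zone indices aligned to the analysis
#'   raster.
#' @param zone_ids Character vector of zone identifiers, one per index.
#' @return An object of class `zone_layer`.
#' @export
zone_layer <- function(labels, zone_ids) {
  storage.mode(labels) <- "integer"
  present <- sort(unique(labels[!is.na(labels)]))
  if (length(present) && max(present) > length(zone_ids))
    stop("zone label exceeds the number of zone_ids")
  structure(list(labels = labels, zone_ids = as.character(zone_ids)),
            class = "zone_layer")
}

#' @export
print.zone_layer <- function(x, ...) {
  cat(sprintf("<zone_layer> %d zone(s): %s\n", length(x$zone_ids),
              paste(x$zone_ids, collapse = ", ")))
  invisible(x)
}

raster_dim_equal <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cell_size),
                     c(b$xmin, b$ymin, b$cell_size))) &&
    identical(a$crs, b$crs)
}

geotransform_string <- function(r) {
  sprintf("xmin=%g ymin=%g cell=%g crs=%s [%d x %d]",
          r$xmin, r$ymin, r$cell_size, r$crs,
          nrow(r$values), ncol(r$values))
}

# x/y coordinates of all cell centers, in raster storage order
# (column-major over the values matrix).
cell_center_coords <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  list(x = r$xmin + (col - 0.5) * r$cell_size,
       y = r$ymin + (nr - row + 0.5) * r$cell_size)
}
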