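# Transition detection and equal-area conversion accounting: per-pixel
# overlay of two harmonized epochs, per-cell areas, zonal aggregation, and
# block ("10 km grid") conversion fractions.

#' Detect per-pixel transitions between two harmonized epochs
#'
#' Overlays the earlier and later epoch cell-for-cell and codes each valid
#' cell with a transition class (see [transition_codes()]):
#' natural-to-cultivated cells are split by source class (`CONV_GRASS`,
#' `CONV_WETLAND`, `CONV_FOREST`), cultivated-to-natural cells are coded
#' `REVERSION`, unchanged cells `STABLE`, and any remaining change
#' `OTHER_CHANGE`. A cell that is nodata in either epoch is nodata in the
#' output (excluded from all numerators and denominators downstream).
#'
#' @param t0,t1 Harmonized [epoch_raster()]s with identical geometry and
#'   dataset, `t0$year < t1$year`.
#' @return A [transition_raster()] for the period `(t0$year, t1$year)`.
#' @export
detect_transitions <- function(t0, t1) {
  stopifnot(inherits(t0, "epoch_raster"), inherits(t1, "epoch_raster"))
  if (!t0$harmonized || !t1$harmonized)
    stop("both epochs must be harmonized before transition detection")
  if (!raster_dim_equal(t0, t1))
    stop("epoch geometry mismatch:\n  t0: ", geotransform_string(t0),
         "\n  t1: ", geotransform_string(t1))
  if (!identical(t0$dataset_id, t1$dataset_id))
    stop("epochs come from different datasets: ",
         t0$dataset_id, " vs ", t1$dataset_id)
  if (t0$year >= t1$year) stop("t0 must predate t1")

  hc <- harmonized_classes(); tc <- transition_codes()
  a <- t0$values; b <- t1$values
  out <- matrix(NA_integer_, nrow(a), ncol(a))
  valid <- !is.na(a) & !is.na(b)
  out[valid] <- tc["OTHER_CHANGE"]
  out[valid & a == b] <- tc["STABLE"]
  cult <- hc["CULTIVATED"]
  out[valid & a == hc["GRASS_SHRUB"] & b == cult] <- tc["CONV_GRASS"]
  out[valid & a == hc["NONFOREST_WETLAND"] & b == cult] <- tc["CONV_WETLAND"]
  out[valid & a == hc["FOREST"] & b == cult] <- tc["CONV_FOREST"]
  natural <- natural_classes()
  out[valid & a == cult & b %in% natural] <- tc["REVERSION"]
  transition_raster(out, c(t0$year, t1$year), t0$dataset_id,
                    xmin = t0$xmin, ymin = t0$ymin,
                    cell_size = t0$cell_size, crs = t0$crs)
}

#' Per-cell areas in hectares
#'
#' For a local equal-area grid every cell has area `cell_size^2 / 10000`
#' ha. For a geographic grid the spherical cell area is computed per row as
#' `R^2 * (sin(lat_top) - sin(lat_bottom)) * dlambda` on the authalic
#' sphere (R = 6371007.181 m), so areas vary with latitude only.
#'
#' @param r An [epoch_raster()] or [transition_raster()].
#' @return Numeric matrix of per-cell areas (ha), same shape as the raster.
#' @export
cell_areas <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  if (r$crs == "local_equal_area") {
    matrix(r$cell_size^2 / 1e4, nr, nc)
  } else if (r$crs == "geographic") {
    R <- 6371007.181
    lat_bot <- r$ymin + (nr - seq_len(nr)) * r$cell_size
    lat_top <- lat_bot + r$cell_size
    row_area <- R^2 * (sinpi(lat_top / 180) - sinpi(lat_bot / 180)) *
      (r$cell_size * pi / 180) / 1e4
    matrix(rep(row_area, times = nc), nr, nc)
  } else {
    stop("unknown crs tag: ", r$crs)
  }
}

#' Aggregate transition areas by zone
#'
#' Sums per-cell areas by (zone, transition class). Cells are assigned to
#' zones by the zone label raster (built by cell-center containment for
#' polygon zones); valid cells outside every zone are reported under the
#' reserved zone `"unassigned"`. Summing the table over zones reproduces
#' the global per-class totals exactly.
#'
#' @param tr A [transition_raster()].
#' @param zones A [zone_layer()] aligned to `tr`.
#' @return An area table: data.frame with columns `zone_id`, `dataset_id`,
#'   `period`, `transition_code`, `area_ha`.
#' @export
aggregate_by_zone <- function(tr, zones) {
  stopifnot(inherits(tr, "transition_raster"), inherits(zones, "zone_layer"))
  if (!identical(dim(zones$labels), dim(tr$values)))
    stop("zone layer and transition raster dimensions differ")
  areas <- cell_areas(tr)
  valid <- !is.na(tr$values)
  if (!any(valid)) {
    warning("no valid cells intersect the zone layer")
    return(data.frame(zone_id = character(), dataset_id = character(),
                      period = character(), transition_code = character(),
                      area_ha = numeric(), stringsAsFactors = FALSE))
  }
  zid <- zones$labels
  zname <- c(zones$zone_ids, "unassigned")
  zid[is.na(zid) & valid] <- length(zones$zone_ids) + 1L
  code_names <- names(transition_codes())
  f_zone <- factor(zname[zid[valid]], levels = zname)
  f_code <- factor(code_names[tr$values[valid]], levels = code_names)
  sums <- tapply(areas[valid], list(f_zone, f_code), sum, default = 0)
  out <- expand.grid(zone_id = zname, transition_code = code_names,
                     stringsAsFactors = FALSE)
  out$area_ha <- as.numeric(sums[cbind(out$zone_id, out$transition_code)])
  keep_zones <- c(zones$zone_ids,
                  if ("unassigned" %in% f_zone) "unassigned")
  out <- out[out$zone_id %in% keep_zones, ]
  data.frame(zone_id = out$zone_id, dataset_id = tr$dataset_id,
             period = period_label(tr$period),
             transition_code = out$transition_code,
             area_ha = out$area_ha, stringsAsFactors = FALSE,
             row.names = NULL)
}

block_index <- function(tr, block_cells) {
  nr <- nrow(tr$values); nc <- ncol(tr$values)
  brow <- (rep(seq_len(nr), times = nc) - 1L) %/% block_cells + 1L
  bcol <- (rep(seq_len(nc), each = nr) - 1L) %/% block_cells + 1L
  nbc <- (nc - 1L) %/% block_cells + 1L
  list(id = (brow - 1L) * nbc + bcol, brow = brow, bcol = bcol)
}

#' Per-block conversion fraction on a coarse grid
#'
#' Partitions the raster into square blocks of `cell_size_m` per side
#' (anchored at the raster origin) and reports, per block, the fraction of
#' valid pixels whose transition code is in `which`, together with the
#' summed converted area. Blocks with zero valid pixels are omitted.
#'
#' @param tr A [transition_raster()] on a local equal-area grid.
#' @param cell_size_m Coarse cell side in metres; must be a positive
#'   multiple of the raster cell size.
#' @param which Integer transition codes counted as "converted" (default
#'   all three natural-to-cultivated codes).
#' @return A grid summary: data.frame with columns `grid_cell_id`,
#'   `block_row`, `block_col`, `dataset_id`, `period`, `valid_cells`,
#'   `fraction_converted`, `area_converted_ha`.
#' @export
grid_fraction <- function(tr, cell_size_m, which = conversion_codes()) {
  stopifnot(inherits(tr, "transition_raster"))
  ratio <- cell_size_m / tr$cell_size
  if (cell_size_m <= 0 || abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf(
      "cell_size_m must be a positive multiple of the raster cell size (%g); nearest valid value: %g",
      tr$cell_size, max(1, round(ratio)) * tr$cell_size))
  block_cells <- as.integer(round(ratio))
  bi <- block_index(tr, block_cells)
  v <- as.integer(tr$values)
  valid <- !is.na(v)
  conv <- valid & v %in% which
  area <- as.numeric(cell_areas(tr))
  n_valid <- tapply(as.numeric(valid), bi$id, sum)
  n_conv <- tapply(as.numeric(conv), bi$id, sum)
  a_conv <- tapply(area * conv, bi$id, sum)
  ids <- as.integer(names(n_valid))
  keep <- n_valid > 0
  nbc <- max(bi$bcol)
  out <- data.frame(
    grid_cell_id = ids[keep],
    block_row = (ids[keep] - 1L) %/% nbc + 1L,
    block_col = (ids[keep] - 1L) %% nbc + 1L,
    dataset_id = tr$dataset_id, period = period_label(tr$period),
    valid_cells = as.integer(n_valid[keep]),
    fraction_converted = as.numeric(n_conv[keep] / n_valid[keep]),
    area_converted_ha = as.numeric(a_conv[keep]),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$grid_cell_id), , drop = FALSE]
}

#' Combine per-period transition rasters over the full study span
#'
#' Cell-wise combination of consecutive-period transition rasters: a cell
#' keeps its earliest non-`STABLE` code (so a cell converted in either
#' decade is coded as converted over the span); cells stable in every
#' period stay `STABLE`; nodata in any period propagates.
#'
#' @param trs List of [transition_raster()]s for consecutive periods of
#'   one dataset, in chronological order.
#' @return A [transition_raster()] spanning the first start to the last
#'   end year.
#' @export
combine_transitions <- function(trs) {
  stopifnot(length(trs) >= 1)
  out <- trs[[1]]$values
  stable <- transition_codes()["STABLE"]
  for (tr in trs[-1]) {
    if (!identical(dim(tr$values), dim(out)))
      stop("transition rasters have differing dimensions")
    take <- !is.na(out) & out == stable & !is.na(tr$values)
    out[take] <- tr$values[take]
    out[is.na(tr$values)] <- NA_integer_
  }
  first <- trs[[1]]; last <- trs[[length(trs)]]
  transition_raster(out, c(first$period[1], last$period[2]),
                    first$dataset_id, xmin = first$xmin,
                    ymin = first$ymin, cell_size = first$cell_size,
                    crs = first$crs)
}

#' Sum conversion areas over periods
#'
#' Multi-decade totals are the sum of the per-period conversion areas (each
#' period detected from its own epoch pair), not an endpoint comparison of
#' the first and last epochs.
#'
#' @param tables A list of area tables (one per period) from
#'   [aggregate_by_zone()].
#' @return One area table with `period` set to the overall span and
#'   `area_ha` summed by (zone, dataset, transition class).
#' @export
sum_periods <- function(tables) {
  all_tab <- do.call(rbind, tables)
  years <- range(as.integer(unlist(strsplit(unique(all_tab$period), "-"))))
  agg <- stats::aggregate(area_ha ~ zone_id + dataset_id + transition_code,
                          data = all_tab, FUN = sum)
  data.frame(zone_id = agg$zone_id, dataset_id = agg$dataset_id,
             period = period_label(years),
             transition_code = agg$transition_code,
             area_ha = agg$area_ha, stringsAsFactors = FALSE)
}
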