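# Protected-area overlay: establishment-year filtering, conversion by IUCN
# category, and inside-vs-outside conversion rates per zone and land class.
# Cells are attributed to PAs by cell-center containment; where PAs of
# different categories overlap, the strictest (lowest-numbered) category
# wins.

land_class_of_conversion <- function() {
  tc <- transition_codes()
  stats::setNames(c("GRASS_SHRUB", "NONFOREST_WETLAND", "FOREST"),
                  names(tc)[1:3])
}

#' Filter protected areas by establishment year
#'
#' Retains PAs established strictly before `cutoff_year` (conversion over a
#' period is only attributed to PAs that already existed at its start).
#' PAs with unknown establishment year are excluded and counted; marine
#' PAs are excluded from land analyses when `drop_marine` is `TRUE`.
#'
#' @param pas A PA [polygon_layer()] with attributes `iucn_category`,
#'   `establishment_year`, and optionally `marine`.
#' @param cutoff_year Calendar year; a PA passes iff
#'   `establishment_year < cutoff_year`.
#' @param drop_marine Drop marine-flagged PAs (default `TRUE`).
#' @return The filtered [polygon_layer()], with attributes
#'   `n_unknown_year` and `n_marine_dropped` recording exclusions.
#' @export
filter_by_year <- function(pas, cutoff_year, drop_marine = TRUE) {
  stopifnot(inherits(pas, "polygon_layer"))
  yr <- pas$table$establishment_year
  unknown <- is.na(yr)
  marine <- if (drop_marine && "marine" %in% names(pas$table))
    pas$table$marine %in% TRUE else rep(FALSE, length(yr))
  keep <- !unknown & !marine & yr < cutoff_year
  out <- subset_layer(pas, keep)
  attr(out, "n_unknown_year") <- sum(unknown)
  attr(out, "n_marine_dropped") <- sum(marine & !unknown)
  out
}

# Category matrix: per cell, the IUCN category index (1 = I ... 6 = VI) of
# the strictest containing PA, NA outside all PAs. Subcategories Ia/Ib are
# collapsed to I upstream of this point.
pa_category_matrix <- function(pas, r) {
  cat_idx <- match(pas$table$iucn_category, iucn_categories())
  if (anyNA(cat_idx))
    stop("PA categories must be one of ",
         paste(iucn_categories(), collapse = ", "))
  # strictest (lowest category number) wins on overlap: burn strict last
  feat <- rasterize_layer(pas, r, precedence = -cat_idx)
  out <- matrix(NA_integer_, nrow(r$values), ncol(r$values))
  inside <- !is.na(feat)
  out[inside] <- cat_idx[feat[inside]]
  out
}

#' Conversion within protected areas by IUCN category
#'
#' Sums converted area per (IUCN category, natural land class) over the
#' supplied PAs, and expresses each category's share of the total converted
#' area across all PA categories per land class.
#'
#' @param tr A [transition_raster()].
#' @param pas A year-filtered PA [polygon_layer()] co-registered with `tr`.
#' @return List with `areas` (data.frame: `iucn_category`, `land_class`,
#'   `converted_area_ha`) and `proportions` (same rows plus `proportion`,
#'   each land class's proportions summing to 1 when any conversion
#'   exists).
#' @export
pa_conversion <- function(tr, pas) {
  stopifnot(inherits(tr, "transition_raster"))
  cat_mat <- pa_category_matrix(pas, tr)
  area <- cell_areas(tr)
  lc <- land_class_of_conversion()
  tc <- transition_codes()
  grid <- expand.grid(iucn_category = iucn_categories(),
                      land_class = unname(lc),
                      stringsAsFactors = FALSE)
  grid$converted_area_ha <- mapply(function(cat, cls) {
    code <- tc[names(lc)[match(cls, lc)]]
    sel <- !is.na(tr$values) & tr$values == code &
      !is.na(cat_mat) & cat_mat == match(cat, iucn_categories())
    sum(area[sel])
  }, grid$iucn_category, grid$land_class)
  prop <- grid
  for (cls in unique(prop$land_class)) {
    i <- prop$land_class == cls
    tot <- sum(prop$converted_area_ha[i])
    prop$proportion[i] <- if (tot > 0) prop$converted_area_ha[i] / tot else 0
  }
  list(areas = grid, proportions = prop)
}

#' Inside- vs outside-PA conversion rates per zone and land class
#'
#' For every (zone, land class, IUCN category) the rate is the converted
#' area of that class inside that category's PAs divided by the class's
#' first-epoch (baseline) area inside those PAs; the `OUTSIDE` row uses the
#' complement of all PAs. Rates with zero baseline are flagged undefined
#' (`NA`) and excluded from summaries.
#'
#' @param tr A [transition_raster()].
#' @param t0 The harmonized first-epoch [epoch_raster()] (baseline areas).
#' @param pas A year-filtered PA [polygon_layer()].
#' @param zones A [zone_layer()]; pass `NULL` for a single global zone.
#' @return Rate table: data.frame with columns `zone_id`, `dataset_id`,
#'   `period`, `land_class`, `category`, `converted_area_ha`,
#'   `baseline_area_ha`, `rate`.
#' @export
conversion_rates <- function(tr, t0, pas, zones = NULL) {
  stopifnot(inherits(tr, "transition_raster"), inherits(t0, "epoch_raster"))
  if (!identical(dim(tr$values), dim(t0$values)))
    stop("transition raster and baseline epoch dimensions differ")
  if (is.null(zones))
    zones <- zone_layer(matrix(1L, nrow(tr$values), ncol(tr$values)),
                        "global")
  cat_mat <- pa_category_matrix(pas, tr)
  area <- cell_areas(tr)
  hc <- harmonized_classes(); tc <- transition_codes()
  lc <- land_class_of_conversion()
  categories <- c(iucn_categories(), "OUTSIDE")
  out <- expand.grid(zone_id = zones$zone_ids, land_class = unname(lc),
                     category = categories, stringsAsFactors = FALSE)
  zmat <- zones$labels
  conv_num <- numeric(nrow(out)); base_den <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    zi <- match(out$zone_id[i], zones$zone_ids)
    cls_code <- hc[out$land_class[i]]
    conv_code <- tc[names(lc)[match(out$land_class[i], lc)]]
    in_cat <- if (out$category[i] == "OUTSIDE") is.na(cat_mat)
      else !is.na(cat_mat) & cat_mat == match(out$category[i],
                                              iucn_categories())
    zone_ok <- !is.na(zmat) & zmat == zi
    base_sel <- zone_ok & in_cat & !is.na(t0$values) &
      t0$values == cls_code & !is.na(tr$values)
    conv_sel <- base_sel & tr$values == conv_code
    base_den[i] <- sum(area[base_sel])
    conv_num[i] <- sum(area[conv_sel])
  }
  out$converted_area_ha <- conv_num
  out$baseline_area_ha <- base_den
  out$rate <- ifelse(base_den > 0, conv_num / base_den, NA_real_)
  data.frame(zone_id = out$zone_id, dataset_id = tr$dataset_id,
             period = period_label(tr$period),
             land_class = out$land_class, category = out$category,
             converted_area_ha = out$converted_area_ha,
             baseline_area_ha = out$baseline_area_ha, rate = out$rate,
             stringsAsFactors = FALSE)
}
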