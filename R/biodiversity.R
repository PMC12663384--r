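# Biodiversity impact summaries: consensus-conversion cells across
# datasets, threatened-species richness on a coarse equal-area grid,
# affected species by taxon and habitat affinity, and KBA conversion with a
# PA comparison. Range-vs-raster overlap uses the package-wide cell-center
# containment rule at the analysis resolution.

parse_habitats <- function(h) {
  parts <- strsplit(h, "+", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) > 0 &&
                 all(p %in% names(natural_classes())), logical(1))
  if (!all(ok))
    stop("invalid or empty habitat-affinity set(s): ",
         paste(h[!ok], collapse = "; "))
  parts
}

threatened_only <- function(ranges) {
  subset_layer(ranges, ranges$table$red_list %in% c("VU", "EN", "CR"))
}

#' Consensus-conversion cells across datasets
#'
#' Coarse grid cells where every supplied dataset detects conversion
#' (fraction of converted pixels > 0 for the codes used to build the
#' grids). With a single dataset this degenerates to its nonzero cells.
#'
#' @param grids List of grid summaries from [grid_fraction()] (one per
#'   dataset) sharing the same cell indexing.
#' @return Sorted integer vector of consensus `grid_cell_id`s.
#' @export
consensus_cells <- function(grids) {
  if (inherits(grids, "data.frame")) grids <- list(grids)
  nonzero <- lapply(grids, function(g)
    g$grid_cell_id[g$fraction_converted > 0])
  sort(Reduce(intersect, nonzero))
}

# Fine-cell mask of one species range (cell-center containment).
range_mask <- function(ring, r) polygon_cell_mask(r, ring)

#' Threatened-species richness on a coarse equal-area grid
#'
#' Counts, per coarse block, the number of distinct threatened (VU/EN/CR)
#' species whose range overlaps the block — overlap meaning the range
#' polygon contains at least one fine-cell center inside the block.
#' Optionally restricted to a consensus-conversion cell set, in which case
#' blocks outside the set are dropped.
#'
#' @param ranges A species-range [polygon_layer()] (attributes `species_id`,
#'   `red_list`); non-threatened species are excluded before counting.
#' @param r An [epoch_raster()] or [transition_raster()] defining the fine
#'   grid.
#' @param cell_size_m Coarse block side in metres (multiple of the fine
#'   cell size); the analysis-scale analogue of the ~30 km richness grid.
#' @param restrict Optional integer vector of coarse `grid_cell_id`s (e.g.
#'   from [consensus_cells()]); `NULL` keeps every block.
#' @return Data.frame with columns `grid_cell_id`, `block_row`,
#'   `block_col`, `species_count`, `restricted_to_consensus`.
#' @export
richness <- function(ranges, r, cell_size_m, restrict = NULL) {
  ranges <- threatened_only(ranges)
  ratio <- cell_size_m / r$cell_size
  if (cell_size_m <= 0 || abs(ratio - round(ratio)) > 1e-9)
    stop("cell_size_m must be a positive multiple of the fine cell size")
  block_cells <- as.integer(round(ratio))
  bi <- block_index(r, block_cells)
  ids <- sort(unique(bi$id))
  counts <- integer(length(ids))
  for (i in seq_len(length(ranges))) {
    m <- range_mask(ranges$geometry[[i]], r)
    hit <- unique(bi$id[as.logical(m)])
    counts[match(hit, ids)] <- counts[match(hit, ids)] + 1L
  }
  nbc <- max(bi$bcol)
  out <- data.frame(grid_cell_id = ids,
                    block_row = (ids - 1L) %/% nbc + 1L,
                    block_col = (ids - 1L) %% nbc + 1L,
                    species_count = counts,
                    restricted_to_consensus = !is.null(restrict))
  if (!is.null(restrict)) out <- out[out$grid_cell_id %in% restrict, ]
  rownames(out) <- NULL
  out
}

#' Species affected by natural-land conversion
#'
#' A species is affected iff its range overlaps at least one cell coded as
#' natural-to-cultivated conversion. Affected species are summarized by
#' taxonomic group and, per focal natural class in the species'
#' habitat-affinity set, by affinity-set size: `endemic` (restricted to
#' that class), `two` (that class plus one other), `three` (all three
#' natural classes). A two-habitat species therefore contributes to the
#' `two` bucket of both of its classes. Only threatened (VU/EN/CR) species
#' are counted.
#'
#' @param tr A [transition_raster()] (one designated dataset at analysis
#'   resolution).
#' @param ranges A species-range [polygon_layer()] with attributes
#'   `species_id`, `taxon`, `red_list`, `habitats` (`+`-separated class
#'   names).
#' @param which Transition codes counted as conversion (default all three
#'   natural-to-cultivated codes).
#' @return List of class `affected_species_summary`: `affected_ids`,
#'   `n_affected`, `by_taxon` (data.frame `taxon`, `n`), `by_affinity`
#'   (data.frame `focal_class`, `bucket`, `n`).
#' @export
affected_species <- function(tr, ranges, which = conversion_codes()) {
  stopifnot(inherits(tr, "transition_raster"))
  ranges <- threatened_only(ranges)
  habs <- parse_habitats(ranges$table$habitats)
  conv <- !is.na(tr$values) & tr$values %in% which
  affected <- vapply(seq_len(length(ranges)), function(i)
    any(range_mask(ranges$geometry[[i]], tr) & conv), logical(1))
  if (length(ranges) == 0) affected <- logical(0)
  taxa <- c("amphibian", "mammal", "reptile", "bird")
  by_taxon <- data.frame(
    taxon = taxa,
    n = vapply(taxa, function(t)
      sum(affected & ranges$table$taxon == t), integer(1)),
    row.names = NULL)
  buckets <- c("endemic", "two", "three")
  grid <- expand.grid(focal_class = names(natural_classes()),
                      bucket = buckets, stringsAsFactors = FALSE)
  grid$n <- mapply(function(cls, b) {
    size <- match(b, buckets)
    sum(vapply(seq_along(habs), function(i)
      affected[i] && length(habs[[i]]) == size && cls %in% habs[[i]],
      logical(1)))
  }, grid$focal_class, grid$bucket)
  structure(list(affected_ids = ranges$table$species_id[affected],
                 n_affected = sum(affected),
                 by_taxon = by_taxon, by_affinity = grid),
            class = "affected_species_summary")
}

#' @export
print.affected_species_summary <- function(x, ...) {
  cat(sprintf("<affected_species_summary> %d threatened species affected\n",
              x$n_affected))
  invisible(x)
}

#' Conversion within KBAs compared with protected areas
#'
#' Per zone and natural land class: converted area inside Key Biodiversity
#' Areas, inside PAs, and the protection gap — converted area inside KBAs
#' but outside every PA.
#'
#' @param tr A [transition_raster()].
#' @param kbas A KBA [polygon_layer()].
#' @param pas A PA [polygon_layer()] (typically year-filtered).
#' @param zones A [zone_layer()]; `NULL` for a single global zone.
#' @return Data.frame with columns `zone_id`, `dataset_id`, `period`,
#'   `land_class`, `kba_converted_ha`, `pa_converted_ha`,
#'   `kba_not_pa_converted_ha`.
#' @export
kba_conversion <- function(tr, kbas, pas, zones = NULL) {
  stopifnot(inherits(tr, "transition_raster"))
  if (is.null(zones))
    zones <- zone_layer(matrix(1L, nrow(tr$values), ncol(tr$values)),
                        "global")
  in_kba <- !is.na(rasterize_layer(kbas, tr))
  in_pa <- !is.na(rasterize_layer(pas, tr))
  area <- cell_areas(tr)
  lc <- land_class_of_conversion()
  tc <- transition_codes()
  out <- expand.grid(zone_id = zones$zone_ids, land_class = unname(lc),
                     stringsAsFactors = FALSE)
  res <- t(vapply(seq_len(nrow(out)), function(i) {
    zi <- match(out$zone_id[i], zones$zone_ids)
    code <- tc[names(lc)[match(out$land_class[i], lc)]]
    conv <- !is.na(tr$values) & tr$values == code &
      !is.na(zones$labels) & zones$labels == zi
    c(kba = sum(area[conv & in_kba]),
      pa = sum(area[conv & in_pa]),
      gap = sum(area[conv & in_kba & !in_pa]))
  }, numeric(3)))
  data.frame(zone_id = out$zone_id, dataset_id = tr$dataset_id,
             period = period_label(tr$period), land_class = out$land_class,
             kba_converted_ha = res[, "kba"],
             pa_converted_ha = res[, "pa"],
             kba_not_pa_converted_ha = res[, "gap"],
             stringsAsFactors = FALSE)
}
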