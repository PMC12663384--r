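# Hotspot identification: the minimal set of coarse grid cells whose mean
# converted area across datasets covers a target share (default 90%) of the
# global total, and hotspot countries from per-dataset top-k rankings.

#' Hotspot grid cells covering a share of total conversion
#'
#' Per-cell converted areas are averaged across the supplied datasets,
#' cells are sorted by mean converted area descending (ties broken by cell
#' id ascending), and cells are included greedily until the cumulative
#' share of the total reaches `threshold`. The selected set is therefore
#' the minimal prefix of the sorted list achieving the target coverage.
#'
#' @param grids List of grid summaries (one per dataset) from
#'   [grid_fraction()], sharing the same cell indexing.
#' @param threshold Target coverage fraction in (0, 1]; default 0.90.
#' @return List of class `hotspot_cells`: `cells` (data.frame of selected
#'   cells with mean areas and cumulative share), `coverage_achieved`,
#'   `threshold`, `total_area_ha`.
#' @export
hotspot_cells <- function(grids, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  if (inherits(grids, "data.frame")) grids <- list(grids)
  ids <- sort(unique(unlist(lapply(grids, `[[`, "grid_cell_id"))))
  per_ds <- vapply(grids, function(g) {
    a <- numeric(length(ids))
    a[match(g$grid_cell_id, ids)] <- g$area_converted_ha
    a
  }, numeric(length(ids)))
  mean_area <- rowMeans(as.matrix(per_ds))
  total <- sum(mean_area)
  if (total <= 0) {
    warning("zero total conversion; empty hotspot set")
    return(structure(list(cells = data.frame(grid_cell_id = integer(),
                                             mean_area_ha = numeric(),
                                             cumulative_share = numeric()),
                          coverage_achieved = 0, threshold = threshold,
                          total_area_ha = 0),
                     class = "hotspot_cells"))
  }
  ord <- order(-mean_area, ids)
  cum <- cumsum(mean_area[ord]) / total
  n_sel <- which(cum >= threshold - 1e-12)[1]
  sel <- ord[seq_len(n_sel)]
  structure(list(
    cells = data.frame(grid_cell_id = ids[sel],
                       mean_area_ha = mean_area[sel],
                       cumulative_share = cum[seq_len(n_sel)],
                       stringsAsFactors = FALSE),
    coverage_achieved = cum[n_sel], threshold = threshold,
    total_area_ha = total), class = "hotspot_cells")
}

#' @export
print.hotspot_cells <- function(x, ...) {
  cat(sprintf("<hotspot_cells> %d cell(s) covering %.1f%% (target %.0f%%) of %.1f ha\n",
              nrow(x$cells), 100 * x$coverage_achieved, 100 * x$threshold,
              x$total_area_ha))
  invisible(x)
}

#' Hotspot countries from per-dataset rankings
#'
#' Per dataset, zones are ranked by summed conversion area over the codes
#' in `which`; a zone is a hotspot when it falls in the top `k` for at
#' least `min_datasets` datasets. Zones absent from a dataset's table count
#' as zero area there (and are flagged). The output is sorted by
#' cross-dataset mean area descending.
#'
#' @param tables List of area tables (one per dataset) from
#'   [aggregate_by_zone()] or [sum_periods()].
#' @param k Top-rank cutoff per dataset (default 10).
#' @param min_datasets Minimum number of datasets in whose top-k a zone
#'   must appear (default 2).
#' @param which Transition codes summed as "conversion" (default the two
#'   non-forest conversion codes).
#' @return Data.frame with one row per zone: per-dataset areas
#'   (`area_<dataset>`), `mean_area_ha`, `n_datasets_top_k`, `is_hotspot`,
#'   `missing_in` (comma-separated datasets without the zone), sorted by
#'   mean area descending.
#' @export
hotspot_countries <- function(tables, k = 10, min_datasets = 2,
                              which = conversion_codes(include_forest = FALSE)) {
  stopifnot(k >= 1, min_datasets >= 1)
  code_names <- names(transition_codes())[which]
  ds_ids <- vapply(tables, function(t) t$dataset_id[1], character(1))
  zone_ids <- sort(unique(unlist(lapply(tables, function(t)
    setdiff(t$zone_id, "unassigned")))))
  area_mat <- vapply(tables, function(t) {
    t <- t[t$transition_code %in% code_names & t$zone_id != "unassigned", ]
    a <- numeric(length(zone_ids))
    s <- tapply(t$area_ha, t$zone_id, sum)
    a[match(names(s), zone_ids)] <- as.numeric(s)
    a
  }, numeric(length(zone_ids)))
  area_mat <- matrix(area_mat, nrow = length(zone_ids),
                     dimnames = list(zone_ids, ds_ids))
  present <- vapply(tables, function(t) zone_ids %in% t$zone_id,
                    logical(length(zone_ids)))
  present <- matrix(present, nrow = length(zone_ids))
  # ties broken by zone id ascending, for determinism
  in_topk <- apply(area_mat, 2, function(a) {
    sel <- order(-a, zone_ids)[seq_len(min(k, length(a)))]
    res <- logical(length(a))
    res[sel] <- TRUE
    res & a > 0
  })
  in_topk <- matrix(in_topk, nrow = length(zone_ids))
  n_top <- rowSums(in_topk)
  out <- data.frame(zone_id = zone_ids, stringsAsFactors = FALSE)
  for (j in seq_along(ds_ids))
    out[[paste0("area_", ds_ids[j])]] <- area_mat[, j]
  out$mean_area_ha <- rowMeans(area_mat)
  out$n_datasets_top_k <- as.integer(n_top)
  out$is_hotspot <- n_top >= min_datasets
  out$missing_in <- apply(!present, 1, function(m)
    paste(ds_ids[m], collapse = ","))
  out <- out[order(-out$mean_area_ha, out$zone_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
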