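# End-to-end orchestration: a declarative run configuration drives
# landscape simulation (or file loading), harmonization, per-period
# transition detection, zonal/grid accounting, hotspot identification, PA
# and biodiversity overlays, and a machine-readable run report. Identical
# config + seed reproduces every CSV byte-identically.

#' Build a pipeline run configuration
#'
#' @param mode `"synthetic"` (inputs generated from `scenario`) or
#'   `"files"` (epoch rasters read from `dataset_files`).
#' @param scenario A [synthetic_scenario()] (synthetic mode).
#' @param dataset_files Files mode: named list, one entry per dataset id,
#'   each a character vector of per-epoch ASCII-grid paths (chronological).
#' @param periods List of `(year_start, year_end)` pairs; consecutive
#'   epochs are compared per period. Defaults to the scenario's epoch
#'   pairs.
#' @param analyses Character subset of
#'   `c("hotspots", "pa", "biodiversity", "kba")` to run.
#' @param threshold Hotspot-cell coverage target (default 0.90).
#' @param k,min_datasets Hotspot-country ranking parameters (defaults 10
#'   and 2).
#' @param block_size_m Coarse grid cell side in metres for grid fractions,
#'   hotspot cells and consensus/richness grids.
#' @param pa_cutoff_year PAs must be established strictly before this year
#'   for the whole-span rate analysis (default the first period start).
#' @param affected_dataset Dataset used for the affected-species overlay
#'   (default the first dataset).
#' @param seed Integer seed for synthetic mode (overrides the scenario's).
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), scenario = NULL,
                       dataset_files = NULL, periods = NULL,
                       analyses = c("hotspots", "pa", "biodiversity",
                                    "kba"),
                       threshold = 0.90, k = 10, min_datasets = 2,
                       block_size_m = NULL, pa_cutoff_year = NULL,
                       affected_dataset = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (is.null(scenario)) scenario <- synthetic_scenario()
    if (!is.null(seed)) scenario$seed <- as.integer(seed)
    if (is.null(periods)) {
      yrs <- scenario$epoch_years
      periods <- lapply(seq_len(length(yrs) - 1),
                        function(i) yrs[c(i, i + 1)])
    }
  } else if (is.null(dataset_files) || is.null(periods)) {
    stop("files mode needs `dataset_files` and `periods`")
  }
  starts <- vapply(periods, `[`, numeric(1), 1)
  ends <- vapply(periods, `[`, numeric(1), 2)
  if (any(ends <= starts) || is.unsorted(starts) ||
      any(starts[-1] < ends[-length(ends)]))
    stop("periods must be ordered and non-overlapping")
  if (length(analyses)) analyses <- match.arg(analyses, several.ok = TRUE)
  structure(list(mode = mode, scenario = scenario,
                 dataset_files = dataset_files, periods = periods,
                 analyses = analyses, threshold = threshold, k = k,
                 min_datasets = min_datasets, block_size_m = block_size_m,
                 pa_cutoff_year = if (is.null(pa_cutoff_year)) starts[1]
                 else pa_cutoff_year,
                 affected_dataset = affected_dataset),
            class = "run_config")
}

#' Run the full conversion-accounting pipeline
#'
#' Executes every enabled stage and writes a deterministic directory of
#' outputs: per-dataset/period transition rasters (`transitions/`), area
#' tables and grid summaries (`tables/`), hotspot cell/country tables,
#' PA-category proportions and inside/outside rate tables, biodiversity
#' summaries, the resolved configuration (`config.yml` for synthetic
#' scenarios), and `run_report.json` reconciling cell counts (valid +
#' nodata = total per dataset and period) and recording excluded PAs and
#' species.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results bundle.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "transitions"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "tables"), showWarnings = FALSE)

  # --- assemble harmonized epochs per dataset --------------------------
  if (config$mode == "synthetic") {
    scn <- config$scenario
    n_epochs <- length(config$periods) + 1L
    land <- generate_landscape(scn, n_epochs = n_epochs)
    layers <- generate_conservation_layers(scn, land)
    ranges <- generate_species_ranges(scn, land)
    styles <- if (length(scn$dataset_styles)) scn$dataset_styles
      else "synthetic"
    epochs_by_ds <- lapply(styles, function(ds)
      lapply(land$epochs, tag_dataset, dataset_id = ds))
    names(epochs_by_ds) <- styles
    zones <- layers$zones
    pas <- layers$pas
    kbas <- layers$kbas
    write_scenario_yaml(scn, file.path(out_dir, "config.yml"))
  } else {
    epochs_by_ds <- lapply(config$dataset_files, function(paths) {
      eps <- lapply(paths, read_ascii_grid)
      lapply(eps, function(e) {
        if (!e$harmonized) harmonize(e, builtin_table(e$dataset_id)) else e
      })
    })
    zones <- NULL; pas <- NULL; kbas <- NULL; ranges <- NULL
  }
  ds_ids <- names(epochs_by_ds)
  first <- epochs_by_ds[[1]][[1]]
  if (is.null(zones))
    zones <- zone_layer(matrix(1L, nrow(first$values), ncol(first$values)),
                        "global")
  block_size <- if (is.null(config$block_size_m))
    10L * round(first$cell_size) else config$block_size_m

  # --- transitions, areas, grid fractions ------------------------------
  report <- list(datasets = ds_ids,
                 periods = vapply(config$periods, period_label,
                                  character(1)),
                 cell_ledger = list())
  trs <- list(); area_tables <- list(); grid_sums <- list()
  for (ds in ds_ids) {
    eps <- epochs_by_ds[[ds]]
    trs[[ds]] <- list(); area_tables[[ds]] <- list()
    grid_sums[[ds]] <- list()
    for (p in seq_along(config$periods)) {
      tr <- detect_transitions(eps[[p]], eps[[p + 1]])
      pl <- period_label(tr$period)
      trs[[ds]][[pl]] <- tr
      write_ascii_grid(tr, file.path(out_dir, "transitions",
                                     sprintf("%s_%s.asc", ds, pl)))
      at <- aggregate_by_zone(tr, zones)
      area_tables[[ds]][[pl]] <- at
      write_output_csv(at, file.path(out_dir, "tables",
                                     sprintf("areas_%s_%s.csv", ds, pl)))
      gs <- grid_fraction(tr, block_size)
      grid_sums[[ds]][[pl]] <- gs
      write_output_csv(gs, file.path(out_dir, "tables",
                                     sprintf("grid_%s_%s.csv", ds, pl)))
      n_total <- length(tr$values)
      n_valid <- sum(!is.na(tr$values))
      report$cell_ledger[[paste(ds, pl, sep = "_")]] <-
        list(total_cells = n_total, valid_cells = n_valid,
             nodata_cells = n_total - n_valid)
    }
    combined <- sum_periods(area_tables[[ds]])
    area_tables[[ds]][["combined"]] <- combined
    write_output_csv(combined, file.path(out_dir, "tables",
                                         sprintf("areas_%s_combined.csv",
                                                 ds)))
  }

  results <- list(config = config, transitions = trs,
                  area_tables = area_tables, grid_summaries = grid_sums,
                  zones = zones, pas = pas, kbas = kbas, ranges = ranges)

  # combined (all-period) grid summaries per dataset, for hotspot cells
  combined_grid <- lapply(ds_ids, function(ds) {
    gs <- grid_sums[[ds]]
    base <- gs[[1]]
    base$area_converted_ha <- Reduce(`+`, lapply(gs, function(g)
      g$area_converted_ha[match(base$grid_cell_id, g$grid_cell_id)]))
    frac <- Reduce(`+`, lapply(gs, function(g)
      (g$fraction_converted * g$valid_cells)[
        match(base$grid_cell_id, g$grid_cell_id)]))
    base$fraction_converted <- pmin(1, frac / base$valid_cells)
    base$period <- "combined"
    base
  })
  names(combined_grid) <- ds_ids

  # whole-span (earliest-code-wins) transition raster per dataset, used by
  # the PA, biodiversity and KBA stages
  span_trs <- lapply(trs, combine_transitions)

  # --- hotspots ---------------------------------------------------------
  if ("hotspots" %in% config$analyses) {
    hs_cells <- hotspot_cells(combined_grid, threshold = config$threshold)
    write_output_csv(hs_cells$cells,
                     file.path(out_dir, "tables", "hotspot_cells.csv"))
    combined_tabs <- lapply(ds_ids, function(ds)
      area_tables[[ds]][["combined"]])
    hs_countries <- hotspot_countries(combined_tabs, k = config$k,
                                      min_datasets = config$min_datasets)
    write_output_csv(hs_countries,
                     file.path(out_dir, "tables", "hotspot_countries.csv"))
    results$hotspot_cells <- hs_cells
    results$hotspot_countries <- hs_countries
  }

  # --- protected areas --------------------------------------------------
  if ("pa" %in% config$analyses && !is.null(pas)) {
    pas_f <- filter_by_year(pas, config$pa_cutoff_year)
    report$pas_excluded_unknown_year <- attr(pas_f, "n_unknown_year")
    report$pas_excluded_marine <- attr(pas_f, "n_marine_dropped")
    pa_props <- list(); rate_tabs <- list()
    for (ds in ds_ids) {
      span_tr <- span_trs[[ds]]
      pc <- pa_conversion(span_tr, pas_f)
      pc$proportions$dataset_id <- ds
      pa_props[[ds]] <- pc$proportions
      rt <- conversion_rates(span_tr, epochs_by_ds[[ds]][[1]], pas_f,
                             zones)
      rate_tabs[[ds]] <- rt
    }
    write_output_csv(do.call(rbind, pa_props),
                     file.path(out_dir, "tables", "pa_proportions.csv"))
    write_output_csv(do.call(rbind, rate_tabs),
                     file.path(out_dir, "tables", "pa_rates.csv"))
    results$pa_proportions <- pa_props
    results$pa_rates <- rate_tabs
  }

  # --- biodiversity -----------------------------------------------------
  if (("biodiversity" %in% config$analyses) && !is.null(ranges)) {
    cons <- consensus_cells(lapply(combined_grid, identity))
    aff_ds <- if (is.null(config$affected_dataset)) ds_ids[1]
      else config$affected_dataset
    rich <- richness(ranges, span_trs[[aff_ds]], block_size,
                     restrict = cons)
    write_output_csv(rich, file.path(out_dir, "tables", "richness.csv"))
    aff <- affected_species(span_trs[[aff_ds]], ranges)
    write_output_csv(aff$by_taxon,
                     file.path(out_dir, "tables",
                               "affected_by_taxon.csv"))
    write_output_csv(aff$by_affinity,
                     file.path(out_dir, "tables",
                               "affected_by_affinity.csv"))
    report$species_input <- length(ranges)
    report$species_threatened <- sum(ranges$table$red_list %in%
                                       c("VU", "EN", "CR"))
    results$consensus_cells <- cons
    results$richness <- rich
    results$affected <- aff
  }

  if ("kba" %in% config$analyses && !is.null(kbas) && !is.null(pas)) {
    pas_f <- filter_by_year(pas, config$pa_cutoff_year)
    kba_tabs <- lapply(ds_ids, function(ds)
      kba_conversion(span_trs[[ds]], kbas, pas_f, zones))
    kba_tab <- do.call(rbind, kba_tabs)
    write_output_csv(kba_tab,
                     file.path(out_dir, "tables", "kba_conversion.csv"))
    results$kba <- kba_tab
  }

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$report <- report
  invisible(results)
}

#' Simulate a scenario to disk
#'
#' Generates the landscape, conservation layers and species ranges for a
#' scenario and writes them as ASCII grids, GeoJSON, and CSV/JSON ground
#' truth.
#'
#' @param scenario A [synthetic_scenario()].
#' @param out_dir Output directory.
#' @return Invisibly, the generated objects.
#' @export
simulate_scenario <- function(scenario, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  land <- generate_landscape(scenario,
                             n_epochs = length(scenario$epoch_years))
  layers <- generate_conservation_layers(scenario, land)
  ranges <- generate_species_ranges(scenario, land)
  for (i in seq_along(land$epochs))
    write_ascii_grid(land$epochs[[i]],
                     file.path(out_dir, sprintf("epoch_%d.asc",
                                                land$epochs[[i]]$year)))
  write_geojson(layers$pas, file.path(out_dir, "pas.geojson"))
  write_geojson(layers$kbas, file.path(out_dir, "kbas.geojson"))
  write_geojson(ranges, file.path(out_dir, "species_ranges.geojson"))
  truth <- do.call(rbind, lapply(seq_along(land$transition_counts),
    function(s) {
      m <- land$transition_counts[[s]]
      data.frame(step = s, from = rep(rownames(m), ncol(m)),
                 to = rep(colnames(m), each = nrow(m)),
                 cells = as.integer(m), stringsAsFactors = FALSE)
    }))
  write_output_csv(truth, file.path(out_dir, "ground_truth.csv"))
  write_scenario_yaml(scenario, file.path(out_dir, "scenario.yml"))
  invisible(list(landscape = land, layers = layers, ranges = ranges))
}
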