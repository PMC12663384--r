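# Synthetic landscape generator. Emulates the statistical structure the
# analysis assumes — patchy categorical land cover at two (or more) epochs
# linked by per-cell transition probabilities, protected-area / KBA / zone
# polygons, and species ranges with habitat affinities — with known ground
# truth, so every downstream stage can be tested without the multi-gigabyte
# global products.

#' Define a synthetic landscape scenario
#'
#' All randomness downstream flows from `seed` via named per-module
#' substreams, so a scenario is a complete, reproducible description of one
#' simulated study region.
#'
#' Default study conditions: a 200 x 200 grid of 100 m equal-area cells;
#' land cover split 25% cultivated, 35% grassland & shrubland, 5%
#' non-forested wetland, 25% forest, 10% other; per-decade conversion
#' probabilities to cultivated land of 0.10 (grassland & shrubland), 0.05
#' (non-forested wetland) and 0.08 (forest), with 0.02 reversion from
#' cultivated land to grassland & shrubland.
#'
#' @param grid_shape Integer `(rows, cols)`.
#' @param cell_size Cell side in metres (local equal-area grid).
#' @param class_proportions Named vector over [harmonized_classes()] names
#'   summing to 1: fraction of valid land in each class at the first epoch.
#' @param transition_matrix Square matrix, dimnames = class names, row
#'   sums 1: per-epoch-step probability a cell of the row class becomes the
#'   column class.
#' @param autocorrelation_range Patch smoothing scale, in cells (Gaussian
#'   kernel standard deviation); 0 gives spatially independent cells.
#' @param nodata_fraction Fraction of cells masked as nodata.
#' @param n_pas,n_kbas,n_species,n_zones Feature counts for the
#'   conservation and species layers.
#' @param pa_category_probs Sampling weights over IUCN categories I-VI.
#' @param pa_year_range Establishment years sampled uniformly in this range.
#' @param pa_unknown_year_prob Probability a PA has unknown establishment
#'   year.
#' @param pa_marine_prob Probability a PA is marine-flagged.
#' @param taxon_probs Sampling weights over amphibian/mammal/reptile/bird.
#' @param threatened_prob Probability a species is threatened (VU/EN/CR,
#'   split `red_list_probs`).
#' @param red_list_probs Weights over VU/EN/CR for threatened species.
#' @param habitat_size_probs Weights over habitat-affinity set sizes 1..3.
#' @param dataset_styles Dataset identifiers to emit (at most 3 of
#'   `"globeland30"`, `"glcluc"`, `"glc_fcs30d"`); co-registered copies of
#'   the one truth landscape, tagged per dataset.
#' @param epoch_years Calendar years of successive epochs.
#' @param seed Integer master seed.
#' @return A validated object of class `synthetic_scenario`.
#' @export
#' @examples
#' scn <- synthetic_scenario(grid_shape = c(60, 60), seed = 7)
#' land <- generate_landscape(scn)
#' land$epochs[[1]]
synthetic_scenario <- function(grid_shape = c(200, 200),
                               cell_size = 100,
                               class_proportions = c(
                                 CULTIVATED = 0.25, GRASS_SHRUB = 0.35,
                                 NONFOREST_WETLAND = 0.05, FOREST = 0.25,
                                 OTHER = 0.10),
                               transition_matrix = default_transition_matrix(),
                               autocorrelation_range = 3,
                               nodata_fraction = 0.02,
                               n_pas = 8, n_kbas = 5, n_species = 40,
                               n_zones = 3,
                               pa_category_probs = c(I = 0.10, II = 0.15,
                                 III = 0.05, IV = 0.25, V = 0.15, VI = 0.30),
                               pa_year_range = c(1950, 2010),
                               pa_unknown_year_prob = 0.05,
                               pa_marine_prob = 0.05,
                               taxon_probs = c(amphibian = 0.30,
                                 mammal = 0.25, reptile = 0.25, bird = 0.20),
                               threatened_prob = 0.6,
                               red_list_probs = c(VU = 0.5, EN = 0.3,
                                                  CR = 0.2),
                               habitat_size_probs = c(0.5, 0.3, 0.2),
                               dataset_styles = c("globeland30", "glcluc",
                                                  "glc_fcs30d"),
                               epoch_years = c(2000, 2010, 2020),
                               seed = 1L) {
  scn <- structure(
    list(grid_shape = as.integer(grid_shape), cell_size = cell_size,
         class_proportions = class_proportions,
         transition_matrix = transition_matrix,
         autocorrelation_range = autocorrelation_range,
         nodata_fraction = nodata_fraction,
         n_pas = n_pas, n_kbas = n_kbas, n_species = n_species,
         n_zones = n_zones,
         pa_category_probs = pa_category_probs,
         pa_year_range = pa_year_range,
         pa_unknown_year_prob = pa_unknown_year_prob,
         pa_marine_prob = pa_marine_prob,
         taxon_probs = taxon_probs, threatened_prob = threatened_prob,
         red_list_probs = red_list_probs,
         habitat_size_probs = habitat_size_probs,
         dataset_styles = dataset_styles,
         epoch_years = as.integer(epoch_years), seed = as.integer(seed)),
    class = "synthetic_scenario")
  validate_scenario(scn)
  scn
}

#' Default per-decade class transition matrix
#'
#' @return A 5 x 5 row-stochastic matrix over the harmonized class names.
#' @export
default_transition_matrix <- function() {
  cls <- names(harmonized_classes())
  tm <- diag(length(cls))
  dimnames(tm) <- list(cls, cls)
  tm["GRASS_SHRUB", "CULTIVATED"] <- 0.10
  tm["NONFOREST_WETLAND", "CULTIVATED"] <- 0.05
  tm["FOREST", "CULTIVATED"] <- 0.08
  tm["CULTIVATED", "GRASS_SHRUB"] <- 0.02
  diag(tm) <- 0
  diag(tm) <- 1 - rowSums(tm)
  tm
}

validate_scenario <- function(scn) {
  if (length(scn$grid_shape) != 2 || any(scn$grid_shape <= 0))
    stop("grid_shape must be two positive integers")
  p <- scn$class_proportions
  if (is.null(names(p)) || !all(names(p) %in% names(harmonized_classes())))
    stop("class_proportions must be named with harmonized class names")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("class_proportions must be non-negative and sum to 1")
  tm <- scn$transition_matrix
  if (!is.matrix(tm) || nrow(tm) != ncol(tm) ||
      is.null(rownames(tm)) || !identical(rownames(tm), colnames(tm)))
    stop("transition_matrix must be square with matching dimnames")
  if (!all(rownames(tm) %in% names(harmonized_classes())))
    stop("transition_matrix dimnames must be harmonized class names")
  if (any(tm < 0) || any(tm > 1))
    stop("transition probabilities must lie in [0, 1]")
  bad <- which(abs(rowSums(tm) - 1) > 1e-9)
  if (length(bad))
    stop("transition_matrix rows must sum to 1; offending row(s): ",
         paste(rownames(tm)[bad], collapse = ", "))
  if (scn$nodata_fraction < 0 || scn$nodata_fraction >= 1)
    stop("nodata_fraction must lie in [0, 1)")
  if (scn$n_zones < 2) stop("n_zones must be at least 2")
  if (length(scn$dataset_styles) > 3)
    stop("at most 3 dataset styles")
  if (length(scn$epoch_years) < 2 || is.unsorted(scn$epoch_years))
    stop("epoch_years must be at least two increasing years")
  invisible(scn)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf("<synthetic_scenario> %d x %d cells of %g m, seed %d\n",
              x$grid_shape[1], x$grid_shape[2], x$cell_size, x$seed))
  invisible(x)
}

# Named RNG substreams derived from the master seed keep the modules'
# random draws independent of one another.
module_seed <- function(seed, module) {
  offsets <- c(landscape = 101L, transitions = 211L, zones = 307L,
               pas = 401L, kbas = 503L, species = 601L)
  (seed * 1009L + offsets[[module]]) %% .Machine$integer.max
}

with_module_seed <- function(seed, module, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(module_seed(seed, module))
  expr
}

# Separable Gaussian smoothing with reflected edges.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  hw <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma)
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    p <- c(rev(v[seq_len(hw)]), v, rev(v[seq(n - hw + 1L, n)]))
    as.numeric(stats::filter(p, k, sides = 2))[seq(hw + 1L, hw + n)]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

# Autocorrelated categorical field: one smoothed Gaussian field, cells
# ranked and cut at the cumulative class proportions, so realized
# proportions are exact to within one cell while patches remain contiguous.
categorical_field <- function(nr, nc, proportions, range_cells) {
  field <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                           range_cells)
  n <- nr * nc
  counts <- diff(round(c(0, cumsum(proportions)) * n))
  codes <- harmonized_classes()[names(proportions)]
  out <- integer(n)
  out[order(field)] <- rep(codes, counts)
  matrix(out, nr, nc)
}

# Apply the transition matrix independently per cell; returns the new
# values plus the realized (from, to) count matrix over valid cells.
apply_transition_step <- function(values, tm) {
  cls <- rownames(tm)
  codes <- harmonized_classes()[cls]
  out <- values
  for (i in seq_along(cls)) {
    idx <- which(values == codes[i])
    if (!length(idx)) next
    cum <- cumsum(tm[i, ])
    u <- stats::runif(length(idx))
    j <- findInterval(u, cum[-length(cum)]) + 1L
    out[idx] <- codes[j]
  }
  counts <- matrix(0L, length(cls), length(cls), dimnames = list(cls, cls))
  valid <- !is.na(values)
  tab <- table(factor(values[valid], levels = codes),
               factor(out[valid], levels = codes))
  counts[] <- as.integer(tab)
  list(values = out, counts = counts)
}

#' Generate a multi-epoch synthetic landscape
#'
#' Draws the first epoch as a spatially autocorrelated categorical field
#' matching the scenario's class proportions (a smoothed Gaussian field cut
#' at the class-proportion quantiles), masks a nodata region, then advances
#' each subsequent epoch by applying the transition matrix independently
#' per cell. Ground-truth realized transition counts are recorded for each
#' step. Identical scenario and seed give identical output.
#'
#' @param scenario A [synthetic_scenario()].
#' @param n_epochs Number of epochs to generate (>= 2; years taken from
#'   `scenario$epoch_years`).
#' @return A list of class `synthetic_landscape` with elements `epochs`
#'   (list of harmonized [epoch_raster()]s, dataset `"synthetic"`),
#'   `transition_counts` (list of realized (from, to) count matrices, one
#'   per step), and `scenario`.
#' @export
generate_landscape <- function(scenario, n_epochs = 2) {
  validate_scenario(scenario)
  if (n_epochs < 2) stop("need at least 2 epochs")
  if (n_epochs > length(scenario$epoch_years))
    stop("scenario$epoch_years has fewer than n_epochs entries")
  nr <- scenario$grid_shape[1]; nc <- scenario$grid_shape[2]

  v0 <- with_module_seed(scenario$seed, "landscape", {
    v <- categorical_field(nr, nc, scenario$class_proportions,
                           scenario$autocorrelation_range)
    if (scenario$nodata_fraction > 0) {
      mask_field <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                                    scenario$autocorrelation_range)
      cut <- stats::quantile(mask_field, scenario$nodata_fraction)
      v[mask_field <= cut] <- NA_integer_
    }
    v
  })

  epochs <- list(epoch_raster(v0, scenario$epoch_years[1],
                              dataset_id = "synthetic",
                              cell_size = scenario$cell_size))
  counts <- list()
  vals <- v0
  with_module_seed(scenario$seed, "transitions", {
    for (step in seq_len(n_epochs - 1)) {
      stepped <- apply_transition_step(vals, scenario$transition_matrix)
      vals <- stepped$values
      counts[[step]] <- stepped$counts
      epochs[[step + 1]] <- epoch_raster(
        vals, scenario$epoch_years[step + 1], dataset_id = "synthetic",
        cell_size = scenario$cell_size)
    }
  })
  structure(list(epochs = epochs, transition_counts = counts,
                 scenario = scenario),
            class = "synthetic_landscape")
}

#' Tag a synthetic epoch raster with a dataset identity
#'
#' The emitted dataset styles are co-registered copies of the single truth
#' landscape (no classification-error emulation); only the `dataset_id`
#' differs.
#'
#' @param raster An [epoch_raster()].
#' @param dataset_id New dataset identifier.
#' @return The raster tagged with `dataset_id`.
#' @export
tag_dataset <- function(raster, dataset_id) {
  raster$dataset_id <- dataset_id
  raster
}

# Rectangle with vertices snapped off cell boundaries (offset 0.31 cells)
# so cell-center containment is unambiguous.
random_rect <- function(xmin, ymin, xmax, ymax, cs) {
  w <- stats::runif(1, 0.06, 0.22) * (xmax - xmin)
  h <- stats::runif(1, 0.06, 0.22) * (ymax - ymin)
  x0 <- stats::runif(1, xmin, xmax - w)
  y0 <- stats::runif(1, ymin, ymax - h)
  snap <- function(z) (floor(z / cs) + 0.31) * cs
  rect_ring(snap(x0), snap(y0), snap(x0 + w), snap(y0 + h))
}

rect_overlap_frac <- function(a, b) {
  ix <- max(0, min(a[2, 1], b[2, 1]) - max(a[1, 1], b[1, 1]))
  iy <- max(0, min(a[3, 2], b[3, 2]) - max(a[1, 2], b[1, 2]))
  area_a <- (a[2, 1] - a[1, 1]) * (a[3, 2] - a[1, 2])
  if (area_a <= 0) return(0)
  ix * iy / area_a
}

#' Generate synthetic conservation layers (PAs, KBAs, zones)
#'
#' Protected areas are rectangles with IUCN category I-VI, establishment
#' year (some unknown) and a marine flag; placement rejects candidates
#' overlapping an existing PA by more than 50% (after repeated rejection a
#' warning is issued and fewer polygons are emitted). KBAs are convex
#' blobs. Zones partition the full extent into `n_zones` vertical strips of
#' seeded random widths. Per-PA ground-truth converted-cell counts (first
#' epoch step, all natural-to-cultivated codes) are recorded in the PA
#' attribute table.
#'
#' @param scenario The [synthetic_scenario()] used for the landscape.
#' @param landscape The matching [generate_landscape()] result.
#' @return List with elements `pas` and `kbas` ([polygon_layer()]s) and
#'   `zones` (a [zone_layer()]).
#' @export
generate_conservation_layers <- function(scenario, landscape) {
  r <- landscape$epochs[[1]]
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  xmax <- r$xmin + nc * cs; ymax <- r$ymin + nr * cs

  zones <- with_module_seed(scenario$seed, "zones", {
    w <- stats::runif(scenario$n_zones, 0.6, 1.4)
    breaks <- round(cumsum(w) / sum(w) * nc)
    breaks <- unique(pmin(pmax(breaks, 1), nc))
    if (length(breaks) < scenario$n_zones)
      breaks <- unique(c(seq_len(scenario$n_zones - 1), nc))
    zone_of_col <- findInterval(seq_len(nc) - 1L, c(0, breaks[-length(breaks)]))
    labels <- matrix(rep(zone_of_col, each = nr), nr, nc)
    zone_layer(labels, sprintf("Z%02d", seq_len(max(zone_of_col))))
  })

  conv_mask <- NULL
  if (length(landscape$epochs) >= 2) {
    tr <- detect_transitions(landscape$epochs[[1]], landscape$epochs[[2]])
    conv_mask <- !is.na(tr$values) & tr$values %in% conversion_codes()
  }

  pas <- with_module_seed(scenario$seed, "pas", {
    rings <- list(); tries <- 0L
    while (length(rings) < scenario$n_pas && tries < scenario$n_pas * 40L) {
      tries <- tries + 1L
      cand <- random_rect(r$xmin, r$ymin, xmax, ymax, cs)
      frac <- if (length(rings))
        max(vapply(rings, rect_overlap_frac, numeric(1), b = cand)) else 0
      if (frac <= 0.5) rings[[length(rings) + 1L]] <- cand
    }
    if (length(rings) < scenario$n_pas)
      warning(sprintf("placed %d of %d PAs without >50%% overlap",
                      length(rings), scenario$n_pas))
    n <- length(rings)
    cat_lv <- iucn_categories()
    categories <- sample(cat_lv, n, replace = TRUE,
                         prob = scenario$pa_category_probs[cat_lv])
    years <- sample(seq(scenario$pa_year_range[1], scenario$pa_year_range[2]),
                    n, replace = TRUE)
    years[stats::runif(n) < scenario$pa_unknown_year_prob] <- NA_integer_
    marine <- stats::runif(n) < scenario$pa_marine_prob
    tab <- data.frame(pa_id = sprintf("PA%03d", seq_len(n)),
                      iucn_category = categories,
                      establishment_year = years,
                      designation = rep_len("synthetic reserve", n),
                      marine = marine,
                      stringsAsFactors = FALSE)
    if (!is.null(conv_mask)) {
      tab$converted_cells_truth <- vapply(rings, function(g)
        sum(polygon_cell_mask(r, g) & conv_mask), integer(1))
    }
    polygon_layer(tab, rings, "pa")
  })

  kbas <- with_module_seed(scenario$seed, "kbas", {
    n <- scenario$n_kbas
    rings <- lapply(seq_len(n), function(i) {
      cx <- stats::runif(1, r$xmin + 0.1 * (xmax - r$xmin),
                         xmax - 0.1 * (xmax - r$xmin))
      cy <- stats::runif(1, r$ymin + 0.1 * (ymax - r$ymin),
                         ymax - 0.1 * (ymax - r$ymin))
      convex_blob(cx, cy, stats::runif(1, 0.05, 0.15) * (xmax - r$xmin))
    })
    tab <- data.frame(kba_id = sprintf("KBA%03d", seq_len(n)),
                      name = sprintf("Synthetic KBA %d", seq_len(n)),
                      stringsAsFactors = FALSE)
    polygon_layer(tab, rings, "kba")
  })

  list(pas = pas, kbas = kbas, zones = zones)
}

#' Generate synthetic species ranges
#'
#' Each species gets a taxon (amphibian/mammal/reptile/bird), a Red List
#' category (threatened VU/EN/CR with probability `threatened_prob`, else
#' `"other"`), a non-empty habitat-affinity set drawn from the three
#' natural classes, and a convex range polygon. A ground-truth `affected`
#' flag records whether the range overlaps any converted cell of the first
#' epoch step (cell-center containment, all natural-to-cultivated codes).
#'
#' @param scenario The [synthetic_scenario()].
#' @param landscape The matching [generate_landscape()] result.
#' @return A [polygon_layer()] of ranges with attributes `species_id`,
#'   `taxon`, `red_list`, `habitats` (`+`-separated class names) and
#'   `affected_truth`.
#' @export
generate_species_ranges <- function(scenario, landscape) {
  r <- landscape$epochs[[1]]
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  xmax <- r$xmin + nc * cs; ymax <- r$ymin + nr * cs
  conv_mask <- NULL
  if (length(landscape$epochs) >= 2) {
    tr <- detect_transitions(landscape$epochs[[1]], landscape$epochs[[2]])
    conv_mask <- !is.na(tr$values) & tr$values %in% conversion_codes()
  }
  with_module_seed(scenario$seed, "species", {
    n <- scenario$n_species
    taxa <- sample(names(scenario$taxon_probs), n, replace = TRUE,
                   prob = scenario$taxon_probs)
    threatened <- stats::runif(n) < scenario$threatened_prob
    red <- ifelse(threatened,
                  sample(names(scenario$red_list_probs), n, replace = TRUE,
                         prob = scenario$red_list_probs),
                  "other")
    nat <- names(natural_classes())
    habitats <- vapply(seq_len(n), function(i) {
      k <- sample(1:3, 1, prob = scenario$habitat_size_probs)
      paste(sort(sample(nat, k)), collapse = "+")
    }, character(1))
    rings <- lapply(seq_len(n), function(i) {
      cx <- stats::runif(1, r$xmin, xmax)
      cy <- stats::runif(1, r$ymin, ymax)
      convex_blob(cx, cy, stats::runif(1, 0.08, 0.35) * (xmax - r$xmin),
                  n_points = 10)
    })
    tab <- data.frame(species_id = sprintf("SP%04d", seq_len(n)),
                      taxon = taxa, red_list = red, habitats = habitats,
                      stringsAsFactors = FALSE)
    if (!is.null(conv_mask)) {
      tab$affected_truth <- vapply(rings, function(g)
        any(polygon_cell_mask(r, g) & conv_mask), logical(1))
    }
    polygon_layer(tab, rings, "species_range")
  })
}
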