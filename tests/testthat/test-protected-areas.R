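# Protected-area overlay: year filter, category attribution, proportions,
# inside/outside rates.

make_pa <- function(rings, categories, years = 1990,
                    marine = FALSE) {
  n <- length(rings)
  polygon_layer(
    data.frame(pa_id = sprintf("PA%02d", seq_len(n)),
               iucn_category = rep_len(categories, n),
               establishment_year = rep_len(years, n),
               designation = rep_len("test", n),
               marine = rep_len(marine, n),
               stringsAsFactors = FALSE),
    rings, "pa")
}

test_that("year filter uses strict inequality and reports exclusions", {
  rings <- replicate(4, rect_ring(10.3, 10.3, 200.3, 200.3),
                     simplify = FALSE)
  pas <- make_pa(rings, "II", years = c(1990, 1999, 2000, 2015))
  kept <- filter_by_year(pas, 2000)
  expect_equal(length(kept), 2)
  expect_true(all(kept$table$establishment_year < 2000))
  # unknown years are excluded and counted; marine PAs dropped
  pas2 <- make_pa(rings, "II", years = c(1990, NA, 1995, 1990),
                  marine = c(FALSE, FALSE, TRUE, FALSE))
  kept2 <- filter_by_year(pas2, 2000)
  expect_equal(length(kept2), 2)
  expect_equal(attr(kept2, "n_unknown_year"), 1)
  expect_equal(attr(kept2, "n_marine_dropped"), 1)
  expect_equal(length(filter_by_year(make_pa(list(), character(0)), 2000)),
               0)
})

test_that("single-PA conversion concentrates the proportion vector", {
  fx <- fixture_pair()
  tr <- detect_transitions(fx$t0, fx$t1)
  # one category-II PA covering the whole grid
  pa <- make_pa(list(rect_ring(-10, -10, 700, 700)), "II")
  pc <- pa_conversion(tr, pa)
  for (cls in unique(pc$proportions$land_class)) {
    p <- pc$proportions[pc$proportions$land_class == cls, ]
    expect_equal(p$proportion[p$iucn_category == "II"], 1, info = cls)
    expect_equal(sum(p$proportion), 1, info = cls)
  }
  # no PA overlap: all-zero table
  pa_far <- make_pa(list(rect_ring(5000, 5000, 6000, 6000)), "III")
  pc0 <- pa_conversion(tr, pa_far)
  expect_true(all(pc0$areas$converted_area_ha == 0))
})

test_that("PA areas match the exhaustive cell-in-polygon oracle", {
  scn <- synthetic_scenario(grid_shape = c(40, 40), seed = 77, n_pas = 5,
                            pa_unknown_year_prob = 0, pa_marine_prob = 0)
  land <- generate_landscape(scn)
  layers <- generate_conservation_layers(scn, land)
  tr <- detect_transitions(land$epochs[[1]], land$epochs[[2]])
  pas <- layers$pas
  pc <- pa_conversion(tr, pas)
  area1 <- cell_areas(tr)[1, 1]
  lc <- c(CONV_GRASS = "GRASS_SHRUB", CONV_WETLAND = "NONFOREST_WETLAND",
          CONV_FOREST = "FOREST")
  # oracle: per cell, find strictest containing PA by looping polygons
  cat_idx <- match(pas$table$iucn_category, iucn_categories())
  for (code_name in names(lc)) {
    code <- tc[[code_name]]
    oracle_area <- stats::setNames(numeric(6), iucn_categories())
    masks <- lapply(pas$geometry, oracle_polygon_cells,
                    r = land$epochs[[1]])
    for (i in seq_len(40)) for (j in seq_len(40)) {
      v <- tr$values[i, j]
      if (is.na(v) || v != code) next
      containing <- which(vapply(masks, function(m) m[i, j], logical(1)))
      if (!length(containing)) next
      strict <- min(cat_idx[containing])
      cat_name <- iucn_categories()[strict]
      oracle_area[cat_name] <- oracle_area[cat_name] + area1
    }
    got <- pc$areas[pc$areas$land_class == lc[[code_name]], ]
    expect_equal(stats::setNames(got$converted_area_ha,
                                 got$iucn_category),
                 oracle_area, info = code_name)
  }
})

test_that("rates are converted/baseline with OUTSIDE as the PA complement", {
  # 20x20 grass grid; left half converts; PA covers left 10 columns
  v0 <- matrix(hc[["GRASS_SHRUB"]], 20, 20)
  v1 <- v0
  v1[, 1:2] <- hc[["CULTIVATED"]]
  t0 <- make_epoch(v0, 2000); t1 <- make_epoch(v1, 2010)
  tr <- detect_transitions(t0, t1)
  pa <- make_pa(list(rect_ring(0.3, 0.3, 1000.3, 2000.3)), "IV")
  rt <- conversion_rates(tr, t0, pa)
  inside <- rt[rt$category == "IV" & rt$land_class == "GRASS_SHRUB", ]
  outside <- rt[rt$category == "OUTSIDE" &
                  rt$land_class == "GRASS_SHRUB", ]
  # PA holds 10x20 = 200 grass cells of which 2 columns (40) convert
  expect_equal(inside$baseline_area_ha, 200)
  expect_equal(inside$converted_area_ha, 40)
  expect_equal(inside$rate, 0.2)
  expect_equal(outside$baseline_area_ha, 200)
  expect_equal(outside$rate, 0)
  # zero-baseline categories are NA-flagged, all defined rates in [0,1]
  expect_true(all(is.na(rt$rate[rt$baseline_area_ha == 0])))
  ok <- !is.na(rt$rate)
  expect_true(all(rt$rate[ok] >= 0 & rt$rate[ok] <= 1))
  # decomposition: inside (all categories) + outside = total conversion
  conv_total <- sum(cell_areas(tr)[!is.na(tr$values) &
                                     tr$values == tc[["CONV_GRASS"]]])
  expect_equal(sum(rt$converted_area_ha[rt$land_class == "GRASS_SHRUB"]),
               conv_total)
})

test_that("overlapping PAs resolve to the strictest category", {
  v0 <- matrix(hc[["GRASS_SHRUB"]], 10, 10)
  v1 <- matrix(hc[["CULTIVATED"]], 10, 10)
  tr <- detect_transitions(make_epoch(v0, 2000), make_epoch(v1, 2010))
  # category V covers everything, category II covers the west half
  pas <- make_pa(list(rect_ring(-1, -1, 1001, 1001),
                      rect_ring(-1, -1, 500.3, 1001)), c("V", "II"))
  pc <- pa_conversion(tr, pas)
  grass <- pc$areas[pc$areas$land_class == "GRASS_SHRUB", ]
  expect_equal(grass$converted_area_ha[grass$iucn_category == "II"],
               50 * 1.0)
  expect_equal(grass$converted_area_ha[grass$iucn_category == "V"],
               50 * 1.0)
  # order of features must not matter
  pc2 <- pa_conversion(tr, make_pa(list(rect_ring(-1, -1, 500.3, 1001),
                                        rect_ring(-1, -1, 1001, 1001)),
                                   c("II", "V")))
  expect_equal(pc2$areas, pc$areas)
})

test_that("rates match a vector-overlay oracle on a small instance", {
  scn <- synthetic_scenario(grid_shape = c(30, 30), seed = 88, n_pas = 3,
                            pa_unknown_year_prob = 0, pa_marine_prob = 0)
  land <- generate_landscape(scn)
  layers <- generate_conservation_layers(scn, land)
  t0 <- land$epochs[[1]]
  tr <- detect_transitions(t0, land$epochs[[2]])
  pas <- layers$pas
  rt <- conversion_rates(tr, t0, pas)
  cat_idx <- match(pas$table$iucn_category, iucn_categories())
  masks <- lapply(pas$geometry, oracle_polygon_cells, r = t0)
  a1 <- cell_areas(tr)[1, 1]
  for (cat in c(iucn_categories(), "OUTSIDE")) {
    num <- 0; den <- 0
    for (i in 1:30) for (j in 1:30) {
      if (is.na(tr$values[i, j]) || is.na(t0$values[i, j])) next
      if (t0$values[i, j] != hc[["GRASS_SHRUB"]]) next
      containing <- which(vapply(masks, function(m) m[i, j], logical(1)))
      cell_cat <- if (!length(containing)) "OUTSIDE"
        else iucn_categories()[min(cat_idx[containing])]
      if (cell_cat != cat) next
      den <- den + a1
      if (tr$values[i, j] == tc[["CONV_GRASS"]]) num <- num + a1
    }
    row <- rt[rt$category == cat & rt$land_class == "GRASS_SHRUB", ]
    expect_equal(row$converted_area_ha, num, info = cat)
    expect_equal(row$baseline_area_ha, den, info = cat)
  }
})
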