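# Synthetic landscape generator: determinism, proportion/transition
# recovery, and ground truth consistency.

test_that("scenario validation rejects malformed probability inputs", {
  expect_error(synthetic_scenario(class_proportions = c(CULTIVATED = 0.5,
                                                        FOREST = 0.4)),
               "sum to 1")
  tm <- default_transition_matrix()
  tm["GRASS_SHRUB", "CULTIVATED"] <- 0.5  # row no longer sums to 1
  expect_error(synthetic_scenario(transition_matrix = tm), "GRASS_SHRUB")
  tm2 <- default_transition_matrix()
  tm2["FOREST", "CULTIVATED"] <- -0.1
  expect_error(synthetic_scenario(transition_matrix = tm2), "\\[0, 1\\]")
  expect_error(synthetic_scenario(grid_shape = c(0, 10)), "positive")
})

test_that("identical scenario and seed give identical outputs", {
  scn <- synthetic_scenario(grid_shape = c(50, 50), seed = 11,
                            n_species = 10)
  a <- generate_landscape(scn)
  b <- generate_landscape(scn)
  expect_identical(a$epochs[[1]]$values, b$epochs[[1]]$values)
  expect_identical(a$epochs[[2]]$values, b$epochs[[2]]$values)
  expect_identical(a$transition_counts, b$transition_counts)
  la <- generate_conservation_layers(scn, a)
  lb <- generate_conservation_layers(scn, b)
  expect_identical(la$pas$table, lb$pas$table)
  expect_identical(la$pas$geometry, lb$pas$geometry)
  expect_identical(generate_species_ranges(scn, a)$table,
                   generate_species_ranges(scn, b)$table)
  # a different seed actually changes the landscape
  c <- generate_landscape(synthetic_scenario(grid_shape = c(50, 50),
                                             seed = 12, n_species = 10))
  expect_false(identical(a$epochs[[1]]$values, c$epochs[[1]]$values))
})

test_that("identity transition matrix leaves the landscape unchanged", {
  cls <- names(harmonized_classes())
  tm <- diag(length(cls)); dimnames(tm) <- list(cls, cls)
  scn <- synthetic_scenario(grid_shape = c(40, 40), seed = 5,
                            transition_matrix = tm)
  land <- generate_landscape(scn)
  expect_identical(land$epochs[[1]]$values, land$epochs[[2]]$values)
  off_diag <- land$transition_counts[[1]]
  diag(off_diag) <- 0L
  expect_true(all(off_diag == 0))
})

test_that("realized class proportions and transition rates match the scenario", {
  scn <- synthetic_scenario(grid_shape = c(200, 200), seed = 9,
                            nodata_fraction = 0)
  land <- generate_landscape(scn)
  v0 <- land$epochs[[1]]$values
  n <- length(v0)
  for (cls in names(scn$class_proportions)) {
    frac <- sum(v0 == harmonized_classes()[cls]) / n
    expect_equal(frac, scn$class_proportions[[cls]], tolerance = 1e-3,
                 info = cls)
  }
  # realized grass-to-cultivated fraction within 3 binomial SE of 0.10
  counts <- land$transition_counts[[1]]
  n_grass <- sum(counts["GRASS_SHRUB", ])
  p_hat <- counts["GRASS_SHRUB", "CULTIVATED"] / n_grass
  se <- sqrt(0.10 * 0.90 / n_grass)
  expect_lt(abs(p_hat - 0.10), 3 * se)
})

test_that("ground-truth transition counts equal a direct cell comparison", {
  scn <- synthetic_scenario(grid_shape = c(60, 60), seed = 21)
  land <- generate_landscape(scn)
  v0 <- land$epochs[[1]]$values; v1 <- land$epochs[[2]]$values
  counts <- land$transition_counts[[1]]
  cls <- rownames(counts)
  for (a in cls) for (b in cls) {
    direct <- sum(v0 == harmonized_classes()[a] &
                    v1 == harmonized_classes()[b], na.rm = TRUE)
    expect_identical(counts[a, b], direct, info = paste(a, "->", b))
  }
  expect_identical(sum(counts), sum(!is.na(v0)))
})

test_that("conservation layers respect counts, years and zone partition", {
  scn <- synthetic_scenario(grid_shape = c(80, 80), seed = 31, n_pas = 6,
                            n_kbas = 4, pa_unknown_year_prob = 0,
                            pa_marine_prob = 0)
  land <- generate_landscape(scn)
  layers <- generate_conservation_layers(scn, land)
  expect_lte(length(layers$pas), 6)
  expect_equal(length(layers$kbas), 4)
  expect_true(all(layers$pas$table$iucn_category %in% iucn_categories()))
  # zones partition every cell of the extent
  expect_false(anyNA(layers$zones$labels))
  expect_gte(length(layers$zones$zone_ids), 2)
  tr <- detect_transitions(land$epochs[[1]], land$epochs[[2]])
  at <- aggregate_by_zone(tr, layers$zones)
  total <- sum(cell_areas(tr)[!is.na(tr$values)])
  expect_equal(sum(at$area_ha), total)

  # forced establishment years drive the cutoff filter exactly
  layers$pas$table$establishment_year <-
    rep(c(1990L, 2015L), length.out = length(layers$pas))
  n_old <- sum(layers$pas$table$establishment_year < 2000)
  expect_equal(length(filter_by_year(layers$pas, 2000)), n_old)
})

test_that("zero PAs give an empty layer and all-zero PA tables", {
  scn <- synthetic_scenario(grid_shape = c(40, 40), seed = 41, n_pas = 0)
  land <- generate_landscape(scn)
  layers <- generate_conservation_layers(scn, land)
  expect_equal(length(layers$pas), 0)
  tr <- detect_transitions(land$epochs[[1]], land$epochs[[2]])
  pc <- pa_conversion(tr, layers$pas)
  expect_true(all(pc$areas$converted_area_ha == 0))
})

test_that("species attributes are well-formed and truth flags match brute force", {
  scn <- synthetic_scenario(grid_shape = c(50, 50), seed = 51,
                            n_species = 20)
  land <- generate_landscape(scn)
  rng <- generate_species_ranges(scn, land)
  expect_equal(length(rng), 20)
  expect_true(all(rng$table$taxon %in% c("amphibian", "mammal", "reptile",
                                         "bird")))
  expect_true(all(rng$table$red_list %in% c("VU", "EN", "CR", "other")))
  habs <- strsplit(rng$table$habitats, "+", fixed = TRUE)
  expect_true(all(lengths(habs) >= 1))
  expect_true(all(unlist(habs) %in% names(natural_classes())))

  # exhaustive cell-in-polygon oracle for the affected-truth flag
  tr <- detect_transitions(land$epochs[[1]], land$epochs[[2]])
  conv <- !is.na(tr$values) & tr$values %in% conversion_codes()
  for (i in seq_len(length(rng))) {
    hits <- oracle_polygon_cells(land$epochs[[1]], rng$geometry[[i]])
    expect_identical(rng$table$affected_truth[i], any(hits & conv),
                     info = rng$table$species_id[i])
  }
})
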