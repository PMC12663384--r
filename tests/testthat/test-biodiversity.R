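# Biodiversity impact summaries: consensus cells, richness, affected
# species, KBA/PA comparison.

make_species <- function(rings, red_list = "VU", taxon = "mammal",
                         habitats = "GRASS_SHRUB") {
  n <- length(rings)
  polygon_layer(
    data.frame(species_id = sprintf("SP%03d", seq_len(n)),
               taxon = rep_len(taxon, n), red_list = rep_len(red_list, n),
               habitats = rep_len(habitats, n), stringsAsFactors = FALSE),
    rings, "species_range")
}

grid_row <- function(ids, fracs, ds) {
  data.frame(grid_cell_id = ids, block_row = 1L, block_col = ids,
             dataset_id = ds, period = "2000-2010", valid_cells = 100L,
             fraction_converted = fracs,
             area_converted_ha = fracs * 100, stringsAsFactors = FALSE)
}

test_that("consensus requires conversion in every dataset", {
  g1 <- grid_row(1:4, c(0.2, 0.0, 0.1, 0.3), "d1")
  g2 <- grid_row(1:4, c(0.1, 0.2, 0.0, 0.3), "d2")
  g3 <- grid_row(1:4, c(0.3, 0.2, 0.1, 0.0), "d3")
  expect_equal(consensus_cells(list(g1, g2, g3)), 1L)
  # cell 4 converts in two of three datasets only -> excluded
  expect_false(4L %in% consensus_cells(list(g1, g2, g3)))
  # single dataset degenerates to its nonzero cells
  expect_equal(consensus_cells(list(g1)), c(1L, 3L, 4L))
  # brute-force conjunction oracle
  ids <- 1:4
  oracle <- ids[vapply(ids, function(i)
    all(c(g1$fraction_converted[i], g2$fraction_converted[i],
          g3$fraction_converted[i]) > 0), logical(1))]
  expect_equal(consensus_cells(list(g1, g2, g3)), oracle)
})

test_that("richness counts distinct threatened species per coarse cell", {
  r <- uniform_epoch(20, 20)  # 2000 m x 2000 m extent, 100 m cells
  # two overlapping ranges over the south-west coarse block, one
  # non-threatened range, one range elsewhere
  rings <- list(rect_ring(50.3, 50.3, 700.3, 700.3),
                rect_ring(100.3, 100.3, 600.3, 600.3),
                rect_ring(50.3, 50.3, 700.3, 700.3),
                rect_ring(1200.3, 1200.3, 1900.3, 1900.3))
  sp <- make_species(rings, red_list = c("VU", "EN", "other", "CR"))
  rich <- richness(sp, r, 1000)
  sw <- rich[rich$block_row == 2 & rich$block_col == 1, ]
  expect_equal(sw$species_count, 2L)  # the non-threatened one is excluded
  ne <- rich[rich$block_row == 1 & rich$block_col == 2, ]
  expect_equal(ne$species_count, 1L)
  # restriction drops blocks outside the consensus set, monotonically
  rich_r <- richness(sp, r, 1000, restrict = sw$grid_cell_id)
  expect_equal(nrow(rich_r), 1)
  expect_lte(rich_r$species_count, sw$species_count)
  # brute-force oracle on the full grid
  bi <- landconvert:::block_index(r, 10L)
  id_mat <- matrix(bi$id, nrow(r$values), ncol(r$values))
  masks <- lapply(sp$geometry, oracle_polygon_cells, r = r)
  threatened <- which(sp$table$red_list %in% c("VU", "EN", "CR"))
  for (b in seq_len(nrow(rich))) {
    in_block <- id_mat == rich$grid_cell_id[b]
    cnt <- sum(vapply(threatened, function(s)
      any(masks[[s]] & in_block), logical(1)))
    expect_equal(rich$species_count[b], cnt)
  }
})

test_that("affected species follow the overlap rule and affinity buckets", {
  # grid: grass converts in the west 5 columns only
  v0 <- matrix(hc[["GRASS_SHRUB"]], 10, 10)
  v1 <- v0; v1[, 1:5] <- hc[["CULTIVATED"]]
  tr <- detect_transitions(make_epoch(v0, 2000), make_epoch(v1, 2010))
  west <- rect_ring(0.3, 0.3, 400.3, 900.3)
  east <- rect_ring(600.3, 0.3, 900.3, 900.3)
  sp <- polygon_layer(
    data.frame(
      species_id = sprintf("SP%03d", 1:5),
      taxon = c("amphibian", "bird", "mammal", "reptile", "amphibian"),
      red_list = c("VU", "CR", "EN", "other", "VU"),
      habitats = c("GRASS_SHRUB", "GRASS_SHRUB+FOREST",
                   "FOREST+GRASS_SHRUB+NONFOREST_WETLAND",
                   "GRASS_SHRUB", "NONFOREST_WETLAND"),
      stringsAsFactors = FALSE),
    list(west, west, west, west, east), "species_range")
  aff <- affected_species(tr, sp)
  # SP4 is not threatened; SP5 overlaps only stable cells
  expect_equal(aff$n_affected, 3L)
  expect_setequal(aff$affected_ids, c("SP001", "SP002", "SP003"))
  expect_equal(aff$by_taxon$n[aff$by_taxon$taxon == "amphibian"], 1L)
  ba <- aff$by_affinity
  pick <- function(cls, b) ba$n[ba$focal_class == cls & ba$bucket == b]
  expect_equal(pick("GRASS_SHRUB", "endemic"), 1L)   # SP1
  expect_equal(pick("GRASS_SHRUB", "two"), 1L)       # SP2
  expect_equal(pick("GRASS_SHRUB", "three"), 1L)     # SP3
  # a two-habitat species counts under both of its classes
  expect_equal(pick("FOREST", "two"), 1L)            # SP2 again
  expect_equal(pick("FOREST", "three"), 1L)
  expect_equal(pick("NONFOREST_WETLAND", "endemic"), 0L)
  # bucket partition: per focal class the buckets sum to the species
  # affected with affinity to that class
  for (cls in names(natural_classes())) {
    habs <- strsplit(sp$table$habitats, "+", fixed = TRUE)
    threatened <- sp$table$red_list %in% c("VU", "EN", "CR")
    expected <- sum(vapply(seq_along(habs), function(i)
      threatened[i] && cls %in% habs[[i]] &&
        sp$table$species_id[i] %in% aff$affected_ids, logical(1)))
    expect_equal(sum(ba$n[ba$focal_class == cls]), expected, info = cls)
  }
})

test_that("affected counts are monotone in the converted set", {
  scn <- synthetic_scenario(grid_shape = c(40, 40), seed = 61,
                            n_species = 15)
  land <- generate_landscape(scn)
  rng <- generate_species_ranges(scn, land)
  tr <- detect_transitions(land$epochs[[1]], land$epochs[[2]])
  aff_nf <- affected_species(tr, rng,
                             which = conversion_codes(include_forest = FALSE))
  aff_all <- affected_species(tr, rng)
  expect_true(all(aff_nf$affected_ids %in% aff_all$affected_ids))
  expect_true(all(aff_all$by_affinity$n >= 0))
  # ground-truth flags from the generator agree with the overlay
  truth <- rng$table$affected_truth[rng$table$red_list %in%
                                      c("VU", "EN", "CR")]
  got <- threatened <- rng$table$species_id[rng$table$red_list %in%
                                              c("VU", "EN", "CR")] %in%
    aff_all$affected_ids
  expect_equal(got, truth)
})

test_that("KBA conversion and the PA protection gap satisfy containment", {
  v0 <- matrix(hc[["GRASS_SHRUB"]], 10, 10)
  v1 <- matrix(hc[["CULTIVATED"]], 10, 10)
  tr <- detect_transitions(make_epoch(v0, 2000), make_epoch(v1, 2010))
  kba <- polygon_layer(data.frame(kba_id = "K1", name = "k"),
                       list(rect_ring(0.3, 0.3, 400.3, 400.3)), "kba")
  # disjoint PA: gap equals the full KBA conversion
  pa_far <- polygon_layer(
    data.frame(pa_id = "P1", iucn_category = "II",
               establishment_year = 1990, designation = "t",
               marine = FALSE),
    list(rect_ring(600.3, 600.3, 900.3, 900.3)), "pa")
  kt <- kba_conversion(tr, kba, pa_far)
  grass <- kt[kt$land_class == "GRASS_SHRUB", ]
  expect_equal(grass$kba_not_pa_converted_ha, grass$kba_converted_ha)
  expect_gt(grass$kba_converted_ha, 0)
  # KBA inside PA: gap zero
  pa_over <- pa_far
  pa_over$geometry <- list(rect_ring(-10, -10, 500.3, 500.3))
  kt2 <- kba_conversion(tr, kba, pa_over)
  expect_equal(kt2$kba_not_pa_converted_ha[kt2$land_class ==
                                             "GRASS_SHRUB"], 0)
  # invariant: gap never exceeds KBA conversion
  expect_true(all(kt$kba_not_pa_converted_ha <= kt$kba_converted_ha))
})
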