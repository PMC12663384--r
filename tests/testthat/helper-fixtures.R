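# Shared fixture builders and independent brute-force oracles. The oracles
# deliberately use plain double loops / direct enumeration so they share no
# code path with the vectorized implementations they check.

hc <- landconvert::harmonized_classes()
tc <- landconvert::transition_codes()

make_epoch <- function(values, year = 2000, dataset_id = "synthetic",
                       cell_size = 100, ...) {
  epoch_raster(values, year = year, dataset_id = dataset_id,
               cell_size = cell_size, ...)
}

# Uniform-class raster with optional nodata cells.
uniform_epoch <- function(nr, nc, class = "GRASS_SHRUB", year = 2000,
                          cell_size = 100) {
  make_epoch(matrix(hc[[class]], nr, nc), year = year,
             cell_size = cell_size)
}

# Brute-force transition coding of a single cell pair.
oracle_transition_cell <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_integer_)
  cult <- hc[["CULTIVATED"]]
  if (a == hc[["GRASS_SHRUB"]] && b == cult) return(tc[["CONV_GRASS"]])
  if (a == hc[["NONFOREST_WETLAND"]] && b == cult)
    return(tc[["CONV_WETLAND"]])
  if (a == hc[["FOREST"]] && b == cult) return(tc[["CONV_FOREST"]])
  if (a == cult && b %in% landconvert::natural_classes())
    return(tc[["REVERSION"]])
  if (a == b) return(tc[["STABLE"]])
  tc[["OTHER_CHANGE"]]
}

oracle_transitions <- function(t0, t1) {
  out <- matrix(NA_integer_, nrow(t0$values), ncol(t0$values))
  for (i in seq_len(nrow(out)))
    for (j in seq_len(ncol(out)))
      out[i, j] <- oracle_transition_cell(t0$values[i, j], t1$values[i, j])
  out
}

# Brute-force zonal area sums: loop every cell.
oracle_zonal <- function(tr, zones) {
  area <- cell_areas(tr)
  acc <- list()
  zname <- c(zones$zone_ids, "unassigned")
  for (i in seq_len(nrow(tr$values)))
    for (j in seq_len(ncol(tr$values))) {
      v <- tr$values[i, j]
      if (is.na(v)) next
      z <- zones$labels[i, j]
      zn <- if (is.na(z)) "unassigned" else zname[z]
      key <- paste(zn, names(tc)[v], sep = "|")
      acc[[key]] <- (acc[[key]] %||% 0) + area[i, j]
    }
  acc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force per-block recount of converted / valid cells.
oracle_block_fraction <- function(tr, block_cells, which) {
  nr <- nrow(tr$values); nc <- ncol(tr$values)
  res <- list()
  for (br in seq_len(ceiling(nr / block_cells)))
    for (bc in seq_len(ceiling(nc / block_cells))) {
      rows <- ((br - 1) * block_cells + 1):min(br * block_cells, nr)
      cols <- ((bc - 1) * block_cells + 1):min(bc * block_cells, nc)
      nv <- 0L; cv <- 0L
      for (i in rows) for (j in cols) {
        v <- tr$values[i, j]
        if (is.na(v)) next
        nv <- nv + 1L
        if (v %in% which) cv <- cv + 1L
      }
      if (nv > 0)
        res[[sprintf("%d_%d", br, bc)]] <- cv / nv
    }
  res
}

# Brute-force polygon overlay: per-cell center-in-polygon test by loop.
oracle_polygon_cells <- function(r, ring) {
  nr <- nrow(r$values); nc <- ncol(r$values); cs <- r$cell_size
  hits <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      x <- r$xmin + (j - 0.5) * cs
      y <- r$ymin + (nr - i + 0.5) * cs
      # winding-independent crossing count along +x ray, written separately
      # from point_in_polygon()
      ringo <- ring
      n <- nrow(ringo)
      if (all(ringo[1, ] == ringo[n, ])) ringo <- ringo[-n, , drop = FALSE]
      n <- nrow(ringo)
      cnt <- 0L
      for (k in seq_len(n)) {
        p1 <- ringo[k, ]; p2 <- ringo[if (k == n) 1 else k + 1, ]
        if ((p1[2] > y) != (p2[2] > y)) {
          xint <- p1[1] + (y - p1[2]) * (p2[1] - p1[1]) / (p2[2] - p1[2])
          if (x < xint) cnt <- cnt + 1L
        }
      }
      hits[i, j] <- (cnt %% 2L) == 1L
    }
  hits
}

# A small deterministic two-epoch fixture with every transition family.
fixture_pair <- function() {
  t0 <- matrix(hc[["GRASS_SHRUB"]], 6, 6)
  t0[1, ] <- hc[["FOREST"]]
  t0[2, ] <- hc[["NONFOREST_WETLAND"]]
  t0[3, 1:3] <- hc[["CULTIVATED"]]
  t0[6, 6] <- hc[["OTHER"]]
  t1 <- t0
  t1[1, 1:2] <- hc[["CULTIVATED"]]   # forest conversion
  t1[2, 1:3] <- hc[["CULTIVATED"]]   # wetland conversion
  t1[4, 1:4] <- hc[["CULTIVATED"]]   # grass conversion
  t1[3, 1] <- hc[["GRASS_SHRUB"]]    # reversion
  t1[6, 6] <- hc[["FOREST"]]         # other change
  t0[5, 5] <- NA; t1[5, 6] <- NA     # nodata in one epoch each
  list(t0 = make_epoch(t0, 2000), t1 = make_epoch(t1, 2010))
}
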