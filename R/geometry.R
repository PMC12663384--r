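# Planar geometry primitives for polygon-raster overlay. All overlay
# decisions in the package use one rule: a cell belongs to a polygon iff its
# center lies inside the polygon (even-odd ray casting). Polygons are single
# exterior rings; synthetic generators emit vertices snapped off cell
# boundaries so the on-edge case does not arise in practice.

#' Point-in-polygon test
#'
#' Even-odd (ray casting) containment of points in a single polygon ring.
#' Points exactly on an edge may fall on either side; callers that care
#' place vertices off the query lattice.
#'
#' @param px,py Numeric vectors of point coordinates.
#' @param ring Numeric `n x 2` matrix of polygon vertices (closing vertex
#'   optional).
#' @return Logical vector, `TRUE` where the point is inside.
#' @export
point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  if (n >= 3 && all(ring[1, ] == ring[n, ])) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Planar polygon area (shoelace formula)
#'
#' @param ring Numeric `n x 2` matrix of polygon vertices.
#' @return Absolute area in squared coordinate units.
#' @export
polygon_area <- function(ring) {
  n <- nrow(ring)
  if (n >= 3 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Logical mask of raster cells whose centers fall inside `ring`.
# Restricted to the ring's bounding box for speed.
polygon_cell_mask <- function(r, ring) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  cs <- r$cell_size
  xr <- range(ring[, 1]); yr <- range(ring[, 2])
  cmin <- max(1L, floor((xr[1] - r$xmin) / cs - 0.5) + 1L)
  cmax <- min(nc, ceiling((xr[2] - r$xmin) / cs + 0.5))
  # row index grows southward: row = nr - (y - ymin)/cs + 0.5
  rmin <- max(1L, floor(nr - (yr[2] - r$ymin) / cs + 0.5))
  rmax <- min(nr, ceiling(nr - (yr[1] - r$ymin) / cs + 0.5))
  mask <- matrix(FALSE, nr, nc)
  if (cmin > cmax || rmin > rmax) return(mask)
  rows <- rmin:rmax; cols <- cmin:cmax
  px <- r$xmin + (rep(cols, each = length(rows)) - 0.5) * cs
  py <- r$ymin + (nr - rep(rows, times = length(cols)) + 0.5) * cs
  inside <- point_in_polygon(px, py, ring)
  mask[cbind(rep(rows, times = length(cols)),
             rep(cols, each = length(rows)))] <- inside
  mask
}

#' Rasterize a polygon layer by cell-center containment
#'
#' Assigns each raster cell the index of a containing polygon. When
#' polygons overlap, `precedence` decides which wins: features are burned
#' in increasing order of `precedence`, so the feature with the highest
#' precedence value claims contested cells.
#'
#' @param layer A [polygon_layer()].
#' @param r An [epoch_raster()] or [transition_raster()] defining the grid.
#' @param precedence Optional numeric vector (one per feature); higher
#'   values overwrite lower. Defaults to feature order.
#' @return Integer matrix of feature indices (`NA` outside all polygons).
#' @export
rasterize_layer <- function(layer, r, precedence = NULL) {
  nfeat <- length(layer$geometry)
  out <- matrix(NA_integer_, nrow(r$values), ncol(r$values))
  if (nfeat == 0) return(out)
  if (is.null(precedence)) precedence <- seq_len(nfeat)
  for (i in order(precedence)) {
    mask <- polygon_cell_mask(r, layer$geometry[[i]])
    out[mask] <- i
  }
  out
}

# Convex blob: convex hull of points jittered around a center. Used by the
# synthetic generators for KBAs and species ranges.
convex_blob <- function(cx, cy, radius, n_points = 8) {
  ang <- sort(stats::runif(n_points, 0, 2 * pi))
  rad <- radius * stats::runif(n_points, 0.5, 1)
  pts <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
  pts[rev(grDevices::chull(pts)), , drop = FALSE]
}

# Axis-aligned rectangle ring.
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}
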