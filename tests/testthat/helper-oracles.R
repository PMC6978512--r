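# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Even-odd ray-casting point-in-polygon (no boundary subtlety; callers use
# geometry where points are well clear of edges).
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Distance from one point to one segment by golden-section search over the
# parameterised segment (numerical route, vs the package's closed form).
oracle_point_segment_distance <- function(px, py, ax, ay, bx, by) {
  f <- function(t) sqrt((px - (ax + t * (bx - ax)))^2 +
                          (py - (ay + t * (by - ay)))^2)
  opt <- stats::optimize(f, c(0, 1), tol = 1e-12)
  min(opt$objective, f(0), f(1))
}

oracle_road_distance <- function(px, py, roads) {
  vapply(seq_along(px), function(i) {
    best <- Inf
    for (line in roads) {
      for (s in seq_len(nrow(line) - 1)) {
        best <- min(best, oracle_point_segment_distance(
          px[i], py[i], line[s, 1], line[s, 2], line[s + 1, 1], line[s + 1, 2]))
      }
    }
    best
  }, numeric(1))
}

# Brute-force DBSCAN via the full distance matrix and explicit
# density-reachability. Returns core flags, noise flags, and the partition
# of core points canonicalised by the smallest member index.
oracle_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  nbr <- d <= eps
  is_core <- unname(rowSums(nbr) >= min_pts)
  # connected components of core points under eps-adjacency
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in which(is_core)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nxt <- which(nbr[v, ] & is_core & is.na(comp))
      stack <- c(stack, nxt)
    }
  }
  # border points: reachable from some core; noise: not core, no core neighbour
  reachable <- is_core | vapply(seq_len(n), function(i) any(nbr[i, ] & is_core),
                                logical(1))
  canon <- function(labels) {
    out <- rep(NA_integer_, n)
    for (k in unique(labels[!is.na(labels)])) {
      m <- which(labels == k)
      out[m] <- min(m)
    }
    out
  }
  list(is_core = is_core, is_noise = !reachable,
       core_partition = canon(ifelse(is_core, comp, NA_integer_)))
}

# Lattice count: integer offsets (i, j) with (s*i)^2 + (s*j)^2 <= eps^2
oracle_lattice_count <- function(eps, spacing = 30) {
  r <- floor(eps / spacing)
  ij <- expand.grid(i = -r:r, j = -r:r)
  sum((spacing * ij$i)^2 + (spacing * ij$j)^2 <= eps^2)
}

# Small hand-built structure grid: constant layers on an n x n grid.
toy_structure <- function(n = 5, tph = 100, bph = 200, vph = 300,
                          variant = "dbh_ge_25cm", pixel_size = 30) {
  spec <- grid_spec(0, n * pixel_size, n, n, pixel_size = pixel_size,
                    crs_id = "TOY")
  structure_grid(spec, variant,
                 tph = matrix(tph, n, n), bph = matrix(bph, n, n),
                 vph = matrix(vph, n, n))
}

# Rectangle polygon covering given pixel index ranges (1-based, inclusive)
pixel_rect <- function(spec, row_lo, row_hi, col_lo, col_hi) {
  x0 <- spec$origin_x + (col_lo - 1) * spec$pixel_size
  x1 <- spec$origin_x + col_hi * spec$pixel_size
  y1 <- spec$origin_y - (row_lo - 1) * spec$pixel_size
  y0 <- spec$origin_y - row_hi * spec$pixel_size
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Compact landscape for fast end-to-end tests
small_landscape <- function(seed = 1, n = 60, n_polys = 3, ...) {
  simulate_landscape(landscape_config(
    seed = seed,
    spec = grid_spec(5e5, 42e5, n, n, pixel_size = 30, crs_id = "SYNTH_TM"),
    n_polygons_per_year = n_polys, ...))
}
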