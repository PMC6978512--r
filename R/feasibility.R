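# Harvest-feasibility screening: DBSCAN isolation filtering with an
# epsilon-neighbourhood selected at the knee of the biomass-removed vs
# cluster-compactness trade-off curve, wilderness/National-Park exclusion,
# a maximum mean tree volume, and a minimum dead-tree density.

#' Density-based clustering of dead-biomass pixels
#'
#' Standard DBSCAN on Euclidean distance between pixel centres. A point's
#' epsilon-neighbourhood includes the point itself; points with at least
#' `min_pts` neighbours are core points, points density-reachable from a core
#' point join its cluster (border points are attached to the first cluster
#' that reaches them, in deterministic scan order), and the rest are noise.
#' With the default `min_pts = 112` on a 30-m pixel lattice, no cluster can
#' form for `eps < 180` m: at most 109 lattice centres fit in a 179-m disc,
#' while a 180-m disc holds exactly 113.
#'
#' Neighbour search uses spatial binning on an `eps`-sized grid, so runtime
#' is near-linear for the pixel densities the pipeline produces.
#'
#' @param x,y Point coordinates (m), typically centres of pixels carrying
#'   dead biomass.
#' @param eps Neighbourhood radius (m), > 0.
#' @param min_pts Minimum neighbourhood size (self included) for a core
#'   point; default 112 pixels (~10 ha of 0.09-ha pixels).
#' @return An object of class `cluster_assignment`: a list with `cluster`
#'   (integer vector, `NA` = noise), `is_core` (logical), and `clusters`
#'   (tibble: `cluster`, `n_points`, `standard_distance`).
#' @export
dbscan_pixels <- function(x, y, eps, min_pts = 112) {
  stopifnot(eps > 0, min_pts >= 1, length(x) == length(y))
  n <- length(x)
  if (n == 0) {
    out <- list(cluster = integer(0), is_core = logical(0),
                clusters = tibble::tibble(cluster = integer(0),
                                          n_points = integer(0),
                                          standard_distance = numeric(0)))
    class(out) <- "cluster_assignment"
    return(out)
  }
  # spatial binning: points in cells of side eps; neighbours live in the
  # 3 x 3 cell block around a point's cell. Cells are hashed in an
  # environment and each cell's candidate block is gathered once.
  cx <- floor(x / eps); cy <- floor(y / eps)
  key <- paste(cx, cy)
  env <- new.env(hash = TRUE, size = n)
  pts_by_cell <- split(seq_len(n), key)
  for (k in names(pts_by_cell)) assign(k, pts_by_cell[[k]], envir = env)
  u_keys <- names(pts_by_cell)
  cell_id <- match(key, u_keys)
  first_pt <- vapply(pts_by_cell, `[[`, integer(1), 1L)
  block_of <- lapply(seq_along(u_keys), function(u) {
    i <- first_pt[[u]]
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      v <- get0(k, envir = env, inherits = FALSE)
      if (!is.null(v)) cand <- c(cand, v)
    }
    cand
  })
  eps2 <- eps^2
  nb <- lapply(seq_len(n), function(i) {
    cand <- block_of[[cell_id[i]]]
    cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= eps2]
  })
  is_core <- lengths(nb) >= min_pts
  cluster <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || !is.na(cluster[i])) next
    cl <- cl + 1L
    cluster[i] <- cl
    queued <- logical(n)
    queue <- nb[[i]]
    queued[queue] <- TRUE
    qpos <- 1L
    while (qpos <= length(queue)) {
      j <- queue[qpos]; qpos <- qpos + 1L
      if (is.na(cluster[j])) {
        cluster[j] <- cl
        if (is_core[j]) {
          new <- nb[[j]]
          new <- new[is.na(cluster[new]) & !queued[new]]
          queued[new] <- TRUE
          queue <- c(queue, new)
        }
      }
    }
  }
  ids <- sort(unique(cluster[!is.na(cluster)]))
  clusters <- dplyr::bind_rows(lapply(ids, function(k) {
    m <- which(cluster == k)
    tibble::tibble(cluster = k, n_points = length(m),
                   standard_distance = standard_distance(x[m], y[m]))
  }))
  if (length(ids) == 0) {
    clusters <- tibble::tibble(cluster = integer(0), n_points = integer(0),
                               standard_distance = numeric(0))
  }
  out <- list(cluster = cluster, is_core = is_core, clusters = clusters)
  class(out) <- "cluster_assignment"
  out
}

#' Standard distance of a point set
#'
#' Compactness measure of a cluster: the root of the summed population
#' variances of the coordinates about the centroid,
#' `sqrt(mean((x - mean(x))^2) + mean((y - mean(y))^2))`. Zero for a single
#' point; invariant under translation.
#'
#' @param x,y Coordinates of the member points (>= 1 point).
#' @return Standard distance (m).
#' @export
standard_distance <- function(x, y) {
  stopifnot(length(x) >= 1, length(x) == length(y))
  sqrt(mean((x - mean(x))^2) + mean((y - mean(y))^2))
}

#' Biomass-removed vs compactness trade-off curve
#'
#' Runs the clustering at each candidate epsilon and records how much dead
#' biomass the isolation filter would discard (the total on noise pixels) and
#' how compact the resulting clusters are (unweighted mean of per-cluster
#' standard distances; `NA` when no cluster forms). Removed biomass is
#' non-increasing in epsilon because density-reachability only grows with the
#' radius.
#'
#' @param grid A `dead_biomass_grid` (clustering operates on its pixels with
#'   positive cumulative dead biomass).
#' @param eps_values Ascending candidate radii (m); default 180 to 400 m in
#'   20-m steps, spanning the smallest radius at which a 112-pixel cluster
#'   can form on a 30-m lattice up to radii too loose to filter scattered
#'   mortality.
#' @param min_pts Minimum cluster size (see [dbscan_pixels()]).
#' @return A tibble of class `tradeoff_curve`: `eps`, `biomass_removed`
#'   (BDT), `mean_standard_distance` (m), `n_clusters`.
#' @export
tradeoff_curve <- function(grid, eps_values = seq(180, 400, by = 20),
                           min_pts = 112) {
  stopifnot(!is.unsorted(eps_values, strictly = TRUE))
  pts <- positive_pixels(grid)
  curve <- dplyr::bind_rows(lapply(eps_values, function(eps) {
    a <- dbscan_pixels(pts$x, pts$y, eps = eps, min_pts = min_pts)
    noise <- is.na(a$cluster)
    tibble::tibble(
      eps = eps,
      biomass_removed = sum(pts$tdbm[noise]),
      mean_standard_distance = if (nrow(a$clusters) > 0)
        mean(a$clusters$standard_distance) else NA_real_,
      n_clusters = nrow(a$clusters))
  }))
  class(curve) <- c("tradeoff_curve", class(curve))
  curve
}

# pixel centres carrying positive cumulative dead biomass
positive_pixels <- function(grid) {
  idx <- which(grid$tdbm > 0, arr.ind = TRUE)
  ctr <- pixel_centers(grid$spec, idx[, 1], idx[, 2])
  ctr$tdbm <- grid$tdbm[idx]
  ctr
}

#' Select the epsilon-neighbourhood at the trade-off knee
#'
#' Chooses the radius at the inflection of the trade-off curve: both axes
#' (biomass removed, mean standard distance) are min-max normalised and the
#' discrete (Menger) curvature is evaluated at each interior point; the
#' epsilon with maximum curvature is returned, ties broken toward the
#' smaller radius (smaller radii give more compact clusters). A curve with
#' no curvature (collinear points) degenerates to the smallest interior
#' epsilon, with a warning.
#'
#' @param curve A [tradeoff_curve()] (rows with undefined compactness are
#'   dropped; at least 3 defined points are required).
#' @return Selected epsilon (m).
#' @export
select_eps <- function(curve) {
  cc <- curve[!is.na(curve$mean_standard_distance), ]
  if (nrow(cc) < 3) stop("need at least 3 defined trade-off points", call. = FALSE)
  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  }
  xs <- norm01(cc$mean_standard_distance)
  ys <- norm01(cc$biomass_removed)
  menger <- function(i) {
    ax <- xs[i - 1]; ay <- ys[i - 1]; bx <- xs[i]; by <- ys[i]
    cx <- xs[i + 1]; cy <- ys[i + 1]
    area2 <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
    d1 <- sqrt((bx - ax)^2 + (by - ay)^2)
    d2 <- sqrt((cx - bx)^2 + (cy - by)^2)
    d3 <- sqrt((cx - ax)^2 + (cy - ay)^2)
    if (d1 * d2 * d3 == 0) 0 else 2 * area2 / (d1 * d2 * d3)
  }
  kappa <- vapply(2:(nrow(cc) - 1), menger, numeric(1))
  if (max(kappa) <= 1e-12) {
    warning("trade-off curve has no curvature; returning smallest interior eps",
            call. = FALSE)
    return(cc$eps[2])
  }
  cc$eps[1 + which.max(kappa)]  # which.max already takes the first (smallest eps) tie
}

#' Zero out spatially isolated dead biomass
#'
#' Applies a cluster assignment as a mask: cumulative dead biomass on noise
#' pixels is removed (set to zero), keeping only mortality that forms
#' harvest-worthy concentrations.
#'
#' @param grid A `dead_biomass_grid`.
#' @param assignment A [dbscan_pixels()] result for this grid's positive
#'   pixels (in [positive_pixels()] order), or a logical "keep" matrix.
#' @return List: `grid` (filtered copy), `removed` (BDT zeroed out).
#' @export
filter_isolated <- function(grid, assignment) {
  keep <- keep_matrix(grid, assignment)
  apply_keep(grid, keep)
}

# Build a logical keep-matrix from a cluster assignment (TRUE where retained)
keep_matrix <- function(grid, assignment) {
  if (is.matrix(assignment)) return(assignment)
  stopifnot(inherits(assignment, "cluster_assignment"))
  pts <- positive_pixels(grid)
  stopifnot(length(assignment$cluster) == nrow(pts))
  keep <- matrix(TRUE, grid$spec$n_rows, grid$spec$n_cols)
  noise <- is.na(assignment$cluster)
  keep[cbind(pts$row[noise], pts$col[noise])] <- FALSE
  keep
}

apply_keep <- function(grid, keep) {
  removed <- sum(grid$tdbm[!keep])
  grid$tdbm[!keep] <- 0
  list(grid = grid, removed = removed)
}

#' Remove dead biomass in wilderness and National Park land
#'
#' Zeroes pixels whose centres fall inside any wilderness/National-Park
#' polygon (mechanical harvest prohibited or uncommon there).
#'
#' @param grid A `dead_biomass_grid`.
#' @param zones A `zone_set` (see [generate_zones()]) or a list of polygon
#'   coordinate matrices.
#' @return List: `grid` (filtered copy), `removed` (BDT zeroed out).
#' @export
filter_zones <- function(grid, zones) {
  polys <- if (inherits(zones, "zone_set")) zones$wilderness_np else zones
  keep <- matrix(TRUE, grid$spec$n_rows, grid$spec$n_cols)
  for (coords in polys) {
    member <- pixels_in_polygon(coords, grid$spec)
    if (nrow(member)) keep[cbind(member$row, member$col)] <- FALSE
  }
  apply_keep(grid, keep)
}

#' Remove oversize-tree and sparse-mortality pixels
#'
#' Zeroes pixels whose mean live tree volume reaches the facility chipping
#' limit (`vpt >= vpt_max`, inclusive: such trees need costly pre-processing)
#' or whose cumulative dead-tree density falls below the minimum
#' (`sum_t DT_i_t / pixel area < min_dead_density`, strict: sparse dead trees
#' amid live ones are costly to extract selectively).
#'
#' @param grid A `dead_biomass_grid` (its uncorrected yearly dead-tree layers
#'   supply the density criterion).
#' @param structure The [structure_grid()] supplying mean tree volume.
#' @param vpt_max Facility chipping limit (m^3/tree), default 11.32.
#' @param min_dead_density Minimum cumulative dead trees per hectare,
#'   default 2.5.
#' @return List: `grid` (filtered copy), `removed` (BDT zeroed out), `keep`
#'   (logical matrix).
#' @export
filter_vpt_and_density <- function(grid, structure, vpt_max = 11.32,
                                   min_dead_density = 2.5) {
  vpt <- mean_tree_volume(structure)
  dt_total <- Reduce(`+`, c(list(matrix(0, grid$spec$n_rows, grid$spec$n_cols)),
                            grid$dt_by_year))
  dead_density <- dt_total / pixel_area_ha(grid$spec)
  keep <- !(!is.na(vpt) & vpt >= vpt_max) & dead_density >= min_dead_density
  res <- apply_keep(grid, keep)
  res$keep <- keep
  res
}

#' Apply the full feasibility cascade to both bounds
#'
#' Runs the three feasibility filters in order — spatial isolation,
#' wilderness/National Park, tree size and dead-tree density — on the
#' upper-bound grid, and applies the identical pixel footprint to the lower
#' bound, so both bounds describe one spatial subset. Clustering operates on
#' the upper-bound grid's positive pixels; when `eps` is `NULL` it is
#' selected at the knee of the trade-off curve.
#'
#' @param bounds A `dead_biomass_bounds` from [run_allocation()].
#' @param zones A `zone_set`.
#' @param structure Upper-bound [structure_grid()] (tree-volume criterion).
#' @param eps Isolation radius (m) or `NULL` to select from the trade-off
#'   curve.
#' @param eps_values Sweep used when selecting `eps` (see
#'   [tradeoff_curve()]).
#' @param min_pts Minimum cluster size, default 112 pixels.
#' @param vpt_max,min_dead_density See [filter_vpt_and_density()].
#' @return An object of class `feasibility_result`: filtered `upper` and
#'   `lower` grids, `eps` used, `curve` (when swept), and `reduction_ledger`
#'   — a tibble with one row per filter giving biomass removed and the new
#'   running total for each bound.
#' @export
apply_feasibility <- function(bounds, zones, structure, eps = NULL,
                              eps_values = seq(180, 400, by = 20),
                              min_pts = 112, vpt_max = 11.32,
                              min_dead_density = 2.5) {
  curve <- NULL
  if (is.null(eps)) {
    curve <- tradeoff_curve(bounds$upper, eps_values, min_pts)
    eps <- select_eps(curve)
  }
  pts <- positive_pixels(bounds$upper)
  assignment <- dbscan_pixels(pts$x, pts$y, eps = eps, min_pts = min_pts)
  keep_iso <- keep_matrix(bounds$upper, assignment)

  up <- bounds$upper; lo <- bounds$lower
  ledger <- list()
  step <- function(name, keep, up, lo) {
    ru <- apply_keep(up, keep); rl <- apply_keep(lo, keep)
    list(row = tibble::tibble(
      filter = name,
      removed_lower = rl$removed, total_lower = sum(rl$grid$tdbm),
      removed_upper = ru$removed, total_upper = sum(ru$grid$tdbm)),
      up = ru$grid, lo = rl$grid)
  }
  s1 <- step("spatial_isolation", keep_iso, up, lo)
  zkeep <- matrix(TRUE, up$spec$n_rows, up$spec$n_cols)
  for (coords in (if (inherits(zones, "zone_set")) zones$wilderness_np else zones)) {
    member <- pixels_in_polygon(coords, up$spec)
    if (nrow(member)) zkeep[cbind(member$row, member$col)] <- FALSE
  }
  s2 <- step("wilderness_np", zkeep, s1$up, s1$lo)
  fv <- filter_vpt_and_density(s2$up, structure, vpt_max, min_dead_density)
  s3 <- step("vpt_or_low_density", fv$keep, s2$up, s2$lo)

  out <- list(upper = s3$up, lower = s3$lo, eps = eps, min_pts = min_pts,
              curve = curve, assignment = assignment,
              reduction_ledger = dplyr::bind_rows(s1$row, s2$row, s3$row))
  class(out) <- "feasibility_result"
  out
}

#' @export
print.feasibility_result <- function(x, ...) {
  cat(sprintf("<feasibility_result> eps = %g m; feasible biomass %.1f (lower) to %.1f (upper) BDT\n",
              x$eps, sum(x$lower$tdbm), sum(x$upper$tdbm)))
  print(x$reduction_ledger)
  invisible(x)
}

#' Plot a trade-off curve
#'
#' Biomass removed by the isolation filter against mean cluster standard
#' distance across the epsilon sweep, the curve whose knee selects the
#' working radius.
#'
#' @param object A [tradeoff_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tradeoff_curve <- function(object, ...) {
  cc <- object[!is.na(object$mean_standard_distance), ]
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$mean_standard_distance,
                                   y = .data$biomass_removed)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$eps), size = 2) +
    ggplot2::scale_colour_viridis_c(name = expression(epsilon ~ "(m)")) +
    ggplot2::labs(x = "Mean cluster standard distance (m)",
                  y = "Biomass removed by isolation filter (BDT)") +
    ggplot2::theme_minimal()
}
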