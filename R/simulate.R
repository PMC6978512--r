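# Synthetic-landscape generator: seeded, internally consistent input bundles
# (structure grids in both detection variants, mortality polygons with
# dead-tree counts, DEM, roads, zones, reference biomass-loss raster) with
# ground truth retained so every pipeline stage has a known answer.

#' Configure a synthetic landscape
#'
#' Collects every knob of the synthetic-data generator with defaults that
#' describe a mid-elevation conifer landscape hit by a multi-year die-off:
#' a 3.6 x 3.6 km, 30-m grid, ~70% forested, live densities of a few hundred
#' trees/ha, six survey years with a handful of mortality patches per year
#' killing 5-35% of the detectable trees in each patch.
#'
#' @param seed Master seed; all component substreams derive from it, so the
#'   same seed yields a bit-identical bundle.
#' @param spec Analysis [grid_spec()].
#' @param forest_fraction Fraction of pixels that are forested.
#' @param tph_mean Mean live tree density (trees/ha, all trees >= 2.5 cm DBH).
#' @param tph_spatial_scale Autocorrelation range of the random fields, in
#'   pixels (Gaussian smoothing scale).
#' @param mean_tree_biomass_range Range (BDT/tree) of the mean biomass of
#'   large (>= 25 cm DBH) trees across the landscape; interpolated
#'   geometrically (log-uniform), concentrating mass at small trees with a
#'   long right tail, and tied to the same latent size field as volume.
#' @param mean_tree_volume_range Range (m^3/tree) of the mean stem volume of
#'   large trees (log-uniform); the upper end deliberately exceeds the
#'   11.32 m^3 facility chipping limit so the size filter is exercised.
#' @param years Survey years.
#' @param n_polygons_per_year Mortality polygons delineated per year.
#' @param mortality_fraction_range Range of the per-patch fraction of
#'   detectable live trees killed. Values above 1 are allowed in
#'   `proportional` mode: the surveyed count then exceeds the patch's
#'   live-tree capacity (as happens with over-reported aerial counts), the
#'   pixel truth saturates at its cap, and the allocation caps are forced to
#'   bind.
#' @param mortality_mode `"proportional"` (pixel-level deaths exactly
#'   proportional to live tree density, so proportional allocation recovers
#'   the truth) or `"size_biased"` (deaths weighted toward pixels with larger
#'   trees, so the estimator is deliberately misspecified).
#' @param blob_radius_range Range (m) of mortality-patch radii.
#' @param slope_mode `"flat"`, `"inclined"` (a plane rising eastward at
#'   `slope_rise_percent`) or `"random"` (smooth random relief).
#' @param slope_rise_percent Rise/run (%) of the inclined-plane DEM.
#' @param relief_m Elevation amplitude (m) of the random DEM.
#' @param n_roads Number of road centrelines crossing the extent.
#' @param zone_fractions Named list: approximate landscape fractions covered
#'   by `wilderness`, HHZ `tier1` and `tier2` (tiers may overlap).
#' @param noise_sd_log SD of the patch-level lognormal noise applied when
#'   building the independent reference biomass-loss raster.
#' @param reference_gain_fraction Fraction of reference pixels flipped to a
#'   net biomass gain (negative loss), exercising the validation exclusion
#'   rule.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(
    seed = 1L,
    spec = grid_spec(origin_x = 5e5, origin_y = 42e5, n_rows = 120,
                     n_cols = 120, pixel_size = 30, crs_id = "SYNTH_TM"),
    forest_fraction = 0.7,
    tph_mean = 300,
    tph_spatial_scale = 8,
    mean_tree_biomass_range = c(0.2, 6),
    mean_tree_volume_range = c(0.3, 13),
    years = 2012:2017,
    n_polygons_per_year = 8,
    mortality_fraction_range = c(0.05, 0.35),
    mortality_mode = c("proportional", "size_biased"),
    blob_radius_range = c(150, 500),
    slope_mode = c("random", "flat", "inclined"),
    slope_rise_percent = 30,
    relief_m = 60,
    n_roads = 4,
    zone_fractions = list(wilderness = 0.12, tier1 = 0.08, tier2 = 0.35),
    noise_sd_log = 0.5,
    reference_gain_fraction = 0.02) {
  mortality_mode <- match.arg(mortality_mode)
  slope_mode <- match.arg(slope_mode)
  stopifnot(forest_fraction >= 0, forest_fraction <= 1,
            all(mortality_fraction_range >= 0),
            diff(mean_tree_biomass_range) >= 0,
            noise_sd_log >= 0, n_polygons_per_year >= 0)
  cfg <- list(seed = as.integer(seed), spec = spec,
              forest_fraction = forest_fraction, tph_mean = tph_mean,
              tph_spatial_scale = tph_spatial_scale,
              mean_tree_biomass_range = mean_tree_biomass_range,
              mean_tree_volume_range = mean_tree_volume_range,
              years = years, n_polygons_per_year = n_polygons_per_year,
              mortality_fraction_range = mortality_fraction_range,
              mortality_mode = mortality_mode,
              blob_radius_range = blob_radius_range,
              slope_mode = slope_mode,
              slope_rise_percent = slope_rise_percent, relief_m = relief_m,
              n_roads = n_roads, zone_fractions = zone_fractions,
              noise_sd_log = noise_sd_log,
              reference_gain_fraction = reference_gain_fraction)
  class(cfg) <- "landscape_config"
  cfg
}

# Per-component substream seeds derived once from the master seed, so a
# component can be regenerated independently yet deterministically.
component_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 7L),
                  c("structure", "mortality", "dem", "roads", "zones",
                    "reference", "spare"))
}

# Spatially autocorrelated standard field: white noise convolved (on the
# torus, via FFT) with a Gaussian kernel of the given scale (pixels), then
# re-standardised to mean 0 / sd 1.
smooth_field <- function(n_rows, n_cols, scale) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (scale <= 0) return(z)
  dy <- seq_len(n_rows) - 1L; dy <- pmin(dy, n_rows - dy)
  dx <- seq_len(n_cols) - 1L; dx <- pmin(dx, n_cols - dx)
  k <- exp(-outer(dy^2, dx^2, "+") / (2 * scale^2))
  f <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE))
  (f - mean(f)) / stats::sd(f)
}

# Map a standard field into [lo, hi] through the normal CDF.
scale_to_range <- function(field, range) {
  range[1] + diff(range) * stats::pnorm(field)
}

# Geometric (log-uniform) version, for right-skewed quantities like tree size.
scale_to_range_log <- function(field, range) {
  exp(scale_to_range(field, log(range)))
}

#' Generate paired forest-structure grids
#'
#' Builds spatially autocorrelated live-structure fields for both detection
#' variants from one latent landscape: each pixel carries a density of large
#' (>= 25 cm DBH) and small trees, with per-tree biomass/volume of small trees
#' a fraction of the large trees'. By construction the >= 25 cm variant has
#' pixelwise lower tree density and higher mean tree biomass than the
#' >= 2.5 cm variant wherever forest is present.
#'
#' @param config A [landscape_config()].
#' @return A list with `structure_grid`s `upper` (>= 25 cm) and `lower`
#'   (>= 2.5 cm).
#' @export
generate_structure <- function(config) {
  spec <- config$spec
  set.seed(component_seeds(config$seed)[["structure"]])
  nr <- spec$n_rows; nc <- spec$n_cols; sc <- config$tph_spatial_scale
  g_forest <- smooth_field(nr, nc, sc)
  n_forest <- round(config$forest_fraction * nr * nc)
  mask <- matrix(FALSE, nr, nc)
  if (n_forest > 0) mask[order(g_forest, decreasing = TRUE)[seq_len(n_forest)]] <- TRUE

  tph_total <- config$tph_mean * exp(0.5 * smooth_field(nr, nc, sc))
  frac_large <- scale_to_range(smooth_field(nr, nc, sc), c(0.2, 0.7))
  # one latent size field drives both per-tree volume and biomass, so
  # big-tree pixels carry more of each (as allometry would give)
  size_latent <- smooth_field(nr, nc, sc)
  v_large <- scale_to_range_log(size_latent, config$mean_tree_volume_range)
  b_large <- scale_to_range_log(0.9 * size_latent + 0.45 * smooth_field(nr, nc, sc),
                                config$mean_tree_biomass_range)
  small_ratio <- scale_to_range(smooth_field(nr, nc, sc), c(0.05, 0.25))

  tph_lo <- tph_total * mask
  tph_up <- frac_large * tph_total * mask
  bph_up <- tph_up * b_large
  bph_lo <- bph_up + (tph_lo - tph_up) * b_large * small_ratio
  vph_up <- tph_up * v_large
  vph_lo <- vph_up + (tph_lo - tph_up) * v_large * small_ratio

  list(
    upper = structure_grid(spec, "dbh_ge_25cm", tph = tph_up, bph = bph_up,
                           vph = vph_up, forest_mask = mask),
    lower = structure_grid(spec, "dbh_ge_2p5cm", tph = tph_lo, bph = bph_lo,
                           vph = vph_lo, forest_mask = mask)
  )
}

# Star-shaped blob polygon: vertices at regular angles with a smooth periodic
# radius perturbation. Always a valid simple polygon.
blob_polygon <- function(cx, cy, radius, n_vertices = 36, roughness = 0.4) {
  m <- 1:3
  a <- stats::rnorm(3); phi <- stats::runif(3, 0, 2 * pi)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  s <- colSums(a * sin(outer(m, theta) + phi))
  s <- s / max(1e-9, max(abs(s)))
  r <- radius * (1 + roughness * s)
  cbind(cx + r * cos(theta), cy + r * sin(theta))
}

#' Generate mortality polygons with retained ground truth
#'
#' Draws blob-shaped survey polygons for each year and assigns each a
#' dead-tree count. Pixel-level true deaths are recorded alongside. In
#' `proportional` mode the truth within each polygon is exactly proportional
#' to the upper-variant live tree density (a constant fraction of each
#' pixel's detectable trees dies), so the per-polygon count divided
#' proportionally to density reproduces the truth exactly; in `size_biased`
#' mode deaths are additionally weighted by mean tree biomass, so a
#' density-proportional estimator is deliberately misspecified.
#'
#' @param config A [landscape_config()].
#' @param structure The upper-bound (>= 25 cm) [structure_grid()] that the
#'   aerial counts refer to.
#' @return A list with `polygons` (tibble: `polygon_id`, `year`,
#'   `dead_trees`, `geometry` list-column of coordinate matrices) and `truth`
#'   (see Details).
#' @details `truth` contains `dt_by_year` (list of matrices of true dead
#'   trees per pixel), `dead_biomass` (matrix, cumulative true dead biomass in
#'   BDT), and `per_polygon` (list keyed by polygon id with each polygon's
#'   member pixels and their true dead trees/biomass).
#' @export
generate_mortality <- function(config, structure) {
  spec <- config$spec
  set.seed(component_seeds(config$seed)[["mortality"]])
  px_ha <- pixel_area_ha(spec)
  ext_x <- spec$origin_x + c(0, spec$n_cols) * spec$pixel_size
  ext_y <- spec$origin_y - c(spec$n_rows, 0) * spec$pixel_size
  tph <- structure$tph
  btree <- matrix(0, spec$n_rows, spec$n_cols)
  pos <- tph > 0
  btree[pos] <- structure$bph[pos] / tph[pos]

  polys <- list(); ids <- character(); yrs <- integer(); counts <- numeric()
  dt_by_year <- lapply(config$years, function(y) matrix(0, spec$n_rows, spec$n_cols))
  names(dt_by_year) <- as.character(config$years)
  per_polygon <- list()
  k <- 0L
  for (y in config$years) {
    for (j in seq_len(config$n_polygons_per_year)) {
      k <- k + 1L
      radius <- stats::runif(1, config$blob_radius_range[1], config$blob_radius_range[2])
      # keep centres inside the extent; on small extents the margin shrinks
      # and blobs are clipped to the grid by pixel selection
      mx <- min(radius, 0.4 * diff(ext_x)); my <- min(radius, 0.4 * diff(ext_y))
      cx <- stats::runif(1, ext_x[1] + mx, ext_x[2] - mx)
      cy <- stats::runif(1, ext_y[1] + my, ext_y[2] - my)
      coords <- blob_polygon(cx, cy, radius)
      m_frac <- stats::runif(1, config$mortality_fraction_range[1],
                             config$mortality_fraction_range[2])
      member <- pixels_in_polygon(coords, spec)
      idx <- cbind(member$row, member$col)
      forested <- nrow(member) > 0 & tph[idx] > 0
      id <- sprintf("p%04d", k)
      dt_true <- numeric(0); midx <- idx[forested, , drop = FALSE]
      count <- 0
      if (sum(forested) > 0) {
        base <- m_frac * tph[midx] * px_ha
        if (config$mortality_mode == "size_biased") {
          w <- btree[midx] / mean(btree[midx])
          dt_true <- pmin(base * w, tph[midx] * px_ha)
          count <- sum(dt_true)
        } else {
          # surveyed count is the raw (uncapped) kill; with fractions > 1
          # it deliberately exceeds the polygon's live-tree capacity so the
          # per-pixel cap truncates, while truth stays physical (capped)
          dt_true <- pmin(base, tph[midx] * px_ha)
          count <- sum(base)
        }
        dt_by_year[[as.character(y)]][midx] <-
          dt_by_year[[as.character(y)]][midx] + dt_true
      }
      polys[[k]] <- coords; ids[k] <- id; yrs[k] <- y
      counts[k] <- count
      per_polygon[[id]] <- list(
        row = midx[, 1], col = midx[, 2], year = y,
        dead_trees = dt_true, dead_biomass = dt_true * btree[midx])
    }
  }
  dead_biomass <- Reduce(`+`, c(list(matrix(0, spec$n_rows, spec$n_cols)),
                                dt_by_year)) * btree
  list(
    polygons = tibble::tibble(polygon_id = ids, year = yrs,
                              dead_trees = counts, geometry = polys),
    truth = list(dt_by_year = dt_by_year, dead_biomass = dead_biomass,
                 per_polygon = per_polygon)
  )
}

#' Generate a digital elevation model
#'
#' @param config A [landscape_config()]; `slope_mode` selects a flat surface,
#'   an eastward-inclined plane with known rise (so the slope operator has an
#'   analytic answer everywhere), or smooth random relief.
#' @return Elevation matrix (m) on the analysis grid.
#' @export
generate_dem <- function(config) {
  spec <- config$spec
  set.seed(component_seeds(config$seed)[["dem"]])
  centers <- pixel_centers(spec)
  dem <- switch(config$slope_mode,
    flat = matrix(1000, spec$n_rows, spec$n_cols),
    inclined = {
      z <- 1000 + (config$slope_rise_percent / 100) * (centers$x - spec$origin_x)
      matrix(z[order(centers$col, centers$row)], spec$n_rows, spec$n_cols)
    },
    random = 1000 + config$relief_m *
      smooth_field(spec$n_rows, spec$n_cols, config$tph_spatial_scale)
  )
  dem
}

#' Generate a simple road network
#'
#' Wavy polylines crossing the extent, alternating west-east and north-south.
#'
#' @param config A [landscape_config()].
#' @return List of 2-column coordinate matrices.
#' @export
generate_roads <- function(config) {
  spec <- config$spec
  set.seed(component_seeds(config$seed)[["roads"]])
  if (config$n_roads == 0) return(list())
  w <- spec$n_cols * spec$pixel_size; h <- spec$n_rows * spec$pixel_size
  x0 <- spec$origin_x; y0 <- spec$origin_y - h
  lapply(seq_len(config$n_roads), function(k) {
    amp <- stats::runif(1, 0.02, 0.08) * min(w, h)
    phase <- stats::runif(1, 0, 2 * pi)
    t <- seq(0, 1, length.out = 25)
    if (k %% 2 == 1) {
      yy <- y0 + h * stats::runif(1, 0.15, 0.85)
      cbind(x0 + t * w, yy + amp * sin(2 * pi * 2 * t + phase))
    } else {
      xx <- x0 + w * stats::runif(1, 0.15, 0.85)
      cbind(xx + amp * sin(2 * pi * 2 * t + phase), y0 + t * h)
    }
  })
}

circle_polygon <- function(cx, cy, radius, n = 48) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + radius * cos(theta), cy + radius * sin(theta))
}

#' Generate administrative zones
#'
#' Produces a wilderness/National-Park polygon, overlapping High Hazard Zone
#' tier-1 and tier-2 polygons sized to the configured landscape fractions,
#' and a 2 x 2 partition of the extent into named counties.
#'
#' @param config A [landscape_config()].
#' @return A `zone_set` list: `wilderness_np`, `hhz_tier1`, `hhz_tier2`
#'   (lists of coordinate matrices) and `counties` (tibble with `county`,
#'   `geometry`).
#' @export
generate_zones <- function(config) {
  spec <- config$spec
  set.seed(component_seeds(config$seed)[["zones"]])
  w <- spec$n_cols * spec$pixel_size; h <- spec$n_rows * spec$pixel_size
  x0 <- spec$origin_x; y1 <- spec$origin_y; y0 <- y1 - h
  area <- w * h
  r_of <- function(frac) sqrt(frac * area / pi)
  zf <- config$zone_fractions
  wild <- if (zf$wilderness > 0) {
    list(circle_polygon(x0 + 0.22 * w, y0 + 0.75 * h, r_of(zf$wilderness)))
  } else list()
  tier2 <- if (zf$tier2 > 0) {
    list(circle_polygon(x0 + 0.6 * w, y0 + 0.45 * h, r_of(zf$tier2)))
  } else list()
  tier1 <- if (zf$tier1 > 0) {
    # nested toward the tier-2 core but offset, so the tiers overlap partially
    list(circle_polygon(x0 + 0.48 * w, y0 + 0.38 * h, r_of(zf$tier1)))
  } else list()
  mx <- x0 + 0.5 * w; my <- y0 + 0.5 * h
  rect <- function(xa, xb, ya, yb) cbind(c(xa, xb, xb, xa), c(ya, ya, yb, yb))
  counties <- tibble::tibble(
    county = c("Alder", "Bristlecone", "Cedar", "Douglas"),
    geometry = list(rect(x0, mx, my, y1), rect(mx, x0 + w, my, y1),
                    rect(x0, mx, y0, my), rect(mx, x0 + w, y0, my))
  )
  structure(list(wilderness_np = wild, hhz_tier1 = tier1, hhz_tier2 = tier2,
                 counties = counties), class = "zone_set")
}

#' Generate an independent reference biomass-loss raster
#'
#' Emulates an independently derived biomass-loss product for validation: the
#' true cumulative dead biomass perturbed by multiplicative lognormal noise
#' applied per mortality patch (one draw per polygon, mimicking the
#' patch-scale bias of a remote-sensing change product). Optionally flips a
#' fraction of in-extent pixels to negative values (apparent net growth) to
#' exercise the validation gain-exclusion rule.
#'
#' @param truth The `truth` element returned by [generate_mortality()].
#' @param spec The analysis [grid_spec()].
#' @param noise_sd_log SD of the per-patch log-noise (>= 0).
#' @param seed Integer seed.
#' @param gain_fraction Fraction of currently zero-loss pixels set to a small
#'   negative loss.
#' @return Matrix of reference biomass loss (BDT per pixel; may contain
#'   negative values when `gain_fraction > 0`).
#' @export
generate_reference_loss <- function(truth, spec, noise_sd_log, seed,
                                    gain_fraction = 0) {
  if (noise_sd_log < 0) stop("noise_sd_log must be >= 0", call. = FALSE)
  set.seed(seed)
  ref <- matrix(0, spec$n_rows, spec$n_cols)
  for (pp in truth$per_polygon) {
    if (length(pp$row) == 0) next
    fac <- exp(stats::rnorm(1, 0, noise_sd_log))
    idx <- cbind(pp$row, pp$col)
    ref[idx] <- ref[idx] + fac * pp$dead_biomass
  }
  if (gain_fraction > 0) {
    zero_idx <- which(ref == 0)
    n_gain <- round(gain_fraction * length(zero_idx))
    if (n_gain > 0) {
      pick <- sample(zero_idx, n_gain)
      ref[pick] <- -stats::runif(n_gain, 0.1, 5)
    }
  }
  ref
}

#' Simulate a complete landscape bundle
#'
#' Runs every generator under one master seed and returns an internally
#' consistent bundle: paired structure grids, mortality polygons with ground
#' truth, DEM, roads, zones and a reference biomass-loss raster.
#'
#' @param config A [landscape_config()].
#' @return An object of class `landscape`: a list with `config`, `structure`
#'   (`$upper`, `$lower`), `mortality` (polygon tibble), `truth`, `dem`,
#'   `roads`, `zones`, `reference_loss`.
#' @export
simulate_landscape <- function(config = landscape_config()) {
  seeds <- component_seeds(config$seed)
  structure_pair <- generate_structure(config)
  mort <- generate_mortality(config, structure_pair$upper)
  bundle <- list(
    config = config,
    structure = structure_pair,
    mortality = mort$polygons,
    truth = mort$truth,
    dem = generate_dem(config),
    roads = generate_roads(config),
    zones = generate_zones(config),
    reference_loss = generate_reference_loss(
      mort$truth, config$spec, config$noise_sd_log,
      seed = seeds[["reference"]],
      gain_fraction = config$reference_gain_fraction)
  )
  class(bundle) <- "landscape"
  bundle
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d px, %d mortality polygons over %d years, seed %d\n",
              x$config$spec$n_rows, x$config$spec$n_cols, nrow(x$mortality),
              length(x$config$years), x$config$seed))
  invisible(x)
}

#' Write a landscape bundle to disk
#'
#' Serialises a simulated bundle in the pipeline's exchange formats: ASCII
#' grids for every raster, GeoJSON for polygons/roads/zones, CSV for the
#' pixel-level ground truth and YAML for the resolved configuration.
#'
#' @param landscape A [simulate_landscape()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- landscape$config$spec
  for (v in c("upper", "lower")) {
    s <- landscape$structure[[v]]
    for (layer in c("tph", "bph", "vph")) {
      write_grid(s[[layer]], spec, file.path(dir, sprintf("%s_%s.asc", layer, v)))
    }
  }
  write_grid(landscape$dem, spec, file.path(dir, "dem.asc"))
  write_grid(landscape$reference_loss, spec, file.path(dir, "reference_loss.asc"))
  write_features(landscape$mortality$geometry,
                 landscape$mortality[, c("polygon_id", "year", "dead_trees")],
                 file.path(dir, "mortality.geojson"), type = "Polygon",
                 crs_id = spec$crs_id)
  if (length(landscape$roads) > 0) {
    write_features(landscape$roads, NULL, file.path(dir, "roads.geojson"),
                   type = "LineString", crs_id = spec$crs_id)
  }
  z <- landscape$zones
  zone_geoms <- c(z$wilderness_np, z$hhz_tier1, z$hhz_tier2, z$counties$geometry)
  zone_props <- tibble::tibble(
    zone = c(rep("wilderness_np", length(z$wilderness_np)),
             rep("hhz_tier1", length(z$hhz_tier1)),
             rep("hhz_tier2", length(z$hhz_tier2)),
             rep("county", nrow(z$counties))),
    name = c(rep(NA_character_, length(z$wilderness_np) + length(z$hhz_tier1) +
                   length(z$hhz_tier2)), z$counties$county))
  write_features(zone_geoms, zone_props, file.path(dir, "zones.geojson"),
                 type = "Polygon", crs_id = spec$crs_id)
  truth_df <- purrr::imap_dfr(landscape$truth$dt_by_year, function(m, y) {
    idx <- which(m > 0, arr.ind = TRUE)
    tibble::tibble(year = as.integer(y), row = idx[, 1], col = idx[, 2],
                   dead_trees = m[idx])
  })
  utils::write.csv(truth_df, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  cfg <- landscape$config
  cfg$spec <- unclass(cfg$spec)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
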