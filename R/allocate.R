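# Dead-biomass allocation: distribute each survey polygon's dead-tree count
# across its forested pixels proportionally to live tree density (with a
# per-pixel live-tree cap), convert counts to biomass via mean tree biomass,
# and accumulate across years under a live-biomass cap.

#' Allocate one polygon's dead-tree count to pixels
#'
#' Spreads a surveyed dead-tree count `DT_p` across the forested pixels of
#' the polygon proportionally to each pixel's live tree density, capping each
#' pixel at its live tree count:
#' `DT_i = min(DT_p * TPH_i / sum(TPH), TPH_i * A)` with `A` the pixel area
#' in hectares (0.09 at 30 m). Surplus truncated by the cap is not
#' redistributed; the shortfall is reported. Pixels without live trees
#' receive nothing. A polygon with dead trees but no forested pixels yields
#' zero allocation and a warning.
#'
#' @param coords Polygon ring (2-column coordinate matrix).
#' @param dead_trees Surveyed dead-tree count for the polygon (>= 0; may be
#'   fractional).
#' @param structure A [structure_grid()].
#' @return A tibble with columns `row`, `col`, `tph`, `dt` (allocated dead
#'   trees per pixel, forested member pixels only), with attributes
#'   `requested` and `allocated`.
#' @export
allocate_polygon <- function(coords, dead_trees, structure) {
  stopifnot(dead_trees >= 0)
  spec <- structure$spec
  member <- pixels_in_polygon(coords, spec)
  idx <- cbind(member$row, member$col)
  tph <- if (nrow(member)) structure$tph[idx] else numeric(0)
  keep <- tph > 0
  out <- tibble::tibble(row = member$row[keep], col = member$col[keep],
                        tph = tph[keep])
  tph_sum <- sum(out$tph)
  if (tph_sum == 0) {
    if (dead_trees > 0) {
      warning(sprintf("polygon with %.3g dead trees has no forested pixels; count unallocated",
                      dead_trees), call. = FALSE)
    }
    out$dt <- numeric(nrow(out))
  } else {
    cap <- out$tph * pixel_area_ha(spec)
    out$dt <- pmin(dead_trees * out$tph / tph_sum, cap)
  }
  attr(out, "requested") <- dead_trees
  attr(out, "allocated") <- sum(out$dt)
  out
}

#' Convert per-pixel dead-tree counts to dead biomass
#'
#' `DBM_i = DT_i * BPH_i / TPH_i`: each dead tree carries the pixel's mean
#' live tree biomass. Zero wherever there are no live trees (such pixels can
#' hold no allocated deaths).
#'
#' @param dt Matrix of dead trees per pixel.
#' @param structure A [structure_grid()] on the same grid.
#' @return Matrix of dead biomass (BDT per pixel).
#' @export
dead_biomass <- function(dt, structure) {
  stopifnot(nrow(dt) == structure$spec$n_rows, ncol(dt) == structure$spec$n_cols)
  dbm <- matrix(0, nrow(dt), ncol(dt))
  pos <- structure$tph > 0
  dbm[pos] <- dt[pos] * structure$bph[pos] / structure$tph[pos]
  dbm
}

#' Accumulate yearly dead biomass under the live-biomass cap
#'
#' Sums per-year dead biomass into a cumulative total and caps each pixel at
#' its live biomass, `TDBM_i = min(sum_t DBM_i_t, BPH_i * A)`. Yearly layers
#' are left uncorrected (the correction cannot be parsed across years); only
#' the cumulative total is capped. The fraction of pixels corrected and the
#' biomass removed by the correction are reported.
#'
#' @param dbm_by_year Named list of per-year dead-biomass matrices on one
#'   grid.
#' @param structure A [structure_grid()] on the same grid.
#' @return A list: `tdbm` (matrix), `corrections` (list with
#'   `n_pixels_corrected`, `frac_pixels_corrected` of pixels with any dead
#'   biomass, `biomass_removed`, `frac_biomass_removed`).
#' @export
accumulate_dead_biomass <- function(dbm_by_year, structure) {
  spec <- structure$spec
  for (m in dbm_by_year) {
    stopifnot(nrow(m) == spec$n_rows, ncol(m) == spec$n_cols)
  }
  total <- Reduce(`+`, c(list(matrix(0, spec$n_rows, spec$n_cols)), dbm_by_year))
  cap <- structure$bph * pixel_area_ha(spec)
  tdbm <- pmin(total, cap)
  corrected <- total > cap
  n_dead <- sum(total > 0)
  removed <- sum(total - tdbm)
  list(
    tdbm = tdbm,
    corrections = list(
      n_pixels_corrected = sum(corrected),
      frac_pixels_corrected = if (n_dead > 0) sum(corrected) / n_dead else 0,
      biomass_removed = removed,
      frac_biomass_removed = if (sum(total) > 0) removed / sum(total) else 0
    )
  )
}

#' Run the full allocation for one detection variant
#'
#' @param polygons Tibble of mortality polygons (`polygon_id`, `year`,
#'   `dead_trees`, `geometry` list-column).
#' @param structure A [structure_grid()].
#' @return An object of class `dead_biomass_grid`: `spec`, `variant`,
#'   `dt_by_year` and `dbm_by_year` (named lists of matrices), `tdbm`
#'   (capped cumulative matrix), `corrections`, and `diagnostics` (tibble of
#'   per-polygon requested vs allocated counts).
#' @export
allocate_variant <- function(polygons, structure) {
  spec <- structure$spec
  years <- sort(unique(polygons$year))
  dt_by_year <- lapply(years, function(y) matrix(0, spec$n_rows, spec$n_cols))
  names(dt_by_year) <- as.character(years)
  diags <- vector("list", nrow(polygons))
  for (i in seq_len(nrow(polygons))) {
    alloc <- allocate_polygon(polygons$geometry[[i]], polygons$dead_trees[i],
                              structure)
    y <- as.character(polygons$year[i])
    if (nrow(alloc)) {
      idx <- cbind(alloc$row, alloc$col)
      dt_by_year[[y]][idx] <- dt_by_year[[y]][idx] + alloc$dt
    }
    diags[[i]] <- tibble::tibble(
      polygon_id = polygons$polygon_id[i], year = polygons$year[i],
      requested = attr(alloc, "requested"),
      allocated = attr(alloc, "allocated"),
      n_pixels = nrow(alloc))
  }
  dbm_by_year <- lapply(dt_by_year, dead_biomass, structure = structure)
  acc <- accumulate_dead_biomass(dbm_by_year, structure)
  out <- list(spec = spec, variant = structure$variant,
              dt_by_year = dt_by_year, dbm_by_year = dbm_by_year,
              tdbm = acc$tdbm, corrections = acc$corrections,
              diagnostics = dplyr::bind_rows(diags))
  class(out) <- "dead_biomass_grid"
  out
}

#' @export
print.dead_biomass_grid <- function(x, ...) {
  cat(sprintf("<dead_biomass_grid> variant %s: %.1f BDT cumulative over %d years (%d polygons)\n",
              x$variant, sum(x$tdbm), length(x$dt_by_year), nrow(x$diagnostics)))
  invisible(x)
}

#' Run the allocation for both detection variants
#'
#' The same surveyed counts drive both variants: the >= 25 cm structure gives
#' the upper-bound biomass estimate (aerial counts attributed to large trees
#' only), the >= 2.5 cm structure the lower bound.
#'
#' @param polygons Mortality polygon tibble (as in [allocate_variant()]).
#' @param structures List with `upper` and `lower` [structure_grid()]s on one
#'   grid.
#' @return An object of class `dead_biomass_bounds`: `upper` and `lower`
#'   `dead_biomass_grid`s plus `yearly_totals`, a tibble of per-year biomass
#'   totals (BDT) per variant.
#' @export
run_allocation <- function(polygons, structures) {
  check_spec(structures$lower$spec, structures$upper$spec, "lower-variant structure")
  upper <- allocate_variant(polygons, structures$upper)
  lower <- allocate_variant(polygons, structures$lower)
  yearly <- dplyr::bind_rows(lapply(names(upper$dbm_by_year), function(y) {
    tibble::tibble(year = as.integer(y),
                   dbm_upper = sum(upper$dbm_by_year[[y]]),
                   dbm_lower = sum(lower$dbm_by_year[[y]]))
  }))
  structure(list(upper = upper, lower = lower, yearly_totals = yearly),
            class = "dead_biomass_bounds")
}

#' @export
print.dead_biomass_bounds <- function(x, ...) {
  cat(sprintf("<dead_biomass_bounds> cumulative dead biomass %.1f (lower) to %.1f (upper) BDT\n",
              sum(x$lower$tdbm), sum(x$upper$tdbm)))
  invisible(x)
}

#' Tidy per-year dead-biomass totals
#'
#' @param x A `dead_biomass_bounds` object.
#' @param ... Unused.
#' @return Tibble with `year`, `bound`, `dead_biomass_bdt` (uncorrected
#'   yearly totals, both variants).
#' @exportS3Method generics::tidy
tidy.dead_biomass_bounds <- function(x, ...) {
  tidyr::pivot_longer(x$yearly_totals, cols = c("dbm_upper", "dbm_lower"),
                      names_to = "bound", names_prefix = "dbm_",
                      values_to = "dead_biomass_bdt")
}

#' One-row summary of an allocation run
#'
#' @param x A `dead_biomass_bounds` object.
#' @param ... Unused.
#' @return Tibble with cumulative totals per bound, cap-correction fractions
#'   and unallocated counts.
#' @exportS3Method generics::glance
glance.dead_biomass_bounds <- function(x, ...) {
  tibble::tibble(
    tdbm_upper_bdt = sum(x$upper$tdbm),
    tdbm_lower_bdt = sum(x$lower$tdbm),
    frac_pixels_corrected_upper = x$upper$corrections$frac_pixels_corrected,
    frac_biomass_removed_upper = x$upper$corrections$frac_biomass_removed,
    unallocated_upper = sum(x$upper$diagnostics$requested -
                              x$upper$diagnostics$allocated),
    unallocated_lower = sum(x$lower$diagnostics$requested -
                              x$lower$diagnostics$allocated)
  )
}
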