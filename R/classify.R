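# Harvest-cost classification of feasible pixels: on-site chipping size
# class, terrain-slope class, road proximity, hazard-zone tier, county, and
# the derived cost-effective subset.

#' Percent slope from a DEM (Horn's method)
#'
#' Terrain slope as 100 x rise/run, with the gradient estimated by Horn's
#' 3 x 3 weighted finite differences; edge pixels use clamped (replicated)
#' neighbourhoods so the operator is defined everywhere.
#'
#' @param dem Elevation matrix (m) on the analysis grid (row 1 = north).
#' @param spec The [grid_spec()] supplying the pixel size.
#' @return Matrix of percent slope.
#' @export
slope_percent <- function(dem, spec) {
  stopifnot(nrow(dem) == spec$n_rows, ncol(dem) == spec$n_cols)
  nr <- nrow(dem); nc <- ncol(dem)
  up <- dem[c(1, seq_len(nr - 1)), , drop = FALSE]      # row above (clamped)
  dn <- dem[c(seq_len(nr - 1) + 1, nr), , drop = FALSE] # row below
  lf <- function(m) m[, c(1, seq_len(nc - 1)), drop = FALSE]  # col left
  rt <- function(m) m[, c(seq_len(nc - 1) + 1, nc), drop = FALSE] # col right
  cell <- spec$pixel_size
  # Horn: dz/dx from the east minus west columns, corners weighted 1, edges 2
  dzdx <- ((rt(up) + 2 * rt(dem) + rt(dn)) - (lf(up) + 2 * lf(dem) + lf(dn))) /
    (8 * cell)
  # dz/dy: north minus south rows (y decreases with row index)
  dzdy <- ((lf(up) + 2 * up + rt(up)) - (lf(dn) + 2 * dn + rt(dn))) / (8 * cell)
  100 * sqrt(dzdx^2 + dzdy^2)
}

pixels_in_any <- function(polys, spec) {
  inside <- matrix(FALSE, spec$n_rows, spec$n_cols)
  for (coords in polys) {
    member <- pixels_in_polygon(coords, spec)
    if (nrow(member)) inside[cbind(member$row, member$col)] <- TRUE
  }
  inside
}

#' Build the per-pixel feedstock classification table
#'
#' For every retained (feasible, positive dead biomass) pixel, records both
#' biomass bounds and the cost-classification labels:
#' * `vpt_class`: `onsite_chippable` (vpt <= 2.26 m^3, the on-site
#'   mechanical chipping limit) vs `facility_only` (2.26 < vpt < 11.32 m^3);
#' * `slope_class`: `ground` (< 30%), `transitional` (30-40%, closed below,
#'   open above) or `cable_heli` (>= 40%);
#' * `road_class`: `near` (<= `road_cutoff` m straight-line to the nearest
#'   road, inclusive) vs `far`;
#' * HHZ tier membership (tiers may overlap) and county;
#' * `cost_effective`: vpt <= 2.26 and slope < 40 and road distance <= the
#'   cutoff.
#'
#' @param feas A `feasibility_result` from [apply_feasibility()] (its
#'   upper-bound footprint defines the retained pixels).
#' @param structure Upper-bound [structure_grid()] (mean tree volume).
#' @param dem Elevation matrix on the analysis grid.
#' @param roads Road network (list of coordinate matrices; may be empty, in
#'   which case every pixel is `far`).
#' @param zones A `zone_set` with HHZ tiers and counties.
#' @param vpt_onsite On-site chipping limit (m^3/tree), default 2.26.
#' @param slope_breaks Slope class breaks (%), default `c(30, 40)`.
#' @param road_cutoff Road-access cutoff (m), default 2000.
#' @return A tibble of class `pixel_feedstock` with one row per retained
#'   pixel: `row`, `col`, `x`, `y`, `tdbm_upper`, `tdbm_lower`, `vpt`,
#'   `vpt_class`, `slope_percent`, `slope_class`, `road_dist_m`,
#'   `road_class`, `hhz_tier1`, `hhz_tier2`, `county`, `cost_effective`.
#' @export
classify_pixels <- function(feas, structure, dem, roads, zones,
                            vpt_onsite = 2.26, slope_breaks = c(30, 40),
                            road_cutoff = 2000) {
  spec <- feas$upper$spec
  idx <- which(feas$upper$tdbm > 0, arr.ind = TRUE)
  tab <- pixel_centers(spec, idx[, 1], idx[, 2])
  tab$tdbm_upper <- feas$upper$tdbm[idx]
  tab$tdbm_lower <- feas$lower$tdbm[idx]
  vpt <- mean_tree_volume(structure)
  tab$vpt <- vpt[idx]
  tab$vpt_class <- ifelse(tab$vpt <= vpt_onsite, "onsite_chippable",
                          "facility_only")
  slope <- slope_percent(dem, spec)
  tab$slope_percent <- slope[idx]
  tab$slope_class <- dplyr::case_when(
    tab$slope_percent < slope_breaks[1] ~ "ground",
    tab$slope_percent < slope_breaks[2] ~ "transitional",
    TRUE ~ "cable_heli")
  tab$road_dist_m <- distance_to_nearest_road(tab$x, tab$y, roads)
  tab$road_class <- ifelse(tab$road_dist_m <= road_cutoff, "near", "far")
  t1 <- pixels_in_any(zones$hhz_tier1, spec)
  t2 <- pixels_in_any(zones$hhz_tier2, spec)
  tab$hhz_tier1 <- t1[idx]
  tab$hhz_tier2 <- t2[idx]
  county <- rep(NA_character_, nrow(tab))
  for (i in seq_len(nrow(zones$counties))) {
    inside <- pixels_in_any(zones$counties$geometry[i], spec)
    county[inside[idx] & is.na(county)] <- zones$counties$county[i]
  }
  tab$county <- county
  tab$cost_effective <- tab$vpt <= vpt_onsite &
    tab$slope_percent < slope_breaks[2] & tab$road_dist_m <= road_cutoff
  class(tab) <- c("pixel_feedstock", class(tab))
  tab
}

#' Summarise the feedstock table into reporting tables
#'
#' Produces the standard accounting views of the classified feedstock, all
#' in BDT with both bounds:
#' * `criteria`: per cost-effectiveness criterion (chipping size, slope,
#'   road access), biomass passing vs failing — the classes within each
#'   criterion partition the feasible total;
#' * `hhz`: feasible and cost-effective biomass by hazard-zone tier, a
#'   combined "total in HHZ" over the tier union (tiers may overlap, so the
#'   per-tier rows can sum to more than the union), and a no-HHZ row;
#' * `county`: per-county gross, feasible and cost-effective totals with the
#'   cost-effective proportion of gross as a percentage rounded to 2
#'   decimals (computed from unrounded totals); pixels outside every county
#'   are dropped from this table;
#' * `county_hhz`: per-county feasible and cost-effective totals within each
#'   tier.
#'
#' @param table A [classify_pixels()] tibble.
#' @param gross A `dead_biomass_bounds` (pre-filter totals for the county
#'   gross column); optional — when absent the gross columns are `NA`.
#' @param zones The `zone_set` used for classification (county geometries,
#'   needed to attribute gross biomass to counties); optional with `gross`.
#' @return A list of tibbles: `criteria`, `hhz`, `county`, `county_hhz`.
#' @export
summarize_feedstock <- function(table, gross = NULL, zones = NULL) {
  sum_b <- function(rows) c(lower = sum(table$tdbm_lower[rows]),
                            upper = sum(table$tdbm_upper[rows]))
  criteria <- dplyr::bind_rows(
    tibble::tibble(criterion = "onsite_chipping",
                   pass = list(table$vpt_class == "onsite_chippable")),
    tibble::tibble(criterion = "ground_based_slope",
                   pass = list(table$slope_class %in% c("ground", "transitional"))),
    tibble::tibble(criterion = "road_access",
                   pass = list(table$road_class == "near"))
  )
  criteria <- dplyr::mutate(criteria,
    not_ce_lower = purrr::map_dbl(.data$pass, ~ sum(table$tdbm_lower[!.x])),
    ce_lower = purrr::map_dbl(.data$pass, ~ sum(table$tdbm_lower[.x])),
    not_ce_upper = purrr::map_dbl(.data$pass, ~ sum(table$tdbm_upper[!.x])),
    ce_upper = purrr::map_dbl(.data$pass, ~ sum(table$tdbm_upper[.x])))
  criteria$pass <- NULL

  ce <- table$cost_effective
  hhz_row <- function(label, members) {
    tibble::tibble(hhz = label,
                   feasible_lower = sum(table$tdbm_lower[members]),
                   feasible_upper = sum(table$tdbm_upper[members]),
                   cost_effective_lower = sum(table$tdbm_lower[members & ce]),
                   cost_effective_upper = sum(table$tdbm_upper[members & ce]))
  }
  hhz <- dplyr::bind_rows(
    hhz_row("tier1", table$hhz_tier1),
    hhz_row("tier2", table$hhz_tier2),
    hhz_row("total_in_hhz", table$hhz_tier1 | table$hhz_tier2),
    hhz_row("no_hhz", !(table$hhz_tier1 | table$hhz_tier2)))

  county <- table |>
    dplyr::filter(!is.na(.data$county)) |>
    dplyr::group_by(.data$county) |>
    dplyr::summarise(
      feasible_upper = sum(.data$tdbm_upper),
      feasible_lower = sum(.data$tdbm_lower),
      cost_effective_upper = sum(.data$tdbm_upper[.data$cost_effective]),
      cost_effective_lower = sum(.data$tdbm_lower[.data$cost_effective]),
      .groups = "drop")
  if (!is.null(gross) && !is.null(zones)) {
    gr <- dplyr::bind_rows(lapply(seq_len(nrow(zones$counties)), function(i) {
      member <- pixels_in_polygon(zones$counties$geometry[[i]],
                                  gross$upper$spec)
      gidx <- cbind(member$row, member$col)
      tibble::tibble(county = zones$counties$county[i],
                     gross_upper = sum(gross$upper$tdbm[gidx]),
                     gross_lower = sum(gross$lower$tdbm[gidx]))
    }))
    county <- dplyr::left_join(gr, county, by = "county") |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                  ~ tidyr::replace_na(.x, 0)))
    county$ce_prop_gross_upper <- round(
      100 * county$cost_effective_upper / pmax(county$gross_upper, 1e-300), 2)
    county$ce_prop_gross_lower <- round(
      100 * county$cost_effective_lower / pmax(county$gross_lower, 1e-300), 2)
  }

  county_hhz <- table |>
    dplyr::filter(!is.na(.data$county)) |>
    tidyr::pivot_longer(cols = c("hhz_tier1", "hhz_tier2"), names_to = "tier",
                        names_prefix = "hhz_", values_to = "in_tier") |>
    dplyr::filter(.data$in_tier) |>
    dplyr::group_by(.data$county, .data$tier) |>
    dplyr::summarise(
      feasible_upper = sum(.data$tdbm_upper),
      feasible_lower = sum(.data$tdbm_lower),
      cost_effective_upper = sum(.data$tdbm_upper[.data$cost_effective]),
      cost_effective_lower = sum(.data$tdbm_lower[.data$cost_effective]),
      .groups = "drop")

  list(criteria = criteria, hhz = hhz, county = county, county_hhz = county_hhz)
}

#' Plot cumulative biomass against a classification variable
#'
#' Running cumulative biomass (both bounds) as a function of mean tree
#' volume or slope, with the relevant class thresholds marked.
#'
#' @param table A [classify_pixels()] tibble.
#' @param by `"vpt"` or `"slope_percent"`.
#' @return A ggplot.
#' @export
plot_cumulative_biomass <- function(table, by = c("vpt", "slope_percent")) {
  by <- match.arg(by)
  breaks <- if (by == "vpt") c(2.26, 11.32) else c(30, 40)
  long <- table |>
    dplyr::arrange(.data[[by]]) |>
    dplyr::mutate(upper = cumsum(.data$tdbm_upper),
                  lower = cumsum(.data$tdbm_lower)) |>
    tidyr::pivot_longer(cols = c("upper", "lower"), names_to = "bound",
                        values_to = "cumulative_bdt")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[by]], y = .data$cumulative_bdt,
                                     colour = .data$bound)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = breaks, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = if (by == "vpt") "Mean tree volume (m³)" else
      "Slope (%)", y = "Cumulative dead biomass (BDT)") +
    ggplot2::theme_minimal()
}
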