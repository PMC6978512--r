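# Energy and carbon accounting: biomass-to-electricity conversion for boiler
# and small-scale gasifier technologies, plant supply-years, facility-radius
# feedstock queries, and biomass-to-carbon mass.

#' Energy conversion parameters
#'
#' Feedstock-to-electricity conversion factors: ~1 BDT/MWh for conventional
#' boiler plants (consistent with an 18-22 GJ/t calorific value, 30% chip
#' moisture and ~90% boiler thermal efficiency) and ~4.7 BDT/MWh for
#' small-scale gasifier-generator systems, with an 80% plant capacity factor.
#'
#' @param bdt_per_mwh_boiler,bdt_per_mwh_gasifier Feedstock demand per MWh.
#' @param capacity_factor Plant capacity factor in (0, 1].
#' @return A list of class `energy_params`.
#' @export
energy_params <- function(bdt_per_mwh_boiler = 1.0, bdt_per_mwh_gasifier = 4.7,
                          capacity_factor = 0.80) {
  stopifnot(bdt_per_mwh_boiler > 0, bdt_per_mwh_gasifier > 0,
            capacity_factor > 0, capacity_factor <= 1)
  structure(list(bdt_per_mwh_boiler = bdt_per_mwh_boiler,
                 bdt_per_mwh_gasifier = bdt_per_mwh_gasifier,
                 capacity_factor = capacity_factor),
            class = "energy_params")
}

#' Carbon accounting parameters
#'
#' A bone-dry ton is 2,000 lb (907.18474 kg) of woody material at 0%
#' moisture; the carbon fraction of dry wood defaults to 0.47.
#'
#' @param kg_per_bdt Mass of one BDT in kg.
#' @param carbon_fraction Carbon mass fraction of dry wood, in (0, 1).
#' @return A list of class `carbon_params`.
#' @export
carbon_params <- function(kg_per_bdt = 907.18474, carbon_fraction = 0.47) {
  stopifnot(kg_per_bdt > 0, carbon_fraction > 0, carbon_fraction < 1)
  structure(list(kg_per_bdt = kg_per_bdt, carbon_fraction = carbon_fraction),
            class = "carbon_params")
}

bdt_per_mwh <- function(params, technology = c("boiler", "gasifier")) {
  technology <- match.arg(technology)
  if (technology == "boiler") params$bdt_per_mwh_boiler else
    params$bdt_per_mwh_gasifier
}

#' Convert biomass to electricity
#'
#' @param biomass Feedstock (BDT, >= 0; vectorised).
#' @param params An [energy_params()].
#' @param technology `"boiler"` or `"gasifier"`.
#' @return Electricity (MWh).
#' @export
bdt_to_mwh <- function(biomass, params = energy_params(),
                       technology = c("boiler", "gasifier")) {
  if (any(biomass < 0)) stop("biomass must be non-negative", call. = FALSE)
  biomass / bdt_per_mwh(params, technology)
}

#' Annual plant generation
#'
#' `MW * 8760 h * capacity factor`, in TWh/yr. The unrounded value is
#' returned; rounding belongs in the report layer.
#'
#' @param plant_mw Nameplate capacity (MW).
#' @param capacity_factor Capacity factor in (0, 1].
#' @return Annual generation (TWh/yr).
#' @export
annual_generation <- function(plant_mw, capacity_factor = 0.80) {
  stopifnot(plant_mw >= 0, capacity_factor > 0, capacity_factor <= 1)
  plant_mw * 8760 * capacity_factor / 1e6
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Years of feedstock supply for a plant
#'
#' How long a biomass stock can feed a plant of given annual generation:
#' `biomass / (annual TWh * 1e6 MWh/TWh * BDT/MWh)`, rounded to the nearest
#' whole year (half away from zero).
#'
#' @param biomass Feedstock stock (BDT).
#' @param annual_twh Plant annual generation (TWh/yr), > 0. Passing the
#'   published round figure for a plant (rather than
#'   [annual_generation()]'s exact value) reproduces headline supply-year
#'   numbers computed from that figure.
#' @param params An [energy_params()].
#' @param technology `"boiler"` or `"gasifier"`.
#' @return Whole years (vectorised over `biomass`).
#' @export
years_of_supply <- function(biomass, annual_twh, params = energy_params(),
                            technology = c("boiler", "gasifier")) {
  if (annual_twh <= 0) stop("annual generation must be positive", call. = FALSE)
  annual_bdt <- annual_twh * 1e6 * bdt_per_mwh(params, technology)
  round_half_away(biomass / annual_bdt)
}

#' Feedstock within radii of a facility site
#'
#' Sums feasible and cost-effective biomass (both bounds) over pixels whose
#' centres lie within each Euclidean radius of a prospective or existing
#' facility. Nested radii give non-decreasing totals.
#'
#' @param table A [classify_pixels()] tibble.
#' @param site Numeric length-2 vector `c(x, y)` in the grid CRS.
#' @param radii Radii (m).
#' @return Tibble: `radius_m`, `feasible_lower`, `feasible_upper`,
#'   `cost_effective_lower`, `cost_effective_upper` (BDT).
#' @export
facility_radius_feedstock <- function(table, site, radii) {
  stopifnot(length(site) == 2, all(radii >= 0))
  d2 <- (table$x - site[1])^2 + (table$y - site[2])^2
  ce <- table$cost_effective
  dplyr::bind_rows(lapply(sort(radii), function(r) {
    m <- d2 <= r^2
    tibble::tibble(radius_m = r,
                   feasible_lower = sum(table$tdbm_lower[m]),
                   feasible_upper = sum(table$tdbm_upper[m]),
                   cost_effective_lower = sum(table$tdbm_lower[m & ce]),
                   cost_effective_upper = sum(table$tdbm_upper[m & ce]))
  }))
}

#' Convert biomass to carbon mass
#'
#' `Tg C = BDT * kg/BDT * carbon fraction / 1e9`.
#'
#' @param biomass Biomass (BDT; vectorised).
#' @param params A [carbon_params()].
#' @return Carbon mass (Tg).
#' @export
bdt_to_tg_carbon <- function(biomass, params = carbon_params()) {
  biomass * params$kg_per_bdt * params$carbon_fraction / 1e9
}
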