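# End-to-end orchestration: configuration, the allocate -> filter ->
# classify -> energy -> validate sequence, report tables and serialisation.

#' Pipeline configuration
#'
#' Gathers every tunable threshold of the pipeline with the standard
#' defaults: DBSCAN minimum cluster size 112 pixels (~10 ha), epsilon sweep
#' 180-400 m in 20-m steps (or a fixed `eps`), facility chipping limit
#' 11.32 m^3/tree, on-site chipping limit 2.26 m^3/tree, minimum dead-tree
#' density 2.5/ha, slope class breaks 30/40%, road cutoff 2000 m, and the
#' energy/carbon parameters. Serialisable to YAML so a run can record its
#' resolved configuration next to its outputs.
#'
#' @param seed Seed forwarded to the synthetic generator when the pipeline
#'   simulates its own inputs.
#' @param eps Fixed isolation radius (m) or `NULL` to select it from the
#'   trade-off curve.
#' @param eps_values Epsilon sweep for the trade-off curve.
#' @param min_pts Minimum cluster size (pixels).
#' @param vpt_max Facility chipping limit (m^3/tree).
#' @param vpt_onsite On-site chipping limit (m^3/tree).
#' @param min_dead_density Minimum cumulative dead-tree density (trees/ha).
#' @param slope_breaks Slope class breaks (%).
#' @param road_cutoff Road-access cutoff (m).
#' @param min_polygon_area Validation minimum polygon area (m^2).
#' @param energy An [energy_params()].
#' @param carbon A [carbon_params()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, eps = NULL,
                            eps_values = seq(180, 400, by = 20),
                            min_pts = 112, vpt_max = 11.32,
                            vpt_onsite = 2.26, min_dead_density = 2.5,
                            slope_breaks = c(30, 40), road_cutoff = 2000,
                            min_polygon_area = 2700,
                            energy = energy_params(),
                            carbon = carbon_params()) {
  cfg <- list(seed = as.integer(seed), eps = eps, eps_values = eps_values,
              min_pts = min_pts, vpt_max = vpt_max, vpt_onsite = vpt_onsite,
              min_dead_density = min_dead_density,
              slope_breaks = slope_breaks, road_cutoff = road_cutoff,
              min_polygon_area = min_polygon_area, energy = energy,
              carbon = carbon)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  x <- lapply(unclass(config), function(v) if (is.list(v)) unclass(v) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(seed = x$seed, eps = x$eps,
                  eps_values = unlist(x$eps_values), min_pts = x$min_pts,
                  vpt_max = x$vpt_max, vpt_onsite = x$vpt_onsite,
                  min_dead_density = x$min_dead_density,
                  slope_breaks = unlist(x$slope_breaks),
                  road_cutoff = x$road_cutoff,
                  min_polygon_area = x$min_polygon_area,
                  energy = do.call(energy_params, x$energy),
                  carbon = do.call(carbon_params, x$carbon))
}

#' Run the full pipeline on a landscape bundle
#'
#' Sequences allocation, feasibility filtering, cost classification, energy
#' and carbon accounting, and (when the bundle carries a reference loss
#' raster) polygon-level validation. Deterministic given the bundle and
#' configuration.
#'
#' @param landscape A [simulate_landscape()] bundle (or any list with the
#'   same elements built from files).
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: `config`, `bounds`
#'   (allocation), `feasibility`, `pixels` (classification table),
#'   `summaries` (report tables), `energy` (potentials/supply tibble),
#'   `carbon` (Tg C tibble), `validation` (records or `NULL`), and
#'   `validation_summary`.
#' @export
run_pipeline <- function(landscape, config = pipeline_config()) {
  bounds <- run_allocation(landscape$mortality, landscape$structure)
  feas <- apply_feasibility(
    bounds, landscape$zones, landscape$structure$upper, eps = config$eps,
    eps_values = config$eps_values, min_pts = config$min_pts,
    vpt_max = config$vpt_max, min_dead_density = config$min_dead_density)
  pixels <- classify_pixels(
    feas, landscape$structure$upper, landscape$dem, landscape$roads,
    landscape$zones, vpt_onsite = config$vpt_onsite,
    slope_breaks = config$slope_breaks, road_cutoff = config$road_cutoff)
  summaries <- summarize_feedstock(pixels, gross = bounds,
                                   zones = landscape$zones)
  totals <- tibble::tibble(
    subset = c("gross", "feasible", "cost_effective"),
    lower_bdt = c(sum(bounds$lower$tdbm), sum(feas$lower$tdbm),
                  sum(pixels$tdbm_lower[pixels$cost_effective])),
    upper_bdt = c(sum(bounds$upper$tdbm), sum(feas$upper$tdbm),
                  sum(pixels$tdbm_upper[pixels$cost_effective])))
  energy <- totals |>
    dplyr::mutate(
      boiler_twh_lower = bdt_to_mwh(.data$lower_bdt, config$energy, "boiler") / 1e6,
      boiler_twh_upper = bdt_to_mwh(.data$upper_bdt, config$energy, "boiler") / 1e6,
      gasifier_twh_lower = bdt_to_mwh(.data$lower_bdt, config$energy, "gasifier") / 1e6,
      gasifier_twh_upper = bdt_to_mwh(.data$upper_bdt, config$energy, "gasifier") / 1e6)
  carbon <- totals |>
    dplyr::mutate(tg_c_lower = bdt_to_tg_carbon(.data$lower_bdt, config$carbon),
                  tg_c_upper = bdt_to_tg_carbon(.data$upper_bdt, config$carbon))
  validation <- NULL; validation_summary <- NULL
  if (!is.null(landscape$reference_loss)) {
    validation <- polygon_comparison(
      landscape$mortality, bounds, landscape$reference_loss, feas = feas,
      structures = landscape$structure,
      min_polygon_area = config$min_polygon_area)
    validation_summary <- glance.validation_records(validation)
  }
  out <- list(config = config, bounds = bounds, feasibility = feas,
              pixels = pixels, summaries = summaries, totals = totals,
              energy = energy, carbon = carbon, validation = validation,
              validation_summary = validation_summary)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  t <- x$totals
  cat("<pipeline_result>\n")
  cat(sprintf("  gross          %12.1f - %12.1f BDT\n", t$lower_bdt[1], t$upper_bdt[1]))
  cat(sprintf("  feasible       %12.1f - %12.1f BDT (eps = %g m)\n",
              t$lower_bdt[2], t$upper_bdt[2], x$feasibility$eps))
  cat(sprintf("  cost-effective %12.1f - %12.1f BDT\n", t$lower_bdt[3], t$upper_bdt[3]))
  if (!is.null(x$validation_summary)) {
    cat(sprintf("  validation log-RMSE %.3f (upper) / %.3f (lower) over %d polygons\n",
                x$validation_summary$log_rmse_upper,
                x$validation_summary$log_rmse_lower,
                x$validation_summary$n_included))
  }
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return Tibble with gross/feasible/cost-effective totals per bound, the
#'   selected epsilon and validation log-RMSEs.
#' @exportS3Method generics::glance
glance.pipeline_result <- function(x, ...) {
  t <- x$totals
  tibble::tibble(
    gross_lower_bdt = t$lower_bdt[1], gross_upper_bdt = t$upper_bdt[1],
    feasible_lower_bdt = t$lower_bdt[2], feasible_upper_bdt = t$upper_bdt[2],
    cost_effective_lower_bdt = t$lower_bdt[3],
    cost_effective_upper_bdt = t$upper_bdt[3],
    eps_m = x$feasibility$eps,
    log_rmse_upper = if (is.null(x$validation_summary)) NA_real_ else
      x$validation_summary$log_rmse_upper,
    log_rmse_lower = if (is.null(x$validation_summary)) NA_real_ else
      x$validation_summary$log_rmse_lower)
}

#' Write pipeline outputs to a directory
#'
#' Emits the cumulative dead-biomass grids (gross and feasible, both
#' bounds), the pixel classification table, every report table, the
#' trade-off curve when one was swept, the yearly totals, the validation
#' records, and the resolved configuration. All tables are CSV; grids are
#' ASCII grids with CRS sidecars.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- result$bounds$upper$spec
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  write_grid(result$bounds$upper$tdbm, spec, file.path(dir, "tdbm_gross_upper.asc"))
  write_grid(result$bounds$lower$tdbm, spec, file.path(dir, "tdbm_gross_lower.asc"))
  write_grid(result$feasibility$upper$tdbm, spec, file.path(dir, "tdbm_feasible_upper.asc"))
  write_grid(result$feasibility$lower$tdbm, spec, file.path(dir, "tdbm_feasible_lower.asc"))
  wcsv(result$pixels, "pixel_feedstock")
  wcsv(result$bounds$yearly_totals, "yearly_totals")
  wcsv(result$feasibility$reduction_ledger, "reduction_ledger")
  if (!is.null(result$feasibility$curve)) wcsv(result$feasibility$curve, "tradeoff_curve")
  wcsv(result$summaries$criteria, "criteria_summary")
  wcsv(result$summaries$hhz, "hhz_summary")
  wcsv(result$summaries$county, "county_summary")
  wcsv(result$summaries$county_hhz, "county_hhz_summary")
  wcsv(result$totals, "totals")
  wcsv(result$energy, "energy_potential")
  wcsv(result$carbon, "carbon")
  if (!is.null(result$validation)) {
    wcsv(result$validation, "validation_records")
    wcsv(result$validation_summary, "validation_summary")
  }
  write_pipeline_config(result$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Plot yearly dead-biomass totals
#'
#' Uncorrected per-year dead biomass for both bounds (the cumulative cap
#' cannot be parsed across years, so yearly bars are shown uncorrected).
#'
#' @param bounds A `dead_biomass_bounds` (or `pipeline_result`).
#' @return A ggplot.
#' @export
plot_yearly_totals <- function(bounds) {
  if (inherits(bounds, "pipeline_result")) bounds <- bounds$bounds
  long <- tidy.dead_biomass_bounds(bounds)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$year),
                                     y = .data$dead_biomass_bdt,
                                     fill = .data$bound)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Survey year", y = "Dead biomass (BDT)",
                  fill = "Bound") +
    ggplot2::theme_minimal()
}
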