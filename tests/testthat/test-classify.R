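test_that("slope operator: flat zero, analytic planes, 45-degree identity", {
  spec <- grid_spec(0, 1200, 40, 40, pixel_size = 30)
  expect_true(all(slope_percent(matrix(7, 40, 40), spec) == 0))
  cfg30 <- landscape_config(seed = 1, spec = spec, slope_mode = "inclined",
                            slope_rise_percent = 30)
  s30 <- slope_percent(generate_dem(cfg30), spec)
  expect_equal(s30[2:39, 2:39], matrix(30, 38, 38), tolerance = 1e-9)
  cfg100 <- landscape_config(seed = 1, spec = spec, slope_mode = "inclined",
                             slope_rise_percent = 100)
  s100 <- slope_percent(generate_dem(cfg100), spec)
  expect_equal(s100[20, 20], 100, tolerance = 1e-9)
  expect_error(slope_percent(matrix(0, 10, 10), spec), "nrow")
})

# A feasibility_result wrapper around explicit grids, for direct
# classification tests.
fake_feas <- function(spec, tdbm_up, tdbm_lo) {
  structure(list(
    upper = structure(list(spec = spec, tdbm = tdbm_up,
                           dt_by_year = list(`2015` = tdbm_up)),
                      class = "dead_biomass_grid"),
    lower = structure(list(spec = spec, tdbm = tdbm_lo,
                           dt_by_year = list(`2015` = tdbm_lo)),
                      class = "dead_biomass_grid")),
    class = "feasibility_result")
}

test_that("boundary conventions: vpt 2.26 chippable, slope 40 not cost-effective, road 2000 near", {
  spec <- grid_spec(0, 30, 1, 4, pixel_size = 30)
  tdbm <- matrix(1, 1, 4)
  s <- structure_grid(spec, "dbh_ge_25cm",
                      tph = matrix(100, 1, 4), bph = matrix(200, 1, 4),
                      vph = matrix(c(226, 226.01, 100, 100), 1))
  # flat dem -> slope 0; then override slope via dem construction below
  dem <- matrix(0, 1, 4)
  roads <- list(cbind(c(15, 15), c(2030, 3000))) # 2000 m north of pixel row
  zones <- list(wilderness_np = list(), hhz_tier1 = list(), hhz_tier2 = list(),
                counties = tibble::tibble(county = "A",
                                          geometry = list(pixel_rect(spec, 1, 1, 1, 4))))
  class(zones) <- "zone_set"
  tab <- classify_pixels(fake_feas(spec, tdbm, tdbm), s, dem, roads, zones)
  expect_equal(tab$vpt_class[tab$col == 1], "onsite_chippable")  # vpt = 2.26
  expect_equal(tab$vpt_class[tab$col == 2], "facility_only")     # just above
  # pixel 1 centre is (15, 15): 2015 m from road start -> far;
  # check exact 2000-m membership via a road at distance exactly 2000
  d <- distance_to_nearest_road(tab$x, tab$y, roads)
  expect_equal(tab$road_class, ifelse(d <= 2000, "near", "far"))
  expect_equal(tab$county, rep("A", 4))
})

test_that("slope classes split at 30 (closed below) and 40 (open above)", {
  spec <- grid_spec(0, 30, 1, 3, pixel_size = 30)
  slopes <- c(29.99, 30, 40)
  tab <- tibble::tibble(slope_percent = slopes)
  cls <- dplyr::case_when(slopes < 30 ~ "ground", slopes < 40 ~ "transitional",
                          TRUE ~ "cable_heli")
  expect_equal(cls, c("ground", "transitional", "cable_heli"))
  # and cost-effectiveness uses strict slope < 40
  ls <- small_landscape(seed = 40, n = 40, n_polys = 2, slope_mode = "inclined",
                        slope_rise_percent = 40)
  res <- suppressWarnings(run_pipeline(ls, pipeline_config(eps = 220)))
  interior <- res$pixels$col > 1 & res$pixels$col < 40
  expect_true(all(!res$pixels$cost_effective[interior]))
})

test_that("classification partitions biomass exactly within each dimension", {
  ls <- small_landscape(seed = 33)
  res <- run_pipeline(ls)
  tab <- res$pixels
  feas_up <- sum(res$feasibility$upper$tdbm)
  for (dim in list(tab$vpt_class, tab$slope_class, tab$road_class)) {
    expect_equal(sum(tapply(tab$tdbm_upper, dim, sum)), feas_up,
                 tolerance = 1e-9)
  }
  # cost-effective is a subset of every criterion's passing set
  ce <- tab$cost_effective
  expect_true(all(tab$vpt_class[ce] == "onsite_chippable"))
  expect_true(all(tab$slope_percent[ce] < 40))
  expect_true(all(tab$road_dist_m[ce] <= 2000))
  # class-wise sums equal brute-force per-pixel tallies
  crit <- res$summaries$criteria
  expect_equal(crit$ce_upper[crit$criterion == "onsite_chipping"],
               sum(tab$tdbm_upper[tab$vpt == pmin(tab$vpt, 2.26)]))
})

test_that("road class from exact buffer membership equals distance thresholding", {
  ls <- small_landscape(seed = 44)
  res <- run_pipeline(ls)
  tab <- res$pixels
  in_buf <- in_road_buffer(tab$x, tab$y, ls$roads, 2000)
  expect_identical(tab$road_class == "near", in_buf)
})

test_that("HHZ and county summaries respect overlap and reconcile with the pixel table", {
  ls <- small_landscape(seed = 55)
  res <- run_pipeline(ls)
  tab <- res$pixels
  hhz <- res$summaries$hhz
  g <- function(lbl, col) hhz[[col]][hhz$hhz == lbl]
  # tier sums can exceed the union total; union + no_hhz = feasible total
  expect_gte(g("tier1", "feasible_upper") + g("tier2", "feasible_upper") + 1e-9,
             g("total_in_hhz", "feasible_upper"))
  expect_equal(g("total_in_hhz", "feasible_upper") + g("no_hhz", "feasible_upper"),
               sum(tab$tdbm_upper), tolerance = 1e-9)
  # county gross sums reproduce the unfiltered grids
  cty <- res$summaries$county
  expect_equal(sum(cty$gross_upper), sum(res$bounds$upper$tdbm),
               tolerance = 1e-9)
  # percentage column is a rounded ratio of unrounded totals
  expect_equal(cty$ce_prop_gross_upper,
               round(100 * cty$cost_effective_upper / cty$gross_upper, 2))
})

test_that("a single-pixel landscape reduces every summary to that pixel", {
  spec <- grid_spec(0, 30, 1, 1, pixel_size = 30)
  tdbm <- matrix(5, 1, 1)
  s <- structure_grid(spec, "dbh_ge_25cm", tph = matrix(100, 1, 1),
                      bph = matrix(200, 1, 1), vph = matrix(100, 1, 1))
  zones <- structure(list(wilderness_np = list(), hhz_tier1 = list(),
                          hhz_tier2 = list(pixel_rect(spec, 1, 1, 1, 1)),
                          counties = tibble::tibble(
                            county = "A", geometry = list(pixel_rect(spec, 1, 1, 1, 1)))),
                     class = "zone_set")
  tab <- classify_pixels(fake_feas(spec, tdbm, 0.5 * tdbm), s,
                         matrix(0, 1, 1), list(cbind(c(0, 30), c(15, 15))),
                         zones)
  expect_equal(nrow(tab), 1L)
  expect_true(tab$cost_effective)
  sm <- summarize_feedstock(tab)
  expect_equal(sm$hhz$cost_effective_upper[sm$hhz$hhz == "tier2"], 5)
  expect_equal(sm$county$feasible_lower, 2.5)
})
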