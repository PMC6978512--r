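test_that("standard distance: single point, square corners, translation invariance", {
  expect_equal(standard_distance(5, 7), 0)
  # corners of a 30-m square at (+-15, +-15): sqrt(225 + 225)
  x <- c(-15, 15, 15, -15); y <- c(-15, -15, 15, 15)
  expect_equal(standard_distance(x, y), sqrt(450), tolerance = 1e-12)
  expect_equal(standard_distance(x + 1e4, y - 2e3), sqrt(450), tolerance = 1e-9)
  expect_error(standard_distance(numeric(0), numeric(0)))
})

test_that("DBSCAN on a full 30-m lattice honours the 112-pixel / 180-m bound", {
  # lattice-counting oracle: centres within a 180-m disc of an interior pixel
  expect_equal(oracle_lattice_count(180), 113)
  expect_equal(oracle_lattice_count(179), 109)
  spec <- grid_spec(0, 750, 25, 25, pixel_size = 30)
  ctr <- pixel_centers(spec)
  below <- dbscan_pixels(ctr$x, ctr$y, eps = 179, min_pts = 112)
  expect_equal(nrow(below$clusters), 0L)
  expect_true(all(is.na(below$cluster)))
  at <- dbscan_pixels(ctr$x, ctr$y, eps = 180, min_pts = 112)
  expect_gt(nrow(at$clusters), 0L)
})

test_that("111 co-located points stay noise at min_pts = 112", {
  set.seed(1)
  x <- rnorm(111, sd = 5); y <- rnorm(111, sd = 5)
  a <- dbscan_pixels(x, y, eps = 100, min_pts = 112)
  expect_true(all(is.na(a$cluster)))
  # one more point tips the same cloud into a single cluster
  a2 <- dbscan_pixels(c(x, 0), c(y, 0), eps = 100, min_pts = 112)
  expect_equal(nrow(a2$clusters), 1L)
})

test_that("DBSCAN matches a brute-force density-reachability oracle", {
  set.seed(42)
  for (k in 1:6) {
    n <- sample(50:300, 1)
    # mixture of tight clumps and scattered noise
    nclump <- sample(2:4, 1)
    cx <- runif(nclump, 0, 1000); cy <- runif(nclump, 0, 1000)
    g <- sample(nclump, n, replace = TRUE)
    x <- cx[g] + rnorm(n, sd = 40); y <- cy[g] + rnorm(n, sd = 40)
    scat <- sample(n, round(n / 4))
    x[scat] <- runif(length(scat), 0, 1000); y[scat] <- runif(length(scat), 0, 1000)
    eps <- runif(1, 50, 150); min_pts <- sample(3:15, 1)
    got <- dbscan_pixels(x, y, eps, min_pts)
    want <- oracle_dbscan(x, y, eps, min_pts)
    expect_identical(got$is_core, want$is_core)
    # noise sets agree; border points may attach to either adjacent cluster
    # but must not be noise
    expect_true(all(!is.na(got$cluster[!want$is_noise & want$is_core])))
    expect_true(all(is.na(got$cluster[want$is_noise])))
    # core points are partitioned identically (canonical labels)
    canon_got <- rep(NA_integer_, n)
    for (cl in unique(got$cluster[want$is_core])) {
      m <- which(got$cluster == cl & want$is_core)
      canon_got[m] <- min(m)
    }
    expect_identical(canon_got[want$is_core],
                     want$core_partition[want$is_core])
  }
})

test_that("DBSCAN core/noise status is invariant to point order", {
  set.seed(9)
  n <- 200
  x <- runif(n, 0, 500); y <- runif(n, 0, 500)
  perm <- sample(n)
  a <- dbscan_pixels(x, y, eps = 60, min_pts = 5)
  b <- dbscan_pixels(x[perm], y[perm], eps = 60, min_pts = 5)
  expect_identical(a$is_core[perm], b$is_core)
  expect_identical(is.na(a$cluster)[perm], is.na(b$cluster))
})

test_that("trade-off curve: removed biomass is non-increasing and drops at formation", {
  # one dense 13x13 blob (169 pixels) plus isolated far-away pixels
  spec <- grid_spec(0, 3000, 100, 100, pixel_size = 30)
  tdbm <- matrix(0, 100, 100)
  tdbm[40:52, 40:52] <- 2          # clustered biomass
  iso <- cbind(c(5, 10, 90, 95), c(5, 95, 5, 95))
  tdbm[iso] <- 3                   # isolated pixels
  grid <- structure(list(spec = spec, tdbm = tdbm,
                         dt_by_year = list(`2015` = tdbm)),
                    class = "dead_biomass_grid")
  curve <- tradeoff_curve(grid, eps_values = seq(160, 400, by = 20),
                          min_pts = 112)
  expect_true(all(diff(curve$biomass_removed) <= 1e-9))
  # below 180 m nothing clusters: everything is "removed"
  expect_equal(curve$biomass_removed[curve$eps == 160], sum(tdbm))
  # at large eps only the 4 isolated pixels are removed
  expect_equal(curve$biomass_removed[curve$eps == 400], 12)
  # the formation radius shows as a sharp drop
  expect_lt(curve$biomass_removed[curve$eps == 180], sum(tdbm))
})

test_that("knee selection finds a constructed elbow, breaks ties to smaller eps", {
  elbow <- tibble::tibble(
    eps = seq(180, 300, by = 20),
    biomass_removed = c(100, 80, 60, 40, 38, 36, 34),
    mean_standard_distance = seq(100, 700, by = 100),
    n_clusters = 1L)
  expect_equal(select_eps(elbow), 240)
  flat <- tibble::tibble(eps = c(180, 200, 220, 240),
                         biomass_removed = c(40, 30, 20, 10),
                         mean_standard_distance = c(1, 2, 3, 4),
                         n_clusters = 1L)
  expect_warning(e <- select_eps(flat), "no curvature")
  expect_equal(e, 200)
  expect_error(select_eps(elbow[1:2, ]), "at least 3")
})

test_that("isolation filter bookkeeping: removed equals the noise biomass", {
  ls <- small_landscape(seed = 14)
  b <- run_allocation(ls$mortality, ls$structure)
  pts <- deadwood:::positive_pixels(b$upper)
  a <- dbscan_pixels(pts$x, pts$y, eps = 220, min_pts = 112)
  res <- filter_isolated(b$upper, a)
  expect_equal(res$removed, sum(pts$tdbm[is.na(a$cluster)]))
  expect_equal(sum(res$grid$tdbm), sum(b$upper$tdbm) - res$removed)
  # all-noise and no-noise degenerate cases
  all_noise <- a; all_noise$cluster <- rep(NA_integer_, length(a$cluster))
  expect_true(all(filter_isolated(b$upper, all_noise)$grid$tdbm == 0))
  no_noise <- a; no_noise$cluster <- rep(1L, length(a$cluster))
  expect_equal(filter_isolated(b$upper, no_noise)$grid$tdbm, b$upper$tdbm)
})

test_that("zone filter removes exactly the in-zone biomass", {
  ls <- small_landscape(seed = 16)
  b <- run_allocation(ls$mortality, ls$structure)
  res <- filter_zones(b$upper, ls$zones)
  member <- dplyr::bind_rows(lapply(ls$zones$wilderness_np,
                                    pixels_in_polygon, spec = b$upper$spec))
  expect_equal(res$removed,
               sum(b$upper$tdbm[cbind(member$row, member$col)]))
  # whole-extent zone wipes the grid; empty zones are the identity
  whole <- list(pixel_rect(b$upper$spec, 1, b$upper$spec$n_rows, 1,
                           b$upper$spec$n_cols))
  expect_true(all(filter_zones(b$upper, whole)$grid$tdbm == 0))
  expect_equal(filter_zones(b$upper, list())$grid$tdbm, b$upper$tdbm)
})

test_that("mean tree volume is VPH/TPH with treeless pixels undefined", {
  s <- toy_structure(n = 2, tph = 300, bph = 100, vph = 600)
  expect_true(all(mean_tree_volume(s) == 2))
  s0 <- structure_grid(s$spec, "dbh_ge_25cm", tph = matrix(c(300, 0, 0, 0), 2),
                       bph = matrix(c(100, 0, 0, 0), 2),
                       vph = matrix(c(600, 0, 0, 0), 2))
  v <- mean_tree_volume(s0)
  expect_equal(v[1, 1], 2)
  expect_true(all(is.na(v[-1])))
})

test_that("size/density filter honours its inclusive and strict boundaries", {
  # 3 pixels: vpt exactly 11.32 (removed), vpt below with density exactly
  # 2.5/ha (retained), low density (removed)
  spec <- grid_spec(0, 30, 1, 3, pixel_size = 30)
  s <- structure_grid(spec, "dbh_ge_25cm",
                      tph = matrix(c(100, 100, 100), 1),
                      bph = matrix(c(200, 200, 200), 1),
                      vph = matrix(c(1132, 500, 500), 1))
  dt <- matrix(c(1, 0.225, 0.2249), 1)   # 2.5/ha boundary at 0.225 trees
  grid <- structure(list(spec = spec, tdbm = matrix(c(5, 5, 5), 1),
                         dt_by_year = list(`2015` = dt)),
                    class = "dead_biomass_grid")
  res <- filter_vpt_and_density(grid, s)
  expect_equal(as.numeric(res$grid$tdbm), c(0, 5, 0))
  expect_equal(res$removed, 10)
})

test_that("feasibility cascade is contractive and applies one footprint to both bounds", {
  ls <- small_landscape(seed = 25)
  b <- run_allocation(ls$mortality, ls$structure)
  feas <- apply_feasibility(b, ls$zones, ls$structure$upper)
  led <- feas$reduction_ledger
  expect_true(all(diff(led$total_upper) <= 1e-9))
  expect_true(all(diff(led$total_lower) <= 1e-9))
  expect_true(all(led$removed_upper >= 0) && all(led$removed_lower >= 0))
  # running totals reconcile with removals
  expect_equal(led$total_upper[1], sum(b$upper$tdbm) - led$removed_upper[1])
  expect_equal(led$total_upper[3], sum(feas$upper$tdbm))
  # both bounds share the pixel footprint
  expect_identical(feas$upper$tdbm > 0,
                   feas$lower$tdbm > 0 & feas$upper$tdbm > 0)
  expect_true(feas$eps %in% seq(180, 400, by = 20))
})
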