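# Hand evaluations of the allocation rule:
#   3 pixels, tph {100,200,300}/ha, 30 dead trees -> shares {5,10,15}, caps
#   {9,18,27} don't bind; 2 pixels {10,300}/ha, 40 dead -> shares
#   {1.2903.., 38.7097..} both above caps {0.9, 27} -> {0.9, 27}.

test_that("proportional shares with and without binding caps match hand evaluation", {
  spec <- grid_spec(0, 30, 1, 3, pixel_size = 30)
  s <- structure_grid(spec, "dbh_ge_25cm",
                      tph = matrix(c(100, 200, 300), 1),
                      bph = matrix(c(200, 400, 600), 1),
                      vph = matrix(c(300, 600, 900), 1))
  poly <- pixel_rect(spec, 1, 1, 1, 3)
  out <- allocate_polygon(poly, 30, s)
  expect_equal(out$dt[order(out$col)], c(5, 10, 15))
  expect_equal(attr(out, "allocated"), 30)

  s2 <- structure_grid(grid_spec(0, 30, 1, 2), "dbh_ge_25cm",
                       tph = matrix(c(10, 300), 1),
                       bph = matrix(c(20, 600), 1),
                       vph = matrix(c(30, 900), 1))
  out2 <- allocate_polygon(pixel_rect(s2$spec, 1, 1, 1, 2), 40, s2)
  expect_equal(out2$dt[order(out2$col)], c(0.9, 27))
  expect_lt(attr(out2, "allocated"), 40)
})

test_that("a one-pixel polygon is capped at the pixel's live tree count", {
  s <- toy_structure(n = 1, tph = 100, bph = 200, vph = 300)
  out <- allocate_polygon(pixel_rect(s$spec, 1, 1, 1, 1), 20, s)
  expect_equal(out$dt, 9)  # 100 trees/ha * 0.09 ha
})

test_that("unforested polygons yield zero allocation and a diagnostics warning", {
  s <- toy_structure(n = 2, tph = 0, bph = 0, vph = 0)
  expect_warning(out <- allocate_polygon(pixel_rect(s$spec, 1, 2, 1, 2), 10, s),
                 "unallocated")
  expect_equal(attr(out, "allocated"), 0)
  expect_equal(attr(out, "requested"), 10)
})

test_that("dead biomass conversion: 9 trees at 2 BDT each is the pixel's live biomass", {
  s <- toy_structure(n = 1, tph = 100, bph = 200, vph = 300)
  dt <- matrix(9, 1, 1)
  expect_equal(dead_biomass(dt, s), matrix(18, 1, 1))  # = 200 * 0.09
  expect_equal(dead_biomass(matrix(0, 1, 1), s), matrix(0, 1, 1))
  # saturated pixel gives exactly the live biomass, by algebra
  sat <- s$tph * pixel_area_ha(s$spec)
  expect_equal(dead_biomass(sat, s), s$bph * pixel_area_ha(s$spec))
})

test_that("cumulative cap: two 60% years collapse to 100% of live biomass", {
  s <- toy_structure(n = 2, tph = 100, bph = 200, vph = 300)
  live <- s$bph * pixel_area_ha(s$spec)
  acc <- accumulate_dead_biomass(list(`2015` = 0.6 * live, `2016` = 0.6 * live), s)
  expect_equal(acc$tdbm, live)
  expect_equal(acc$corrections$n_pixels_corrected, 4L)
  expect_equal(acc$corrections$frac_pixels_corrected, 1)
  expect_equal(acc$corrections$biomass_removed, 0.2 * sum(live))
  # no-cap case is the identity with zero corrections
  acc2 <- accumulate_dead_biomass(list(`2015` = 0.5 * live), s)
  expect_equal(acc2$tdbm, 0.5 * live)
  expect_equal(acc2$corrections$n_pixels_corrected, 0L)
  # all-zero input stays zero
  acc3 <- accumulate_dead_biomass(list(`2015` = 0 * live), s)
  expect_true(all(acc3$tdbm == 0))
})

test_that("empty polygon list gives zero grids for both variants", {
  ls <- small_landscape(seed = 1, n = 30, n_polys = 0)
  b <- run_allocation(ls$mortality[0, ], ls$structure)
  expect_true(all(b$upper$tdbm == 0) && all(b$lower$tdbm == 0))
})

test_that("proportional-mode allocation recovers the ground truth exactly", {
  ls <- small_landscape(seed = 31)
  b <- run_allocation(ls$mortality, ls$structure)
  for (y in names(ls$truth$dt_by_year)) {
    truth <- ls$truth$dt_by_year[[y]]
    got <- b$upper$dt_by_year[[y]]
    expect_lt(max(abs(got - truth)) / max(truth), 1e-10)
  }
  # and the cumulative biomass matches the truth raster wherever no cap binds
  expect_lt(max(abs(b$upper$tdbm - pmin(ls$truth$dead_biomass,
                                        ls$structure$upper$bph *
                                          pixel_area_ha(ls$config$spec)))),
            1e-8)
})

test_that("allocation is monotone and scale-equivariant in the polygon count", {
  ls <- small_landscape(seed = 8, n = 40, n_polys = 2)
  s <- ls$structure$upper
  # pick a polygon that overlaps forest so reallocation is non-trivial
  forested <- vapply(ls$mortality$geometry, function(g) {
    m <- pixels_in_polygon(g, s$spec)
    nrow(m) > 0 && any(s$tph[cbind(m$row, m$col)] > 0)
  }, logical(1))
  poly <- ls$mortality$geometry[[which(forested)[1]]]
  base <- allocate_polygon(poly, 50, s)
  more <- allocate_polygon(poly, 80, s)
  expect_true(all(more$dt >= base$dt - 1e-12))
  # doubling with no caps binding doubles every pixel share
  small <- allocate_polygon(poly, 1, s)
  dbl <- allocate_polygon(poly, 2, s)
  expect_equal(dbl$dt, 2 * small$dt, tolerance = 1e-12)
})

test_that("vectorised allocation equals a naive per-pixel loop", {
  ls <- small_landscape(seed = 12, n = 40, n_polys = 3)
  s <- ls$structure$upper
  a_ha <- pixel_area_ha(s$spec)
  for (i in seq_len(nrow(ls$mortality))) {
    poly <- ls$mortality$geometry[[i]]
    dtp <- ls$mortality$dead_trees[i]
    got <- allocate_polygon(poly, dtp, s)
    member <- pixels_in_polygon(poly, s$spec)
    tphs <- s$tph[cbind(member$row, member$col)]
    denom <- sum(tphs[tphs > 0])
    want <- numeric(0)
    for (j in seq_len(nrow(member))) {
      t_j <- s$tph[member$row[j], member$col[j]]
      if (t_j > 0) want <- c(want, min(dtp * t_j / denom, t_j * a_ha))
    }
    expect_equal(got$dt, want, tolerance = 1e-10)
  }
})

test_that("cap-correction accounting balances exactly and bounds hold everywhere", {
  # force heavy capping with saturating mortality over repeated years
  ls <- small_landscape(seed = 3, n = 40, n_polys = 4,
                        mortality_fraction_range = c(0.8, 1))
  b <- run_allocation(ls$mortality, ls$structure)
  for (side in list(b$upper, b$lower)) {
    a_ha <- pixel_area_ha(side$spec)
    str <- ls$structure[[if (side$variant == "dbh_ge_25cm") "upper" else "lower"]]
    # the live-tree cap holds per polygon (overlapping polygons are
    # allocated independently; only the cumulative biomass cap reconciles)
    for (i in seq_len(nrow(ls$mortality))) {
      al <- allocate_polygon(ls$mortality$geometry[[i]],
                             ls$mortality$dead_trees[i], str)
      expect_true(all(al$dt <= al$tph * a_ha + 1e-9))
    }
    total <- Reduce(`+`, side$dbm_by_year)
    expect_true(all(side$tdbm <= str$bph * a_ha + 1e-9))
    expect_equal(side$corrections$biomass_removed, sum(total - side$tdbm),
                 tolerance = 1e-9)
    # per polygon, allocation never exceeds the surveyed count
    expect_true(all(side$diagnostics$allocated <=
                      side$diagnostics$requested + 1e-9))
  }
})

test_that("upper-bound cumulative biomass dominates the lower bound statewide", {
  ls <- small_landscape(seed = 19)
  b <- run_allocation(ls$mortality, ls$structure)
  expect_gte(sum(b$upper$tdbm), sum(b$lower$tdbm))
  # same seed rerun is bit-identical
  b2 <- run_allocation(ls$mortality, ls$structure)
  expect_identical(b$upper$tdbm, b2$upper$tdbm)
})

test_that("tidy/glance views agree with the underlying grids", {
  ls <- small_landscape(seed = 22, n = 40, n_polys = 2)
  b <- run_allocation(ls$mortality, ls$structure)
  td <- tidy(b)
  expect_equal(sum(td$dead_biomass_bdt[td$bound == "upper"]),
               sum(Reduce(`+`, b$upper$dbm_by_year)))
  gl <- glance(b)
  expect_equal(gl$tdbm_upper_bdt, sum(b$upper$tdbm))
})
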