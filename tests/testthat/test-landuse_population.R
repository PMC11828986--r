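# Land-use recoding and dasymetric disaggregation.

lu_grid <- function(v, cellsize = 5, xll = 0, yll = 0)
  raster_grid(v, xll, yll, cellsize)

test_that("six classes collapse to informal/formal/other as specified", {
  v <- matrix(c(LANDUSE_CODES[["atomistic"]],
                LANDUSE_CODES[["informal_subdivision"]],
                LANDUSE_CODES[["formal_subdivision"]],
                LANDUSE_CODES[["housing_project"]],
                LANDUSE_CODES[["open_space"]],
                LANDUSE_CODES[["non_residential"]],
                NA, NA, NA), 3, 3)
  r <- recode_landuse(lu_grid(v))
  expect_equal(r$values[1, 1], RECODED_CODES[["informal"]])  # atomistic
  expect_equal(r$values[2, 1], RECODED_CODES[["informal"]])  # informal subdiv
  expect_equal(r$values[3, 1], RECODED_CODES[["formal"]])    # formal subdiv
  expect_equal(r$values[1, 2], RECODED_CODES[["formal"]])    # housing project
  expect_equal(r$values[2, 2], RECODED_CODES[["other"]])     # open space
  expect_equal(r$values[3, 2], RECODED_CODES[["other"]])     # non-residential
  expect_equal(r$values[1, 3], RECODED_CODES[["other"]])     # nodata -> other
  # geometry untouched
  expect_true(same_grid(r, lu_grid(v)))
})

test_that("unknown codes error and recoding is idempotent", {
  bad <- lu_grid(matrix(c(1, 2, 9, 42), 2, 2))
  expect_error(recode_landuse(bad), "9, 42")
  r <- recode_landuse(lu_grid(matrix(1:6, 2, 3)))
  expect_identical(recode_landuse(r), r)
})

# a 100-m population cell over a 20x20 block of 5-m cells, aligned origins
aligned_fixture <- function(lu_vals, pop_vals) {
  list(rlu = recode_landuse(lu_grid(lu_vals, cellsize = 5)),
       pop = raster_grid(pop_vals, 0, 0, 100))
}

test_that("uniform_all splits a coarse cell equally over its subcells", {
  fx <- aligned_fixture(matrix(LANDUSE_CODES[["atomistic"]], 20, 20),
                        matrix(400, 1, 1))
  cp <- disaggregate(fx$pop, fx$rlu, "uniform_all")
  expect_true(all(cp$pop == 1.0))
  expect_equal(sum(cp$pop), 400)
})

test_that("residential_only splits over residential subcells only", {
  lu <- matrix(LANDUSE_CODES[["non_residential"]], 20, 20)
  lu[1:5, 1:20] <- LANDUSE_CODES[["formal_subdivision"]]  # 100 residential
  fx <- aligned_fixture(lu, matrix(400, 1, 1))
  cp <- disaggregate(fx$pop, fx$rlu, "residential_only")
  expect_equal(unique(as.vector(cp$pop[1:5, ])), 4.0)
  expect_true(all(cp$pop[6:20, ] == 0))
  expect_equal(sum(cp$pop), 400)

  # no residential subcell: population falls back to `other` and is logged
  lu2 <- matrix(LANDUSE_CODES[["open_space"]], 20, 20)
  fx2 <- aligned_fixture(lu2, matrix(400, 1, 1))
  cp2 <- disaggregate(fx2$pop, fx2$rlu, "residential_only")
  expect_equal(sum(cp2$pop), 400)
  expect_equal(attr(cp2, "n_fallback_cells"), 1L)
})

test_that("disaggregation conserves totals on random rasters in both modes", {
  set.seed(314)
  for (rep in 1:5) {
    pop_vals <- matrix(runif(100, 0, 500), 10, 10)
    pop_vals[sample(100, 10)] <- NA         # nodata contributes zero
    lu_vals <- matrix(sample(LANDUSE_CODES, 200 * 200, replace = TRUE),
                      200, 200)
    fx <- aligned_fixture(lu_vals, pop_vals)
    for (mode in c("uniform_all", "residential_only")) {
      cp <- disaggregate(fx$pop, fx$rlu, mode)
      expect_equal(sum(cp$pop), sum(pop_vals, na.rm = TRUE),
                   tolerance = 1e-6)
    }
  }
  expect_error(
    disaggregate(raster_grid(matrix(-1, 1, 1), 0, 0, 100),
                 aligned_fixture(matrix(1, 20, 20), matrix(0, 1, 1))$rlu),
    "negative")
})

test_that("misaligned grids resolve by centroid membership and conserve
           the covered population", {
  # population grid shifted 40 m: fine centroids still map by containment
  lu_vals <- matrix(LANDUSE_CODES[["atomistic"]], 40, 40)  # 200 m x 200 m
  rlu <- recode_landuse(lu_grid(lu_vals, cellsize = 5))
  pop <- raster_grid(matrix(c(100, 200, 300, 400), 2, 2), 40, 40, 100)
  cp <- disaggregate(pop, rlu, "uniform_all")
  # part of the shifted coarse cells lies outside the fine grid; what is
  # covered must still sum to source minus the unallocated remainder
  expect_equal(sum(cp$pop) + attr(cp, "unallocated"), 1000, tolerance = 1e-9)
  expect_equal(attr(cp, "unallocated"), 0)  # 40-240 m sits inside 0-200 m grid
})

test_that("class totals and informal share follow the residential convention", {
  cls <- matrix(RECODED_CODES[["informal"]], 2, 2)
  cp <- toy_cell_population(matrix(25, 2, 2), cls)
  ct <- class_totals(cp)
  expect_equal(ct$informal_share, 1.0)
  expect_equal(ct$city_total, 100)

  cls2 <- matrix(c(RECODED_CODES[["informal"]], RECODED_CODES[["formal"]],
                   RECODED_CODES[["other"]], RECODED_CODES[["other"]]), 2, 2)
  cp2 <- toy_cell_population(matrix(50, 2, 2), cls2)
  ct2 <- class_totals(cp2)
  expect_equal(ct2$informal_share, 0.5)
  expect_equal(ct2$city_total, 100)      # `other` mass excluded
  expect_equal(ct2$other, 100)

  cp3 <- toy_cell_population(matrix(10, 1, 1),
                             matrix(RECODED_CODES[["other"]], 1, 1))
  expect_false(class_totals(cp3)$share_defined)
})

test_that("pipeline class totals match the generator ledger", {
  for (seed in c(21, 22)) {
    b <- generate_random_city(seed = seed, n_nodes = 25, area_m = 600,
                              n_facilities = 3)
    rlu <- recode_landuse(b$landuse)
    cp <- disaggregate(b$population, rlu, "uniform_all")
    ct <- class_totals(cp)
    expect_equal(ct$informal, unname(b$ledger$class_pop["informal"]),
                 tolerance = 1e-6)
    expect_equal(ct$formal, unname(b$ledger$class_pop["formal"]),
                 tolerance = 1e-6)
    expect_equal(ct$other, unname(b$ledger$class_pop["other"]),
                 tolerance = 1e-6)
    expect_equal(sum(cp$pop), b$ledger$total_pop, tolerance = 1e-6)
  }
})
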