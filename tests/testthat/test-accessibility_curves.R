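# SA curves, speed scenarios, threshold reports and the 2-h metrics.

test_that("SA curve basics: full coverage, split population, closed threshold", {
  cls <- matrix(RECODED_CODES[["informal"]], 2, 2)
  cp <- toy_cell_population(matrix(1, 2, 2), cls)

  all0 <- sa_curve(cp, toy_field(matrix(0, 2, 2)), "all")
  expect_true(all(all0$shares == 1))

  # half the population at 10 min, half at 40 min
  f <- toy_field(matrix(c(10, 10, 40, 40), 2, 2))
  cv <- sa_curve(cp, f, "all")
  expect_equal(cv$shares[15], 0.5)
  expect_equal(cv$shares[30], 0.5)
  expect_equal(cv$shares[60], 1.0)
  # closed threshold: mass exactly at t counts at t
  expect_equal(cv$shares[10], 0.5)
  expect_equal(cv$shares[9], 0.0)

  # +Inf mass never enters; nondecreasing and bounded
  f2 <- toy_field(matrix(c(10, Inf, 40, 130), 2, 2))
  cv2 <- sa_curve(cp, f2, "all")
  expect_equal(cv2$shares[120], 0.5)
  expect_true(all(diff(cv2$shares) >= 0))
  expect_true(all(cv2$shares >= 0 & cv2$shares <= 1))
})

test_that("zero-population filters give the undefined sentinel", {
  cls <- matrix(RECODED_CODES[["informal"]], 2, 2)
  cp <- toy_cell_population(matrix(1, 2, 2), cls)
  cv <- sa_curve(cp, toy_field(matrix(0, 2, 2)), "formal")
  expect_true(cv$undefined)
  expect_true(all(is.na(cv$shares)))
  expect_true(is.na(pct_outside_2h(cv)))
  expect_true(is.na(surgical_benchmark(cv)))
})

test_that("grid-city SA curve equals exhaustive enumeration", {
  b <- generate_grid_city(n = 21, pop_per_node = 50)  # corner at 20 min
  cfg <- city_config(city_name = "grid")
  rlu <- recode_landuse(b$landuse)
  ntt <- multi_source_travel_times(b$network, b$facilities,
                                   cfg$snap_radius_m, cfg$base_speed_kmh)
  field <- raster_travel_times(ntt, b$network, rlu, cfg$snap_radius_m,
                               cfg$base_speed_kmh)
  cp <- disaggregate(b$population, rlu, "uniform_all")
  got <- sa_curve(cp, field, "all")
  want <- ref_sa_shares(cp, field, RECODED_CODES[c("informal", "formal")])
  expect_equal(got$shares, pmin(want, 1), tolerance = 1e-12)
  got_i <- sa_curve(cp, field, "informal")
  expect_equal(got_i$shares, pmin(ref_sa_shares(cp, field,
                                                RECODED_CODES["informal"]), 1),
               tolerance = 1e-12)
})

test_that("the all-class curve decomposes into the class curves", {
  b <- generate_random_city(seed = 33, n_nodes = 30, area_m = 800,
                            n_facilities = 2)
  cfg <- city_config(city_name = "r")
  rlu <- recode_landuse(b$landuse)
  ntt <- multi_source_travel_times(b$network, b$facilities, 500, 3.6)
  field <- raster_travel_times(ntt, b$network, rlu, 500, 3.6)
  cp <- disaggregate(b$population, rlu)
  a <- sa_curve(cp, field, "all")
  i <- sa_curve(cp, field, "informal")
  f <- sa_curve(cp, field, "formal")
  w <- i$denom / (i$denom + f$denom)
  expect_equal(a$shares, w * i$shares + (1 - w) * f$shares, tolerance = 1e-9)
})

test_that("speed scenarios: identity at factor 1, exact rescaling, monotone", {
  cls <- matrix(RECODED_CODES[["informal"]], 2, 2)
  cp <- toy_cell_population(matrix(1, 2, 2), cls)
  f <- toy_field(matrix(c(15, 100, 40, 7), 2, 2))
  cfg <- city_config(city_name = "toy")
  bnd <- run_speed_scenarios(cp, f, cfg)
  expect_equal(bundle_curve(bnd, "all", 1.0)$shares,
               sa_curve(cp, f, "all")$shares)

  # a cell at exactly 15.0 min becomes 12.5 min at factor 1.2:
  # shares[13] flips 0 -> 1
  cp1 <- toy_cell_population(matrix(1, 1, 1),
                             matrix(RECODED_CODES[["informal"]], 1, 1))
  f1 <- toy_field(matrix(15, 1, 1))
  b1 <- run_speed_scenarios(cp1, f1, cfg)
  expect_equal(bundle_curve(b1, "all", 1.0)$shares[13], 0)
  expect_equal(bundle_curve(b1, "all", 1.2)$shares[13], 1)

  # bundle ordering: share at 1.2 >= share at 1.0 >= share at 0.8
  for (cl in c("all", "informal")) {
    s08 <- bundle_curve(bnd, cl, 0.8)$shares
    s10 <- bundle_curve(bnd, cl, 1.0)$shares
    s12 <- bundle_curve(bnd, cl, 1.2)$shares
    expect_true(all(s12 >= s10 & s10 >= s08))
  }
})

test_that("threshold reports extract shares with lo/hi brackets", {
  cls <- matrix(RECODED_CODES[["informal"]], 2, 2)
  cp <- toy_cell_population(matrix(1, 2, 2), cls)
  f <- toy_field(matrix(c(5, 20, 50, 110), 2, 2))
  cfg <- city_config(city_name = "toy")
  bnd <- run_speed_scenarios(cp, f, cfg)

  cv <- bundle_curve(bnd, "all", 1.0)
  rep1 <- threshold_report(cv, c(15, 30, 60))
  expect_equal(nrow(rep1), 3)
  expect_equal(rep1$share, cv$shares[c(15, 30, 60)])

  rep2 <- threshold_report(bnd, c(15, 30, 60), "all")
  expect_true(all(rep2$lo <= rep2$share & rep2$share <= rep2$hi))
  expect_error(threshold_report(cv, 121), "horizon")
})

test_that("outside-2h and the surgical benchmark agree with direct recounts", {
  cls <- matrix(RECODED_CODES[["informal"]], 3, 3)
  set.seed(12)
  w <- matrix(runif(9, 1, 10), 3, 3)
  m <- matrix(c(runif(6, 0, 119), 125, 400, Inf), 3, 3)
  cp <- toy_cell_population(w, cls)
  f <- toy_field(m)
  cv <- sa_curve(cp, f, "all")
  direct <- sum(w[m > 120]) / sum(w)
  expect_equal(pct_outside_2h(cv), direct, tolerance = 1e-12)
  expect_equal(surgical_benchmark(cv), cv$shares[120] >= 0.80)
  expect_equal(surgical_benchmark(cv), pct_outside_2h(cv) <= 0.20)

  # boundary decisions
  mk <- function(s120) {
    cv$shares[] <- s120; cv
  }
  expect_true(surgical_benchmark(mk(0.80)))
  expect_false(surgical_benchmark(mk(0.799)))
  expect_equal(pct_outside_2h(mk(0.724)), 0.276)
  expect_equal(pct_outside_2h(mk(1.0)), 0.0)
})
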