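test_that("noise-free climate follows the configured latitudinal gradient", {
  g <- tiny_grid(noise = 0)
  ann <- colMeans((g$tmax_c + g$tmin_c) / 2)
  co <- grid_coords(g)
  # rows 1 degree apart differ in annual mean by the 0.6 gradient
  r1 <- mean(ann[co$lat == g$lat[1]])
  r2 <- mean(ann[abs(co$lat - (g$lat[1] - 2)) < 1e-9])
  expect_equal(r1 - r2, -0.6 * 2, tolerance = 1e-12)
  # regression recovers the gradient essentially exactly
  fit <- lm(ann ~ co$lat)
  expect_equal(unname(coef(fit)[2]), -0.6, tolerance = 1e-10)
  # seasonality grows with |latitude|
  amp <- apply((g$tmax_c + g$tmin_c) / 2, 2, function(x) max(x) - min(x))
  expect_gt(mean(amp[co$lat > 35]), mean(amp[co$lat < 25]))
  # July is the warm month in the northern hemisphere
  expect_true(all(apply((g$tmax_c + g$tmin_c) / 2, 2, which.max) == 7))
})

test_that("generator is reproducible and its noise has the configured scale", {
  g1 <- tiny_grid(noise = 1.5, seed = 42)
  g2 <- tiny_grid(noise = 1.5, seed = 42)
  expect_identical(g1, g2)
  g3 <- tiny_grid(noise = 1.5, seed = 43)
  expect_false(identical(g1$tmax_c, g3$tmax_c))

  # deviations of cell annual means from the deterministic surface
  det <- tiny_grid(noise = 0, res = 24)
  noisy <- tiny_grid(noise = 2, seed = 7, res = 24)
  expect_gte(ectoclim:::n_cells(det), 1000)
  dev <- colMeans((noisy$tmax_c + noisy$tmin_c) / 2) -
    colMeans((det$tmax_c + det$tmin_c) / 2)
  expect_lt(abs(sd(dev) - 2), 0.2)
})

test_that("generator rejects degenerate input, naming the field", {
  expect_error(generate_monthly_climate(list(lat_min = 20, lat_max = 20.001,
                                             lon_min = 100, lon_max = 100.001),
                                        resolution_arcmin = 60),
               "zero-cell")
  expect_error(generate_monthly_climate(tiny_extent(), resolution_arcmin = -5),
               "resolution_arcmin")
  expect_error(generate_monthly_climate(tiny_extent(), 60,
                                        params = list(t_ref_c = NaN)),
               "t_ref_c")
  expect_error(generate_monthly_climate(list(lat_min = 20, lat_max = 40),
                                        60), "lon_min")
})

test_that("warming scenarios shift temperatures and scale precipitation", {
  g <- tiny_grid()
  expect_equal(apply_warming_scenario(g, warming_scenario(0, 1)), g)
  b0 <- compute_bioclim(g)
  w <- apply_warming_scenario(g, warming_scenario(2, 0.8))
  b1 <- compute_bioclim(w)
  expect_equal(b1$bio1, b0$bio1 + 2, tolerance = 1e-12)
  expect_equal(b1$bio12, b0$bio12 * 0.8, tolerance = 1e-12)
  expect_true(all(w$tmax_c >= w$tmin_c))
  expect_error(warming_scenario(2, 0), "precip_factor")
  # monthly vector form
  wv <- apply_warming_scenario(g, warming_scenario(c(rep(1, 6), rep(3, 6))))
  expect_equal(wv$tmax_c[1, ], g$tmax_c[1, ] + 1)
  expect_equal(wv$tmax_c[12, ], g$tmax_c[12, ] + 3)
})

test_that("projection averaging is an element-wise mean", {
  g <- tiny_grid()
  expect_equal(average_projections(list(g)), g)
  ga <- apply_warming_scenario(g, warming_scenario(-2))
  gb <- apply_warming_scenario(g, warming_scenario(2))
  avg <- average_projections(list(ga, gb))
  expect_equal(avg$tmax_c, g$tmax_c, tolerance = 1e-12)
  # three-grid brute-force oracle
  gc <- apply_warming_scenario(g, warming_scenario(1, 1.3))
  avg3 <- average_projections(list(ga, gb, gc))
  for (f in c("tmax_c", "tmin_c", "precip_mm"))
    expect_equal(avg3[[f]], (ga[[f]] + gb[[f]] + gc[[f]]) / 3,
                 tolerance = 1e-12)
  bad <- generate_monthly_climate(list(lat_min = 20, lat_max = 30,
                                       lon_min = 100, lon_max = 110), 120)
  expect_error(average_projections(list(g, bad)), "geometry")
})

test_that("warming then averaging commutes with per-cell arithmetic", {
  g <- tiny_grid(noise = 1, seed = 5)
  sc <- warming_scenario(1.7, 0.9)
  g2 <- tiny_grid(noise = 1, seed = 6)
  lhs <- average_projections(list(apply_warming_scenario(g, sc),
                                  apply_warming_scenario(g2, sc)))
  rhs <- apply_warming_scenario(average_projections(list(g, g2)), sc)
  expect_equal(lhs$tmax_c, rhs$tmax_c, tolerance = 1e-12)
  expect_equal(lhs$precip_mm, rhs$precip_mm, tolerance = 1e-12)
})

test_that("virtual-species suitability follows its parametric composition", {
  tr <- default_traits()
  vs <- virtual_species(tr, list(
    a = list(type = "logistic", midpoint = 10, scale = 2, sign = 1),
    b = list(type = "gaussian", optimum = 5, breadth = 1)))
  expect_equal(true_suitability(vs, list(a = 10, b = 0)),
               0.5 * exp(-12.5))
  expect_equal(true_suitability(vs, list(a = 1e6, b = 5)), 1)
  # product rule: 0.8 * 0.5
  x_for <- function(p) 10 + 2 * log(p / (1 - p))
  expect_equal(true_suitability(vs, list(a = x_for(0.8), b = 5)) *
                 true_suitability(vs, list(a = x_for(0.5), b = 5)) /
                 true_suitability(vs, list(a = 1e6, b = 5)),
               0.4, tolerance = 1e-12)
  expect_error(true_suitability(vs, list(a = 1)), "missing predictor")
  vm <- virtual_species(tr, vs$response_spec, combine_rule = "mean")
  expect_equal(true_suitability(vm, list(a = 10, b = 5)), 0.75)
})

test_that("occurrence sampling is suitability-weighted, jittered and reproducible", {
  g <- tiny_grid()
  tr <- default_traits()
  vs <- virtual_species(tr, list(bio1 = list(type = "gaussian", optimum = 20,
                                             breadth = 5)))
  n <- ectoclim:::n_cells(g)
  co <- grid_coords(g)
  # all suitability in the northern half: every point lands there
  suit <- as.numeric(co$lat > 30)
  occ <- sample_occurrences(vs, g, suit, n = 200, seed = 1)
  expect_true(all(occ$records$lat > 29))
  # two live cells 0.9/0.1: binomial expectation within 2 points
  suit2 <- numeric(n); suit2[1] <- 0.9; suit2[2] <- 0.1
  occ2 <- sample_occurrences(vs, g, suit2, n = 10000, seed = 2)
  cells <- cell_from_lonlat(g, occ2$records$lon, occ2$records$lat)
  expect_lt(abs(mean(cells == 1) - 0.9), 0.02)
  # reproducibility and the error contract
  expect_identical(sample_occurrences(vs, g, suit, 50, seed = 9),
                   sample_occurrences(vs, g, suit, 50, seed = 9))
  expect_error(sample_occurrences(vs, g, numeric(n), 10), "positive sum")
})

test_that("climate and occurrence CSV round-trips are exact", {
  g <- tiny_grid(noise = 1, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_climate_csv(g, f)
  g2 <- read_climate_csv(f, resolution_arcmin = g$resolution_arcmin)
  expect_equal(g2$tmax_c, g$tmax_c, tolerance = 1e-12)
  expect_equal(g2$lat, g$lat, tolerance = 1e-12)

  occ <- occurrence_set(data.frame(lon = c(101, 102), lat = c(25, 26),
                                   source = "lit"), "spA")
  f2 <- tempfile(fileext = ".csv")
  write_occurrences_csv(occ, f2)
  occ2 <- read_occurrences_csv(f2)
  expect_equal(occ2$records$lon, occ$records$lon)
  expect_identical(occ2$species_id, "spA")
})
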