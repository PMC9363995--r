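test_that("saturation vapour density follows Tetens with ideal-gas conversion", {
  # oracle evaluated independently
  tet <- function(t) 610.78 * exp(17.27 * t / (t + 237.3)) /
    (461.5 * (t + 273.15)) * 1000
  expect_lt(abs(saturation_vapor_density(20) - 17.3), 0.5)
  for (t in c(-10, 0, 15, 33.3, 50))
    expect_equal(saturation_vapor_density(t), tet(t), tolerance = 1e-12)
  grid <- seq(-40, 60, by = 0.1)
  expect_true(all(diff(saturation_vapor_density(grid)) > 0))
  expect_gt(saturation_vapor_density(30), saturation_vapor_density(20) * 1.5)
  expect_error(saturation_vapor_density(80), "outside")
})

test_that("operative temperature collapses to air temperature in an isothermal, sunless world", {
  tr <- default_traits()
  env <- list(t_air_animal_c = 30, solar_wm2 = 0, t_sky_c = 30,
              t_ground_surface_c = 30, wind_ms = 1)
  expect_equal(as.numeric(operative_temperature(env, tr)), 30,
               tolerance = 1e-6)
  # radiative load raises Te above air temperature
  env$solar_wm2 <- 600
  expect_gt(as.numeric(operative_temperature(env, tr)), 30)
  # shaded posture sheds the solar load entirely
  expect_equal(as.numeric(operative_temperature(env, tr, "shaded")), 30,
               tolerance = 1e-6)
  env$solar_wm2 <- NA
  expect_error(operative_temperature(env, tr), "non-finite")
})

test_that("solver root matches the brute-force energy-balance scan", {
  tr <- default_traits()
  envs <- random_environments(200, seed = 8)
  for (i in seq_len(nrow(envs))) {
    env <- as.list(envs[i, ])
    te <- as.numeric(operative_temperature(env, tr))
    expect_lt(abs(te - te_scan_oracle(env, tr)), 0.01)
  }
})

test_that("behavioural rules follow the diurnal decision cascade", {
  tr <- default_traits()  # vt 26-34, t_pref 30, emerge 17
  soil <- c("0.05" = 24, "0.2" = 29, "1" = 31)
  # in the activity band: active above ground
  s <- behavioural_step(30, 28, soil, daylight = TRUE, tr)
  expect_identical(s$state, "active")
  expect_equal(s$t_body_c, 30)
  expect_equal(s$depth_m, 0)
  # dangerously hot open habitat: retreat underground
  s <- behavioural_step(tr$ctmax_c + 2, 35, soil, daylight = TRUE, tr)
  expect_identical(s$state, "retreat")
  expect_gt(s$depth_m, 0)
  # 29 and 31 are both 1 degC from t_pref = 30; tie goes to the shallower
  expect_equal(s$t_body_c, 29)
  expect_equal(s$depth_m, 0.2)
  # basking band between emergence and vt_min
  s <- behavioural_step(20, 18, soil, daylight = TRUE, tr)
  expect_identical(s$state, "basking")
  # too cold to emerge
  s <- behavioural_step(10, 8, soil, daylight = TRUE, tr)
  expect_identical(s$state, "retreat")
  # night: always in the retreat
  s <- behavioural_step(30, 30, soil, daylight = FALSE, tr)
  expect_identical(s$state, "retreat")
  expect_error(behavioural_step(30, 30, numeric(0), TRUE, tr), "soil")
})

test_that("retreat picks the depth nearest the preferred temperature, shallow on ties", {
  tr <- default_traits()
  s <- behavioural_step(50, 40, c("0.05" = 29, "0.2" = 31, "1" = 15),
                        daylight = TRUE, tr)
  expect_equal(s$depth_m, 0.05)  # tie |29-30| = |31-30| broken shallow
  s2 <- behavioural_step(50, 40, c("0.05" = 50, "0.2" = 45, "1" = 33),
                         daylight = TRUE, tr)
  expect_equal(s2$depth_m, 1)
  # body temperature clamps to the tolerance range
  s3 <- behavioural_step(50, 40, c("0.05" = 60), daylight = TRUE, tr)
  expect_equal(s3$t_body_c, tr$ctmax_c)
})

test_that("metabolic allometry evaluates and scales as specified", {
  tr <- default_traits(met_a = 0.1, met_b = 0.8, met_q = 0.07)
  expect_equal(metabolic_rate(5, 30, tr), 0.1 * 5^0.8 * exp(2.1),
               tolerance = 1e-12)
  tr2 <- default_traits(met_a = 0.2)
  expect_equal(metabolic_rate(5, 30, tr2), 2 * metabolic_rate(5, 30, tr))
  expect_gt(metabolic_rate(5, 30, tr), metabolic_rate(5, 20, tr))
  expect_gt(metabolic_rate(10, 25, tr), metabolic_rate(5, 25, tr))
  expect_error(metabolic_rate(5, tr$ctmax_c + 1, tr), "outside")
})

test_that("water loss vanishes without a vapour gradient and sums exactly", {
  tr <- default_traits()
  env <- list(t_air_animal_c = 30, rh_pct = 100)
  wl <- water_loss_rate(30, env, "active", tr, vo2 = 2)
  expect_equal(wl$total_g_h, 0)
  expect_equal(wl$cutaneous_g_h + wl$respiratory_g_h + wl$ocular_g_h, 0)
  # halving O2 extraction doubles respiratory loss at fixed VO2
  env$rh_pct <- 40
  tr_half <- default_traits(o2_extraction = tr$o2_extraction / 2)
  expect_equal(water_loss_rate(32, env, "active", tr_half, 2)$respiratory_g_h,
               2 * water_loss_rate(32, env, "active", tr, 2)$respiratory_g_h,
               tolerance = 1e-12)
  # eyes closed in the retreat: no ocular loss
  expect_equal(water_loss_rate(32, env, "retreat", tr, 2)$ocular_g_h, 0)
  expect_gt(water_loss_rate(32, env, "active", tr, 2)$ocular_g_h, 0)
  expect_error(water_loss_rate(32, env, "active", tr, -1), "vo2")
})

test_that("water loss matches an independently coded evaluation", {
  tr <- default_traits()
  A <- ectoclim:::body_geometry(tr)$area_m2
  svd <- function(t) 610.78 * exp(17.27 * t / (t + 237.3)) /
    (461.5 * (t + 273.15)) * 1000
  set.seed(21)
  for (i in 1:100) {
    tb <- runif(1, 15, 40); ta <- runif(1, 5, 45)
    rh <- runif(1, 0, 100); vo2 <- runif(1, 0, 5)
    st <- sample(c("active", "basking", "retreat"), 1)
    got <- water_loss_rate(tb, list(t_air_animal_c = ta, rh_pct = rh),
                           st, tr, vo2)
    grad <- max(0, svd(tb) - rh / 100 * svd(ta))
    cut <- A * grad / (tr$skin_resistance_s_per_m +
                         tr$boundary_resistance_s_per_m) * 3600
    resp <- vo2 / (0.2094 * tr$o2_extraction) * 1e-6 * grad
    ocu <- if (st == "retreat") 0 else
      tr$eye_area_fraction * A * grad / tr$boundary_resistance_s_per_m * 3600
    expect_equal(got$total_g_h, cut + resp + ocu, tolerance = 1e-10)
    expect_true(all(unlist(got) >= 0))
  }
})

test_that("a year at preferred temperature yields full diurnal activity", {
  tr <- default_traits()
  mic <- make_micro(t_air = tr$t_pref_c)  # sunless, isothermal at t_pref
  sim <- simulate_year(mic, tr)
  expect_equal(sim$summary$activity_h_yr, 12 * 365)  # 12 daylight h/day
  expect_equal(sim$summary$t_e_max_c, tr$t_pref_c, tolerance = 1e-6)
  expect_equal(sim$summary$tsm_c, tr$ctmax_c - sim$summary$t_e_max_c)
})

test_that("an always-overheated year gives zero activity and the TSM identity", {
  tr <- default_traits()
  mic <- make_micro(t_air = tr$vt_max_c + 10, soil_temps = c(30, 28, 26))
  sim <- simulate_year(mic, tr)
  expect_equal(sim$summary$activity_h_yr, 0)
  expect_equal(sim$summary$tsm_c,
               tr$ctmax_c - max(sim$hours$t_e_open_c), tolerance = 1e-12)
  expect_true(all(sim$hours$state != "active"))
})

test_that("energy-balance residuals stay negligible across a simulated year", {
  g <- tiny_grid()
  tr <- default_traits()
  sim <- simulate_year(build_microclimate_year(g, 30), tr)
  expect_lt(max(abs(attr(sim$hours, "te_residual_wm2"))), 1e-6)
  # water loss components non-negative, total = sum, exact
  with(sim$hours, {
    expect_true(all(cutaneous_g_h >= 0 & respiratory_g_h >= 0 &
                      ocular_g_h >= 0))
    expect_equal(total_g_h, cutaneous_g_h + respiratory_g_h + ocular_g_h,
                 tolerance = 1e-12)
  })
})

test_that("uniform warming raises Te-max and erodes the thermal safety margin", {
  g <- tiny_grid()
  tr <- default_traits()
  warm <- apply_warming_scenario(g, warming_scenario(2))
  for (cell in c(5, 25, 45)) {
    s0 <- simulate_year(build_microclimate_year(g, cell), tr)$summary
    s2 <- simulate_year(build_microclimate_year(warm, cell), tr)$summary
    expect_gt(s2$t_e_max_c, s0$t_e_max_c)
    expect_lt(s2$tsm_c, s0$tsm_c)
  }
})

test_that("activity quantiles use the linear-interpolation definition", {
  tb <- c(22, 25, 27, 29, 31, 33, 35, 38)
  q <- activity_quantiles(tb)
  expect_equal(unname(q), unname(quantile(tb, c(0.25, 0.75), type = 7)))
  expect_lt(q[["vt_min_c"]], q[["vt_max_c"]])
})
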