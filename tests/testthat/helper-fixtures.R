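# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

tiny_extent <- function() {
  list(lat_min = 20, lat_max = 40, lon_min = 100, lon_max = 110)
}

tiny_grid <- function(noise = 0, seed = 1, res = 120, ...) {
  generate_monthly_climate(tiny_extent(), resolution_arcmin = res,
                           params = list(noise_sd_c = noise, ...),
                           seed = seed)
}

default_traits <- function(...) species_traits(...)

# A hand-built microclimate year with full control over the environment:
# every hour gets the supplied air/sky/surface temperatures; daylight is
# hours 6..17 of each representative day.
make_micro <- function(t_air = 25, solar = 0, t_sky = t_air, t_surf = t_air,
                       wind = 1, rh = 50, soil_temps = c(25, 25, 25),
                       soil_depths = c(0.05, 0.2, 1.0)) {
  n <- 288L
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  hours <- rep(0:23, times = 12L)
  df <- data.frame(month = rep(1:12, each = 24L),
                   rep_day_of_year = rep(ectoclim:::REP_DOY, each = 24L),
                   hour = hours,
                   t_air_ref_c = rec(t_air), t_air_animal_c = rec(t_air),
                   solar_wm2 = rec(solar), t_sky_c = rec(t_sky),
                   t_ground_surface_c = rec(t_surf), wind_ms = rec(wind),
                   rh_pct = rec(rh), is_daylight = hours >= 6 & hours <= 17)
  soil <- matrix(rep(soil_temps, each = n), nrow = n)
  attr(df, "soil") <- soil
  attr(df, "depths_m") <- soil_depths
  attr(df, "month_days") <- ectoclim:::MONTH_DAYS
  attr(df, "lat") <- 30
  attr(df, "lon") <- 105
  class(df) <- c("microclimate", "data.frame")
  df
}

# random but physically plausible hourly environments for solver oracles
random_environments <- function(n, seed) {
  set.seed(seed)
  data.frame(t_air_animal_c = runif(n, -5, 45),
             solar_wm2 = runif(n, 0, 1000) * rbinom(n, 1, 0.6),
             t_sky_c = runif(n, -25, 40),
             t_ground_surface_c = runif(n, -5, 70),
             wind_ms = runif(n, 0.05, 8),
             rh_pct = runif(n, 5, 100))
}

# brute-force operative-temperature oracle: sign-change scan of the energy
# balance on a 0.001 degC grid (coarse bracketing first, then the fine grid
# inside the bracket)
te_scan_oracle <- function(env, traits) {
  geom <- ectoclim:::body_geometry(traits)
  h <- ectoclim:::convective_coefficient(env$wind_ms, geom$diameter_m)
  sig <- 5.670374419e-8
  eps <- traits$emissivity
  gain <- traits$absorptance * env$solar_wm2 * traits$solar_silhouette_fraction +
    eps * sig * (0.5 * (env$t_sky_c + 273.15)^4 +
                   0.5 * (env$t_ground_surface_c + 273.15)^4)
  f <- function(te) gain - eps * sig * (te + 273.15)^4 - h * (te - env$t_air_animal_c)
  coarse <- seq(env$t_air_animal_c - 60, env$t_air_animal_c + 90, by = 0.5)
  fc <- f(coarse)
  i <- which(fc[-1] * fc[-length(fc)] <= 0)[1]
  fine <- seq(coarse[i], coarse[i + 1], by = 0.001)
  ff <- f(fine)
  j <- which(ff[-1] * ff[-length(ff)] <= 0)[1]
  (fine[j] + fine[j + 1]) / 2
}

# hand-built single-member ensemble whose score is an exact logistic in a
# chosen predictor (all other coefficients zero); used by attribution tests
logistic_ensemble <- function(vars, var, intercept, slope) {
  df <- data.frame(matrix(stats::rnorm(20 * length(vars)), 20,
                          dimnames = list(NULL, vars)))
  df2 <- cbind(df, setNames(as.data.frame(as.matrix(df)^2),
                            paste0(vars, "_sq")))
  df2$.y <- rep(c(0L, 1L), 10)
  fit <- suppressWarnings(glm(.y ~ ., family = binomial(), data = df2))
  co <- fit$coefficients
  co[] <- 0
  co["(Intercept)"] <- intercept
  co[var] <- slope
  fit$coefficients <- co
  member <- list(learner_id = "GLM", replicate = 1L, auc = 1, tss = 1,
                 threshold_at_max_tss = 0.5,
                 scaler = list(mu = setNames(rep(0, length(vars)), vars),
                               sd = setNames(rep(1, length(vars)), vars)),
                 model = list(learner_id = "GLM", fit = fit, vars = vars),
                 scores_presence = 1, scores_absence = 0)
  structure(list(members = list(member), weights = 1, tss_cutoff = 0.6,
                 threshold = 0.5, predictors = vars,
                 evaluation = data.frame(), design = NULL),
            class = "sdm_ensemble")
}

# predictor stack straight from named layer vectors on a 1-row grid
vector_stack <- function(layers) {
  n <- length(layers[[1]])
  g <- climate_grid(lat = 0.5, lon = seq(0.5, by = 1, length.out = n),
                    tmax_c = matrix(25, 12, n), tmin_c = matrix(15, 12, n),
                    precip_mm = matrix(100, 12, n), resolution_arcmin = 60)
  predictor_stack(g, layers)
}
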