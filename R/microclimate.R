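#' Solar zenith angle and daylight flag
#'
#' Standard declination / hour-angle spherical astronomy in local solar time.
#' Daylight is defined as the sun being above the horizon (zenith < 90 deg).
#'
#' @param lat latitude, degrees (|lat| <= 90).
#' @param day_of_year integer day of year (1-365).
#' @param hour local solar hour, 0-23 (fractions allowed).
#' @return list with \code{zenith_deg} and \code{daylight} (both vectorized).
#' @export
solar_geometry <- function(lat, day_of_year, hour) {
  if (any(abs(lat) > 90)) stop("solar_geometry: |lat| must be <= 90")
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
  phi <- lat * pi / 180
  H <- (hour - 12) * 15 * pi / 180
  cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(H)
  cosz <- pmin(1, pmax(-1, cosz))
  z <- acos(cosz) * 180 / pi
  list(zenith_deg = z, daylight = z < 90)
}

# Sunrise hour (local solar time); NA for polar night, 0 for polar day.
sunrise_hour <- function(lat, day_of_year) {
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + day_of_year) / 365)
  cosH <- -tan(lat * pi / 180) * tan(decl)
  if (cosH >= 1) return(NA_real_)
  if (cosH <= -1) return(0)
  12 - acos(cosH) * 180 / pi / 15
}

#' Diurnal air-temperature interpolation
#'
#' Expands a (tmax, tmin) pair into 24 hourly reference-height temperatures:
#' the minimum sits at the (rounded) sunrise hour, a half-sine rise reaches
#' tmax at a configurable lag after solar noon, and the night branch decays
#' exponentially back to tmin at the next sunrise. The default decay constant
#' (0.04 h^-1) gives near-linear nocturnal cooling, which keeps the daily
#' mean close to (tmax + tmin)/2 — the property monthly normals assume.
#' During polar night the series is flat at the midpoint.
#'
#' @param tmax_c,tmin_c monthly normal daily extremes, deg C (tmax >= tmin).
#' @param lat latitude in degrees (sets sunrise).
#' @param day_of_year representative day of year.
#' @param peak_lag_h hours after solar noon at which tmax occurs (default 1).
#' @param night_decay_per_h exponential decay constant of the night branch.
#' @return numeric vector of 24 temperatures (hours 0-23), all within
#'   [tmin, tmax], attaining both bounds when the sun rises that day.
#' @export
hourly_air_temperature <- function(tmax_c, tmin_c, lat, day_of_year,
                                   peak_lag_h = 1, night_decay_per_h = 0.04) {
  if (tmax_c < tmin_c) stop("hourly_air_temperature: tmax < tmin")
  hours <- 0:23
  sr <- sunrise_hour(lat, day_of_year)
  if (is.na(sr)) return(rep((tmax_c + tmin_c) / 2, 24L))
  t_sr <- max(0, round(sr))
  t_pk <- 12 + peak_lag_h
  if (t_pk <= t_sr) t_pk <- t_sr + 1
  rng <- tmax_c - tmin_c
  k <- night_decay_per_h
  D <- t_sr + 24 - t_pk  # night-branch duration (peak to next sunrise)
  day_idx <- hours >= t_sr & hours <= t_pk
  out <- numeric(24L)
  out[day_idx] <- tmin_c + rng * sin(pi / 2 * (hours[day_idx] - t_sr) / (t_pk - t_sr))
  dt <- (hours[!day_idx] - t_pk) %% 24
  out[!day_idx] <- tmin_c + rng *
    (exp(-k * dt) - exp(-k * D)) / (1 - exp(-k * D))
  out
}

#' Damped-sinusoid soil temperature
#'
#' Classic one-dimensional heat-conduction solution for a homogeneous soil
#' forced by sinusoidal surface waves: the temperature at depth z is the
#' annual mean plus an annual and a diurnal sinusoid, each damped by
#' exp(-z/d) and phase-lagged by z/d radians, where d is the corresponding
#' damping depth. The annual wave's present-day phase is anchored so that at
#' the surface the daily mean equals \code{day_mean_c}; its sign (warming or
#' cooling season) is taken from the day of year relative to the annual
#' thermal peak (day 196 in the north).
#'
#' @param depth_m depth below the surface, m (>= 0).
#' @param hour local solar hour (0-23).
#' @param day_mean_c today's mean surface temperature, deg C.
#' @param day_amplitude_c half-amplitude of today's surface diurnal wave.
#' @param annual_mean_c annual mean soil-surface temperature.
#' @param annual_amplitude_c half-amplitude of the annual surface wave.
#' @param day_of_year integer day of year.
#' @param diurnal_damping_m,annual_damping_m damping depths, m (> 0).
#' @param peak_hour hour of the surface diurnal maximum (default 14).
#' @param annual_peak_doy day of year of the annual surface maximum.
#' @return soil temperature, deg C (vectorized over depth and hour).
#' @export
soil_temperature <- function(depth_m, hour, day_mean_c, day_amplitude_c,
                             annual_mean_c, annual_amplitude_c, day_of_year,
                             diurnal_damping_m = 0.10, annual_damping_m = 1.9,
                             peak_hour = 14, annual_peak_doy = 196) {
  if (any(depth_m < 0)) stop("soil_temperature: negative depth")
  if (diurnal_damping_m <= 0 || annual_damping_m <= 0)
    stop("soil_temperature: damping depths must be > 0")
  zd <- depth_m / diurnal_damping_m
  za <- depth_m / annual_damping_m
  # annual phase angle since the thermal peak, anchored to today's surface mean
  if (annual_amplitude_c > 0) {
    c0 <- pmin(1, pmax(-1, (day_mean_c - annual_mean_c) / annual_amplitude_c))
    cooling <- ((day_of_year - annual_peak_doy) %% 365) < 182.5
    phi <- ifelse(cooling, acos(c0), 2 * pi - acos(c0))
    annual <- annual_amplitude_c * exp(-za) * cos(phi - za)
  } else {
    annual <- (day_mean_c - annual_mean_c) * exp(-za)
  }
  diurnal <- day_amplitude_c * exp(-zd) *
    cos(2 * pi * (hour - peak_hour) / 24 - zd)
  annual_mean_c + annual + diurnal
}

#' Log-profile interpolation of temperature to animal height
#'
#' Interpolates between the ground-surface temperature and the
#' reference-height air temperature along a logarithmic boundary-layer
#' profile in \code{ln((z + z0)/z0)}; exact at both ends.
#'
#' @param t_ref_c air temperature at reference height, deg C.
#' @param t_surface_c ground-surface temperature, deg C.
#' @param ref_height_m reference height (> 0), m.
#' @param animal_height_m height of the animal's midpoint (0 < z <= ref), m.
#' @param roughness_m surface roughness length z0 (> 0), m.
#' @return temperature at animal height, deg C (vectorized in temperatures).
#' @export
air_profile_to_animal_height <- function(t_ref_c, t_surface_c,
                                         ref_height_m = 1.2,
                                         animal_height_m = 0.01,
                                         roughness_m = 0.004) {
  if (ref_height_m <= 0 || animal_height_m <= 0)
    stop("air_profile_to_animal_height: heights must be positive")
  if (animal_height_m > ref_height_m)
    stop("air_profile_to_animal_height: animal height above reference height")
  if (roughness_m <= 0)
    stop("air_profile_to_animal_height: roughness must be positive")
  f <- log((animal_height_m + roughness_m) / roughness_m) /
    log((ref_height_m + roughness_m) / roughness_m)
  t_surface_c + (t_ref_c - t_surface_c) * f
}

#' Microclimate configuration
#'
#' Defaults are conventional for open short-grass habitat: reference height
#' 1.2 m, animal midpoint 0.01 m, roughness 4 mm, 1 m/s reference wind with
#' log-profile reduction, atmospheric transmissivity 0.7, a clear-sky
#' longwave offset of 20 deg C reduced by humidity, a solar-driven surface
#' excess of 0.015 deg C per W m^-2, and a saturating precipitation-to-
#' humidity map rh = rh_min + (rh_max - rh_min)(1 - exp(-P/phi)), phi = 60 mm.
#'
#' @param ... overrides of the defaults listed above.
#' @export
microclimate_config <- function(...) {
  cfg <- list(ref_height_m = 1.2, animal_height_m = 0.01, roughness_m = 0.004,
              wind_ref_ms = 1.0,
              soil_depths_m = c(0.025, 0.05, 0.1, 0.2, 0.5, 1.0),
              diurnal_damping_m = 0.10, annual_damping_m = 1.9,
              solar_constant_wm2 = 1361, transmissivity = 0.7,
              sky_offset_c = 20, sky_humidity_factor = 0.5,
              surface_solar_excess_c_per_wm2 = 0.015,
              rh_min_pct = 20, rh_max_pct = 95, rh_precip_scale_mm = 60,
              peak_lag_h = 1, night_decay_per_h = 0.04)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("microclimate_config: unknown setting(s): ",
         paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

# Representative day of year for the 15th of each month.
REP_DOY <- c(15L, 46L, 74L, 105L, 135L, 166L, 196L, 227L, 258L, 288L, 319L, 349L)
MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Build one cell-year of hourly microclimate
#'
#' Converts a cell's monthly normals into 12 representative days (the 15th of
#' each month) of 24 hourly records: reference and animal-height air
#' temperature, clear-sky solar flux, sky radiant temperature, ground-surface
#' temperature, wind speed at animal height, relative humidity and soil
#' temperature at the configured depths. Solar flux is the clear-sky beam
#' scaled by the zenith cosine and transmissivity, zero when the sun is below
#' the horizon; the ground surface runs above air temperature in proportion
#' to solar flux; sky temperature sits below air temperature by a clear-sky
#' offset shrunk under humid conditions; relative humidity follows a
#' saturating function of monthly precipitation.
#'
#' @param grid a \code{\link{climate_grid}}.
#' @param cell cell index (1-based, row-major).
#' @param config a \code{\link{microclimate_config}}.
#' @return object of class \code{microclimate}: a data.frame of 288 rows
#'   (12 months x 24 h) with attributes \code{soil} (288 x n_depths matrix),
#'   \code{depths_m}, \code{lat}, \code{lon}, \code{month_days}.
#' @export
build_microclimate_year <- function(grid, cell, config = microclimate_config()) {
  n <- n_cells(grid)
  if (!is.numeric(cell) || length(cell) != 1L || cell < 1 || cell > n)
    stop("build_microclimate_year: invalid cell index")
  cell <- as.integer(cell)
  co <- grid_coords(grid)
  lat <- co$lat[cell]; lon <- co$lon[cell]

  tmax <- grid$tmax_c[, cell]; tmin <- grid$tmin_c[, cell]
  precip <- grid$precip_mm[, cell]
  t_monthly_mean <- (tmax + tmin) / 2
  annual_mean <- mean(t_monthly_mean)
  annual_amp <- (max(t_monthly_mean) - min(t_monthly_mean)) / 2
  annual_peak_doy <- REP_DOY[which.max(t_monthly_mean)]

  rh_m <- config$rh_min_pct + (config$rh_max_pct - config$rh_min_pct) *
    (1 - exp(-precip / config$rh_precip_scale_mm))

  wind_animal <- config$wind_ref_ms *
    log((config$animal_height_m + config$roughness_m) / config$roughness_m) /
    log((config$ref_height_m + config$roughness_m) / config$roughness_m)

  hours <- 0:23
  rows <- vector("list", 12L)
  soil <- matrix(NA_real_, 288L, length(config$soil_depths_m))
  for (m in 1:12) {
    doy <- REP_DOY[m]
    t_ref <- hourly_air_temperature(tmax[m], tmin[m], lat, doy,
                                    peak_lag_h = config$peak_lag_h,
                                    night_decay_per_h = config$night_decay_per_h)
    sg <- solar_geometry(lat, doy, hours)
    cosz <- cos(sg$zenith_deg * pi / 180)
    solar <- ifelse(sg$daylight,
                    config$solar_constant_wm2 * config$transmissivity * pmax(0, cosz),
                    0)
    t_surf <- t_ref + config$surface_solar_excess_c_per_wm2 * solar
    t_sky <- t_ref - config$sky_offset_c *
      (1 - config$sky_humidity_factor * rh_m[m] / 100)
    t_animal <- air_profile_to_animal_height(
      t_ref, t_surf, config$ref_height_m, config$animal_height_m,
      config$roughness_m)
    idx <- (m - 1L) * 24L + seq_len(24L)
    # surface wave driving the soil: daily mean/amplitude of the surface temp
    day_mean_surf <- mean(t_surf)
    day_amp_surf <- (max(t_surf) - min(t_surf)) / 2
    for (d in seq_along(config$soil_depths_m)) {
      soil[idx, d] <- soil_temperature(
        config$soil_depths_m[d], hours,
        day_mean_c = day_mean_surf, day_amplitude_c = day_amp_surf,
        annual_mean_c = annual_mean, annual_amplitude_c = annual_amp,
        day_of_year = doy,
        diurnal_damping_m = config$diurnal_damping_m,
        annual_damping_m = config$annual_damping_m,
        annual_peak_doy = annual_peak_doy)
    }
    rows[[m]] <- data.frame(
      month = m, rep_day_of_year = doy, hour = hours,
      t_air_ref_c = t_ref, t_air_animal_c = t_animal,
      solar_wm2 = solar, t_sky_c = t_sky, t_ground_surface_c = t_surf,
      wind_ms = wind_animal, rh_pct = rh_m[m], is_daylight = sg$daylight)
  }
  out <- do.call(rbind, rows)
  attr(out, "soil") <- soil
  attr(out, "depths_m") <- config$soil_depths_m
  attr(out, "lat") <- lat
  attr(out, "lon") <- lon
  attr(out, "month_days") <- MONTH_DAYS
  class(out) <- c("microclimate", "data.frame")
  out
}

#' Export an hourly microclimate series as CSV
#'
#' Columns: \code{month,day,hour,t_air_ref,t_air_animal,solar,t_sky,
#' t_surface,wind,rh,t_soil_<depth>}.
#'
#' @param micro a \code{microclimate}; \code{path} a file path.
#' @export
write_microclimate_csv <- function(micro, path) {
  soil <- attr(micro, "soil")
  colnames(soil) <- paste0("t_soil_", attr(micro, "depths_m"))
  df <- data.frame(month = micro$month, day = micro$rep_day_of_year,
                   hour = micro$hour, t_air_ref = micro$t_air_ref_c,
                   t_air_animal = micro$t_air_animal_c,
                   solar = micro$solar_wm2, t_sky = micro$t_sky_c,
                   t_surface = micro$t_ground_surface_c,
                   wind = micro$wind_ms, rh = micro$rh_pct, soil)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
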