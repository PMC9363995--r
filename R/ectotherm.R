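STEFAN_BOLTZMANN <- 5.670374419e-8  # W m^-2 K^-4
K_AIR <- 0.0257                     # thermal conductivity of air, W m^-1 K^-1
NU_AIR <- 1.55e-5                   # kinematic viscosity of air, m^2 s^-1
O2_FRACTION <- 0.2094               # O2 volume fraction of air

#' Saturation water-vapour density
#'
#' Tetens saturation vapour pressure converted to an absolute density by the
#' ideal gas law; strictly increasing in temperature.
#'
#' @param t_c air temperature, deg C (valid -40 to 60).
#' @return vapour density at saturation, g m^-3 (vectorized).
#' @export
saturation_vapor_density <- function(t_c) {
  if (any(t_c < -40 | t_c > 60))
    stop("saturation_vapor_density: temperature outside [-40, 60] degC")
  es_pa <- 610.78 * exp(17.27 * t_c / (t_c + 237.3))
  es_pa / (461.5 * (t_c + 273.15)) * 1000
}

# Convective heat-transfer coefficient for a cylinder in cross-flow:
# forced-convection correlation h = C (k/D) Re^0.5 with a free-convection
# floor for still air.
convective_coefficient <- function(wind_ms, diameter_m, c_forced = 0.6,
                                   h_free_floor = 5) {
  re <- pmax(0, wind_ms) * diameter_m / NU_AIR
  pmax(c_forced * K_AIR / diameter_m * sqrt(re), h_free_floor)
}

# Vectorized steady-state operative temperature: root of
#   alpha S f_sil + eps sigma (F_sky Tsky^4 + F_gnd Tsurf^4)
#     - eps sigma Te^4 - h (Te - Tair) = 0
# (per unit total area). Left side strictly decreasing in Te, so the root is
# unique; solved by damped Newton iteration from Te = Tair.
te_solve <- function(solar_wm2, t_sky_c, t_surf_c, t_air_c, wind_ms, traits,
                     tol_c = 1e-6, max_iter = 100L) {
  geom <- body_geometry(traits)
  h <- convective_coefficient(wind_ms, geom$diameter_m)
  eps <- traits$emissivity
  sig <- STEFAN_BOLTZMANN
  gain <- traits$absorptance * solar_wm2 * traits$solar_silhouette_fraction +
    eps * sig * (0.5 * (t_sky_c + 273.15)^4 + 0.5 * (t_surf_c + 273.15)^4)
  te <- t_air_c
  for (i in seq_len(max_iter)) {
    tk <- te + 273.15
    f <- gain - eps * sig * tk^4 - h * (te - t_air_c)
    fp <- -4 * eps * sig * tk^3 - h
    step <- f / fp
    te <- te - step
    if (max(abs(step)) < tol_c) break
  }
  attr(te, "residual_wm2") <- gain - eps * sig * (te + 273.15)^4 -
    h * (te - t_air_c)
  te
}

#' Operative (environmental equilibrium) temperature
#'
#' The steady-state temperature of the animal-shaped object in one hourly
#' microclimate record, balancing absorbed shortwave and longwave radiation
#' against emitted longwave and convection. In the shaded posture direct
#' solar is zero and the radiant surroundings (sky and ground) are at the
#' local air temperature, so the shaded operative temperature collapses to
#' air temperature.
#'
#' @param env one row of a \code{microclimate} series (fields
#'   \code{t_air_animal_c}, \code{solar_wm2}, \code{t_sky_c},
#'   \code{t_ground_surface_c}, \code{wind_ms}).
#' @param traits a \code{\link{species_traits}}.
#' @param posture "exposed" (full sun) or "shaded".
#' @return operative temperature, deg C, with the energy-balance residual
#'   (W m^-2) attached as attribute \code{residual_wm2}.
#' @export
operative_temperature <- function(env, traits,
                                  posture = c("exposed", "shaded")) {
  posture <- match.arg(posture)
  vals <- c(env$t_air_animal_c, env$solar_wm2, env$t_sky_c,
            env$t_ground_surface_c, env$wind_ms)
  if (any(!is.finite(vals)))
    stop("operative_temperature: non-finite environment fields")
  if (posture == "shaded") {
    te_solve(0, env$t_air_animal_c, env$t_air_animal_c, env$t_air_animal_c,
             env$wind_ms, traits)
  } else {
    te_solve(env$solar_wm2, env$t_sky_c, env$t_ground_surface_c,
             env$t_air_animal_c, env$wind_ms, traits)
  }
}

#' Metabolic rate (oxygen consumption)
#'
#' Allometric-exponential model VO2 = met_a * mass^met_b * exp(met_q * Tb),
#' ml O2 h^-1; strictly increasing in both mass and body temperature.
#'
#' @param mass_g body mass, g.
#' @param t_body_c body temperature, deg C; must lie within
#'   [ctmin_c, ctmax_c] of the traits.
#' @param traits a \code{\link{species_traits}} (supplies met_a, met_b,
#'   met_q and the tolerance bounds).
#' @return ml O2 h^-1 (vectorized over t_body_c).
#' @export
metabolic_rate <- function(mass_g, t_body_c, traits) {
  if (any(mass_g <= 0)) stop("metabolic_rate: mass must be > 0")
  if (any(t_body_c < traits$ctmin_c - 1e-9 | t_body_c > traits$ctmax_c + 1e-9))
    stop("metabolic_rate: body temperature outside [ctmin, ctmax]")
  traits$met_a * mass_g^traits$met_b * exp(traits$met_q * t_body_c)
}

# Vectorized water-loss components, g/h. eyes_open: logical vector.
# t_air_c / rh_pct describe the air the animal is actually in (burrow air for
# retreating animals).
water_loss_components <- function(t_body_c, t_air_c, rh_pct, eyes_open,
                                  traits, vo2_ml_h) {
  A <- body_geometry(traits)$area_m2
  grad <- pmax(0, saturation_vapor_density(t_body_c) -
                 rh_pct / 100 * saturation_vapor_density(t_air_c))
  cut <- A * grad /
    (traits$skin_resistance_s_per_m + traits$boundary_resistance_s_per_m) * 3600
  vent_m3_h <- vo2_ml_h / (O2_FRACTION * traits$o2_extraction) * 1e-6
  resp <- vent_m3_h * grad
  ocu <- ifelse(eyes_open,
                traits$eye_area_fraction * A * grad /
                  traits$boundary_resistance_s_per_m * 3600,
                0)
  data.frame(cutaneous_g_h = cut, respiratory_g_h = resp, ocular_g_h = ocu,
             total_g_h = cut + resp + ocu)
}

#' Evaporative water loss with components
#'
#' Total water loss is the sum of cutaneous, respiratory and ocular
#' evaporation. Cutaneous loss drives the skin-air vapour density gradient
#' through skin plus boundary-layer resistance; respiratory loss saturates
#' the ventilated air volume (ventilation from VO2, the oxygen content of
#' air and the lung's extraction efficiency); ocular loss is free-surface
#' evaporation from the wet eye area and occurs only with eyes open (active
#' or basking). All gradients are floored at zero.
#'
#' @param t_body_c body temperature, deg C.
#' @param env one microclimate record (uses \code{t_air_animal_c},
#'   \code{rh_pct}).
#' @param state "active", "basking" or "retreat".
#' @param traits a \code{\link{species_traits}}.
#' @param vo2 current oxygen consumption, ml O2 h^-1 (>= 0).
#' @return one-row data.frame with \code{cutaneous_g_h},
#'   \code{respiratory_g_h}, \code{ocular_g_h}, \code{total_g_h}.
#' @export
water_loss_rate <- function(t_body_c, env, state, traits, vo2) {
  if (any(vo2 < 0)) stop("water_loss_rate: vo2 must be >= 0")
  if (!state %in% c("active", "basking", "retreat"))
    stop("water_loss_rate: unknown state '", state, "'")
  water_loss_components(t_body_c, env$t_air_animal_c, env$rh_pct,
                        eyes_open = state %in% c("active", "basking"),
                        traits = traits, vo2_ml_h = vo2)
}

#' One hour of behavioural thermoregulation
#'
#' Decision order: (1) night: in the retreat; (2) the open-habitat operative
#' temperature lies within the activity band [vt_min, vt_max]: active at
#' that temperature; (3) it is below the band but at or above the emergence
#' temperature: basking (not counted as activity); (4) otherwise (too cold
#' to emerge, or dangerously hot): burrowed at the depth whose soil
#' temperature is closest to the preferred temperature (ties to the
#' shallower depth), body temperature clamped to [ctmin, ctmax].
#'
#' @param t_e_open,t_e_shade operative temperatures, deg C, in the two
#'   postures (shade currently informs no decision but is carried through).
#' @param t_soil named numeric vector of soil temperatures; names are depths
#'   in metres.
#' @param daylight logical.
#' @param traits a \code{\link{species_traits}}.
#' @param prev previous \code{HourState} (unused by the memoryless rules;
#'   accepted for interface stability).
#' @return list with \code{state}, \code{t_e_c} (open-posture Te),
#'   \code{t_body_c}, \code{depth_m} (0 above ground).
#' @export
behavioural_step <- function(t_e_open, t_e_shade, t_soil, daylight, traits,
                             prev = NULL) {
  if (!length(t_soil)) stop("behavioural_step: empty soil profile")
  depths <- as.numeric(names(t_soil))
  if (any(is.na(depths)))
    stop("behavioural_step: t_soil names must be depths in metres")
  retreat <- function() {
    i <- which.min(abs(t_soil - traits$t_pref_c))  # which.min takes first tie
    list(state = "retreat", t_e_c = t_e_open,
         t_body_c = min(max(t_soil[[i]], traits$ctmin_c), traits$ctmax_c),
         depth_m = depths[i])
  }
  if (!daylight) return(retreat())
  if (t_e_open >= traits$vt_min_c && t_e_open <= traits$vt_max_c)
    return(list(state = "active", t_e_c = t_e_open, t_body_c = t_e_open,
                depth_m = 0))
  if (t_e_open < traits$vt_min_c && t_e_open >= traits$t_emerge_c)
    return(list(state = "basking", t_e_c = t_e_open, t_body_c = t_e_open,
                depth_m = 0))
  retreat()
}

#' Simulate a lizard's year in one cell
#'
#' Applies \code{\link{behavioural_step}} to every hour of a 12 x 24
#' representative-day microclimate year, evaluating operative temperatures
#' in the exposed and shaded postures, metabolic rate and water loss per
#' hour. Annual activity is the sum over months of the representative day's
#' active hours times the month length. The thermal safety margin is
#' TSM = CTmax - Te-max, with Te-max the annual maximum of the open-posture
#' (full sun) operative temperature over all hours.
#'
#' @param micro a \code{microclimate} from
#'   \code{\link{build_microclimate_year}} (288 records).
#' @param traits a \code{\link{species_traits}}.
#' @param burrow_rh_pct relative humidity of retreat air (default 95).
#' @return list with \code{hours} (data.frame of per-hour states and rates)
#'   and \code{summary} (class \code{ecto_summary}: tsm_c, activity_h_yr,
#'   max_mr_ml_o2_h, max_wl_g_h, t_e_max_c).
#' @export
simulate_year <- function(micro, traits, burrow_rh_pct = 95) {
  if (nrow(micro) != 288L)
    stop("simulate_year: need a 288-record microclimate year")
  validate_traits(traits)
  soil <- attr(micro, "soil")
  depths <- attr(micro, "depths_m")
  month_days <- attr(micro, "month_days")
  if (is.null(soil) || is.null(depths))
    stop("simulate_year: microclimate lacks a soil profile")

  te_open <- te_solve(micro$solar_wm2, micro$t_sky_c,
                      micro$t_ground_surface_c, micro$t_air_animal_c,
                      micro$wind_ms, traits)
  te_shade <- te_solve(0, micro$t_air_animal_c, micro$t_air_animal_c,
                       micro$t_air_animal_c, micro$wind_ms, traits)
  res_open <- attr(te_open, "residual_wm2")
  te_open <- as.numeric(te_open); te_shade <- as.numeric(te_shade)

  active <- micro$is_daylight & te_open >= traits$vt_min_c &
    te_open <= traits$vt_max_c
  basking <- micro$is_daylight & !active & te_open < traits$vt_min_c &
    te_open >= traits$t_emerge_c
  in_retreat <- !(active | basking)

  # retreat depth: nearest soil temperature to Tpref, ties to shallower
  didx <- max.col(-abs(soil - traits$t_pref_c), ties.method = "first")
  t_soil_chosen <- soil[cbind(seq_len(nrow(soil)), didx)]

  t_body <- ifelse(in_retreat,
                   pmin(pmax(t_soil_chosen, traits$ctmin_c), traits$ctmax_c),
                   te_open)
  depth <- ifelse(in_retreat, depths[didx], 0)
  state <- ifelse(active, "active", ifelse(basking, "basking", "retreat"))

  mr <- metabolic_rate(traits$mass_g, t_body, traits)
  air_t <- ifelse(in_retreat, t_body, micro$t_air_animal_c)
  air_rh <- ifelse(in_retreat, burrow_rh_pct, micro$rh_pct)
  wl <- water_loss_components(t_body, air_t, air_rh, eyes_open = !in_retreat,
                              traits = traits, vo2_ml_h = mr)

  activity_h <- sum(tapply(active, micro$month, sum) * month_days)
  t_e_max <- max(te_open)
  summary <- structure(
    list(tsm_c = traits$ctmax_c - t_e_max,
         activity_h_yr = as.numeric(activity_h),
         max_mr_ml_o2_h = max(mr), max_wl_g_h = max(wl$total_g_h),
         t_e_max_c = t_e_max),
    class = "ecto_summary")

  hours <- data.frame(month = micro$month, hour = micro$hour, state = state,
                      t_e_open_c = te_open, t_e_shade_c = te_shade,
                      t_body_c = t_body, depth_m = depth,
                      mr_ml_o2_h = mr, wl)
  attr(hours, "te_residual_wm2") <- res_open
  list(hours = hours, summary = summary)
}

#' @export
print.ecto_summary <- function(x, ...) {
  cat(sprintf("ecto_summary: TSM %.2f degC (Te-max %.2f), activity %.0f h/yr, max VO2 %.3f ml/h, max water loss %.4f g/h\n",
              x$tsm_c, x$t_e_max_c, x$activity_h_yr, x$max_mr_ml_o2_h,
              x$max_wl_g_h))
  invisible(x)
}

#' Expand a representative-day year to a full hourly year
#'
#' Repeats each month's 24-hour representative day for the month's number of
#' days, giving an 8760-hour cyclic series.
#'
#' @param series_288 numeric vector of 288 values (12 months x 24 h).
#' @param month_days days per month (default non-leap calendar).
#' @return numeric vector of 8760 values.
#' @export
expand_representative_year <- function(series_288, month_days = MONTH_DAYS) {
  if (length(series_288) != 288L)
    stop("expand_representative_year: need 288 values")
  unlist(lapply(1:12, function(m) {
    rep(series_288[(m - 1L) * 24L + 1:24], times = month_days[m])
  }), use.names = FALSE)
}

#' Per-cell biophysical layers for a whole grid
#'
#' Runs the microclimate and ectotherm models (and, when a development model
#' is supplied, the embryo model at the nest depth) for every cell of a
#' climate grid. This is the workhorse behind the hybrid-SDM's biophysical
#' predictors.
#'
#' @param grid a \code{\link{climate_grid}}.
#' @param traits a \code{\link{species_traits}}.
#' @param dev_model optional \code{\link{fit_development_model}} result; when
#'   given, \code{incubation_days} and \code{time_window_h} are computed from
#'   hourly nest temperatures.
#' @param config a \code{\link{microclimate_config}}.
#' @param nest_depth_m soil depth of the nest (default 0.05 m; must be one of
#'   the configured soil depths).
#' @param cells optional subset of cell indices.
#' @return data.frame, one row per cell: \code{cell, lon, lat, tsm_c,
#'   activity_h_yr, max_mr_ml_o2_h, max_wl_g_h, t_e_max_c} and, with a
#'   development model, \code{incubation_days, time_window_h}.
#' @export
compute_biophysical_layers <- function(grid, traits, dev_model = NULL,
                                       config = microclimate_config(),
                                       nest_depth_m = 0.05, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(n_cells(grid))
  co <- grid_coords(grid)
  nd <- match(nest_depth_m, config$soil_depths_m)
  if (!is.null(dev_model) && is.na(nd))
    stop("compute_biophysical_layers: nest_depth_m must be a configured soil depth")
  out <- vector("list", length(cells))
  for (k in seq_along(cells)) {
    cell <- cells[k]
    micro <- build_microclimate_year(grid, cell, config)
    sim <- simulate_year(micro, traits)
    row <- data.frame(cell = cell, lon = co$lon[cell], lat = co$lat[cell],
                      tsm_c = sim$summary$tsm_c,
                      activity_h_yr = sim$summary$activity_h_yr,
                      max_mr_ml_o2_h = sim$summary$max_mr_ml_o2_h,
                      max_wl_g_h = sim$summary$max_wl_g_h,
                      t_e_max_c = sim$summary$t_e_max_c)
    if (!is.null(dev_model)) {
      nest288 <- attr(micro, "soil")[, nd]
      nest_year <- expand_representative_year(nest288)
      start <- oviposition_start(nest288, dev_model)
      inc <- if (is.na(start)) NA_real_ else
        incubation_period(nest_year, dev_model, start_hour = start)
      # cells where development never completes are censored at one year so
      # the layer stays defined over the whole grid
      row$incubation_days <- if (is.na(inc)) 365 else inc
      row$time_window_h <- time_window(nest288, dev_model)
    }
    out[[k]] <- row
  }
  do.call(rbind, out)
}

#' Write per-cell ectotherm summaries to CSV
#'
#' Columns \code{cell,lon,lat,tsm,activity_h,max_mr,max_wl} plus
#' \code{incubation_days,time_window_h} when present.
#'
#' @param layers data.frame from \code{\link{compute_biophysical_layers}};
#'   \code{path} a file path.
#' @export
write_ecto_summary_csv <- function(layers, path) {
  df <- data.frame(cell = layers$cell, lon = layers$lon, lat = layers$lat,
                   tsm = layers$tsm_c, activity_h = layers$activity_h_yr,
                   max_mr = layers$max_mr_ml_o2_h, max_wl = layers$max_wl_g_h)
  if (!is.null(layers$incubation_days)) {
    df$incubation_days <- layers$incubation_days
    df$time_window_h <- layers$time_window_h
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
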