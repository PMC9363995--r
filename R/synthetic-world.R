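#' Generate a parametric monthly climate grid
#'
#' Builds a synthetic but climatologically structured grid of monthly normals:
#' an annual-mean surface that is linear in latitude, sinusoidal seasonality
#' whose amplitude grows with distance from the equator (peaking in July in
#' the northern hemisphere, January in the southern), a fixed diurnal range
#' splitting the monthly mean into tmax/tmin, and a summer-wet precipitation
#' cycle. Optional cell-level Gaussian noise perturbs the annual mean;
#' precipitation noise is multiplicative log-normal. Elevation defaults to
#' sea level; when supplied (or generated) a lapse rate couples it to
#' temperature.
#'
#' @param extent list or named vector with \code{lat_min}, \code{lat_max},
#'   \code{lon_min}, \code{lon_max} (degrees).
#' @param resolution_arcmin cell size in arc-minutes (> 0).
#' @param params list of surface parameters, see Details. Unspecified entries
#'   take the defaults of \code{synthetic_world_params()}.
#' @param seed integer seed controlling the noise field; same seed, same grid.
#'
#' @details Parameters (all finite; defaults in parentheses):
#' \describe{
#'   \item{t_ref_c (28)}{annual mean temperature at the equator, deg C.}
#'   \item{lapse_per_deg_lat (-0.6)}{change in annual mean per degree of
#'     absolute latitude, deg C / deg.}
#'   \item{seasonal_amp_base_c (2)}{seasonal half-amplitude at the equator.}
#'   \item{seasonal_amp_per_deg (0.35)}{growth of the half-amplitude per
#'     degree of absolute latitude.}
#'   \item{diurnal_range_c (10)}{tmax - tmin, constant across months.}
#'   \item{precip_base_mm (80)}{mean monthly precipitation.}
#'   \item{precip_seasonality (0.5)}{relative amplitude of the summer-wet
#'     precipitation cycle (0 = aseasonal).}
#'   \item{noise_sd_c (0)}{s.d. of the per-cell annual-mean temperature
#'     offset (applied to tmax and tmin alike).}
#'   \item{precip_noise_sd (0)}{s.d. of the per-cell log-normal
#'     precipitation factor.}
#'   \item{elevation_lapse_c_per_km (-6.5)}{temperature lapse with elevation.}
#' }
#'
#' @return a \code{\link{climate_grid}}.
#' @export
generate_monthly_climate <- function(extent, resolution_arcmin = 10,
                                     params = list(), seed = 1L) {
  p <- utils::modifyList(synthetic_world_params(), params)
  bad <- names(Filter(function(v) !all(is.finite(v)), p))
  if (length(bad))
    stop("generate_monthly_climate: non-finite params: ",
         paste(bad, collapse = ", "))
  if (!is.numeric(resolution_arcmin) || resolution_arcmin <= 0)
    stop("generate_monthly_climate: 'resolution_arcmin' must be > 0")
  ex <- as.list(extent)
  for (nm in c("lat_min", "lat_max", "lon_min", "lon_max"))
    if (is.null(ex[[nm]]) || !is.finite(ex[[nm]]))
      stop("generate_monthly_climate: extent is missing field '", nm, "'")
  res_deg <- resolution_arcmin / 60
  axis <- function(lo, hi) {
    if (lo + res_deg / 2 > hi) numeric(0)
    else seq(lo + res_deg / 2, hi, by = res_deg)
  }
  lat <- rev(axis(ex$lat_min, ex$lat_max))
  lon <- axis(ex$lon_min, ex$lon_max)
  if (!length(lat) || !length(lon))
    stop("generate_monthly_climate: zero-cell extent (check lat_min/lat_max, lon_min/lon_max)")

  co <- expand.grid(lon = lon, lat_row = seq_along(lat))  # row-major cells
  cell_lat <- lat[co$lat_row]
  n_cell <- length(cell_lat)

  t_mean <- p$t_ref_c + p$lapse_per_deg_lat * abs(cell_lat)
  amp <- p$seasonal_amp_base_c + p$seasonal_amp_per_deg * abs(cell_lat)
  # month of thermal peak: July in the NH, January in the SH
  peak <- ifelse(cell_lat >= 0, 7, 1)
  month <- 1:12
  seas <- outer(month, seq_len(n_cell),
                function(m, j) cos(2 * pi * (m - peak[j]) / 12))
  t_monthly <- sweep(seas * rep(amp, each = 12L), 2L, t_mean, `+`)

  elev <- numeric(n_cell)
  if (p$elevation_amp_m > 0) {
    # smooth dome of terrain, centred on the extent
    clat <- mean(range(cell_lat)); clon <- mean(range(co$lon))
    r2 <- ((cell_lat - clat) / max(1e-9, diff(range(cell_lat)) / 2))^2 +
      ((co$lon - clon) / max(1e-9, diff(range(co$lon)) / 2))^2
    elev <- p$elevation_amp_m * exp(-r2)
  }
  t_monthly <- sweep(t_monthly, 2L, p$elevation_lapse_c_per_km * elev / 1000, `+`)

  wet_peak <- ifelse(cell_lat >= 0, 7, 1)
  pseas <- outer(month, seq_len(n_cell),
                 function(m, j) 1 + p$precip_seasonality *
                   cos(2 * pi * (m - wet_peak[j]) / 12))
  precip <- p$precip_base_mm * pseas

  set.seed(as.integer(seed))
  if (p$noise_sd_c > 0) {
    off <- stats::rnorm(n_cell, 0, p$noise_sd_c)
    t_monthly <- sweep(t_monthly, 2L, off, `+`)
  }
  if (p$precip_noise_sd > 0) {
    fac <- exp(stats::rnorm(n_cell, 0, p$precip_noise_sd))
    precip <- sweep(precip, 2L, fac, `*`)
  }
  precip[precip < 0] <- 0

  climate_grid(lat, lon,
               tmax_c = t_monthly + p$diurnal_range_c / 2,
               tmin_c = t_monthly - p$diurnal_range_c / 2,
               precip_mm = precip, elevation_m = elev,
               resolution_arcmin = resolution_arcmin)
}

#' @rdname generate_monthly_climate
#' @export
synthetic_world_params <- function() {
  list(t_ref_c = 28, lapse_per_deg_lat = -0.6,
       seasonal_amp_base_c = 2, seasonal_amp_per_deg = 0.35,
       diurnal_range_c = 10,
       precip_base_mm = 80, precip_seasonality = 0.5,
       noise_sd_c = 0, precip_noise_sd = 0,
       elevation_amp_m = 0, elevation_lapse_c_per_km = -6.5)
}

#' Warming scenario
#'
#' An additive temperature offset plus a multiplicative precipitation factor,
#' the shape in which GCM projection anomalies are applied to the baseline
#' normals. \code{delta_t_c} may be a scalar, a length-12 monthly vector, or
#' a full 12 x n_cell matrix.
#'
#' @param delta_t_c additive warming, deg C.
#' @param precip_factor multiplicative precipitation factor (> 0).
#' @param label scenario name.
#' @export
warming_scenario <- function(delta_t_c = 0, precip_factor = 1,
                             label = "scenario") {
  if (any(!is.finite(precip_factor)) || any(precip_factor <= 0))
    stop("warming_scenario: 'precip_factor' must be > 0")
  if (any(!is.finite(delta_t_c)))
    stop("warming_scenario: 'delta_t_c' must be finite")
  structure(list(delta_t_c = delta_t_c, precip_factor = precip_factor,
                 label = label), class = "warming_scenario")
}

#' Apply a warming scenario to a climate grid
#'
#' Shifts tmax and tmin by the scenario's temperature offset and scales
#' precipitation; the tmax >= tmin ordering is preserved because both bounds
#' receive the same shift.
#'
#' @param grid a \code{climate_grid}.
#' @param scenario a \code{\link{warming_scenario}}.
#' @return a new \code{climate_grid}.
#' @export
apply_warming_scenario <- function(grid, scenario) {
  stopifnot(inherits(grid, "climate_grid"), inherits(scenario, "warming_scenario"))
  d <- scenario$delta_t_c
  if (is.matrix(d)) {
    if (nrow(d) != 12L || ncol(d) != n_cells(grid))
      stop("apply_warming_scenario: delta_t_c matrix must be 12 x n_cell")
  } else if (!(length(d) %in% c(1L, 12L))) {
    stop("apply_warming_scenario: delta_t_c must be scalar, length 12 or 12 x n_cell")
  }
  climate_grid(grid$lat, grid$lon,
               tmax_c = grid$tmax_c + d,
               tmin_c = grid$tmin_c + d,
               precip_mm = grid$precip_mm * scenario$precip_factor,
               elevation_m = grid$elevation_m,
               resolution_arcmin = grid$resolution_arcmin)
}

#' Average several climate projections cell-wise
#'
#' Equal-weight element-wise mean of tmax, tmin and precipitation across
#' grids with identical geometry — the conventional multi-model ensemble
#' mean of GCM projections.
#'
#' @param grids list of \code{climate_grid}s sharing geometry.
#' @return a \code{climate_grid}.
#' @export
average_projections <- function(grids) {
  if (!length(grids)) stop("average_projections: need at least one grid")
  g1 <- grids[[1L]]
  for (g in grids[-1L])
    if (!same_geometry(g1, g))
      stop("average_projections: grids differ in geometry")
  mean_of <- function(field) Reduce(`+`, lapply(grids, `[[`, field)) / length(grids)
  climate_grid(g1$lat, g1$lon,
               tmax_c = mean_of("tmax_c"), tmin_c = mean_of("tmin_c"),
               precip_mm = mean_of("precip_mm"),
               elevation_m = Reduce(`+`, lapply(grids, `[[`, "elevation_m")) / length(grids),
               resolution_arcmin = g1$resolution_arcmin)
}

#' Virtual species with known response curves
#'
#' A virtual species couples organismal traits to a known parametric
#' suitability surface, so that distribution-model recovery can be tested
#' against ground truth. Each predictor response is logistic
#' (\code{plogis(sign * (x - midpoint) / scale)}) or Gaussian
#' (\code{exp(-0.5 ((x - optimum)/breadth)^2)}); responses are combined by
#' product or mean.
#'
#' @param traits a \code{\link{species_traits}} object.
#' @param response_spec named list, one entry per predictor, each a list with
#'   \code{type} ("logistic" or "gaussian") and its parameters
#'   (\code{midpoint}, \code{scale}, \code{sign} / \code{optimum},
#'   \code{breadth}).
#' @param combine_rule "product" or "mean".
#' @param species_id species label.
#' @export
virtual_species <- function(traits, response_spec,
                            combine_rule = c("product", "mean"),
                            species_id = "virtual_sp") {
  combine_rule <- match.arg(combine_rule)
  if (!length(response_spec) || is.null(names(response_spec)) ||
      any(!nzchar(names(response_spec))))
    stop("virtual_species: 'response_spec' must be a named list of responses")
  for (nm in names(response_spec)) {
    r <- response_spec[[nm]]
    if (!r$type %in% c("logistic", "gaussian"))
      stop("virtual_species: unknown response type for '", nm, "'")
  }
  structure(list(traits = traits, response_spec = response_spec,
                 combine_rule = combine_rule, species_id = species_id),
            class = "virtual_species")
}

eval_response <- function(r, x) {
  switch(r$type,
         logistic = stats::plogis(if (is.null(r$sign)) 1 else r$sign *
                                    (x - r$midpoint) / r$scale),
         gaussian = exp(-0.5 * ((x - r$optimum) / r$breadth)^2),
         stop("unknown response type"))
}

#' True suitability of a virtual species
#'
#' Evaluates the species' parametric response composition on per-cell
#' predictor values. Deterministic; output in [0, 1].
#'
#' @param species a \code{\link{virtual_species}}.
#' @param predictors named list (or data.frame) of per-cell numeric vectors;
#'   must contain every predictor named in the species' response spec.
#' @return numeric vector of per-cell suitabilities.
#' @export
true_suitability <- function(species, predictors) {
  need <- names(species$response_spec)
  miss <- setdiff(need, names(predictors))
  if (length(miss))
    stop("true_suitability: missing predictor(s): ", paste(miss, collapse = ", "))
  parts <- lapply(need, function(nm)
    eval_response(species$response_spec[[nm]], predictors[[nm]]))
  out <- switch(species$combine_rule,
                product = Reduce(`*`, parts),
                mean = Reduce(`+`, parts) / length(parts))
  pmin(1, pmax(0, out))
}

#' Occurrence set
#'
#' @param records data.frame with columns \code{lon}, \code{lat} and
#'   optionally \code{source}.
#' @param species_id species label.
#' @export
occurrence_set <- function(records, species_id = "sp") {
  records <- as.data.frame(records)
  if (!all(c("lon", "lat") %in% names(records)))
    stop("occurrence_set: records need 'lon' and 'lat' columns")
  if (is.null(records$source))
    records$source <- rep("synthetic", nrow(records))
  structure(list(records = records[, c("lon", "lat", "source")],
                 species_id = species_id), class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set '%s': %d records\n",
              x$species_id, nrow(x$records)))
  invisible(x)
}

#' Sample occurrence records from a suitability surface
#'
#' Draws cells with probability proportional to suitability (with
#' replacement), then jitters each point uniformly within its cell, emulating
#' presence-only sampling of a species whose density follows habitat quality.
#'
#' @param species a \code{\link{virtual_species}} (supplies the species id).
#' @param grid the \code{climate_grid} defining cell geometry.
#' @param suitability per-cell non-negative weights; must not be all zero.
#' @param n number of records (>= 1).
#' @param seed integer seed; same seed, same points.
#' @return an \code{\link{occurrence_set}}.
#' @export
sample_occurrences <- function(species, grid, suitability, n, seed = 1L) {
  if (n < 1) stop("sample_occurrences: 'n' must be >= 1")
  if (length(suitability) != n_cells(grid))
    stop("sample_occurrences: suitability length != number of cells")
  if (any(suitability < 0) || !any(suitability > 0))
    stop("sample_occurrences: suitability must be non-negative with positive sum")
  set.seed(as.integer(seed))
  cells <- sample.int(length(suitability), n, replace = TRUE,
                      prob = suitability)
  co <- grid_coords(grid)
  half <- grid$resolution_arcmin / 60 / 2
  jlon <- stats::runif(n, -half, half)
  jlat <- stats::runif(n, -half, half)
  occurrence_set(data.frame(lon = co$lon[cells] + jlon,
                            lat = co$lat[cells] + jlat,
                            source = "sampled"),
                 species_id = species$species_id)
}

#' Occurrence CSV I/O (\code{species,lon,lat,source})
#'
#' @param occ an \code{occurrence_set}; \code{path} a file path.
#' @rdname occurrence_csv
#' @export
write_occurrences_csv <- function(occ, path) {
  df <- data.frame(species = occ$species_id, occ$records)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname occurrence_csv
#' @export
read_occurrences_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("read_occurrences_csv: need columns ", paste(need, collapse = ", "))
  occurrence_set(df[, c("lon", "lat", intersect("source", names(df)))],
                 species_id = as.character(df$species[1L]))
}

#' Map coordinates to grid cell indices
#'
#' @param grid a \code{climate_grid}; \code{lon}, \code{lat} point vectors.
#' @return integer cell indices (NA for points outside the grid extent).
#' @export
cell_from_lonlat <- function(grid, lon, lat) {
  res <- grid$resolution_arcmin / 60
  nr <- length(grid$lat); nc <- length(grid$lon)
  row <- round((grid$lat[1L] - lat) / res) + 1L
  col <- round((lon - grid$lon[1L]) / res) + 1L
  ok <- row >= 1L & row <= nr & col >= 1L & col <= nc
  out <- rep(NA_integer_, length(lon))
  out[ok] <- (row[ok] - 1L) * nc + col[ok]
  out
}
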