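#' Species trait set for the biophysical model
#'
#' All organismal parameters of the heat/water-budget simulation. Activity is
#' bounded by the 25% and 75% quantiles of field body temperatures
#' (\code{vt_min_c}, \code{vt_max_c}); animals leave the retreat when the
#' open-habitat operative temperature reaches \code{t_emerge_c} (default
#' 17 deg C, the average minimum field body temperature across the study
#' species). Geometry is a cylinder of length:diameter 6:1 at tissue density
#' 1000 kg m^-3. Metabolic allometry is
#' VO2 = met_a * mass^met_b * exp(met_q * Tb) in ml O2 h^-1; the default
#' coefficients are documented assumptions, not literature fits.
#'
#' @param mass_g body mass, g (> 0).
#' @param ctmax_c,ctmin_c critical thermal maximum / minimum, deg C.
#' @param vt_min_c,vt_max_c 25% and 75% quantiles of field body temperature.
#' @param t_pref_c preferred (selected) body temperature.
#' @param t_emerge_c leaving-retreat temperature.
#' @param absorptance solar absorptivity (0-1).
#' @param emissivity longwave emissivity (0-1).
#' @param met_a,met_b,met_q metabolic allometry coefficients.
#' @param skin_resistance_s_per_m cutaneous resistance to water vapour, s/m.
#' @param boundary_resistance_s_per_m boundary-layer vapour resistance, s/m.
#' @param o2_extraction oxygen extraction efficiency of the lung (0-1).
#' @param eye_area_fraction fraction of skin area that is wet eye surface.
#' @param solar_silhouette_fraction fraction of total area intercepting beam
#'   solar radiation.
#' @param length_diameter_ratio cylinder elongation (length / diameter).
#' @return object of class \code{species_traits}.
#' @export
species_traits <- function(mass_g = 5, ctmax_c = 42, ctmin_c = 4,
                           vt_min_c = 26, vt_max_c = 34, t_pref_c = 30,
                           t_emerge_c = 17,
                           absorptance = 0.85, emissivity = 0.95,
                           met_a = 0.1, met_b = 0.8, met_q = 0.07,
                           skin_resistance_s_per_m = 12000,
                           boundary_resistance_s_per_m = 300,
                           o2_extraction = 0.16, eye_area_fraction = 0.002,
                           solar_silhouette_fraction = 0.4,
                           length_diameter_ratio = 6) {
  tr <- list(mass_g = mass_g, ctmax_c = ctmax_c, ctmin_c = ctmin_c,
             vt_min_c = vt_min_c, vt_max_c = vt_max_c, t_pref_c = t_pref_c,
             t_emerge_c = t_emerge_c, absorptance = absorptance,
             emissivity = emissivity, met_a = met_a, met_b = met_b,
             met_q = met_q,
             skin_resistance_s_per_m = skin_resistance_s_per_m,
             boundary_resistance_s_per_m = boundary_resistance_s_per_m,
             o2_extraction = o2_extraction,
             eye_area_fraction = eye_area_fraction,
             solar_silhouette_fraction = solar_silhouette_fraction,
             length_diameter_ratio = length_diameter_ratio)
  validate_traits(tr)
  structure(tr, class = "species_traits")
}

validate_traits <- function(tr) {
  if (tr$mass_g <= 0) stop("species_traits: mass_g must be > 0")
  if (!(tr$ctmin_c < tr$vt_min_c && tr$vt_min_c <= tr$t_pref_c &&
        tr$t_pref_c <= tr$vt_max_c && tr$vt_max_c < tr$ctmax_c))
    stop("species_traits: need ctmin < vt_min <= t_pref <= vt_max < ctmax")
  for (nm in c("absorptance", "emissivity", "o2_extraction",
               "eye_area_fraction", "solar_silhouette_fraction")) {
    v <- tr[[nm]]
    if (v < 0 || v > 1)
      stop("species_traits: '", nm, "' must lie in [0, 1]")
  }
  if (tr$skin_resistance_s_per_m < 0 || tr$boundary_resistance_s_per_m <= 0)
    stop("species_traits: vapour resistances must be non-negative (boundary > 0)")
  invisible(tr)
}

#' @export
print.species_traits <- function(x, ...) {
  g <- body_geometry(x)
  cat(sprintf("species_traits: %.1f g lizard, CTmin %.1f | VTmin %.1f | Tpref %.1f | VTmax %.1f | CTmax %.1f degC\n",
              x$mass_g, x$ctmin_c, x$vt_min_c, x$t_pref_c, x$vt_max_c,
              x$ctmax_c))
  cat(sprintf("  cylinder D = %.1f mm, L = %.1f mm, skin area %.1f cm^2\n",
              1000 * g$diameter_m, 1000 * g$length_m, 1e4 * g$area_m2))
  invisible(x)
}

# Cylinder geometry from mass at tissue density 1000 kg/m^3.
body_geometry <- function(traits) {
  vol_m3 <- traits$mass_g * 1e-6
  k <- traits$length_diameter_ratio
  d <- (4 * vol_m3 / (pi * k))^(1 / 3)
  list(diameter_m = d, length_m = k * d,
       area_m2 = pi * d^2 * k + pi * d^2 / 2)  # lateral + both end caps
}

#' Field-quantile activity bounds from body-temperature samples
#'
#' Computes the 25% and 75% quantiles of a sample of field body temperatures
#' with the linear-interpolation quantile definition (type 7), the bounds
#' within which the animal is scored active.
#'
#' @param tb_samples numeric vector of field body temperatures, deg C.
#' @return named vector \code{c(vt_min_c=, vt_max_c=)}.
#' @export
activity_quantiles <- function(tb_samples) {
  if (length(tb_samples) < 2L)
    stop("activity_quantiles: need at least two samples")
  q <- stats::quantile(tb_samples, c(0.25, 0.75), names = FALSE, type = 7)
  c(vt_min_c = q[1L], vt_max_c = q[2L])
}

#' Traits CSV I/O (one row per species)
#'
#' Columns match the arguments of \code{\link{species_traits}} plus a
#' \code{species} label column.
#'
#' @param path file path; \code{traits_list} a named list of
#'   \code{species_traits}.
#' @rdname traits_csv
#' @export
write_traits_csv <- function(traits_list, path) {
  rows <- lapply(names(traits_list), function(nm)
    data.frame(species = nm, as.data.frame(unclass(traits_list[[nm]]))))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname traits_csv
#' @export
read_traits_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"species" %in% names(df))
    stop("read_traits_csv: need a 'species' column")
  out <- lapply(seq_len(nrow(df)), function(i) {
    args <- as.list(df[i, setdiff(names(df), "species")])
    do.call(species_traits, args)
  })
  names(out) <- df$species
  out
}
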