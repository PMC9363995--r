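#' Monthly climate grid
#'
#' The central climate container: a rectangular lon/lat grid of monthly
#' normals. Temperatures are degrees Celsius, precipitation is mm per month.
#' Row 1 is the northernmost row; cells are numbered row-major, so cell
#' \code{(i, j)} has index \code{(i - 1) * n_lon + j}. Coordinates refer to
#' cell centres (WGS84 lon/lat).
#'
#' @param lat numeric vector of cell-centre latitudes, strictly decreasing
#'   (north to south), degrees north.
#' @param lon numeric vector of cell-centre longitudes, strictly increasing,
#'   degrees east.
#' @param tmax_c,tmin_c 12 x n_cell matrices of monthly maximum / minimum
#'   air temperature (deg C).
#' @param precip_mm 12 x n_cell matrix of monthly precipitation (mm).
#' @param elevation_m per-cell elevation in metres (length n_cell); defaults
#'   to sea level.
#' @param resolution_arcmin grid resolution in arc-minutes.
#'
#' @return An object of class \code{climate_grid}.
#' @export
climate_grid <- function(lat, lon, tmax_c, tmin_c, precip_mm,
                         elevation_m = NULL, resolution_arcmin = 10) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (length(lat) < 1L || length(lon) < 1L)
    stop("climate_grid: 'lat' and 'lon' must be non-empty (zero-cell extent)")
  if (length(lat) > 1L && any(diff(lat) >= 0))
    stop("climate_grid: 'lat' must be strictly decreasing (row 1 is north)")
  if (length(lon) > 1L && any(diff(lon) <= 0))
    stop("climate_grid: 'lon' must be strictly increasing")
  n_cell <- length(lat) * length(lon)
  for (nm in c("tmax_c", "tmin_c", "precip_mm")) {
    m <- get(nm)
    if (!is.matrix(m) || nrow(m) != 12L || ncol(m) != n_cell)
      stop(sprintf("climate_grid: '%s' must be a 12 x %d matrix", nm, n_cell))
    if (any(!is.finite(m)))
      stop(sprintf("climate_grid: '%s' contains non-finite values", nm))
  }
  if (any(tmax_c < tmin_c))
    stop("climate_grid: 'tmax_c' must be >= 'tmin_c' everywhere")
  if (any(precip_mm < 0))
    stop("climate_grid: 'precip_mm' must be non-negative")
  if (is.null(elevation_m)) elevation_m <- numeric(n_cell)
  if (length(elevation_m) != n_cell)
    stop("climate_grid: 'elevation_m' must have one value per cell")
  structure(
    list(lat = lat, lon = lon,
         tmax_c = tmax_c, tmin_c = tmin_c, precip_mm = precip_mm,
         elevation_m = as.numeric(elevation_m),
         resolution_arcmin = resolution_arcmin),
    class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("climate_grid: %d x %d cells (%.4g arc-min)\n",
              length(x$lat), length(x$lon), x$resolution_arcmin))
  cat(sprintf("  lat %.3f .. %.3f, lon %.3f .. %.3f\n",
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  cat(sprintf("  annual mean T: %.2f .. %.2f degC, annual precip: %.0f .. %.0f mm\n",
              min(colMeans((x$tmax_c + x$tmin_c) / 2)),
              max(colMeans((x$tmax_c + x$tmin_c) / 2)),
              min(colSums(x$precip_mm)), max(colSums(x$precip_mm))))
  invisible(x)
}

n_cells <- function(grid) length(grid$lat) * length(grid$lon)

#' Per-cell coordinates of a climate grid
#'
#' @param grid a \code{climate_grid}.
#' @return data.frame with columns \code{cell}, \code{row}, \code{col},
#'   \code{lon}, \code{lat} in row-major cell order.
#' @export
grid_coords <- function(grid) {
  nr <- length(grid$lat); nc <- length(grid$lon)
  data.frame(cell = seq_len(nr * nc),
             row = rep(seq_len(nr), each = nc),
             col = rep(seq_len(nc), times = nr),
             lon = rep(grid$lon, times = nr),
             lat = rep(grid$lat, each = nc))
}

same_geometry <- function(a, b, tol = 1e-9) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    max(abs(a$lat - b$lat)) <= tol && max(abs(a$lon - b$lon)) <= tol
}

#' Write / read a climate grid as long-format CSV
#'
#' One row per (cell, month) with columns
#' \code{cell,row,col,lon,lat,elevation_m,month,tmax_c,tmin_c,precip_mm}.
#' A plain-text exchange format; \code{read_climate_csv} inverts
#' \code{write_climate_csv} exactly.
#'
#' @param grid a \code{climate_grid}.
#' @param path file path.
#' @rdname climate_csv
#' @export
write_climate_csv <- function(grid, path) {
  co <- grid_coords(grid)
  df <- data.frame(
    cell = rep(co$cell, each = 12L), row = rep(co$row, each = 12L),
    col = rep(co$col, each = 12L), lon = rep(co$lon, each = 12L),
    lat = rep(co$lat, each = 12L),
    elevation_m = rep(grid$elevation_m, each = 12L),
    month = rep(1:12, times = nrow(co)),
    tmax_c = as.vector(grid$tmax_c[, co$cell]),
    tmin_c = as.vector(grid$tmin_c[, co$cell]),
    precip_mm = as.vector(grid$precip_mm[, co$cell]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param resolution_arcmin resolution recorded in the restored grid.
#' @rdname climate_csv
#' @export
read_climate_csv <- function(path, resolution_arcmin = 10) {
  df <- utils::read.csv(path)
  need <- c("cell", "month", "lon", "lat", "elevation_m",
            "tmax_c", "tmin_c", "precip_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_climate_csv: missing columns: ", paste(miss, collapse = ", "))
  lat <- sort(unique(df$lat), decreasing = TRUE)
  lon <- sort(unique(df$lon))
  n_cell <- length(lat) * length(lon)
  ord <- order(df$cell, df$month)
  df <- df[ord, ]
  shape <- function(v) matrix(v, nrow = 12L, ncol = n_cell)
  climate_grid(lat, lon, shape(df$tmax_c), shape(df$tmin_c),
               shape(df$precip_mm),
               elevation_m = df$elevation_m[df$month == 1L],
               resolution_arcmin = resolution_arcmin)
}
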