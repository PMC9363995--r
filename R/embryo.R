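#' Incubation experiment table
#'
#' Laboratory incubation results: incubation period and hatching success at
#' a series of constant temperatures.
#'
#' @param temperature_c tested incubation temperatures, deg C (>= 3 distinct).
#' @param incubation_days days to hatching at each temperature (> 0).
#' @param hatching_success proportion hatching (0-1).
#' @return data.frame of class \code{incubation_table}.
#' @export
incubation_table <- function(temperature_c, incubation_days,
                             hatching_success) {
  df <- data.frame(temperature_c = temperature_c,
                   incubation_days = incubation_days,
                   hatching_success = hatching_success)
  if (length(unique(df$temperature_c)) < 3L)
    stop("incubation_table: need at least 3 distinct temperatures")
  if (any(df$incubation_days <= 0))
    stop("incubation_table: incubation_days must be > 0")
  if (any(df$hatching_success < 0 | df$hatching_success > 1))
    stop("incubation_table: hatching_success must lie in [0, 1]")
  class(df) <- c("incubation_table", "data.frame")
  df
}

#' @rdname incubation_table
#' @param path CSV with columns \code{temp_c,days,success}.
#' @export
read_incubation_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("temp_c", "days", "success")
  if (!all(need %in% names(df)))
    stop("read_incubation_csv: need columns ", paste(need, collapse = ", "))
  incubation_table(df$temp_c, df$days, df$success)
}

#' Viable temperature bounds from hatching success
#'
#' The lowest and highest tested temperatures whose hatching success meets
#' the threshold, each extended outward by half the spacing to the adjacent
#' tested temperature (at the ends of the tested range, the inward spacing
#' is used).
#'
#' @param table an \code{\link{incubation_table}}.
#' @param threshold minimum hatching success counted as viable (default 0.5).
#' @return named vector \code{c(viable_lo_c=, viable_hi_c=)}.
#' @export
viable_bounds <- function(table, threshold = 0.5) {
  agg <- stats::aggregate(hatching_success ~ temperature_c,
                          data = as.data.frame(table), FUN = mean)
  agg <- agg[order(agg$temperature_c), ]
  pass <- which(agg$hatching_success >= threshold)
  if (!length(pass))
    stop("viable_bounds: no temperature reaches hatching success >= ",
         threshold)
  t <- agg$temperature_c
  k <- length(t)
  lo_i <- min(pass); hi_i <- max(pass)
  gap_lo <- if (lo_i > 1L) t[lo_i] - t[lo_i - 1L] else t[lo_i + 1L] - t[lo_i]
  gap_hi <- if (hi_i < k) t[hi_i + 1L] - t[hi_i] else t[hi_i] - t[hi_i - 1L]
  c(viable_lo_c = t[lo_i] - gap_lo / 2, viable_hi_c = t[hi_i] + gap_hi / 2)
}

#' Fit a degree-day embryonic development model
#'
#' Regresses development rate (1/incubation days) on temperature by ordinary
#' least squares over the temperatures whose hatching success meets the
#' threshold; the slope s and intercept c give the thermal constant
#' (degree-days = 1/s) and developmental zero (t0 = -c/s). Viable bounds come
#' from \code{\link{viable_bounds}} on the full table.
#'
#' @param table an \code{\link{incubation_table}}.
#' @param success_threshold rows with hatching success below this are
#'   excluded from the rate regression (default 0.5).
#' @return object of class \code{dev_rate_model} with fields \code{t0_c},
#'   \code{degree_days}, \code{viable_lo_c}, \code{viable_hi_c}.
#' @export
fit_development_model <- function(table, success_threshold = 0.5) {
  df <- as.data.frame(table)
  keep <- df[df$hatching_success >= success_threshold, ]
  if (length(unique(keep$temperature_c)) < 2L)
    stop("fit_development_model: fewer than two viable temperatures")
  fit <- stats::lm(I(1 / incubation_days) ~ temperature_c, data = keep)
  s <- unname(stats::coef(fit)[2L]); c0 <- unname(stats::coef(fit)[1L])
  if (!is.finite(s) || s <= 0)
    stop("fit_development_model: non-positive rate slope (no thermal development signal)")
  vb <- viable_bounds(table, success_threshold)
  dev_rate_model(t0_c = -c0 / s, degree_days = 1 / s,
                 viable_lo_c = vb[["viable_lo_c"]],
                 viable_hi_c = vb[["viable_hi_c"]])
}

#' @rdname fit_development_model
#' @param t0_c developmental zero, deg C.
#' @param degree_days thermal constant, deg C day (> 0).
#' @param viable_lo_c,viable_hi_c temperature bounds of suitability.
#' @export
dev_rate_model <- function(t0_c, degree_days, viable_lo_c, viable_hi_c) {
  if (degree_days <= 0) stop("dev_rate_model: degree_days must be > 0")
  if (viable_lo_c >= viable_hi_c)
    stop("dev_rate_model: viable_lo_c must be below viable_hi_c")
  if (t0_c > viable_lo_c + 1e-9)
    warning("dev_rate_model: developmental zero above the lower viable bound")
  structure(list(t0_c = t0_c, degree_days = degree_days,
                 viable_lo_c = viable_lo_c, viable_hi_c = viable_hi_c),
            class = "dev_rate_model")
}

#' @export
print.dev_rate_model <- function(x, ...) {
  cat(sprintf("dev_rate_model: t0 = %.2f degC, %.0f degree-days, viable %.1f-%.1f degC\n",
              x$t0_c, x$degree_days, x$viable_lo_c, x$viable_hi_c))
  invisible(x)
}

# hourly development increments for a temperature series
dev_increments <- function(t_c, model) {
  inc <- pmax(0, t_c - model$t0_c) / (24 * model$degree_days)
  inc[t_c < model$viable_lo_c | t_c > model$viable_hi_c] <- 0
  inc
}

#' Incubation period from an hourly nest-temperature year
#'
#' Accumulates hourly development increments
#' max(0, T - t0) / (24 * degree_days), zeroed outside the viable bounds
#' (development arrests rather than fails), starting at the oviposition hour
#' and wrapping cyclically around the year. Returns the elapsed days when
#' cumulative development reaches 1, or \code{NA} if hatching is not reached
#' within 365 days.
#'
#' @param nest_temps_c hourly nest temperatures covering a full year
#'   (8760 values, treated as cyclic).
#' @param model a \code{\link{dev_rate_model}}.
#' @param start_hour 1-based hour index of oviposition.
#' @return incubation period in days, or \code{NA_real_}.
#' @export
incubation_period <- function(nest_temps_c, model, start_hour = 1L) {
  n <- length(nest_temps_c)
  if (n < 8760L)
    stop("incubation_period: need a full cyclic year of hourly temperatures (8760 values)")
  start_hour <- ((as.integer(start_hour) - 1L) %% n) + 1L
  rotated <- c(nest_temps_c[start_hour:n],
               nest_temps_c[seq_len(start_hour - 1L)])[seq_len(8760L)]
  cum <- cumsum(dev_increments(rotated, model))
  idx <- which(cum >= 1)[1L]
  if (is.na(idx)) return(NA_real_)
  idx / 24
}

#' Representative oviposition hour
#'
#' The first representative day (calendar order) whose daily mean nest
#' temperature reaches the lower viable bound; returns the 1-based index of
#' that month's first hour in the expanded 8760-h year, or \code{NA} when no
#' month qualifies.
#'
#' @param nest_288 hourly nest temperatures on the 12 representative days.
#' @param model a \code{\link{dev_rate_model}}.
#' @param month_days days per month.
#' @export
oviposition_start <- function(nest_288, model, month_days = MONTH_DAYS) {
  daily_mean <- colMeans(matrix(nest_288, nrow = 24L))
  m <- which(daily_mean >= model$viable_lo_c)[1L]
  if (is.na(m)) return(NA_integer_)
  if (m == 1L) 1L else as.integer(sum(month_days[seq_len(m - 1L)]) * 24L + 1L)
}

#' Annual time window suitable for embryonic development
#'
#' Number of hours per year with nest temperature inside the viable bounds;
#' each representative-day hour is weighted by its month's length.
#'
#' @param nest_288 hourly nest temperatures on the 12 representative days
#'   (12 x 24 values).
#' @param model a \code{\link{dev_rate_model}}.
#' @param month_days days per month.
#' @return hours per year in [0, 8760].
#' @export
time_window <- function(nest_288, model, month_days = MONTH_DAYS) {
  if (length(nest_288) != 288L) stop("time_window: need 288 hourly values")
  ok <- nest_288 >= model$viable_lo_c & nest_288 <= model$viable_hi_c
  month <- rep(1:12, each = 24L)
  sum(tapply(ok, month, sum) * month_days)
}
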