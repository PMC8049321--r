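#' Front intensity index from a gridded SST field
#'
#' The front intensity index (FII) is the maximum magnitude of the
#' sea-surface-temperature gradient within a given radius of the
#' observation point. Gradients are computed per cell by central finite
#' differences (one-sided at field edges) on the km grid, and the
#' maximum is taken over cells whose centres lie within `radius_km` of
#' `center`.
#'
#' @param grid Tibble of one SST field: `x_km`, `y_km`, `sst` on a
#'   regular rectangular grid.
#' @param radius_km Disc radius; the survey protocol uses 5, 10, 15 and
#'   20 km.
#' @param center Length-2 numeric, the observation point in grid
#'   coordinates (default the origin).
#' @return FII in degrees C per km (non-negative scalar).
#' @export
front_intensity_index <- function(grid, radius_km, center = c(0, 0)) {
  xs <- sort(unique(grid$x_km))
  ys <- sort(unique(grid$y_km))
  if (min(xs) > center[1] - radius_km || max(xs) < center[1] + radius_km ||
      min(ys) > center[2] - radius_km || max(ys) < center[2] + radius_km) {
    stop("grid does not cover the ", radius_km, " km disc", call. = FALSE)
  }
  m <- matrix(NA_real_, nrow = length(xs), ncol = length(ys))
  m[cbind(match(grid$x_km, xs), match(grid$y_km, ys))] <- grid$sst
  if (anyNA(m)) stop("grid is not complete on its bounding rectangle",
                     call. = FALSE)
  gx <- grad_1d(m, xs, along = 1)
  gy <- grad_1d(m, ys, along = 2)
  mag <- sqrt(gx^2 + gy^2)
  d2 <- outer((xs - center[1])^2, (ys - center[2])^2, `+`)
  max(mag[d2 <= radius_km^2])
}

# finite-difference gradient along rows (along = 1) or columns (2):
# central in the interior, one-sided at the edges
grad_1d <- function(m, coords, along) {
  if (along == 2) return(t(grad_1d(t(m), coords, 1)))
  n <- nrow(m)
  g <- matrix(0, n, ncol(m))
  if (n >= 3) {
    g[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) /
      (coords[3:n] - coords[1:(n - 2)])
  }
  if (n >= 2) {
    g[1, ] <- (m[2, ] - m[1, ]) / (coords[2] - coords[1])
    g[n, ] <- (m[n, ] - m[n - 1, ]) / (coords[n] - coords[n - 1])
  }
  g
}

#' Daily cross-shore Ekman transport from coastal wind
#'
#' Computes alongshore wind stress with the bulk formula
#' tau = rho_air * C_d * |W| * W_alongshore and the cross-shore Ekman
#' transport tau / (rho_sw * f), reported per 100 m of coastline
#' (m^3/s/100m). The sign convention is oceanographic for an eastern
#' boundary: positive transport = upwelling-favorable (equatorward
#' alongshore wind).
#'
#' @param wind Tibble with `date`, `u`, `v`: wind vector components in
#'   m/s, eastward and northward.
#' @param latitude Latitude in degrees (sets the Coriolis parameter).
#' @param coast_angle Orientation of the coastline in degrees
#'   clockwise from north; 0 = coast runs north-south (equatorward =
#'   southward).
#' @param rho_air,c_d,rho_sw Bulk-formula constants: air density
#'   (kg/m^3), drag coefficient, seawater density (kg/m^3).
#' @return The input tibble with `stress` (N/m^2, alongshore,
#'   positive equatorward) and `transport` (m^3/s/100m) columns.
#' @export
ekman_transport <- function(wind, latitude = 38, coast_angle = 0,
                            rho_air = 1.22, c_d = 1.3e-3, rho_sw = 1025) {
  if (abs(latitude) < 1) {
    stop("Coriolis parameter vanishes near the equator; |latitude| must be >= 1",
         call. = FALSE)
  }
  theta <- coast_angle * pi / 180
  # unit vector pointing equatorward along the coast (southward for
  # coast_angle = 0 in the northern hemisphere)
  eq_sign <- if (latitude >= 0) -1 else 1
  along <- eq_sign * (wind$v * cos(theta) + wind$u * sin(theta))
  speed <- sqrt(wind$u^2 + wind$v^2)
  stress <- rho_air * c_d * speed * along
  f <- 2 * 7.2921e-5 * sin(latitude * pi / 180)
  transport <- stress / (rho_sw * abs(f)) * 100   # per 100 m coastline
  wind %>% mutate(stress = stress, transport = transport)
}

#' Spring transition date from a year of daily Ekman transport
#'
#' The spring transition marks the onset of the sustained upwelling
#' season: the day of year at which the cumulative sum of daily
#' upwelling-favorable transport (from January 1) reaches its minimum.
#' Winter downwelling drives the cumulative curve down; it turns when
#' equatorward winds set in. Also returned is the anomaly from day 90,
#' the climatological reference date.
#'
#' @param transport Numeric vector of daily transport for one year, in
#'   day order (>= 300 days).
#' @return A list: `stb_day` (day of year), `stb_anomaly`
#'   (`stb_day - 90`).
#' @export
spring_transition <- function(transport) {
  transport <- transport[!is.na(transport)]
  if (length(transport) < 300) {
    stop("need >= 300 days of transport to locate the spring transition",
         call. = FALSE)
  }
  cum <- cumsum(transport)
  if (all(diff(cum) > 0)) {
    warning("cumulative transport increases monotonically (no winter ",
            "downwelling); returning day 1")
    day <- 1L
  } else {
    day <- which.min(cum)
  }
  list(stb_day = as.integer(day), stb_anomaly = as.integer(day) - 90L)
}

#' Seasonal and annual averages of an environmental series
#'
#' Averages a monthly (or daily, averaged to monthly first) series over
#' the standard seasons: winter = Dec-Feb, spring = Mar-May, summer =
#' Jun-Aug, fall = Sep-Nov. Winter of year Y spans Dec(Y-1) through
#' Feb(Y). Under the `"adjusted"` year convention months are first
#' assigned to the June-1-start species year and seasons are then read
#' off the calendar months as usual.
#'
#' @param series Tibble with `year`, `month`, and `value` columns.
#' @param season One of `"winter"`, `"spring"`, `"summer"`, `"fall"`,
#'   or `"annual"`.
#' @param year Target year (calendar label, or adjusted-year label).
#' @param year_convention `"calendar"` or `"adjusted"`.
#' @return The arithmetic mean of the member months; errors if a member
#'   month is missing, naming it.
#' @export
seasonal_average <- function(series, season, year,
                             year_convention = c("calendar", "adjusted")) {
  year_convention <- match.arg(year_convention)
  stopifnot(all(c("year", "month", "value") %in% names(series)))
  months <- member_months(season, year, year_convention)
  vals <- dplyr::inner_join(months, series, by = c("year", "month"))
  if (nrow(vals) < nrow(months)) {
    miss <- dplyr::anti_join(months, series, by = c("year", "month"))
    stop("missing month(s): ",
         paste(miss$year, miss$month, sep = "-", collapse = ", "),
         call. = FALSE)
  }
  mean(vals$value)
}

# calendar (year, month) pairs making up a season of a species year
member_months <- function(season, year, year_convention) {
  if (year_convention == "calendar") {
    switch(season,
      annual = tibble(year = year, month = 1:12),
      winter = tibble(year = c(year - 1, year, year), month = c(12, 1, 2)),
      spring = tibble(year = year, month = 3:5),
      summer = tibble(year = year, month = 6:8),
      fall   = tibble(year = year, month = 9:11),
      stop("unknown season: ", season, call. = FALSE))
  } else {
    # adjusted year Y = Jun(Y)..May(Y+1); seasons keep their calendar
    # months, mapped into that window
    switch(season,
      annual = tibble(year = c(rep(year, 7), rep(year + 1, 5)),
                      month = c(6:12, 1:5)),
      winter = tibble(year = c(year, year + 1, year + 1), month = c(12, 1, 2)),
      spring = tibble(year = year + 1, month = 3:5),
      summer = tibble(year = year, month = 6:8),
      fall   = tibble(year = year, month = 9:11),
      stop("unknown season: ", season, call. = FALSE))
  }
}

#' Lag a monthly series by whole months
#'
#' The value reported for month m is the raw value at month m - k, so a
#' lagged covariate carries information already available k months
#' earlier. Months whose lag reaches before the series start are NA.
#'
#' @param series Tibble with `year`, `month`, `value`, in any order.
#' @param k Lag in months (1, 2, or 3 in the standard covariate set).
#' @return The series with `value` replaced by the lagged value.
#' @export
lag_series <- function(series, k) {
  stopifnot(k >= 0, k == round(k))
  series %>%
    arrange(.data$year, .data$month) %>%
    mutate(value = dplyr::lag(.data$value, n = k))
}
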