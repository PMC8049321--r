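#' Build the per species-year environmental covariate table
#'
#' Assembles the covariate set the timing models screen: annual and
#' seasonal averages of SST, SSS, and the upwelling index; annual front
#' intensity index at 5/10/15/20 km radii; the spring transition date;
#' and annual, seasonal, previous-winter/previous-spring, and 1-3 month
#' lagged versions of the monthly basin-scale climate indices (SOI,
#' PDO, NPGO). "Previous winter"/"previous spring" are the named season
#' of the species year immediately preceding the focal one, under that
#' species' year convention.
#'
#' @param env Environment tables as produced by
#'   [simulate_environment()]: `ocean`, `sst_grid`, `wind`, `climate`.
#' @param years Integer vector of species-year labels to cover.
#' @param year_convention `"calendar"` or `"adjusted"` (June-1-start).
#' @param ui_monthly Optional monthly upwelling-index series (`year`,
#'   `month`, `value`, m^3/s/100m). When absent it is synthesised from
#'   the daily wind via [ekman_transport()] monthly means.
#' @param latitude Latitude for the Ekman computation.
#' @return A tibble with one row per species-year and one column per
#'   covariate variant; the `availability` attribute maps each covariate
#'   to the last day (on the species axis) at which its raw data window
#'   closes, used for forecast eligibility.
#' @export
build_covariate_table <- function(env, years,
                                  year_convention = c("calendar", "adjusted"),
                                  ui_monthly = NULL, latitude = 38) {
  year_convention <- match.arg(year_convention)
  monthly <- list()
  to_monthly <- function(daily, var) {
    daily %>%
      mutate(year = lubridate::year(.data$date),
             month = lubridate::month(.data$date)) %>%
      group_by(.data$year, .data$month) %>%
      summarise(value = mean(.data[[var]]), .groups = "drop")
  }
  monthly$sst <- to_monthly(env$ocean, "sst")
  monthly$sss <- to_monthly(env$ocean, "sss")
  for (idx in c("soi", "pdo", "npgo")) {
    monthly[[idx]] <- env$climate %>%
      select("year", "month", value = dplyr::all_of(idx))
  }
  if (is.null(ui_monthly)) {
    ui_monthly <- ekman_transport(env$wind, latitude = latitude) %>%
      to_monthly("transport")
  }
  monthly$ui <- ui_monthly

  seasons <- c("annual", "winter", "spring", "summer", "fall")
  rows <- purrr::map(years, function(y) {
    out <- list(species_year = y)
    grab <- function(series, season, year) {
      tryCatch(seasonal_average(series, season, year, year_convention),
               error = function(e) NA_real_)
    }
    for (v in c("sst", "sss", "ui", "soi", "pdo", "npgo")) {
      for (s in seasons) {
        nm <- if (s == "annual") paste0(v, "_annual") else paste0(v, "_", s)
        out[[nm]] <- grab(monthly[[v]], s, y)
      }
      out[[paste0(v, "_prev_winter")]] <- grab(monthly[[v]], "winter", y - 1)
      out[[paste0(v, "_prev_spring")]] <- grab(monthly[[v]], "spring", y - 1)
    }
    for (k in 1:3) {
      for (v in c("soi", "pdo", "npgo")) {
        out[[paste0(v, "_lag", k)]] <-
          grab(lag_series(monthly[[v]], k), "annual", y)
      }
    }
    as_tibble(out)
  }) %>% bind_rows()

  # annual FII per radius from the monthly gridded fields
  if (!is.null(env$sst_grid)) {
    fii <- env$sst_grid %>%
      mutate(cal_year = lubridate::year(.data$date)) %>%
      tidyr::nest(field = c("x_km", "y_km", "sst")) %>%
      dplyr::rowwise() %>%
      dplyr::reframe(cal_year = .data$cal_year, date = .data$date,
                     fii_r5 = front_intensity_index(.data$field, 5),
                     fii_r10 = front_intensity_index(.data$field, 10),
                     fii_r15 = front_intensity_index(.data$field, 15),
                     fii_r20 = front_intensity_index(.data$field, 20))
    fii_m <- fii %>%
      mutate(month = lubridate::month(.data$date)) %>%
      select("cal_year", "month", dplyr::starts_with("fii_"))
    fii_year <- purrr::map(years, function(y) {
      mm <- member_months("annual", y, year_convention)
      joined <- dplyr::inner_join(mm, fii_m,
                                  by = c(year = "cal_year", "month"))
      tibble(species_year = y,
             fii_r5 = mean(joined$fii_r5), fii_r10 = mean(joined$fii_r10),
             fii_r15 = mean(joined$fii_r15), fii_r20 = mean(joined$fii_r20))
    }) %>% bind_rows()
    rows <- left_join(rows, fii_year, by = "species_year")
  }

  # spring transition per species year: the upwelling onset in the
  # spring that falls inside the species year
  if (!is.null(env$wind)) {
    tr <- ekman_transport(env$wind, latitude = latitude) %>%
      mutate(cal_year = lubridate::year(.data$date))
    stb_cal <- tr %>%
      group_by(.data$cal_year) %>%
      summarise(stb = list(tryCatch(
        suppressWarnings(spring_transition(.data$transport)),
        error = function(e) list(stb_day = NA_integer_,
                                 stb_anomaly = NA_integer_))),
        .groups = "drop") %>%
      mutate(stb_day = purrr::map_int(.data$stb, "stb_day"),
             stb_anomaly = purrr::map_int(.data$stb, "stb_anomaly")) %>%
      select("cal_year", "stb_day", "stb_anomaly")
    offset <- if (year_convention == "adjusted") 1L else 0L
    rows <- rows %>%
      left_join(stb_cal, by = c(species_year = "cal_year")) %>%
      { if (offset == 1L) {
          select(., -"stb_day", -"stb_anomaly") %>%
            left_join(stb_cal %>%
                        mutate(species_year = .data$cal_year - 1L) %>%
                        select("species_year", "stb_day", "stb_anomaly"),
                      by = "species_year")
        } else . }
  }

  attr(rows, "availability") <-
    covariate_availability(setdiff(names(rows), "species_year"),
                           year_convention)
  rows
}

#' Forecast availability day of a covariate variant
#'
#' For each covariate column name, the last day on the species-year
#' axis on which the underlying raw data window closes. A forecast
#' model may only use covariates whose window closes before the
#' migration period begins. Previous-season covariates close before the
#' species year starts (non-positive day).
#'
#' @param covariates Character vector of covariate column names as
#'   produced by [build_covariate_table()].
#' @param year_convention `"calendar"` or `"adjusted"`.
#' @return Named numeric vector of availability days.
#' @export
covariate_availability <- function(covariates,
                                   year_convention = c("calendar", "adjusted")) {
  year_convention <- match.arg(year_convention)
  # day on the species axis at which each calendar season's last month ends
  ends <- if (year_convention == "calendar") {
    c(winter = 59, spring = 151, summer = 243, fall = 334, annual = 365)
  } else {
    # adjusted year starts Jun 1: summer ends Aug 31 (day 92), fall
    # Nov 30 (day 183), winter Feb 28 (day 273), spring May 31 (day 365)
    c(winter = 273, spring = 365, summer = 92, fall = 183, annual = 365)
  }
  vapply(covariates, function(nm) {
    if (grepl("_prev_winter$", nm)) return(ends[["winter"]] - 365)
    if (grepl("_prev_spring$", nm)) return(ends[["spring"]] - 365)
    if (grepl("_lag([123])$", nm)) {
      k <- as.numeric(sub(".*_lag([123])$", "\\1", nm))
      return(ends[["annual"]] - 30.4 * k)
    }
    if (grepl("_winter$", nm)) return(ends[["winter"]])
    if (grepl("_spring$", nm)) return(ends[["spring"]])
    if (grepl("_summer$", nm)) return(ends[["summer"]])
    if (grepl("_fall$", nm)) return(ends[["fall"]])
    if (grepl("^stb", nm)) return(ends[["spring"]])
    if (grepl("^fii", nm)) return(ends[["annual"]])
    ends[["annual"]]
  }, numeric(1))
}
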