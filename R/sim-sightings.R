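#' Generate synthetic daily whale sightings
#'
#' Draws daily counts for each configured species from a negative
#' binomial (NB2) distribution around a seasonal intensity curve. The
#' curve is a Gaussian (or, for the bimodal gray season, a two-component
#' Gaussian mixture) on the species' own year axis; its centre drifts by
#' `timing_trend` days per year and the expected annual total follows the
#' log-polynomial `abundance_trend`. Species surveyed twice daily (the
#' gray-whale winter protocol) get independent morning and evening
#' draws whose average is the daily value.
#'
#' @param config A [sim_config()] object.
#' @param species Character vector of species to generate; defaults to
#'   all configured species.
#' @return A tibble with one row per species-day: `date`, `species`,
#'   `species_year`, `day` (on the species axis), `count` (daily value;
#'   the morning/evening average for twice-daily species), `morning`,
#'   `evening` (NA for once-daily species), and `mu_true`, the noiseless
#'   intensity. The `truth` attribute holds a tibble of per species-year
#'   true peak days and the arrival/peak/departure days of the noiseless
#'   curve.
#' @export
simulate_sightings <- function(config, species = names(config$species_profiles)) {
  stopifnot(inherits(config, "sim_config"))
  out <- purrr::imap(config$species_profiles[species], function(pr, sp) {
    withr::with_seed(substream(config$seed, 10L + match(sp, names(config$species_profiles))),
                     simulate_species(config, pr, sp))
  })
  truth <- purrr::map(out, attr, "truth") %>% bind_rows()
  res <- bind_rows(purrr::map(out, ~ .x))
  attr(res, "truth") <- truth
  res
}

simulate_species <- function(config, pr, sp) {
  years <- config$start_year + seq_len(config$n_years) - 1L
  grid <- purrr::map(seq_along(years), function(i) {
    yr <- years[i]
    start <- if (pr$convention == "calendar") {
      as.Date(paste0(yr, "-01-01"))
    } else {
      as.Date(paste0(yr, "-06-01"))
    }
    dates <- seq(start, start + 364L, by = "day")
    t <- i - (config$n_years + 1) / 2   # centered year index
    log_total <- log(pr$annual_total) +
      pr$abundance_trend[1] * t + pr$abundance_trend[2] * t^2 +
      (if (length(pr$abundance_trend) > 2) pr$abundance_trend[3] * t^3 else 0)
    mu_peaks <- pr$peaks$mu + pr$timing_trend * (i - 1)
    day <- seq_len(365L)
    dens <- seasonal_density(day, mu_peaks, pr$peaks$sigma, pr$peaks$weight)
    mu <- exp(log_total) * dens
    tp <- curve_percentiles(day, mu)
    list(tbl = tibble(date = dates, species = sp, species_year = yr,
                      day = day, mu_true = mu),
         truth = tibble(species = sp, species_year = yr,
                        peak_mu = list(mu_peaks),
                        annual_total_true = exp(log_total),
                        arrival_true = tp[1], peak_true = tp[2],
                        departure_true = tp[3]))
  })
  tbl <- bind_rows(purrr::map(grid, "tbl"))
  draw <- function(mu) {
    if (pr$dispersion > 0) {
      rnbinom(length(mu), size = 1 / pr$dispersion, mu = mu)
    } else {
      stats::rpois(length(mu), mu)
    }
  }
  if (isTRUE(pr$twice_daily)) {
    tbl$morning <- draw(tbl$mu_true)
    tbl$evening <- draw(tbl$mu_true)
    tbl$count <- (tbl$morning + tbl$evening) / 2
  } else {
    tbl$morning <- NA_real_
    tbl$evening <- NA_real_
    tbl$count <- draw(tbl$mu_true)
  }
  attr(tbl, "truth") <- bind_rows(purrr::map(grid, "truth"))
  tbl
}

# normalized mixture-of-Gaussians seasonal weight over days 1..365
seasonal_density <- function(day, mu, sigma, weight) {
  w <- weight / sum(weight)
  dens <- rowSums(vapply(seq_along(mu), function(k) {
    w[k] * dnorm(day, mu[k], sigma[k])
  }, numeric(length(day))))
  dens / sum(dens)
}

# arrival/peak/departure of a noiseless intensity curve (10/50/90th
# percentile of cumulative intensity, smallest-day >= rule)
curve_percentiles <- function(day, mu, probs = c(0.1, 0.5, 0.9)) {
  cum <- cumsum(mu) / sum(mu)
  vapply(probs, function(p) day[which(cum >= p)[1]], numeric(1))
}

#' Censor synthetic sightings with weather-driven observation effort
#'
#' Draws a daily effort indicator from a logistic model on the weather
#' table and censors the sighting record the way a historical database
#' without effort metadata does: on no-effort days the count is blanked
#' to missing, and in the years before effort recording began
#' (`known_years` trailing years have metadata) zero-count effort days
#' are also stored as missing, so a missing value is ambiguous between
#' "no whales" and "no survey". True effort labels are kept in
#' `effort_true` for evaluation only.
#'
#' @param config A [sim_config()] object.
#' @param sightings Daily sightings from [simulate_sightings()].
#' @param weather Daily weather from [simulate_weather()].
#' @return The sightings tibble with columns `effort_true` (0/1),
#'   `effort_known` (logical: metadata recorded that year),
#'   `effort_obs` (0/1 where known, NA otherwise) and `count_obs`
#'   (the stored count: NA on no-effort days and on unrecorded
#'   zero-count days of unknown-effort years).
#' @export
simulate_effort <- function(config, sightings, weather) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config$effort_params$coef
  vars <- setdiff(names(cf), "(Intercept)")
  missing_vars <- setdiff(vars, names(weather))
  if (length(missing_vars) > 0) {
    stop("weather table lacks effort predictors: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  eta <- cf[["(Intercept)"]] +
    as.matrix(weather[vars]) %*% cf[vars]
  eff <- withr::with_seed(substream(config$seed, 20L), {
    tibble(date = weather$date,
           effort_p = as.numeric(stats::plogis(eta)),
           effort_true = rbinom(nrow(weather), 1, .data$effort_p))
  })
  known_from <- config$start_year + config$n_years -
    config$effort_params$known_years
  sightings %>%
    left_join(eff, by = "date") %>%
    mutate(effort_known = lubridate::year(.data$date) >= known_from,
           effort_obs = ifelse(.data$effort_known, .data$effort_true, NA),
           count_obs = dplyr::case_when(
             effort_true == 0 ~ NA_real_,
             !effort_known & count == 0 ~ NA_real_,
             TRUE ~ as.numeric(count)))
}

#' Generate synthetic daily weather records
#'
#' Daily in-situ weather for the effort model: cloud cover, visibility,
#' pressure, air temperature, precipitation, wind, and swell, with mild
#' seasonal structure (rougher, wetter winters).
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per day.
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  years <- config$start_year + seq_len(config$n_years) - 1L
  # runs through May of the following year so adjusted (June-start)
  # species years are fully covered
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years) + 1, "-05-31")), by = "day")
  winterness <- cos(2 * pi * (lubridate::yday(dates) - 15) / 365.25)
  withr::with_seed(substream(config$seed, 21L), {
    n <- length(dates)
    tibble(date = dates,
           cloud_cover = pmin(pmax(rnorm(n, 50 + 20 * winterness, 25), 0), 100),
           visibility_km = pmax(rnorm(n, 16 - 4 * winterness, 6), 0.1),
           pressure = rnorm(n, 1015, 6),
           air_temp = rnorm(n, 13 - 3 * winterness, 2.5),
           precip = pmax(rnorm(n, 0.02 + 0.06 * winterness, 0.12), 0),
           wind_dir = runif(n, 0, 360),
           wind_speed = pmax(rnorm(n, 12 + 4 * winterness, 5), 0),
           swell_height = pmax(rnorm(n, 6 + 2.5 * winterness, 3), 0),
           swell_dir = runif(n, 0, 360))
  })
}

#' Generate synthetic monthly entanglement counts
#'
#' Monthly confirmed entanglements for the configured species as a
#' rounded, floored-at-zero linear function of the monthly whale count
#' and the year's arrival day, plus Gaussian noise.
#'
#' @param config A [sim_config()] object.
#' @param monthly_counts Tibble with `species`, `year`, `month`, `count`.
#' @param timing Tibble with `species`, `species_year`, `arrival_day`.
#' @return Tibble `species`, `year`, `month`, `entanglements`.
#' @export
simulate_entanglements <- function(config, monthly_counts, timing) {
  stopifnot(inherits(config, "sim_config"))
  pp <- config$entanglement_params
  base <- monthly_counts %>%
    filter(.data$species == pp$species) %>%
    left_join(timing %>% select("species", "species_year", "arrival_day"),
              by = c("species", year = "species_year"))
  withr::with_seed(substream(config$seed, 30L), {
    raw <- pp$intercept + pp$slope_count * base$count +
      pp$slope_arrival * dplyr::coalesce(base$arrival_day, 0) +
      rnorm(nrow(base), 0, pp$noise_sd)
    base %>%
      mutate(entanglements = pmax(round(raw), 0)) %>%
      select("species", "year", "month", "entanglements")
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs all four generators in order and returns every table the
#' pipeline consumes, with ground truth attached for recovery tests.
#'
#' @param config A [sim_config()] object.
#' @return A list: `environment` tables, `weather`, `sightings`
#'   (censored, with truth columns), `entanglements`, and `truth`
#'   (per species-year true timing/abundance).
#' @export
simulate_dataset <- function(config = sim_config()) {
  env <- simulate_environment(config)
  weather <- simulate_weather(config)
  raw <- simulate_sightings(config)
  sightings <- simulate_effort(config, raw, weather)
  truth <- attr(raw, "truth")
  # monthly counts and arrival for the entanglement coupling come from
  # the uncensored truth so the generator does not depend on the
  # analysis stages
  monthly <- raw %>%
    mutate(year = lubridate::year(.data$date),
           month = lubridate::month(.data$date)) %>%
    group_by(.data$species, .data$year, .data$month) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  arrivals <- truth %>%
    select("species", "species_year", arrival_day = "arrival_true")
  entanglements <- simulate_entanglements(config, monthly, arrivals)
  list(environment = env, weather = weather, sightings = sightings,
       entanglements = entanglements, truth = truth)
}
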