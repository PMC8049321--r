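#' Simulation configuration for the synthetic monitoring series
#'
#' Builds the configuration object consumed by the synthetic-data
#' generators ([simulate_environment()], [simulate_sightings()],
#' [simulate_effort()], [simulate_entanglements()], [simulate_dataset()]).
#' Defaults emulate a 24-year daily visual survey of humpback, blue, and
#' gray whales from a fixed island observation point: unimodal summer
#' occupancy for humpback and blue whales, a bimodal gray-whale season
#' (south-bound winter peak, north-bound spring peak) expressed on an
#' adjusted year that starts June 1, overdispersed daily counts,
#' weather-driven gaps in observation effort that censor counts to
#' missing, autocorrelated monthly basin-scale climate indices, and
#' monthly entanglements linearly coupled to monthly counts and arrival
#' day.
#'
#' @param n_years Number of survey years (>= 3).
#' @param start_year First calendar year of the series.
#' @param species_profiles A list of per-species seasonal profiles; see
#'   Details. Defaults cover `humpback`, `blue`, and `gray`.
#' @param env_params List of environmental-series parameters: monthly
#'   climate index AR(1) coefficients, means and marginal SDs; daily SST
#'   mean, annual-cycle amplitude, interannual linear trend (degrees C per
#'   year) and noise SD; daily SSS analogues; spring wind-reversal
#'   day-of-year and daily wind noise; SST-grid spacing/extent and front
#'   gradient distribution.
#' @param effort_params Logistic-regression coefficients (on the linear
#'   predictor scale) of daily observation effort on weather variables,
#'   plus `known_years`, the number of trailing years with recorded effort
#'   metadata.
#' @param entanglement_params Linear coefficients of monthly
#'   entanglements on monthly count (`slope_count`) and on the year's
#'   arrival day (`slope_arrival`), plus `intercept` and Gaussian
#'   `noise_sd`. Applies to the species named in `species`.
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical tables.
#'
#' @details
#' Each species profile is a list with elements:
#' * `convention`: `"calendar"` (day 1 = Jan 1) or `"adjusted"`
#'   (day 1 = Jun 1, used for gray whales so the south-bound migration is
#'   not split across calendar years);
#' * `peaks`: a data frame with columns `mu` (peak day on the species
#'   axis), `sigma` (spread, days), `weight` (mixture weight); one row for
#'   unimodal species, two for the bimodal gray season;
#' * `annual_total`: expected annual sighting total in year 1;
#' * `abundance_trend`: polynomial coefficients (linear, quadratic,
#'   cubic) on centered year for the log of the annual total;
#' * `timing_trend`: drift of the seasonal peak(s), days per year;
#' * `dispersion`: NB2 dispersion alpha (variance = mu + alpha * mu^2);
#'   0 gives Poisson counts;
#' * `twice_daily`: logical; if `TRUE` a morning and an evening count are
#'   drawn per day (the gray-whale protocol) and the daily value is their
#'   average.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_years = 5, seed = 1)
#' str(cfg$species_profiles$humpback)
sim_config <- function(n_years = 24,
                       start_year = 1993,
                       species_profiles = default_species_profiles(),
                       env_params = default_env_params(),
                       effort_params = default_effort_params(),
                       entanglement_params = default_entanglement_params(),
                       seed = 1L) {
  stopifnot(is.numeric(n_years), n_years >= 3,
            is.numeric(start_year), length(seed) == 1L)
  for (sp in names(species_profiles)) {
    pr <- species_profiles[[sp]]
    if (any(pr$peaks$sigma <= 0)) {
      stop("species profile '", sp, "': sigma must be > 0", call. = FALSE)
    }
    if (!pr$convention %in% c("calendar", "adjusted")) {
      stop("species profile '", sp, "': unknown year convention", call. = FALSE)
    }
  }
  for (idx in c("soi", "pdo", "npgo")) {
    phi <- env_params$indices[[idx]]$phi
    if (abs(phi) >= 1) {
      stop("AR(1) coefficient for ", idx, " must satisfy |phi| < 1",
           call. = FALSE)
    }
  }
  structure(
    list(n_years = as.integer(n_years),
         start_year = as.integer(start_year),
         species_profiles = species_profiles,
         env_params = env_params,
         effort_params = effort_params,
         entanglement_params = entanglement_params,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @rdname sim_config
#' @export
default_species_profiles <- function() {
  list(
    humpback = list(
      convention = "calendar",
      peaks = data.frame(mu = 250, sigma = 45, weight = 1),
      annual_total = 150,
      # accelerating increase: flat early, ~3x by the end of the series
      abundance_trend = c(0.046, 0.002, 0),
      timing_trend = -5.2,
      dispersion = 0.5,
      twice_daily = FALSE),
    blue = list(
      convention = "calendar",
      peaks = data.frame(mu = 245, sigma = 40, weight = 1),
      annual_total = 141,
      abundance_trend = c(0.01, 0, 0.0002),
      timing_trend = -4.3,
      dispersion = 0.5,
      twice_daily = FALSE),
    gray = list(
      convention = "adjusted",
      # adjusted axis: day 229 ~ Jan 15 (south-bound), day 288 ~ Mar 15
      # (north-bound)
      peaks = data.frame(mu = c(229, 288), sigma = c(15, 12),
                         weight = c(0.55, 0.45)),
      annual_total = 1200,
      abundance_trend = c(-0.02, 0.003, 0),
      timing_trend = 0,
      dispersion = 0.5,
      twice_daily = TRUE)
  )
}

#' @rdname sim_config
#' @export
default_env_params <- function() {
  list(
    indices = list(
      soi  = list(phi = 0.6, mean = -0.20, sd = 1.85),
      pdo  = list(phi = 0.9, mean = 0.133, sd = 1.14),
      npgo = list(phi = 0.9, mean = 0.245, sd = 1.25)),
    sst = list(mean = 12.49, amplitude = 1.5, trend = 0.013, sd = 0.45,
               peak_day = 258),
    sss = list(mean = 33.40, amplitude = 0.25, trend = 0, sd = 0.15,
               peak_day = 60),
    wind = list(reversal_day = 100, reversal_sd = 8,
                poleward_speed = 3, equatorward_speed = 5, sd = 2),
    grid = list(spacing_km = 2, extent_km = 20,
                fii_mean = 0.0331, fii_sd = 0.0144)
  )
}

#' @rdname sim_config
#' @export
default_effort_params <- function() {
  # sharp coupling: observation effort in this protocol is essentially a
  # deterministic function of weather (visibility/wind/swell criteria),
  # so the logistic is steep; residual randomness stands in for
  # unrecorded factors (fog patches, staffing)
  list(coef = c(`(Intercept)` = 12,
                swell_height = -1.6,
                visibility_km = 0.48,
                wind_speed = -0.48,
                cloud_cover = -0.016),
       known_years = 4L)
}

#' @rdname sim_config
#' @export
default_entanglement_params <- function() {
  list(species = "humpback", intercept = 1.2, slope_count = 0.012,
       slope_arrival = -0.008, noise_sd = 0.6)
}

# deterministic sub-stream seed: one master seed, one offset per table
substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 97L + k * 7919) %% 2147483629)
}
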