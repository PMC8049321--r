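#' Generate the synthetic environmental series
#'
#' Produces the environmental tables the covariate stage consumes: daily
#' in-situ SST and SSS, a monthly gridded SST field around the
#' observation point (for the front intensity index), daily coastal wind
#' vectors with a spring reversal from poleward (downwelling-favorable)
#' to equatorward (upwelling-favorable) flow, and monthly basin-scale
#' climate indices (SOI, PDO, NPGO) as stationary AR(1) series with
#' configured mean and marginal SD.
#'
#' @param config A [sim_config()] object.
#' @return A list of tibbles: `ocean` (date, sst, sss), `sst_grid`
#'   (date, x_km, y_km, sst; one field per month), `wind` (date, u, v in
#'   m/s, eastward/northward), `climate` (year, month, soi, pdo, npgo),
#'   and `truth` (per-year wind reversal day).
#' @export
simulate_environment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ep <- config$env_params
  years <- config$start_year + seq_len(config$n_years) - 1L
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  t_years <- as.numeric(dates - dates[1]) / 365.25

  ocean <- withr::with_seed(substream(config$seed, 1L), {
    ann <- function(p) {
      p$mean + p$trend * t_years +
        p$amplitude * cos(2 * pi * (lubridate::yday(dates) - p$peak_day) / 365.25) +
        rnorm(length(dates), 0, p$sd)
    }
    tibble(date = dates, sst = ann(ep$sst), sss = ann(ep$sss))
  })

  climate <- withr::with_seed(substream(config$seed, 2L), {
    months <- tidyr::expand_grid(year = years, month = 1:12)
    draw <- function(p) {
      n <- nrow(months)
      innov_sd <- p$sd * sqrt(1 - p$phi^2)
      x <- numeric(n)
      x[1] <- rnorm(1, 0, p$sd)
      for (i in seq_len(n - 1)) {
        x[i + 1] <- p$phi * x[i] + rnorm(1, 0, innov_sd)
      }
      p$mean + x
    }
    months %>%
      mutate(soi = draw(ep$indices$soi),
             pdo = draw(ep$indices$pdo),
             npgo = draw(ep$indices$npgo))
  })

  wind <- withr::with_seed(substream(config$seed, 3L), {
    reversal <- round(rnorm(length(years), ep$wind$reversal_day,
                            ep$wind$reversal_sd))
    names(reversal) <- years
    yday <- lubridate::yday(dates)
    yr <- as.character(lubridate::year(dates))
    # alongshore flow: poleward (+v) before the reversal, equatorward
    # (-v) after; equatorward wind is upwelling-favorable on an eastern
    # boundary
    v_mean <- ifelse(yday < reversal[yr],
                     ep$wind$poleward_speed, -ep$wind$equatorward_speed)
    tibble(date = dates,
           u = rnorm(length(dates), 0, ep$wind$sd),
           v = v_mean + rnorm(length(dates), 0, ep$wind$sd))
  })

  sst_grid <- withr::with_seed(substream(config$seed, 4L), {
    ax <- seq(-ep$grid$extent_km, ep$grid$extent_km, by = ep$grid$spacing_km)
    cells <- tidyr::expand_grid(x_km = ax, y_km = ax)
    fields <- tidyr::expand_grid(year = years, month = 1:12) %>%
      mutate(date = as.Date(paste(.data$year, .data$month, 1, sep = "-")),
             grad = pmax(rnorm(dplyr::n(), ep$grid$fii_mean, ep$grid$fii_sd), 0),
             theta = runif(dplyr::n(), 0, 2 * pi),
             base = rnorm(dplyr::n(), ep$sst$mean, 1))
    nf <- nrow(fields); nc <- nrow(cells)
    long <- fields[rep(seq_len(nf), each = nc), ]
    long_cells <- cells[rep(seq_len(nc), times = nf), ]
    tibble(date = long$date,
           x_km = long_cells$x_km, y_km = long_cells$y_km,
           sst = long$base + long$grad * (cos(long$theta) * long_cells$x_km +
                                          sin(long$theta) * long_cells$y_km))
  })

  truth_wind <- withr::with_seed(substream(config$seed, 3L), {
    tibble(year = years,
           reversal_day = round(rnorm(length(years), ep$wind$reversal_day,
                                      ep$wind$reversal_sd)))
  })

  list(ocean = ocean, sst_grid = sst_grid, wind = wind, climate = climate,
       truth = truth_wind)
}
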