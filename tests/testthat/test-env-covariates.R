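planar_grid <- function(gx, gy = 0, spacing = 1, extent = 25) {
  ax <- seq(-extent, extent, by = spacing)
  tidyr::expand_grid(x_km = ax, y_km = ax) %>%
    dplyr::mutate(sst = 12 + gx * x_km + gy * y_km)
}

test_that("FII closed forms: uniform, planar, and step-front fields", {
  uni <- planar_grid(0)
  for (r in c(5, 10, 15, 20)) {
    expect_equal(front_intensity_index(uni, r), 0)
  }
  plan <- planar_grid(0.05)
  for (r in c(5, 10, 15, 20)) {
    expect_equal(front_intensity_index(plan, r), 0.05, tolerance = 1e-12)
  }
  # step front of magnitude delta at x = 12 km, unit spacing: the
  # central-difference stencil sees delta / 2 at the cells flanking the
  # jump (x = 11, 12), all beyond radius 10 of the origin
  delta <- 2
  step <- planar_grid(0) %>%
    dplyr::mutate(sst = 12 + delta * (x_km >= 12))
  expect_equal(front_intensity_index(step, 5), 0)
  expect_equal(front_intensity_index(step, 10), 0)
  expect_equal(front_intensity_index(step, 15), delta / 2)
  expect_equal(front_intensity_index(step, 20), delta / 2)
  expect_error(front_intensity_index(planar_grid(0, extent = 8), 10),
               "disc")
})

test_that("FII is non-negative and non-decreasing in radius", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- planar_grid(runif(1, -0.1, 0.1), runif(1, -0.1, 0.1)) %>%
      dplyr::mutate(sst = sst + rnorm(dplyr::n(), 0, 0.2))
    vals <- vapply(c(5, 10, 15, 20), function(r) {
      front_intensity_index(g, r)
    }, numeric(1))
    expect_true(all(vals >= 0))
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("Ekman transport follows the bulk formula and its symmetries", {
  calm <- tibble::tibble(date = Sys.Date(), u = 0, v = 0)
  expect_equal(ekman_transport(calm)$transport, 0)
  # reversing the wind flips the sign of the stress and transport
  w <- tibble::tibble(date = Sys.Date() + 0:1, u = c(2, -2), v = c(-7, 7))
  tr <- ekman_transport(w)
  expect_equal(tr$transport[1], -tr$transport[2])
  # constant 10-knot (5.144 m/s) equatorward wind at 38 N: hand formula
  ws <- 10 * 0.514444
  hand_tau <- 1.22 * 1.3e-3 * ws * ws
  f <- 2 * 7.2921e-5 * sin(38 * pi / 180)
  hand_transport <- hand_tau / (1025 * f) * 100
  tr10 <- ekman_transport(tibble::tibble(date = Sys.Date(), u = 0, v = -ws),
                          latitude = 38)
  expect_equal(tr10$transport, hand_transport, tolerance = 1e-12)
  expect_error(ekman_transport(calm, latitude = 0.5), "latitude")
})

test_that("spring transition is the cumulative-minimum day", {
  # piecewise: downwelling before day 80, upwelling after -> STB 80
  x <- c(rep(-1, 80), rep(1, 285))
  st <- spring_transition(x)
  expect_equal(st$stb_day, 80)
  expect_equal(st$stb_anomaly, -10)
  # pure upwelling all year: day 1 with a warning
  expect_warning(st2 <- spring_transition(rep(1, 365)), "monotonically")
  expect_equal(st2$stb_day, 1)
  expect_error(spring_transition(rep(1, 100)), "300")
  # time-axis relabeling does not change the detected day
  expect_equal(spring_transition(x)$stb_day,
               spring_transition(unname(x))$stb_day)
})

test_that("noisy wind reversal around day 100 is located within 3 days", {
  stbs <- vapply(1:50, function(seed) {
    set.seed(seed)
    v <- c(rep(3, 99), rep(-5, 266)) + rnorm(365, 0, 2)
    w <- tibble::tibble(date = as.Date("2000-01-01") + 0:364, u = 0, v = v)
    tr <- ekman_transport(w)
    spring_transition(tr$transport)$stb_day
  }, numeric(1))
  expect_lte(abs(median(stbs) - 100), 3)
})

test_that("seasonal averages respect season membership and conventions", {
  # Jan..Dec of Y valued 1..12, Dec(Y-1) = 12 -> winter(Y) = 5
  s <- dplyr::bind_rows(
    tibble::tibble(year = 1999, month = 12, value = 12),
    tibble::tibble(year = 2000, month = 1:12, value = 1:12))
  expect_equal(seasonal_average(s, "winter", 2000), 5)
  expect_equal(seasonal_average(s, "spring", 2000), 4)
  expect_equal(seasonal_average(s, "summer", 2000), 7)
  expect_equal(seasonal_average(s, "fall", 2000), 10)
  expect_equal(seasonal_average(s, "annual", 2000), 6.5)
  expect_error(seasonal_average(s, "winter", 1999), "1998-12")
  # constant series: every mean is the constant, both conventions
  cs <- tidyr::expand_grid(year = 1998:2002, month = 1:12) %>%
    dplyr::mutate(value = 7.5)
  for (season in c("annual", "winter", "spring", "summer", "fall")) {
    expect_equal(seasonal_average(cs, season, 2000, "calendar"), 7.5)
    expect_equal(seasonal_average(cs, season, 2000, "adjusted"), 7.5)
  }
})

test_that("adjusted-year seasons map onto the June-start window", {
  # value = calendar year * 100 + month, so means identify their months
  s <- tidyr::expand_grid(year = 1998:2002, month = 1:12) %>%
    dplyr::mutate(value = year * 100 + month)
  # adjusted year 2000 = Jun 2000..May 2001
  expect_equal(seasonal_average(s, "summer", 2000, "adjusted"),
               mean(c(200006, 200007, 200008)))
  expect_equal(seasonal_average(s, "winter", 2000, "adjusted"),
               mean(c(200012, 200101, 200102)))
  expect_equal(seasonal_average(s, "spring", 2000, "adjusted"),
               mean(c(200103, 200104, 200105)))
  # previous-winter for species-year Y is winter of species year Y-1:
  # hand-built mapping on a 3-year fixture
  prev_cal <- vapply(2000:2002, function(y) {
    seasonal_average(s, "winter", y - 1, "calendar")
  }, numeric(1))
  expect_equal(prev_cal, c(mean(c(199812, 199901, 199902)),
                           mean(c(199912, 200001, 200002)),
                           mean(c(200012, 200101, 200102))))
})

test_that("lag_series shifts by exactly k months", {
  s <- tibble::tibble(year = 2000, month = 1:4, value = c(10, 20, 30, 40))
  l2 <- lag_series(s, 2)
  expect_equal(l2$value, c(NA, NA, 10, 20))
  # lag then lead restores the interior of the series
  l1 <- lag_series(s, 1)
  restored <- dplyr::mutate(l1, value = dplyr::lead(value, 1))
  expect_equal(restored$value[1:3], s$value[1:3])
  # seasonal mean of a lag-2 series equals the hand-shifted mean
  s2 <- tidyr::expand_grid(year = 2000:2001, month = 1:12) %>%
    dplyr::mutate(value = dplyr::row_number())
  expect_equal(seasonal_average(lag_series(s2, 2), "summer", 2001),
               mean(c(16, 17, 18)))
})

test_that("the covariate table carries availability metadata", {
  avail <- covariate_availability(
    c("soi_prev_winter", "soi_winter", "sst_summer", "pdo_lag2",
      "sst_annual", "stb_day"), "calendar")
  expect_lt(avail[["soi_prev_winter"]], 0)
  expect_equal(avail[["soi_winter"]], 59)
  expect_equal(avail[["sst_summer"]], 243)
  expect_equal(avail[["sst_annual"]], 365)
  expect_lt(avail[["pdo_lag2"]], 365)
  a2 <- covariate_availability(c("sst_summer", "sss_prev_winter"),
                               "adjusted")
  expect_equal(a2[["sst_summer"]], 92)
  expect_lt(a2[["sss_prev_winter"]], 0)
})
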