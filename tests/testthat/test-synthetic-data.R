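test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_years = 4, seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$sightings, d2$sightings)
  expect_identical(d1$environment$climate, d2$environment$climate)
  expect_identical(d1$environment$sst_grid, d2$environment$sst_grid)
  expect_identical(d1$entanglements, d2$entanglements)
  d3 <- simulate_dataset(sim_config(n_years = 4, seed = 100))
  expect_false(identical(d1$sightings$count, d3$sightings$count))
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(n_years = 2), "n_years")
  prof <- default_species_profiles()
  prof$humpback$peaks$sigma <- -1
  expect_error(sim_config(species_profiles = prof), "sigma")
  ep <- default_env_params()
  ep$indices$pdo$phi <- 1.2
  expect_error(sim_config(env_params = ep), "phi")
})

test_that("AR(1) climate indices have the configured marginal moments", {
  # white-noise limit: phi = 0, SD 1 -> sample SD within 5% of 1
  ep <- default_env_params()
  ep$indices$soi <- list(phi = 0, mean = 0, sd = 1)
  cfg <- sim_config(n_years = 840, env_params = ep, seed = 7)  # ~10^4 months
  env <- simulate_environment(cfg)
  expect_gt(nrow(env$climate), 1e4)
  expect_lt(abs(sd(env$climate$soi) - 1), 0.05)
  expect_lt(abs(mean(env$climate$soi)), 0.05)
  # autocorrelated index: lag-1 correlation near phi
  r1 <- cor(env$climate$pdo[-1], env$climate$pdo[-nrow(env$climate)])
  expect_lt(abs(r1 - ep$indices$pdo$phi), 0.05)
})

test_that("SST interannual trend is recoverable by least squares", {
  cfg <- sim_config(n_years = 24, seed = 5)
  env <- simulate_environment(cfg)
  annual <- env$ocean %>%
    dplyr::mutate(year = lubridate::year(date)) %>%
    dplyr::group_by(year) %>%
    dplyr::summarise(sst = mean(sst))
  fit <- lm(sst ~ year, data = annual)
  ci <- confint(fit)["year", ]
  expect_true(ci[1] <= 0.013 && 0.013 <= ci[2])
})

test_that("seasonal count curves have the stated shape and dispersion", {
  cfg <- sim_config(n_years = 12, seed = 21)
  raw <- simulate_sightings(cfg)
  # humpback/blue unimodal, gray bimodal on the adjusted axis
  hb <- raw %>% dplyr::filter(species == "humpback") %>%
    dplyr::group_by(day) %>% dplyr::summarise(mu = mean(mu_true))
  expect_equal(sum(diff(hb$mu > max(hb$mu) / 4) != 0), 2)  # one hump
  gr <- raw %>% dplyr::filter(species == "gray") %>%
    dplyr::group_by(day) %>% dplyr::summarise(mu = mean(mu_true))
  expect_equal(sum(diff(gr$mu > max(gr$mu) / 4) != 0), 4)  # two humps
  # overdispersion: weekly variance exceeds weekly mean
  wk <- raw %>% dplyr::filter(species == "humpback") %>%
    dplyr::mutate(week = pmin(ceiling(day / 7), 52)) %>%
    dplyr::group_by(species_year, week) %>%
    dplyr::summarise(count = sum(count), .groups = "drop")
  expect_gt(var(wk$count), mean(wk$count))
})

test_that("a timing drift in the generator moves the true percentile days", {
  prof <- default_species_profiles()["humpback"]
  prof$humpback$timing_trend <- -5
  prof$humpback$peaks$mu <- 250   # keep the drifting curve off the year edge
  cfg <- sim_config(n_years = 24, species_profiles = prof, seed = 17)
  truth <- attr(simulate_sightings(cfg), "truth")
  fit <- lm(arrival_true ~ species_year, data = truth)
  expect_lt(abs(coef(fit)[2] - (-5)), 0.2)
  # stationary case: no drift -> arrival SD well under sigma/2
  prof$humpback$timing_trend <- 0
  cfg0 <- sim_config(n_years = 24, species_profiles = prof, seed = 17)
  truth0 <- attr(simulate_sightings(cfg0), "truth")
  expect_lt(sd(truth0$arrival_true), prof$humpback$peaks$sigma / 2)
})

test_that("effort censoring blanks exactly the no-effort days", {
  cfg <- sim_config(n_years = 4, seed = 31)
  weather <- simulate_weather(cfg)
  raw <- simulate_sightings(cfg, species = "humpback")
  cen <- simulate_effort(cfg, raw, weather)
  expect_true(all(is.na(cen$count_obs[cen$effort_true == 0])))
  known <- cen %>% dplyr::filter(effort_known, effort_true == 1)
  expect_identical(known$count_obs, as.numeric(known$count))
  # pre-metadata years additionally blank true zeros (count ambiguity)
  unk <- cen %>% dplyr::filter(!effort_known, effort_true == 1)
  expect_true(all(is.na(unk$count_obs[unk$count == 0])))
  expect_identical(unk$count_obs[unk$count > 0],
                   as.numeric(unk$count[unk$count > 0]))
})

test_that("forcing effort probability to one produces no censoring", {
  ef <- default_effort_params()
  ef$coef[] <- 0
  ef$coef["(Intercept)"] <- 50   # plogis(50) == 1
  cfg <- sim_config(n_years = 3, effort_params = ef, seed = 8)
  cen <- simulate_effort(cfg, simulate_sightings(cfg, species = "blue"),
                         simulate_weather(cfg))
  expect_true(all(cen$effort_true == 1))
  expect_false(anyNA(cen$count_obs[cen$effort_known]))
})

test_that("a strong swell penalty lowers effort on high-swell days", {
  cfg <- sim_config(n_years = 6, seed = 12)
  weather <- simulate_weather(cfg)
  cen <- simulate_effort(cfg, simulate_sightings(cfg, species = "humpback"),
                         weather)
  d <- dplyr::left_join(dplyr::distinct(cen, date, effort_true),
                        weather, by = "date")
  hi <- mean(d$effort_true[d$swell_height > median(d$swell_height)])
  lo <- mean(d$effort_true[d$swell_height <= median(d$swell_height)])
  expect_gt(lo - hi, 0)
})

test_that("entanglement generator obeys its linear contract", {
  cfg <- sim_config(n_years = 10, seed = 3)
  counts <- tidyr::expand_grid(species = "humpback", year = 1993:2002,
                               month = 1:12) %>%
    dplyr::mutate(count = 100)
  timing <- tibble::tibble(species = "humpback", species_year = 1993:2002,
                           arrival_day = 150)
  # b = c = 0, no noise -> constant series at the intercept
  ep <- default_entanglement_params()
  ep$slope_count <- 0; ep$slope_arrival <- 0; ep$noise_sd <- 0
  ep$intercept <- 3
  cfg0 <- sim_config(n_years = 10, entanglement_params = ep, seed = 3)
  ent0 <- simulate_entanglements(cfg0, counts, timing)
  expect_true(all(ent0$entanglements == 3))
  # negative raw draws floored at zero
  ep$intercept <- -5
  cfgn <- sim_config(n_years = 10, entanglement_params = ep, seed = 3)
  entn <- simulate_entanglements(cfgn, counts, timing)
  expect_true(all(entn$entanglements == 0))
  # b > 0, large n: least squares on count recovers the slope
  ep$intercept <- 1; ep$slope_count <- 0.05; ep$noise_sd <- 0.3
  cfgb <- sim_config(n_years = 10, entanglement_params = ep, seed = 3)
  counts_v <- counts %>%
    dplyr::mutate(count = withr::with_seed(4, runif(dplyr::n(), 0, 400)))
  entb <- simulate_entanglements(cfgb, counts_v, timing)
  d <- dplyr::left_join(entb, counts_v, by = c("species", "year", "month"))
  slope <- coef(lm(entanglements ~ count, data = d))["count"]
  expect_lt(abs(slope - 0.05), 0.01)
})
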