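# shared fixtures; everything generated in code, seeded

# small config for fast end-to-end runs
small_config <- function(n_years = 10, seed = 42, ...) {
  pipeline_config(sim = sim_config(n_years = n_years, seed = seed), ...)
}

# one cached mid-size pipeline run reused by invariant checks
cached_run <- local({
  env <- new.env()
  function(n_years = 16, seed = 2024) {
    key <- paste0("r", n_years, "_", seed)
    if (is.null(env[[key]])) {
      outdir <- file.path(tempdir(), paste0("whalephen_", key))
      cfg <- pipeline_config(sim = sim_config(n_years = n_years, seed = seed))
      env[[key]] <- list(cfg = cfg, outdir = outdir,
                         res = suppressWarnings(run_pipeline(cfg, outdir)))
    }
    env[[key]]
  }
})

# brute-force best first split by Gini impurity over all
# variable/threshold pairs; oracle for the CART stump
brute_force_split <- function(X, y) {
  gini <- function(lab) {
    if (length(lab) == 0) return(0)
    p <- mean(lab)
    2 * p * (1 - p)
  }
  best <- list(impurity = Inf)
  for (v in names(X)) {
    u <- sort(unique(X[[v]]))
    if (length(u) < 2) next
    for (thr in (u[-1] + u[-length(u)]) / 2) {
      left <- y[X[[v]] < thr]
      right <- y[X[[v]] >= thr]
      imp <- (length(left) * gini(left) + length(right) * gini(right)) /
        length(y)
      if (imp < best$impurity - 1e-12) {
        best <- list(var = v, threshold = thr, impurity = imp,
                     p_left = mean(left), p_right = mean(right))
      }
    }
  }
  best
}

# daily table builder for phenology unit tests
daily_fixture <- function(days, counts, species = "humpback", year = 2000) {
  tibble::tibble(
    species = species, species_year = year, day = days,
    date = as.Date(paste0(year, "-01-01")) + days - 1,
    count_obs = counts, morning = NA_real_, evening = NA_real_)
}

# weekly-count simulator on the model's own scale (log mu as polynomial
# in the internally scaled year), used by NB recovery tests
simulate_weekly_nb <- function(n_years = 24, beta = c(1.0, 0.3, -0.2),
                               alpha = 0.5, effort = NULL, seed = 1) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(species_year = seq_len(n_years) + 1992,
                               week = 1:52)
    z <- as.numeric(scale(grid$species_year))
    if (is.null(effort)) effort <- sample(3:7, nrow(grid), replace = TRUE)
    log_mu <- beta[1] + beta[2] * z + (if (length(beta) > 2) beta[3] * z^2 else 0) +
      log(effort)
    grid$count <- rnbinom(nrow(grid), size = 1 / alpha, mu = exp(log_mu))
    grid$effort_days <- effort
    grid$month <- pmin(ceiling(grid$week / 4.4), 12)
    grid$week_start <- as.Date(paste0(grid$species_year, "-01-01")) +
      (grid$week - 1) * 7
    grid
  })
}
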