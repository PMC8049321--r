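# small per-year dataset builder with controllable signal structure
timing_data <- function(n = 24, seed = 1, f = function(x1, x2, x3) 2 * x1,
                        noise_sd = 1) {
  withr::with_seed(seed, {
    d <- tibble::tibble(species_year = seq_len(n) + 1992,
                        x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                        x4 = rnorm(n), x5 = rnorm(n))
    d$metric <- f(d$x1, d$x2, d$x3) + rnorm(n, 0, noise_sd)
    d
  })
}

test_that("univariate screening finds the right order", {
  hits_lin <- hits_quad <- null_hits <- 0
  for (s in 1:40) {
    d1 <- timing_data(seed = s, f = function(x1, x2, x3) 2 * x1)
    r1 <- univariate_screen(d1, "metric", "x1")
    if (nrow(r1) == 1 && r1$order == 1) hits_lin <- hits_lin + 1
    d2 <- timing_data(seed = s + 100,
                      f = function(x1, x2, x3) 1.5 * x1^2, noise_sd = 1)
    r2 <- univariate_screen(d2, "metric", "x1")
    if (nrow(r2) == 1 && r2$order == 2) hits_quad <- hits_quad + 1
    r0 <- univariate_screen(d1, "metric", "x2")   # independent covariate
    if (nrow(r0) == 1) null_hits <- null_hits + 1
  }
  expect_gte(hits_lin, 33)    # allow the occasional spurious higher order
  expect_gte(hits_quad, 33)
  expect_lte(null_hits, 10)   # ~3 tests at alpha 0.05 -> low forward rate
  # zero-variance covariate is skipped
  d <- timing_data()
  d$flat <- 1
  expect_equal(nrow(univariate_screen(d, "metric", "flat")), 0)
})

test_that("backward elimination retains true predictors, drops noise", {
  kept_true <- 0
  for (s in 1:40) {
    d <- timing_data(seed = s, f = function(x1, x2, x3) 3 * x1,
                     noise_sd = 1)
    scr <- screen_covariates(d, "metric",
                             covariates = paste0("x", 1:5))
    m <- backward_eliminate(d, "metric", scr)
    if ("x1" %in% m$terms$covariate) kept_true <- kept_true + 1
    # contract: every retained top term significant, hierarchy intact
    if (!m$not_significant) {
      td <- tidy(m)
      tops <- td[!is.na(td$covariate), ]
      for (cv in unique(m$terms$covariate)) {
        o <- m$terms$order[m$terms$covariate == cv]
        top_nm <- paste0(cv, "_o", o)
        expect_lt(td$p.value[td$term == top_nm], 0.05)
        expect_true(all(paste0(cv, "_o", seq_len(o)) %in% td$term))
      }
      if (!is.null(m$vif)) expect_lt(max(m$vif$vif), 10)
    }
  }
  expect_gte(kept_true, 34)   # >= 85/100 equivalent rate
})

test_that("an all-significant candidate set is a fixed point", {
  d <- timing_data(seed = 5, f = function(x1, x2, x3) 3 * x1 - 2 * x2,
                   noise_sd = 0.5)
  scr <- screen_covariates(d, "metric", covariates = c("x1", "x2"))
  m <- backward_eliminate(d, "metric", scr)
  expect_setequal(m$terms$covariate, c("x1", "x2"))
})

test_that("perfect collinearity removes one copy, never both", {
  d <- timing_data(seed = 6, f = function(x1, x2, x3) 3 * x1,
                   noise_sd = 0.5)
  d$x1_dup <- d$x1
  scr <- dplyr::bind_rows(
    screen_covariates(d, "metric", covariates = c("x1", "x1_dup")))
  m <- backward_eliminate(d, "metric", scr)
  expect_equal(sum(c("x1", "x1_dup") %in% m$terms$covariate), 1)
  expect_false(m$not_significant)
})

test_that("VIF equals closed forms and brute-force auxiliary regressions", {
  # orthogonal (mean-zero) design: all VIF = 1
  X <- unclass(stats::poly(1:20, 3))
  colnames(X) <- c("a", "b", "c")
  expect_equal(unname(vif_terms(X)), rep(1, 3), tolerance = 1e-10)
  # two correlated columns: VIF = 1 / (1 - r^2) both
  withr::with_seed(7, {
    a <- rnorm(200)
    b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(200)
  })
  X2 <- cbind(a = a, b = b)
  r2 <- cor(a, b)^2
  expect_equal(unname(vif_terms(X2)), rep(1 / (1 - r2), 2),
               tolerance = 1e-10)
  # 5-column fixture vs brute-force per-column regressions
  withr::with_seed(8, X5 <- matrix(rnorm(100), 20, 5))
  colnames(X5) <- paste0("v", 1:5)
  brute <- vapply(1:5, function(j) {
    1 / (1 - summary(lm(X5[, j] ~ X5[, -j]))$r.squared)
  }, numeric(1))
  expect_equal(unname(vif_terms(X5)), brute, tolerance = 1e-10)
  # cross-check against the standard automotive implementation
  if (requireNamespace("car", quietly = TRUE)) {
    df <- data.frame(y = rnorm(20), X5)
    fit <- lm(y ~ ., data = df)
    expect_equal(unname(vif_terms(X5)), unname(car::vif(fit)),
                 tolerance = 1e-8)
  }
  # perfect collinearity: Inf marker, no crash
  X3 <- cbind(a = a, b = 2 * a)
  expect_true(any(is.infinite(suppressWarnings(vif_terms(X3)))))
})

test_that("margins reduce to the fitted line and hand linear algebra", {
  d <- timing_data(seed = 9, f = function(x1, x2, x3) 2 * x1, noise_sd = 0.5)
  scr <- screen_covariates(d, "metric", covariates = "x1")
  m <- backward_eliminate(d, "metric", scr)
  mg <- margins(m, "x1", grid = d$x1)
  expect_equal(mg$predicted, unname(fitted(m$fit)), tolerance = 1e-10)
  # prediction at the focus covariate's mean equals the mean fitted value
  mg_mean <- margins(m, "x1", grid = mean(d$x1))
  expect_equal(mg_mean$predicted, mean(fitted(m$fit)), tolerance = 1e-10)
  # two-covariate hand computation with frozen means
  d2 <- timing_data(seed = 10, f = function(x1, x2, x3) 2 * x1 - x2,
                    noise_sd = 0.3)
  scr2 <- screen_covariates(d2, "metric", covariates = c("x1", "x2"))
  m2 <- backward_eliminate(d2, "metric", scr2)
  beta <- coef(m2$fit)
  grid <- c(-1, 0, 1)
  hand <- beta[["(Intercept)"]] +
    beta[["x1_o1"]] * (grid - mean(d2$x1)) +
    beta[["x2_o1"]] * (mean(d2$x2) - mean(d2$x2))
  expect_equal(margins(m2, "x1", grid = grid)$predicted, unname(hand),
               tolerance = 1e-10)
  expect_error(margins(m2, "x9"), "not retained")
})

test_that("forecast reduction respects availability and nesting", {
  d <- timing_data(seed = 11,
                   f = function(x1, x2, x3) 2 * x1 + 2 * x2, noise_sd = 0.5)
  scr <- screen_covariates(d, "metric", covariates = c("x1", "x2"))
  m <- backward_eliminate(d, "metric", scr,
                          availability = c(x1 = -300, x2 = 200))
  # arrival near day 150: x2's window (day 200) closes too late
  fc <- forecast_model(m, arrival_days = rep(150, 24))
  expect_equal(fc$dropped, "x2")
  expect_lte(fc$r2_forecast, fc$r2_full + 1e-12)
  expect_equal(fc$ratio, fc$r2_forecast / fc$r2_full)
  # all covariates pre-season: forecast equals the full model, ratio 1
  m_pre <- backward_eliminate(d, "metric", scr,
                              availability = c(x1 = -300, x2 = -200))
  fc_pre <- forecast_model(m_pre, arrival_days = rep(150, 24))
  expect_equal(fc_pre$ratio, 1.0)
  expect_length(fc_pre$dropped, 0)
  # everything post-season: flagged, no forecast
  m_post <- backward_eliminate(d, "metric", scr,
                               availability = c(x1 = 300, x2 = 300))
  fc_post <- forecast_model(m_post, arrival_days = rep(150, 24))
  expect_true(fc_post$no_forecast)
})

test_that("year-removal validation matches an independent fold oracle", {
  d <- timing_data(seed = 12, f = function(x1, x2, x3) 2 * x1 - x2,
                   noise_sd = 0.8)
  m <- backward_eliminate(
    d, "metric", tibble::tibble(covariate = c("x1", "x2"), order = 1L))
  val <- year_removal_validate(m)
  # oracle: rebuild the design from scratch per fold with plain lm
  centers <- sapply(c("x1", "x2"), function(v) mean(d[[v]]))
  oracle <- vapply(seq_len(nrow(d)), function(i) {
    tr <- d[-i, ]
    fit <- lm(metric ~ I(x1 - centers["x1"]) + I(x2 - centers["x2"]),
              data = tr)
    predict(fit, newdata = d[i, ])
  }, numeric(1))
  expect_equal(val$predictions$predicted, unname(oracle), tolerance = 1e-9)
  # noiseless linear data: validation R^2 = 1
  d0 <- timing_data(seed = 13, f = function(x1, x2, x3) 2 * x1,
                    noise_sd = 0)
  m0 <- suppressWarnings(
    backward_eliminate(d0, "metric",
                       screen_covariates(d0, "metric", covariates = "x1")))
  expect_equal(suppressWarnings(year_removal_validate(m0))$r2_validation,
               1, tolerance = 1e-9)
})

test_that("pure-noise metrics yield near-zero validation skill", {
  r2s <- vapply(1:30, function(s) {
    d <- timing_data(seed = 500 + s, f = function(x1, x2, x3) 0,
                     noise_sd = 1)
    m <- backward_eliminate(
      d, "metric",
      tibble::tibble(covariate = "x1", order = 1L, p_top = 0.5),
      alpha = 0.999)   # force retention of the noise covariate
    val <- year_removal_validate(m)
    val$r2_validation - val$r2_full
  }, numeric(1))
  # out-of-sample never systematically beats in-sample
  expect_lt(median(r2s), 0.05)
})
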