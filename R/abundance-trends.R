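#' Aggregate filtered daily counts into weekly counts with effort
#'
#' Sums the filtered daily counts over consecutive 7-day blocks from
#' day 1 of the species year (calendar Jan 1; adjusted Jun 1) and
#' records the number of retained (on-effort) days per block, whose log
#' is the model offset. Blocks with no retained days are omitted (not
#' zero-filled). The 1-2 leftover days at the end of the year are
#' merged into week 52. Where morning/evening pairs exist (gray-whale
#' protocol) the daily value is their average before summation.
#'
#' @param daily Filtered daily tibble from [remove_false_zeros()] with
#'   `species`, `species_year`, `day`, `count_obs`, `date`, and
#'   optionally `morning`/`evening`.
#' @return A tibble: `species`, `species_year`, `week`, `count`,
#'   `effort_days`, `week_start` (date of the block's first day),
#'   `month` (calendar month of the block midpoint), `year_centered`.
#' @export
aggregate_weekly <- function(daily) {
  if (anyNA(daily$day)) stop("daily table needs a species-axis 'day' column")
  if (any(duplicated(daily[c("species", "species_year", "day")]))) {
    stop("duplicate daily records for a species-day", call. = FALSE)
  }
  daily <- daily %>%
    mutate(daily_value = dplyr::if_else(
      !is.na(.data$morning) & !is.na(.data$evening),
      (.data$morning + .data$evening) / 2,
      as.numeric(.data$count_obs)),
      week = pmin(ceiling(.data$day / 7), 52))
  wk <- daily %>%
    group_by(.data$species, .data$species_year, .data$week) %>%
    summarise(count = sum(.data$daily_value),
              effort_days = dplyr::n(),
              week_start = min(.data$date) - (min(.data$day) - 1) %% 7,
              month = lubridate::month(min(.data$date) + 3),
              .groups = "drop")
  wk %>%
    mutate(year_centered = .data$species_year - mean(unique(.data$species_year)))
}

#' Negative-binomial trend model of weekly counts
#'
#' Fits an NB2 regression (variance mu + alpha * mu^2, log link) of
#' weekly counts on polynomial year and month terms with
#' log(effort days) as offset, by maximum likelihood. Year and month
#' are centered and scaled before polynomial expansion to stabilise the
#' fit; coefficients are reported on that internal scale.
#'
#' @param weekly Weekly table from [aggregate_weekly()].
#' @param year_degree,month_degree Polynomial degrees (1-3) for year
#'   and month.
#' @param interactions If `TRUE`, include the product of the linear
#'   year and month terms.
#' @return An object of class `nb_trend_fit`: the `glm` fit, `alpha`
#'   (NB2 dispersion), coefficient table, AIC, and the scaling used.
#' @export
fit_nb_trend <- function(weekly, year_degree = 1, month_degree = 2,
                         interactions = FALSE) {
  stopifnot(all(weekly$effort_days >= 1), all(weekly$count >= 0))
  n_par <- 1 + year_degree + month_degree + interactions
  if (nrow(weekly) < 10 * n_par) {
    warning("fewer than 10 weeks per parameter; estimates may be unstable")
  }
  dat <- weekly %>%
    mutate(yr = as.numeric(scale(.data$species_year)),
           mo = as.numeric(scale(.data$month)),
           count = round(.data$count))
  scaling <- list(
    year = c(center = mean(weekly$species_year), scale = sd(weekly$species_year)),
    month = c(center = mean(weekly$month), scale = sd(weekly$month)))
  terms <- c(paste0("I(yr^", seq_len(year_degree), ")"),
             if (month_degree > 0) paste0("I(mo^", seq_len(month_degree), ")"),
             if (interactions) "yr:mo")
  fml <- stats::as.formula(
    paste("count ~", paste(terms, collapse = " + "),
          "+ offset(log(effort_days))"))
  fit <- tryCatch(
    MASS::glm.nb(fml, data = dat, control = stats::glm.control(maxit = 100)),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(MASS::glm.nb(fml, data = dat,
                                    control = stats::glm.control(maxit = 100)))
    })
  poisson_fallback <- FALSE
  if (is.null(fit) || !isTRUE(fit$converged) || fit$theta > 1e5) {
    if (!is.null(fit) && isTRUE(fit$converged) && fit$theta > 1e5) {
      warning("dispersion at the Poisson boundary; falling back to Poisson")
      fit <- stats::glm(fml, data = dat, family = stats::poisson())
      poisson_fallback <- TRUE
    } else if (is.null(fit)) {
      stop("negative-binomial fit failed to converge", call. = FALSE)
    }
  }
  alpha <- if (poisson_fallback) 0 else 1 / fit$theta
  sm <- summary(fit)$coefficients
  structure(list(fit = fit, alpha = alpha,
                 coefficients = tibble(term = rownames(sm),
                                       estimate = sm[, 1], std.error = sm[, 2],
                                       statistic = sm[, 3], p.value = sm[, 4]),
                 aic = AIC(fit), year_degree = year_degree,
                 month_degree = month_degree, interactions = interactions,
                 scaling = scaling, poisson = poisson_fallback,
                 n_weeks = nrow(dat)),
            class = "nb_trend_fit")
}

#' Select the polynomial shape of the year trend
#'
#' Fits cubic, quadratic, and linear year terms (with the month terms
#' throughout) and retains the highest order whose top year coefficient
#' is significant (two-sided Wald P < 0.05), keeping all lower orders.
#'
#' @param weekly Weekly table from [aggregate_weekly()].
#' @param month_degree,interactions Passed to [fit_nb_trend()].
#' @param alpha Significance level.
#' @return The chosen `nb_trend_fit` with `shape` (`"L(+)"` ...
#'   `"C(-)"`, or `"NA"`) and the per-degree p-value table attached.
#' @export
select_trend_shape <- function(weekly, month_degree = 2,
                               interactions = FALSE, alpha = 0.05) {
  fits <- purrr::map(1:3, function(d) {
    tryCatch(fit_nb_trend(weekly, year_degree = d,
                          month_degree = month_degree,
                          interactions = interactions),
             error = function(e) NULL)
  })
  ptab <- purrr::imap_dfr(fits, function(f, d) {
    if (is.null(f)) return(tibble(degree = d, p_top = NA_real_,
                                  sign_top = NA_real_))
    top <- paste0("I(yr^", d, ")")
    row <- f$coefficients[f$coefficients$term == top, ]
    tibble(degree = d, p_top = row$p.value, sign_top = sign(row$estimate))
  })
  sig <- which(!is.na(ptab$p_top) & ptab$p_top < alpha)
  if (length(sig) == 0) {
    best <- fits[[1]]
    best$shape <- "NA"
  } else {
    d <- max(sig)
    best <- fits[[d]]
    sgn <- if (ptab$sign_top[d] >= 0) "+" else "-"
    best$shape <- paste0(c("L", "Q", "C")[d], "(", sgn, ")")
  }
  best$shape_candidates <- ptab
  best
}

#' Predicted weekly counts on a year-by-month grid
#'
#' Mean predicted count at a reference effort, with 95% confidence
#' intervals from the delta method on the linear predictor
#' (back-transformed through the log link, so intervals are positive).
#'
#' @param object An `nb_trend_fit`.
#' @param years,months Grid values on the original scales.
#' @param effort_days Reference effort (days per week) for the offset.
#' @return Tibble `species_year`, `month`, `predicted`, `conf.low`,
#'   `conf.high`, and `extrapolated` (outside the fitted year range).
#' @export
predict_weekly <- function(object, years, months = 1:12, effort_days = 7) {
  stopifnot(inherits(object, "nb_trend_fit"))
  sc <- object$scaling
  grid <- tidyr::expand_grid(species_year = years, month = months) %>%
    mutate(yr = (.data$species_year - sc$year["center"]) / sc$year["scale"],
           mo = (.data$month - sc$month["center"]) / sc$month["scale"],
           effort_days = effort_days)
  lp <- predict(object$fit, newdata = grid, type = "link", se.fit = TRUE)
  fitted_years <- object$fit$model
  rng <- range(object$scaling$year["center"] +
                 object$scaling$year["scale"] * range(fitted_years$yr))
  out <- grid %>%
    mutate(predicted = exp(lp$fit),
           conf.low = exp(lp$fit - 1.96 * lp$se.fit),
           conf.high = exp(lp$fit + 1.96 * lp$se.fit),
           extrapolated = .data$species_year < rng[1] - 0.5 |
             .data$species_year > rng[2] + 0.5) %>%
    select("species_year", "month", "predicted", "conf.low", "conf.high",
           "extrapolated")
  if (any(out$extrapolated)) {
    warning("grid extends beyond the fitted year range")
  }
  out
}

#' @exportS3Method
tidy.nb_trend_fit <- function(x, ...) x$coefficients

#' @exportS3Method
glance.nb_trend_fit <- function(x, ...) {
  tibble(alpha = x$alpha, AIC = x$aic,
         logLik = as.numeric(logLik(x$fit)),
         shape = if (!is.null(x$shape)) x$shape else NA_character_,
         year_degree = x$year_degree, n_weeks = x$n_weeks,
         poisson_fallback = x$poisson)
}

#' @export
print.nb_trend_fit <- function(x, ...) {
  cat("NB2 weekly count trend: year degree", x$year_degree,
      "| alpha =", signif(x$alpha, 3), "| AIC =", round(x$aic, 1), "\n")
  if (!is.null(x$shape)) cat("Selected shape:", x$shape, "\n")
  invisible(x)
}
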