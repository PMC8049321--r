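#' Univariate screening of one environmental covariate
#'
#' Regresses the timing metric on the covariate with linear, quadratic,
#' and cubic candidates (raw powers of the centered covariate) and
#' forwards the highest order whose top term is significant (two-sided
#' P < 0.05). Covariates with no significant order are not forwarded.
#'
#' @param data Tibble with one row per species-year containing the
#'   metric and the covariate.
#' @param metric,covariate Column names.
#' @param alpha Significance level.
#' @param max_order Highest polynomial order tried.
#' @return One-row tibble `covariate`, `order`, `p_top`; zero rows when
#'   nothing is significant or the covariate has (near-)zero variance.
#' @export
univariate_screen <- function(data, metric, covariate, alpha = 0.05,
                              max_order = 3) {
  d <- data %>%
    select(y = dplyr::all_of(metric), x = dplyr::all_of(covariate)) %>%
    filter(complete.cases(.))
  if (nrow(d) < 6) {
    stop("need >= 6 complete years for screening", call. = FALSE)
  }
  if (sd(d$x) < 1e-12) {
    return(tibble(covariate = character(), order = integer(),
                  p_top = numeric()))
  }
  sel <- select_polynomial(d$y, d$x - mean(d$x), max_degree = max_order,
                           alpha = alpha)
  if (sel$degree == 0) {
    return(tibble(covariate = character(), order = integer(),
                  p_top = numeric()))
  }
  tibble(covariate = covariate, order = sel$degree,
         p_top = sel$candidates$p_top[sel$degree])
}

#' Screen a whole covariate table against a timing metric
#'
#' @param data Joined tibble of the metric and covariate columns, one
#'   row per species-year.
#' @param metric Metric column name.
#' @param covariates Covariate column names to screen; defaults to all
#'   numeric columns except the metric and `species_year`.
#' @inheritParams univariate_screen
#' @return Tibble of forwarded terms (`covariate`, `order`, `p_top`).
#' @export
screen_covariates <- function(data, metric, covariates = NULL,
                              alpha = 0.05, max_order = 3) {
  if (is.null(covariates)) {
    covariates <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          c(metric, "species_year"))
  }
  purrr::map(covariates, function(v) {
    tryCatch(univariate_screen(data, metric, v, alpha, max_order),
             error = function(e) tibble(covariate = character(),
                                        order = integer(),
                                        p_top = numeric()))
  }) %>% bind_rows()
}

# design matrix for a set of (covariate, order) blocks: centered raw
# powers, columns named <covariate>_o<k>
build_design <- function(data, terms, centers = NULL) {
  if (nrow(terms) == 0) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0))
  }
  cols <- purrr::pmap(terms, function(covariate, order, ...) {
    x <- data[[covariate]]
    ctr <- if (!is.null(centers)) centers[[covariate]] else mean(x, na.rm = TRUE)
    out <- vapply(seq_len(order), function(k) (x - ctr)^k,
                  numeric(length(x)))
    out <- matrix(out, nrow = length(x))
    colnames(out) <- paste0(covariate, "_o", seq_len(order))
    out
  })
  do.call(cbind, cols)
}

#' Hierarchy-preserving backward elimination of timing covariates
#'
#' Starting from the screened terms, iteratively drops the covariate
#' whose highest-order term has the largest non-significant p-value
#' (P >= 0.05). Per the hierarchy rule, a covariate whose top term
#' falls is first retried at the next lower order; only when its linear
#' term fails is the whole block removed. After convergence the
#' variance inflation factors of the retained design columns are
#' checked; any VIF at or above `vif_limit` removes the higher-p member
#' of the most collinear pair and re-runs the elimination. Finally the
#' model AIC is compared against every single-block-deletion submodel.
#'
#' @param data Tibble of metric + covariates per species-year (must
#'   include `species_year`).
#' @param metric Metric column name.
#' @param terms Screened terms tibble (`covariate`, `order`) from
#'   [screen_covariates()].
#' @param alpha Significance level for retention.
#' @param vif_limit Collinearity threshold (default 10).
#' @param availability Optional named vector of availability days (for
#'   later forecast reduction); defaults to the `availability` attribute
#'   of `data` if present.
#' @return An object of class `timing_model`; see
#'   [tidy.timing_model()], [glance.timing_model()], [margins()].
#' @export
backward_eliminate <- function(data, metric, terms, alpha = 0.05,
                               vif_limit = 10, availability = NULL) {
  if (is.null(availability)) availability <- attr(data, "availability")
  keep_cols <- unique(c("species_year", metric, terms$covariate))
  dat <- data %>% select(dplyr::all_of(keep_cols)) %>% filter(complete.cases(.))
  n <- nrow(dat)
  if (n < 6) stop("too few years for the candidate set", call. = FALSE)
  # the preliminary model must be estimable: if screening forwarded more
  # parameters than the years can support, keep the strongest candidates
  # (smallest screening p) until it fits
  if ("p_top" %in% names(terms)) terms <- terms %>% arrange(.data$p_top)
  while (nrow(terms) > 0 && n <= sum(terms$order) + 3) {
    terms <- terms[-nrow(terms), ]
  }
  centers <- purrr::map(setNames(terms$covariate, terms$covariate),
                        ~ mean(dat[[.x]]))
  terms <- terms %>% select("covariate", "order") %>% distinct()

  fit_terms <- function(tt) {
    X <- build_design(dat, tt, centers)
    df <- data.frame(y = dat[[metric]], X, check.names = FALSE)
    lm(y ~ ., data = df)
  }
  top_p <- function(fit, tt) {
    sm <- summary(fit)$coefficients
    vapply(seq_len(nrow(tt)), function(i) {
      nm <- paste0(tt$covariate[i], "_o", tt$order[i])
      if (nm %in% rownames(sm)) sm[nm, 4] else NA_real_
    }, numeric(1))
  }

  eliminate <- function(tt) {
    repeat {
      if (nrow(tt) == 0) return(tt)
      fit <- fit_terms(tt)
      p <- top_p(fit, tt)
      p[is.na(p)] <- 1   # aliased term: certainly not significant
      bad <- which(p >= alpha)
      if (length(bad) == 0) return(tt)
      # worst covariate block; deterministic tie-break by name
      worst <- bad[order(-p[bad], tt$covariate[bad])][1]
      if (tt$order[worst] > 1) {
        tt$order[worst] <- tt$order[worst] - 1L
      } else {
        tt <- tt[-worst, ]
      }
    }
  }

  tt <- eliminate(terms)
  # collinearity pass: VIF on the retained design columns
  vif_tab <- NULL
  repeat {
    if (nrow(tt) < 2) break
    X <- build_design(dat, tt, centers)
    v <- vif_terms(X)
    vif_tab <- tibble(term = colnames(X), vif = v)
    if (max(v) < vif_limit) break
    offender <- colnames(X)[which.max(v)]
    partner <- most_collinear_partner(X, offender)
    fit <- fit_terms(tt)
    p <- top_p(fit, tt)
    cov_of <- function(col) sub("_o[0-9]+$", "", col)
    pair <- c(cov_of(offender), cov_of(partner))
    pair <- pair[pair %in% tt$covariate]
    if (length(unique(pair)) == 1) {
      drop_cov <- pair[1]
    } else {
      p_pair <- p[match(pair, tt$covariate)]
      p_pair[is.na(p_pair)] <- 1
      drop_cov <- pair[which.max(p_pair)]
    }
    tt <- tt[tt$covariate != drop_cov, ]
    tt <- eliminate(tt)
  }

  not_significant <- nrow(tt) == 0
  fit <- fit_terms(tt)
  sm <- summary(fit)
  # parsimony check: AIC of every single-block deletion
  aic_check <- if (nrow(tt) > 0) {
    purrr::map_dfr(seq_len(nrow(tt)), function(i) {
      tibble(dropped = tt$covariate[i],
             aic = AIC(fit_terms(tt[-i, ])))
    }) %>% bind_rows(tibble(dropped = "(none)", aic = AIC(fit)))
  } else {
    tibble(dropped = "(none)", aic = AIC(fit))
  }
  structure(list(fit = fit, terms = tt, metric = metric, data = dat,
                 centers = centers, n = n,
                 r.squared = sm$r.squared,
                 adj.r.squared = sm$adj.r.squared,
                 aic = AIC(fit), vif = vif_tab,
                 overall_p = overall_f_p(sm),
                 aic_check = aic_check,
                 availability = availability, alpha = alpha,
                 vif_limit = vif_limit,
                 not_significant = not_significant),
            class = "timing_model")
}

overall_f_p <- function(sm) {
  if (is.null(sm$fstatistic)) return(NA_real_)
  unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                   lower.tail = FALSE))
}

# the column most correlated with `offender` among the others
most_collinear_partner <- function(X, offender) {
  others <- setdiff(colnames(X), offender)
  if (length(others) == 0) return(offender)
  r <- vapply(others, function(o) {
    suppressWarnings(abs(stats::cor(X[, offender], X[, o])))
  }, numeric(1))
  r[is.na(r)] <- 0
  others[which.max(r)]
}

#' Variance inflation factors by auxiliary regression
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from regressing design column j
#' on all other columns. Perfect collinearity is reported as `Inf`
#' rather than an error.
#'
#' @param X Numeric design matrix (or data frame) of at least two
#'   columns, intercept excluded.
#' @return Named numeric vector of VIFs.
#' @export
vif_terms <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 2)
  vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

#' Partial predictions over one covariate (margins)
#'
#' Predictions of the timing metric over a grid of one covariate with
#' every other covariate in the model held at its sample mean, with
#' pointwise 95% confidence intervals using the t distribution at the
#' residual degrees of freedom.
#'
#' @param model A `timing_model`.
#' @param covariate Focus covariate name (must be retained).
#' @param grid Grid of covariate values; defaults to 25 points across
#'   the observed range.
#' @param level Confidence level.
#' @return Tibble `covariate`, `value`, `predicted`, `conf.low`,
#'   `conf.high`, `extrapolated`.
#' @export
margins <- function(model, covariate, grid = NULL, level = 0.95) {
  stopifnot(inherits(model, "timing_model"))
  if (!covariate %in% model$terms$covariate) {
    stop("covariate not retained in the model: ", covariate, call. = FALSE)
  }
  obs <- model$data[[covariate]]
  if (is.null(grid)) grid <- seq(min(obs), max(obs), length.out = 25)
  newdata <- purrr::map_dfc(setNames(model$terms$covariate,
                                     model$terms$covariate),
                            function(v) {
                              if (v == covariate) grid
                              else rep(mean(model$data[[v]]), length(grid))
                            })
  X <- build_design(newdata, model$terms, model$centers)
  df <- data.frame(X, check.names = FALSE)
  pr <- predict(model$fit, newdata = df, se.fit = TRUE)
  tcrit <- qt(1 - (1 - level) / 2, model$fit$df.residual)
  tibble(covariate = covariate, value = grid,
         predicted = unname(pr$fit),
         conf.low = unname(pr$fit - tcrit * pr$se.fit),
         conf.high = unname(pr$fit + tcrit * pr$se.fit),
         extrapolated = grid < min(obs) | grid > max(obs))
}

#' Reduce a timing model to its pre-season forecast version
#'
#' Keeps only the retained covariates whose raw-data window closes
#' before the migration period begins (the species' earliest observed
#' arrival day minus `lead` days) and refits without re-elimination.
#' When nothing is dropped the forecast model is the full model. The
#' unadjusted R^2 ratio forecast/full is reported; by nesting it is
#' at most 1.
#'
#' @param model A fitted `timing_model`.
#' @param arrival_days Observed arrival days across years (species
#'   axis) used to locate the start of the migration period.
#' @param lead Lead time in days subtracted from the earliest arrival.
#' @return A list of class `forecast_model`: `forecast` (a
#'   `timing_model`, or `NULL` when every term was dropped),
#'   `dropped` covariates, `r2_full`, `r2_forecast`, `ratio`.
#' @export
forecast_model <- function(model, arrival_days, lead = 0) {
  stopifnot(inherits(model, "timing_model"))
  if (is.null(model$availability)) {
    stop("model carries no covariate availability metadata", call. = FALSE)
  }
  cutoff <- min(arrival_days, na.rm = TRUE) - lead
  avail <- model$availability[model$terms$covariate]
  droppable <- model$terms$covariate[is.na(avail) | avail >= cutoff]
  keep <- model$terms %>% filter(!.data$covariate %in% droppable)
  if (nrow(keep) == 0) {
    return(structure(list(forecast = NULL, dropped = droppable,
                          r2_full = model$r.squared,
                          r2_forecast = NA_real_, ratio = NA_real_,
                          cutoff_day = cutoff,
                          no_forecast = TRUE),
                     class = "forecast_model"))
  }
  fx <- refit_terms(model, keep)
  structure(list(forecast = fx, dropped = droppable,
                 r2_full = model$r.squared,
                 r2_forecast = fx$r.squared,
                 ratio = fx$r.squared / model$r.squared,
                 cutoff_day = cutoff, no_forecast = FALSE),
            class = "forecast_model")
}

# refit a timing_model on a fixed term set (no elimination)
refit_terms <- function(model, terms) {
  X <- build_design(model$data, terms, model$centers)
  df <- data.frame(y = model$data[[model$metric]], X, check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)
  out <- model
  out$fit <- fit
  out$terms <- terms
  out$r.squared <- sm$r.squared
  out$adj.r.squared <- sm$adj.r.squared
  out$aic <- AIC(fit)
  out$overall_p <- overall_f_p(sm)
  out$vif <- if (nrow(terms) >= 2 && ncol(X) >= 2) {
    tibble(term = colnames(X), vif = vif_terms(X))
  } else NULL
  out
}

#' Year-removal (leave-one-year-out) validation of a timing model
#'
#' Refits the model with its fixed retained-term set once per year with
#' that year's observation removed, predicts the held-out year, and
#' reports the validation R^2 together with its ratio to the
#' full-model in-sample R^2.
#'
#' @param model A `timing_model`.
#' @param method Validation R^2 definition: `"cor"` (squared Pearson
#'   correlation of observed vs out-of-sample predictions, default) or
#'   `"ss"` (1 - SSE/SST).
#' @return A list of class `year_removal`: `predictions` tibble
#'   (`species_year`, `observed`, `predicted`), `r2_validation`,
#'   `r2_full`, `ratio`, `p_value` (of the observed~predicted
#'   regression).
#' @export
year_removal_validate <- function(model, method = c("cor", "ss")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "timing_model"))
  dat <- model$data
  n <- nrow(dat)
  if (n < 6) stop("need >= 6 years to validate", call. = FALSE)
  preds <- purrr::map_dbl(seq_len(n), function(i) {
    train <- dat[-i, ]
    X <- build_design(train, model$terms, model$centers)
    df <- data.frame(y = train[[model$metric]], X, check.names = FALSE)
    fit <- tryCatch(lm(y ~ ., data = df), error = function(e) NULL)
    if (is.null(fit) || anyNA(coef(fit))) return(NA_real_)
    Xi <- build_design(dat[i, ], model$terms, model$centers)
    unname(predict(fit, newdata = data.frame(Xi, check.names = FALSE)))
  })
  obs <- dat[[model$metric]]
  ok <- !is.na(preds)
  degenerate <- sd(preds[ok]) < 1e-12
  r2 <- if (degenerate) {
    0
  } else if (method == "cor") {
    stats::cor(obs[ok], preds[ok])^2
  } else {
    1 - sum((obs[ok] - preds[ok])^2) / sum((obs[ok] - mean(obs[ok]))^2)
  }
  pfit <- if (degenerate) NULL else summary(lm(obs[ok] ~ preds[ok]))
  structure(list(predictions = tibble(species_year = dat$species_year,
                                      observed = obs, predicted = preds),
                 r2_validation = r2, r2_full = model$r.squared,
                 ratio = r2 / model$r.squared,
                 p_value = if (is.null(pfit)) NA_real_ else overall_f_p(pfit),
                 method = method),
            class = "year_removal")
}

#' @exportS3Method
tidy.timing_model <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  out <- tibble(term = rownames(sm), estimate = sm[, 1],
                std.error = sm[, 2], statistic = sm[, 3],
                p.value = sm[, 4])
  shapes <- x$terms %>%
    mutate(term = paste0(.data$covariate, "_o", .data$order),
           shape = paste0(c("L", "Q", "C")[.data$order],
                          ifelse(coef(x$fit)[.data$term] >= 0, "(+)", "(-)")))
  left_join(out, shapes %>% select("term", "covariate", "shape"),
            by = "term")
}

#' @exportS3Method
glance.timing_model <- function(x, ...) {
  tibble(r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
         AIC = x$aic, p.value = x$overall_p, n = x$n,
         n_covariates = nrow(x$terms),
         max_vif = if (!is.null(x$vif)) max(x$vif$vif) else NA_real_,
         not_significant = x$not_significant)
}

#' @export
print.timing_model <- function(x, ...) {
  if (x$not_significant) {
    cat("Timing model (", x$metric, "): not significant (no retained terms)\n",
        sep = "")
    return(invisible(x))
  }
  cat("Timing model (", x$metric, "): ", nrow(x$terms),
      " covariate(s), adj R2 = ", round(x$adj.r.squared, 3),
      ", overall P = ", signif(x$overall_p, 3), "\n", sep = "")
  print(x$terms, n = Inf)
  invisible(x)
}

#' @export
print.forecast_model <- function(x, ...) {
  cat("Forecast model: R2 ", round(x$r2_forecast, 3), " / full ",
      round(x$r2_full, 3), " (ratio ",
      ifelse(is.na(x$ratio), "NA", round(x$ratio, 3)), ")\n", sep = "")
  if (length(x$dropped)) {
    cat("Dropped (window closes after migration start):",
        paste(x$dropped, collapse = ", "), "\n")
  } else {
    cat("No variables removed\n")
  }
  invisible(x)
}
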