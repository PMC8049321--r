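#' Species-specific exclusions for count analyses
#'
#' Applies the dataset conventions before aggregation or timing:
#' * **blue**: January-February days are dropped — blue whales are
#'   essentially absent in winter, and the single anomalous winter
#'   influx would otherwise dominate;
#' * **gray_south**: adjusted-year weeks 1-18 (June-September) are
#'   dropped — the small summer resident group is not part of the
#'   migrating population;
#' * **anomaly years** (any species): a species-year whose annual total
#'   is below `anomaly_fraction` of the cross-year median annual total
#'   is excluded outright (an ecological-anomaly year in which timing
#'   cannot be assessed).
#'
#' @param daily Daily sighting tibble with `species`, `species_year`,
#'   `day` (species-axis day), `count_obs`, `date`.
#' @param species Species label governing the rules (`"blue"`,
#'   `"gray_south"`, `"gray_north"`, `"humpback"`, ...).
#' @param anomaly_fraction Threshold as a fraction of the median annual
#'   total (default 0.05).
#' @return The filtered tibble; the `exclusions` attribute logs dropped
#'   species-years and row counts per rule.
#' @export
apply_exclusions <- function(daily, species, anomaly_fraction = 0.05) {
  log <- list()
  if (species == "blue") {
    drop <- lubridate::month(daily$date) %in% c(1, 2)
    log$winter_days <- sum(drop)
    daily <- daily[!drop, ]
  }
  if (species == "gray_south") {
    wk <- pmin(ceiling(daily$day / 7), 52)
    drop <- wk <= 18
    log$summer_weeks_days <- sum(drop)
    daily <- daily[!drop, ]
  }
  totals <- daily %>%
    group_by(.data$species_year) %>%
    summarise(total = sum(.data$count_obs, na.rm = TRUE), .groups = "drop")
  med <- median(totals$total)
  anomalous <- totals$species_year[totals$total < anomaly_fraction * med]
  log$anomaly_years <- anomalous
  daily <- daily %>% filter(!.data$species_year %in% anomalous)
  attr(daily, "exclusions") <- log
  daily
}

#' Split a gray-whale daily table into the two migration datasets
#'
#' The gray season is bimodal on the adjusted (June-1-start) year: a
#' south-bound breeding peak in January and a north-bound feeding peak
#' in March. The two are analysed separately; days at or before
#' `split_day` (adjusted axis, default 260 ~ mid-February, the trough
#' between the peaks) go to `gray_south`, later days to `gray_north`.
#'
#' @param daily Gray-whale daily tibble with a `day` column on the
#'   adjusted axis.
#' @param split_day Adjusted-year day separating the two migrations.
#' @return The tibble with `species` relabelled `gray_south` /
#'   `gray_north`.
#' @export
split_gray <- function(daily, split_day = 260) {
  daily %>%
    mutate(species = ifelse(.data$day <= split_day,
                            "gray_south", "gray_north"))
}

#' Arrival, peak, and departure timing for one species-year
#'
#' Timing statistics are percentile days of the cumulative annual
#' sighting distribution: arrival is the first day on which cumulative
#' sightings reach 10% of the annual total, peak 50%, departure 90%
#' (smallest-day >= rule, no interpolation). Residency is departure
#' minus arrival.
#'
#' @param daily Daily counts for one species-year: `day` (species-axis
#'   day) and `count_obs`.
#' @return One-row tibble: `arrival_day`, `peak_day`, `departure_day`,
#'   `residency_days`, `annual_total`, `excluded`, `reason`.
#' @export
compute_timing <- function(daily) {
  daily <- daily %>% arrange(.data$day)
  total <- sum(daily$count_obs, na.rm = TRUE)
  if (total <= 0) {
    return(tibble(arrival_day = NA_real_, peak_day = NA_real_,
                  departure_day = NA_real_, residency_days = NA_real_,
                  annual_total = 0, excluded = TRUE,
                  reason = "no sightings"))
  }
  cum <- cumsum(dplyr::coalesce(daily$count_obs, 0))
  pct_day <- function(p) daily$day[which(cum >= p * total)[1]]
  arr <- pct_day(0.1); pk <- pct_day(0.5); dep <- pct_day(0.9)
  tibble(arrival_day = arr, peak_day = pk, departure_day = dep,
         residency_days = dep - arr, annual_total = total,
         excluded = FALSE, reason = NA_character_)
}

#' Timing table across species-years
#'
#' Applies [compute_timing()] per species-year of an (already
#' exclusion-filtered) daily table.
#'
#' @param daily Daily tibble with `species`, `species_year`, `day`,
#'   `count_obs`.
#' @return Tibble with one row per species-year.
#' @export
compute_timing_table <- function(daily) {
  daily %>%
    group_by(.data$species, .data$species_year) %>%
    dplyr::group_modify(~ compute_timing(.x)) %>%
    ungroup()
}

#' Polynomial trend of a timing metric on year
#'
#' Fits ordinary least squares of the metric day on (centered) year
#' with linear, quadratic, and cubic candidates and retains the highest
#' order whose top term is significant (two-sided P < 0.05), keeping
#' all lower orders. The shape label is `"L"`, `"Q"`, `"C"`, or `"NA"`
#' with the sign of the top coefficient.
#'
#' @param timing Timing tibble from [compute_timing_table()].
#' @param metric `"arrival_day"`, `"peak_day"`, `"departure_day"`, or
#'   `"residency_days"`.
#' @param alpha Significance level for the top-order Wald/t test.
#' @return An object of class `timing_trend_fit`: the selected `lm`,
#'   `shape` (e.g. `"L(-)"`), `degree`, linear-term slope in days per
#'   year (for degree 1), and the candidate-fit table.
#' @export
fit_timing_trend <- function(timing, metric = "arrival_day", alpha = 0.05) {
  dat <- timing %>%
    filter(!.data$excluded, !is.na(.data[[metric]])) %>%
    select(year = "species_year", y = dplyr::all_of(metric))
  if (nrow(dat) < 6) stop("need >= 6 non-excluded years", call. = FALSE)
  dat$x <- dat$year - mean(dat$year)
  sel <- select_polynomial(dat$y, dat$x, max_degree = 3, alpha = alpha)
  slope <- if (sel$degree == 1) unname(coef(sel$fit)["x1"]) else NA_real_
  structure(list(fit = sel$fit, shape = sel$shape, degree = sel$degree,
                 slope_per_year = slope, metric = metric,
                 candidates = sel$candidates, data = dat,
                 n_years = nrow(dat)),
            class = "timing_trend_fit")
}

# shared machinery: fit y ~ poly(x, d, raw) for d = max..1, keep the
# highest degree whose top coefficient is significant
select_polynomial <- function(y, x, max_degree = 3, alpha = 0.05) {
  cand <- purrr::map(seq_len(max_degree), function(d) {
    X <- stats::poly(x, degree = d, raw = TRUE)
    colnames(X) <- paste0("x", seq_len(d))
    df <- data.frame(y = y, X)
    fit <- lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    top <- paste0("x", d)
    p <- if (top %in% rownames(sm)) sm[top, 4] else NA_real_
    list(degree = d, fit = fit, p_top = p,
         sign_top = sign(coef(fit)[[top]]))
  })
  ptab <- tibble(degree = purrr::map_int(cand, "degree"),
                 p_top = purrr::map_dbl(cand, "p_top"))
  sig <- which(ptab$p_top < alpha & !is.na(ptab$p_top))
  if (length(sig) == 0) {
    return(list(degree = 0L, fit = lm(y ~ 1), shape = "NA",
                candidates = ptab))
  }
  best <- max(sig)
  letter <- c("L", "Q", "C")[best]
  sgn <- if (cand[[best]]$sign_top >= 0) "+" else "-"
  list(degree = best, fit = cand[[best]]$fit,
       shape = paste0(letter, "(", sgn, ")"), candidates = ptab)
}

#' @exportS3Method
tidy.timing_trend_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' @exportS3Method
glance.timing_trend_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(shape = x$shape, degree = x$degree,
         slope_per_year = x$slope_per_year,
         r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
         AIC = AIC(x$fit), n_years = x$n_years)
}

#' @export
print.timing_trend_fit <- function(x, ...) {
  cat("Timing trend (", x$metric, "): shape ", x$shape, sep = "")
  if (!is.na(x$slope_per_year)) {
    cat(sprintf(", slope %.2f d/yr", x$slope_per_year))
  }
  cat(", n =", x$n_years, "years\n")
  invisible(x)
}
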