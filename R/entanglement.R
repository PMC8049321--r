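#' Join monthly entanglements with monthly counts and timing
#'
#' Builds the monthly analysis table for the entanglement models.
#' Monthly whale counts are derived from the weekly counts by
#' day-proportional apportionment: a week contributes
#' `count * overlap_days / week_days` to each calendar month it
#' overlaps. Arrival and departure days are attached by species-year.
#'
#' @param entanglements Tibble `species`, `year`, `month`,
#'   `entanglements`.
#' @param weekly Weekly counts from [aggregate_weekly()] (needs
#'   `week_start`).
#' @param timing Timing table from [compute_timing_table()].
#' @param species Species to build the design for.
#' @return Tibble `year`, `month`, `entanglements`, `count`,
#'   `arrival_day`, `departure_day`, `no_sightings` (flag for months
#'   with no sighting data).
#' @export
build_monthly_design <- function(entanglements, weekly, timing, species) {
  sp <- species
  ent <- entanglements %>% filter(.data$species == sp)
  wk <- weekly %>% filter(.data$species == sp)
  tm <- timing %>% filter(.data$species == sp, !.data$excluded)
  if (nrow(ent) == 0 || nrow(wk) == 0) {
    stop("species not present in entanglement or weekly table: ", sp,
         call. = FALSE)
  }
  # apportion each week's count across the months it overlaps
  monthly_counts <- purrr::pmap(
    list(wk$week_start, wk$week, wk$count),
    function(week_start, week, count) {
      days <- seq(week_start, week_start + ifelse(week == 52, 8, 6),
                  by = "day")
      tibble(year = lubridate::year(days),
             month = lubridate::month(days),
             part = count / length(days))
    }) %>%
    bind_rows() %>%
    group_by(.data$year, .data$month) %>%
    summarise(count = sum(.data$part), .groups = "drop")
  ent %>%
    left_join(monthly_counts, by = c("year", "month")) %>%
    left_join(tm %>% select(species_year = "species_year",
                            "arrival_day", "departure_day"),
              by = c(year = "species_year")) %>%
    mutate(no_sightings = is.na(.data$count),
           count = dplyr::coalesce(.data$count, 0)) %>%
    select("year", "month", "entanglements", "count",
           "arrival_day", "departure_day", "no_sightings")
}

#' Entanglement trend and combined sightings + timing models
#'
#' Two ordinary-least-squares models of monthly entanglements:
#' a trend model on year, and a combined model starting from monthly
#' whale count, arrival day, and departure day (each screened for
#' linear/quadratic/cubic form) reduced by hierarchy-preserving
#' backward elimination to all-significant terms with a VIF check —
#' the same protocol as the environmental timing models.
#'
#' @param monthly Design from [build_monthly_design()].
#' @param alpha,vif_limit Elimination parameters.
#' @param min_entanglements Models are not fitted when the series total
#'   is below this (sparse-species guard); default 10.
#' @return A list of class `entanglement_models`: `trend` (`lm`),
#'   `combined` (`timing_model`), and the input row count.
#' @export
fit_entanglement_models <- function(monthly, alpha = 0.05, vif_limit = 10,
                                    min_entanglements = 10) {
  if (sum(monthly$entanglements) < min_entanglements) {
    stop("too few entanglements for model fitting (",
         sum(monthly$entanglements), " < ", min_entanglements, ")",
         call. = FALSE)
  }
  if (nrow(monthly) < 24) {
    stop("need >= 24 monthly rows", call. = FALSE)
  }
  trend <- lm(entanglements ~ year, data = monthly)
  dat <- monthly %>%
    filter(!.data$no_sightings, complete.cases(.)) %>%
    mutate(species_year = .data$year)
  screened <- screen_covariates(dat, "entanglements",
                                covariates = c("count", "arrival_day",
                                               "departure_day"),
                                alpha = alpha)
  combined <- backward_eliminate(dat, "entanglements", screened,
                                 alpha = alpha, vif_limit = vif_limit,
                                 availability = NULL)
  structure(list(trend = trend, combined = combined, n = nrow(dat)),
            class = "entanglement_models")
}

#' Relative variance contribution of two predictors via squared t
#'
#' In a linear model the share of variance in the response attributable
#' to a predictor is proportional to the square of its t statistic.
#' Returns t^2 for both terms and how much more (in percent, rounded to
#' the nearest integer) term A accounts for than term B:
#' `(t2_a / t2_b - 1) * 100`.
#'
#' @param model A `timing_model` (e.g. the combined entanglement
#'   model) or any object whose [tidy()] has `term`, `statistic`.
#' @param term_a,term_b Design-column names (e.g. `"count_o1"`).
#' @return A list `t2_a`, `t2_b`, `percent_more`.
#' @export
variance_attribution <- function(model, term_a, term_b) {
  tt <- tidy(model)
  get_t <- function(nm) {
    row <- tt[tt$term == nm, ]
    if (nrow(row) != 1) stop("term not in model: ", nm, call. = FALSE)
    row$statistic
  }
  t_a <- get_t(term_a)
  t_b <- get_t(term_b)
  if (abs(t_b) < 1e-12) {
    return(list(t2_a = t_a^2, t2_b = 0, percent_more = NA_real_,
                undefined = TRUE))
  }
  list(t2_a = t_a^2, t2_b = t_b^2,
       percent_more = percent_more_variance(t_a^2, t_b^2))
}

#' @rdname variance_attribution
#' @param t2_a,t2_b Squared t statistics.
#' @export
percent_more_variance <- function(t2_a, t2_b) {
  round((t2_a / t2_b - 1) * 100)
}

#' @export
print.entanglement_models <- function(x, ...) {
  cat("Entanglement models (n =", x$n, "months)\n")
  cat("Trend on year: slope", signif(coef(x$trend)[2], 3), "\n")
  print(x$combined)
  invisible(x)
}
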