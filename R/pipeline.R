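#' Pipeline configuration
#'
#' Bundles every stage's hyperparameters with the simulation
#' configuration and the output directory layout. All analysis
#' defaults mirror the survey protocol: significance level 0.05, VIF
#' limit 10, anomaly threshold 5% of the median annual total,
#' optimal-cutoff criterion "accuracy".
#'
#' @param sim A [sim_config()] for the `simulate` stage.
#' @param species Species datasets to analyse.
#' @param cart List of CART hyperparameters.
#' @param cutoff_criterion `"accuracy"` or `"youden"`.
#' @param anomaly_fraction,alpha,vif_limit,forecast_lead,gray_split_day,min_entanglements
#'   Stage parameters; see the stage functions.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            species = c("humpback", "blue",
                                        "gray_south", "gray_north"),
                            cart = list(max_depth = 5, min_leaf = 5,
                                        xval = 10, cp = 0.01),
                            cutoff_criterion = "accuracy",
                            anomaly_fraction = 0.05,
                            alpha = 0.05, vif_limit = 10,
                            forecast_lead = 0, gray_split_day = 260,
                            min_entanglements = 10) {
  stopifnot(alpha > 0, alpha < 1, vif_limit > 1)
  structure(list(sim = sim, species = species, cart = cart,
                 cutoff_criterion = cutoff_criterion,
                 anomaly_fraction = anomaly_fraction, alpha = alpha,
                 vif_limit = vif_limit, forecast_lead = forecast_lead,
                 gray_split_day = gray_split_day,
                 min_entanglements = min_entanglements),
            class = "pipeline_config")
}

stage_order <- c("simulate", "effort", "trends", "phenology",
                 "covariates", "timing", "forecast", "entangle")

stage_inputs <- list(
  simulate = character(),
  effort = c("sightings.csv", "weather.csv"),
  trends = "filtered_sightings.csv",
  phenology = "filtered_sightings.csv",
  covariates = c("climate_indices.csv", "wind.csv", "ocean.csv"),
  timing = c("timing.csv", "covariates_calendar.csv"),
  forecast = c("timing.csv", "covariates_calendar.csv"),
  entangle = c("entanglements.csv", "weekly_counts.csv", "timing.csv"))

#' Run one pipeline stage against an output directory
#'
#' Stages communicate through delimited text files in `outdir`
#' (models additionally as JSON), so a stage can be re-run in
#' isolation; a missing upstream artifact raises an error naming the
#' stage to run first. Re-running a stage with unchanged inputs and
#' seed reproduces identical outputs.
#'
#' @param stage One of `"simulate"`, `"effort"`, `"trends"`,
#'   `"phenology"`, `"covariates"`, `"timing"`, `"forecast"`,
#'   `"entangle"`, or `"all"`.
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The stage's main result, invisibly.
#' @export
run_stage <- function(stage, config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (stage == "all") return(run_pipeline(config, outdir))
  stage <- match.arg(stage, stage_order)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  need <- stage_inputs[[stage]]
  missing_in <- need[!file.exists(file.path(outdir, need))]
  if (length(missing_in) > 0) {
    prior <- stage_order[seq_len(match(stage, stage_order) - 1)]
    stop("missing upstream artifact(s) ",
         paste(missing_in, collapse = ", "),
         "; run an earlier stage first (one of: ",
         paste(prior, collapse = ", "), ")", call. = FALSE)
  }
  fn <- get(paste0("stage_", stage), mode = "function")
  invisible(fn(config, outdir))
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  res <- purrr::map(stage_order, run_stage, config = config,
                    outdir = outdir)
  invisible(setNames(res, stage_order))
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
}

stage_simulate <- function(config, outdir) {
  ds <- simulate_dataset(config$sim)
  readr::write_csv(ds$sightings %>%
                     select("date", "species", "species_year", "day",
                            "count_obs", "morning", "evening",
                            "effort_obs", "effort_known", "effort_true"),
                   file.path(outdir, "sightings.csv"))
  readr::write_csv(ds$weather, file.path(outdir, "weather.csv"))
  readr::write_csv(ds$environment$climate,
                   file.path(outdir, "climate_indices.csv"))
  readr::write_csv(ds$environment$wind, file.path(outdir, "wind.csv"))
  readr::write_csv(ds$environment$ocean, file.path(outdir, "ocean.csv"))
  readr::write_csv(ds$environment$sst_grid,
                   file.path(outdir, "sst_grid.csv"))
  readr::write_csv(ds$entanglements,
                   file.path(outdir, "entanglements.csv"))
  readr::write_csv(ds$truth %>% select(-"peak_mu"),
                   file.path(outdir, "truth.csv"))
  ds
}

stage_effort <- function(config, outdir) {
  sightings <- readr::read_csv(file.path(outdir, "sightings.csv"),
                               show_col_types = FALSE)
  weather <- readr::read_csv(file.path(outdir, "weather.csv"),
                             show_col_types = FALSE)
  # one row per date for the effort model (species share the survey)
  by_date <- sightings %>%
    distinct(.data$date, .data$effort_obs, .data$effort_known) %>%
    left_join(weather, by = "date")
  labeled <- by_date %>% filter(.data$effort_known, !is.na(.data$effort_obs))
  clf <- fit_effort_cart(labeled %>% rename(effort = "effort_obs"),
                         max_depth = config$cart$max_depth,
                         min_leaf = config$cart$min_leaf,
                         xval = config$cart$xval, cp = config$cart$cp)
  p_lab <- predict_effort(clf, labeled)
  cut <- optimal_cutoff(p_lab, labeled$effort_obs,
                        criterion = config$cutoff_criterion)
  p_all <- predict_effort(clf, by_date)
  class_all <- ifelse(by_date$effort_known & !is.na(by_date$effort_obs),
                      by_date$effort_obs,
                      as.integer(p_all >= cut))
  class_tbl <- tibble(date = by_date$date, effort_class = class_all)
  daily <- sightings %>% left_join(class_tbl, by = "date")
  filtered <- remove_false_zeros(daily, daily$effort_class)
  readr::write_csv(filtered, file.path(outdir, "filtered_sightings.csv"))
  rep <- effort_report(clf, p_lab, labeled$effort_obs, cut)
  write_json_out(list(cutoff = rep$cutoff, accuracy = rep$accuracy,
                      confusion = as.data.frame(rep$confusion),
                      variable_importance = as.list(rep$variable_importance)),
                 file.path(outdir, "effort_report.json"))
  list(classifier = clf, cutoff = cut, filtered = filtered, report = rep)
}

# filtered daily table with gray split applied and per-species axis
load_filtered <- function(config, outdir) {
  filtered <- readr::read_csv(file.path(outdir, "filtered_sightings.csv"),
                              show_col_types = FALSE)
  if ("gray" %in% filtered$species) {
    filtered <- bind_rows(
      filtered %>% filter(.data$species != "gray"),
      filtered %>% filter(.data$species == "gray") %>%
        split_gray(split_day = config$gray_split_day))
  }
  filtered
}

stage_trends <- function(config, outdir) {
  filtered <- load_filtered(config, outdir)
  res <- purrr::map(config$species, function(sp) {
    d <- filtered %>% filter(.data$species == sp)
    if (nrow(d) == 0) return(NULL)
    d <- apply_exclusions(d, sp, config$anomaly_fraction)
    wk <- aggregate_weekly(d)
    fit <- select_trend_shape(wk, alpha = config$alpha)
    yrs <- sort(unique(wk$species_year))
    preds <- suppressWarnings(
      predict_weekly(fit, years = yrs,
                     months = sort(unique(wk$month))))
    list(species = sp, weekly = wk, fit = fit, predictions = preds)
  }) %>% setNames(config$species)
  res <- purrr::compact(res)
  weekly_all <- bind_rows(purrr::map(res, "weekly"))
  readr::write_csv(weekly_all, file.path(outdir, "weekly_counts.csv"))
  readr::write_csv(bind_rows(purrr::map(res, function(r) {
    r$predictions %>% mutate(species = r$species)
  })), file.path(outdir, "predictions.csv"))
  write_json_out(purrr::map(res, function(r) {
    list(shape = r$fit$shape, alpha = r$fit$alpha, aic = r$fit$aic,
         coefficients = r$fit$coefficients)
  }), file.path(outdir, "trend_fit.json"))
  res
}

stage_phenology <- function(config, outdir) {
  filtered <- load_filtered(config, outdir)
  res <- purrr::map(config$species, function(sp) {
    d <- filtered %>% filter(.data$species == sp)
    if (nrow(d) == 0) return(NULL)
    d <- apply_exclusions(d, sp, config$anomaly_fraction)
    tt <- compute_timing_table(d)
    trends <- purrr::map(
      c(arrival = "arrival_day", peak = "peak_day",
        departure = "departure_day"),
      function(m) tryCatch(fit_timing_trend(tt, m, alpha = config$alpha),
                           error = function(e) NULL))
    list(species = sp, timing = tt, trends = trends)
  }) %>% purrr::compact()
  timing_all <- bind_rows(purrr::map(res, "timing"))
  readr::write_csv(timing_all, file.path(outdir, "timing.csv"))
  write_json_out(purrr::map(res, function(r) {
    purrr::map(purrr::compact(r$trends), function(f) {
      list(shape = f$shape, slope_per_year = f$slope_per_year,
           n_years = f$n_years)
    })
  }) %>% setNames(purrr::map_chr(res, "species")),
  file.path(outdir, "timing_trends.json"))
  res
}

stage_covariates <- function(config, outdir) {
  env <- list(
    climate = readr::read_csv(file.path(outdir, "climate_indices.csv"),
                              show_col_types = FALSE),
    wind = readr::read_csv(file.path(outdir, "wind.csv"),
                           show_col_types = FALSE),
    ocean = readr::read_csv(file.path(outdir, "ocean.csv"),
                            show_col_types = FALSE),
    sst_grid = if (file.exists(file.path(outdir, "sst_grid.csv"))) {
      readr::read_csv(file.path(outdir, "sst_grid.csv"),
                      show_col_types = FALSE)
    } else NULL)
  years <- sort(unique(env$climate$year))
  out <- purrr::map(c("calendar", "adjusted"), function(conv) {
    cov <- build_covariate_table(env, years, year_convention = conv)
    readr::write_csv(cov,
                     file.path(outdir, paste0("covariates_", conv, ".csv")))
    write_json_out(as.list(attr(cov, "availability")),
                   file.path(outdir,
                             paste0("covariate_availability_", conv, ".json")))
    cov
  }) %>% setNames(c("calendar", "adjusted"))
  out
}

species_convention <- function(species) {
  if (grepl("^gray", species)) "adjusted" else "calendar"
}

fit_species_timing_models <- function(config, outdir,
                                      metrics = c("arrival_day",
                                                  "departure_day")) {
  timing <- readr::read_csv(file.path(outdir, "timing.csv"),
                            show_col_types = FALSE)
  purrr::map(config$species, function(sp) {
    conv <- species_convention(sp)
    cov_path <- file.path(outdir, paste0("covariates_", conv, ".csv"))
    cov <- readr::read_csv(cov_path, show_col_types = FALSE)
    avail <- covariate_availability(setdiff(names(cov), "species_year"),
                                    conv)
    tt <- timing %>% filter(.data$species == sp, !.data$excluded)
    models <- purrr::map(setNames(metrics, metrics), function(m) {
      dat <- tt %>%
        select("species_year", dplyr::all_of(m)) %>%
        left_join(cov, by = "species_year")
      attr(dat, "availability") <- avail
      screened <- tryCatch(
        screen_covariates(dat, m, alpha = config$alpha),
        error = function(e) tibble(covariate = character(),
                                   order = integer(), p_top = numeric()))
      tryCatch(
        backward_eliminate(dat, m, screened, alpha = config$alpha,
                           vif_limit = config$vif_limit,
                           availability = avail),
        error = function(e) NULL)
    })
    list(species = sp, arrival = tt$arrival_day, models = models)
  }) %>% setNames(config$species)
}

stage_timing <- function(config, outdir) {
  res <- fit_species_timing_models(config, outdir)
  write_json_out(purrr::map(res, function(r) {
    purrr::map(r$models, function(m) {
      if (is.null(m)) return(NULL)
      list(not_significant = m$not_significant,
           adj_r_squared = m$adj.r.squared, r_squared = m$r.squared,
           aic = m$aic, overall_p = m$overall_p,
           terms = tidy(m) %>% filter(!is.na(.data$covariate)))
    })
  }), file.path(outdir, "timing_model.json"))
  marg <- purrr::map(res, function(r) {
    purrr::map(r$models, function(m) {
      if (is.null(m) || m$not_significant) return(NULL)
      bind_rows(purrr::map(unique(m$terms$covariate),
                           ~ margins(m, .x))) %>%
        mutate(metric = m$metric)
    }) %>% bind_rows()
  }) %>% purrr::imap(~ if (nrow(.x) > 0) mutate(.x, species = .y)) %>%
    bind_rows()
  readr::write_csv(marg, file.path(outdir, "margins.csv"))
  res
}

stage_forecast <- function(config, outdir) {
  res <- fit_species_timing_models(config, outdir)
  out <- purrr::map(res, function(r) {
    purrr::map(r$models, function(m) {
      if (is.null(m) || m$not_significant ||
          is.na(m$overall_p) || m$overall_p >= config$alpha) {
        return(NULL)
      }
      fc <- forecast_model(m, r$arrival, lead = config$forecast_lead)
      val <- year_removal_validate(m)
      list(r2_full = m$r.squared, adj_r2_full = m$adj.r.squared,
           p_full = m$overall_p,
           r2_forecast = fc$r2_forecast,
           p_forecast = if (!fc$no_forecast) fc$forecast$overall_p else NA,
           dropped = fc$dropped,
           ratio_forecast_full = fc$ratio,
           r2_validation = val$r2_validation,
           p_validation = val$p_value,
           ratio_validation_full = val$ratio)
    })
  })
  write_json_out(out, file.path(outdir, "forecast_validation.json"))
  out
}

stage_entangle <- function(config, outdir) {
  ent <- readr::read_csv(file.path(outdir, "entanglements.csv"),
                         show_col_types = FALSE)
  weekly <- readr::read_csv(file.path(outdir, "weekly_counts.csv"),
                            show_col_types = FALSE)
  timing <- readr::read_csv(file.path(outdir, "timing.csv"),
                            show_col_types = FALSE)
  out <- purrr::map(intersect(unique(ent$species), config$species),
                    function(sp) {
    monthly <- build_monthly_design(ent, weekly, timing, sp)
    models <- tryCatch(
      fit_entanglement_models(monthly, alpha = config$alpha,
                              vif_limit = config$vif_limit,
                              min_entanglements = config$min_entanglements),
      error = function(e) NULL)
    if (is.null(models)) return(list(species = sp, skipped = TRUE))
    attribution <- if (all(c("count", "arrival_day") %in%
                             models$combined$terms$covariate)) {
      variance_attribution(models$combined, "count_o1", "arrival_day_o1")
    } else NULL
    list(species = sp, skipped = FALSE, monthly = monthly,
         models = models, attribution = attribution)
  })
  keep <- purrr::keep(out, ~ !isTRUE(.x$skipped))
  write_json_out(purrr::map(keep, function(r) {
    list(species = r$species,
         trend_slope = unname(coef(r$models$trend)[2]),
         combined = list(
           not_significant = r$models$combined$not_significant,
           adj_r_squared = r$models$combined$adj.r.squared,
           overall_p = r$models$combined$overall_p,
           terms = tidy(r$models$combined) %>%
             filter(!is.na(.data$covariate))))
  }), file.path(outdir, "entanglement_model.json"))
  write_json_out(purrr::map(keep, function(r) {
    c(list(species = r$species), r$attribution)
  }), file.path(outdir, "attribution.json"))
  out
}
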