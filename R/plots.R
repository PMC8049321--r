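#' Plot predicted weekly count trends
#'
#' Average predicted weekly counts by year (averaged over months) with
#' the 95% confidence band, the analogue of an interannual trend panel.
#'
#' @param predictions Output of [predict_weekly()].
#' @return A ggplot object.
#' @export
plot_weekly_trend <- function(predictions) {
  annual <- predictions %>%
    group_by(.data$species_year) %>%
    summarise(predicted = mean(.data$predicted),
              conf.low = mean(.data$conf.low),
              conf.high = mean(.data$conf.high), .groups = "drop")
  ggplot2::ggplot(annual, ggplot2::aes(.data$species_year, .data$predicted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Year", y = "Predicted weekly count") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.nb_trend_fit <- function(object, ...) {
  yrs <- round(object$scaling$year["center"] +
                 object$scaling$year["scale"] *
                 range(object$fit$model$yr))
  preds <- suppressWarnings(predict_weekly(object, seq(yrs[1], yrs[2])))
  plot_weekly_trend(preds) +
    ggplot2::ggtitle(paste("Weekly count trend",
                           if (!is.null(object$shape)) object$shape else ""))
}

#' Plot a timing series with its fitted trend
#'
#' @param object A `timing_trend_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.timing_trend_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- stats::fitted(object$fit)
  ggplot2::ggplot(d, ggplot2::aes(.data$year, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "Year", y = paste(object$metric, "(day of species year)"),
                  title = paste("Timing trend:", object$shape)) +
    ggplot2::theme_minimal()
}

#' Margins panel for a timing model
#'
#' One partial-prediction curve per retained covariate, other
#' covariates held at their means.
#'
#' @param object A `timing_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.timing_model <- function(object, ...) {
  if (object$not_significant) {
    stop("model retained no terms; nothing to plot", call. = FALSE)
  }
  curves <- bind_rows(purrr::map(unique(object$terms$covariate),
                                 ~ margins(object, .x)))
  ggplot2::ggplot(curves, ggplot2::aes(.data$value, .data$predicted)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~covariate, scales = "free_x") +
    ggplot2::labs(x = "Covariate value",
                  y = paste("Predicted", object$metric)) +
    ggplot2::theme_minimal()
}

#' Observed vs out-of-sample predicted timing
#'
#' @param object A `year_removal` validation result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.year_removal <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Out-of-sample prediction", y = "Observed",
                  title = sprintf("Year-removal validation R² = %.3f",
                                  object$r2_validation)) +
    ggplot2::theme_minimal()
}
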