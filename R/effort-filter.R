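#' Fit a classification tree of observation effort on weather
#'
#' Learns the association between daily weather and whether a survey was
#' conducted, from the years in which effort metadata exist. The tree is
#' a standard binary recursive partition (Gini impurity, greedy splits)
#' with cost-complexity pruning by internal cross-validation; each leaf
#' carries the fraction of effort days that reached it, so predictions
#' are effort probabilities in [0, 1].
#'
#' @param labeled Tibble of weather variables plus an `effort` column
#'   (0/1 or logical).
#' @param vars Character vector of predictor columns; defaults to every
#'   numeric column except `effort`.
#' @param max_depth,min_leaf,xval Tree hyperparameters: maximum depth,
#'   minimum records per leaf, and the number of cross-validation folds
#'   used for cost-complexity pruning (0 disables pruning).
#' @param cp Complexity parameter passed to the tree grower.
#' @return An object of class `effort_cart`: the fitted tree, the
#'   training variable medians (used to impute missing predictors at
#'   prediction time), and later the classification cutoff.
#' @export
fit_effort_cart <- function(labeled, vars = NULL, max_depth = 5,
                            min_leaf = 5, xval = 10, cp = 0.01) {
  stopifnot("effort" %in% names(labeled))
  eff <- as.integer(labeled$effort)
  stopifnot(all(eff %in% c(0L, 1L)))
  if (is.null(vars)) {
    vars <- names(labeled)[vapply(labeled, is.numeric, logical(1))]
    vars <- setdiff(vars, "effort")
  }
  if (nrow(labeled) < 2) {
    stop("need at least 2 labeled days", call. = FALSE)
  }
  medians <- vapply(labeled[vars], median, numeric(1), na.rm = TRUE)
  dat <- labeled[vars]
  for (v in vars) dat[[v]][is.na(dat[[v]])] <- medians[[v]]
  dat$effort <- factor(eff, levels = c(0L, 1L))
  single_class <- length(unique(eff)) < 2
  if (single_class) {
    warning("single-class effort labels: degenerate single-leaf tree")
  }
  fit <- rpart::rpart(
    effort ~ ., data = dat, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(maxdepth = max_depth,
                                   minbucket = min_leaf,
                                   minsplit = 2 * min_leaf,
                                   cp = cp, xval = xval))
  if (xval > 0 && !single_class && nrow(fit$cptable) > 1) {
    cptab <- fit$cptable
    best <- which.min(cptab[, "xerror"])
    within_1se <- which(cptab[, "xerror"] <=
                          cptab[best, "xerror"] + cptab[best, "xstd"])[1]
    fit <- rpart::prune(fit, cp = cptab[within_1se, "CP"])
  }
  structure(list(tree = fit, vars = vars, medians = medians,
                 prevalence = mean(eff), cutoff = NULL),
            class = "effort_cart")
}

#' Predict daily effort probability from weather
#'
#' Routes each day down the fitted tree and returns the leaf's effort
#' fraction. Missing predictor values are imputed with the training
#' medians stored in the classifier; if a needed predictor column is
#' absent entirely, an error names it.
#'
#' @param object An `effort_cart` from [fit_effort_cart()].
#' @param weather Tibble of daily weather.
#' @return Numeric vector of effort probabilities in [0, 1].
#' @export
predict_effort <- function(object, weather) {
  stopifnot(inherits(object, "effort_cart"))
  missing_vars <- setdiff(object$vars, names(weather))
  if (length(missing_vars) > 0) {
    stop("missing predictor column(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  dat <- weather[object$vars]
  for (v in object$vars) dat[[v]][is.na(dat[[v]])] <- object$medians[[v]]
  pr <- predict(object$tree, newdata = dat, type = "prob")
  if ("1" %in% colnames(pr)) as.numeric(pr[, "1"]) else rep(0, nrow(dat))
}

#' Optimal probability cutoff for effort classification
#'
#' Scans candidate thresholds (the midpoints between sorted unique
#' predicted probabilities, plus the two extremes) and returns the one
#' maximising overall classification accuracy against known labels. A
#' day is classed as effort when its probability is `>=` the cutoff.
#' Ties are broken toward the lower threshold, i.e. toward classifying
#' days as effort. `criterion = "youden"` maximises sensitivity +
#' specificity - 1 instead.
#'
#' @param probabilities Predicted effort probabilities.
#' @param labels True effort labels (0/1 or logical).
#' @param criterion `"accuracy"` (default) or `"youden"`.
#' @return The chosen threshold, with the achieved value of the
#'   criterion in attribute `"objective"`.
#' @export
optimal_cutoff <- function(probabilities, labels,
                           criterion = c("accuracy", "youden")) {
  criterion <- match.arg(criterion)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("both effort classes must be present to choose a cutoff",
         call. = FALSE)
  }
  u <- sort(unique(probabilities))
  cand <- c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            max(u) + 1e-9)
  score <- vapply(cand, function(t) {
    pred <- as.integer(probabilities >= t)
    if (criterion == "accuracy") {
      mean(pred == labels)
    } else {
      sens <- mean(pred[labels == 1] == 1)
      spec <- mean(pred[labels == 0] == 0)
      sens + spec - 1
    }
  }, numeric(1))
  best <- cand[which(score == max(score))[1]]   # ties -> lowest threshold
  structure(best, objective = max(score))
}

#' Remove likely false-zero days from a daily sighting table
#'
#' A day is a false zero when nothing was recorded because no survey
#' took place, not because whales were absent. The rule: a day is
#' dropped if and only if its recorded count is zero or missing AND its
#' predicted effort class is 0. Every positive-count day is retained
#' regardless of the prediction (a sighting implies a survey), and a
#' retained zero-or-missing day is treated as a true zero with one
#' effort-day of survey time.
#'
#' @param daily Tibble with a `count_obs` column (NA = no record) and a
#'   `date` column.
#' @param effort_class Integer/logical vector (one per row of `daily`):
#'   predicted effort class. For days where effort metadata exist this
#'   should be the recorded label, not a prediction.
#' @return The filtered tibble with `count_obs` coalesced to 0 on
#'   retained no-record days and a logical `dropped_false_zero`
#'   attribute-free audit column removed; rows failing the rule are
#'   removed.
#' @export
remove_false_zeros <- function(daily, effort_class) {
  stopifnot(nrow(daily) == length(effort_class))
  effort_class <- as.integer(effort_class)
  if (anyNA(effort_class)) {
    stop("every day needs a predicted effort class", call. = FALSE)
  }
  keep <- !(dplyr::coalesce(daily$count_obs, 0) == 0 & effort_class == 0L)
  daily %>%
    filter(keep) %>%
    mutate(count_obs = dplyr::coalesce(.data$count_obs, 0))
}

#' Rule-based effort labels from survey weather criteria
#'
#' The operational definition of an observation day: visibility above
#' 11.2 km, wind at or below Beaufort 4 (~16 knots), and swell below
#' 3 m. Useful as a sanity check against the learned classifier.
#'
#' @param weather Tibble with `visibility_km`, `wind_speed` (knots) and
#'   `swell_height` (feet).
#' @return Integer 0/1 vector.
#' @export
effort_rule <- function(weather) {
  swell_m <- weather$swell_height * 0.3048
  as.integer(weather$visibility_km > 11.2 &
               weather$wind_speed <= 16 &
               swell_m < 3)
}

#' Summary report for the effort reconstruction
#'
#' @param object An `effort_cart` with predictions evaluated.
#' @param probabilities,labels Predicted probabilities and true labels
#'   on labelled days.
#' @param cutoff Threshold from [optimal_cutoff()].
#' @return A list: confusion matrix, accuracy, cutoff, tree variable
#'   importance.
#' @export
effort_report <- function(object, probabilities, labels, cutoff) {
  pred <- as.integer(probabilities >= cutoff)
  labels <- as.integer(labels)
  cm <- table(predicted = factor(pred, levels = 0:1),
              actual = factor(labels, levels = 0:1))
  list(confusion = cm,
       accuracy = mean(pred == labels),
       cutoff = as.numeric(cutoff),
       variable_importance = object$tree$variable.importance)
}
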