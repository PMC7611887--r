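# Weather-corrected counterfactual modelling: predict daily pollutant
# concentrations from calendar and meteorological features, trained on
# pre-2020 history, then predict 2020 "as if no restrictions" and quantify the
# anomaly (observed vs predicted annual mean) with a moving-block bootstrap
# confidence interval.
#
# Feature encoding of the calendar: year_index carries the long-term trend,
# a 7-level day-of-week factor the weekly cycle, and a day-of-year sin/cos
# pair the seasonal cycle. Meteorological drivers enter both same-day and
# lagged by `lag_days` calendar days, allowing delayed responses of
# concentrations to weather.

DOW_LEVELS <- paste0("dow", 1:7) # Monday..Sunday, locale-independent

#' Default gradient-boosting hyperparameters
#'
#' 500 shallow trees (depth 3), learning rate 0.05, 80% row subsampling:
#' a conservative boosting configuration for smooth daily environmental
#' series. Override any element via the `params` argument of
#' [fit_counterfactual()].
#'
#' @return Named list of hyperparameters.
#' @export
gbr_params <- function() {
  list(nrounds = 500, max_depth = 3, eta = 0.05, subsample = 0.8)
}

#' Build the counterfactual feature table
#'
#' One row per date with complete features. Weather variables absent from the
#' weather table city-wide (e.g. a city where only temperature is recorded)
#' are omitted from the feature set entirely, together with their lags.
#'
#' @param pollutant Optional tibble with `date` and `value` (the training
#'   target); rows with missing value are excluded and counted.
#' @param weather Weather tibble (one city) as from [read_weather_csv()]; must
#'   cover the requested dates minus the lag.
#' @param lag_days Non-negative lag (calendar days) for the lagged copies of
#'   the meteorological variables.
#' @param dates Dates to build rows for; defaults to the pollutant dates.
#' @return Tibble with `date`, feature columns and (if `pollutant` given)
#'   `value`. Attribute `"n_excluded"` counts rows dropped for missing
#'   features or target.
#' @export
build_features <- function(pollutant = NULL, weather, lag_days = 3, dates = NULL) {
  if (lag_days < 0) stop_validation("lag_days must be non-negative")
  if (is.null(dates)) {
    if (is.null(pollutant)) stop_validation("either `pollutant` or `dates` must be given")
    dates <- pollutant$date
  }
  met_vars <- intersect(WEATHER_VARS, names(weather))
  wx <- weather[, c("date", met_vars)]
  if (anyDuplicated(wx$date)) {
    stop_validation("weather table must have one row per date (a single city)")
  }
  feat <- tibble::tibble(date = sort(unique(dates)))
  feat$year_index <- lubridate::year(feat$date) - 2015
  feat$day_of_week <- factor(
    paste0("dow", lubridate::wday(feat$date, week_start = 1)),
    levels = DOW_LEVELS
  )
  ang <- 2 * pi * lubridate::yday(feat$date) / 365.25
  feat$day_of_year_sin <- sin(ang)
  feat$day_of_year_cos <- cos(ang)
  i_now <- match(feat$date, wx$date)
  i_lag <- match(feat$date - lag_days, wx$date)
  for (v in met_vars) {
    feat[[v]] <- wx[[v]][i_now]
    feat[[paste0(v, "_lag", lag_days)]] <- wx[[v]][i_lag]
  }
  if (!is.null(pollutant)) {
    feat$value <- pollutant$value[match(feat$date, pollutant$date)]
  }
  complete <- stats::complete.cases(feat[, setdiff(names(feat), "date")])
  out <- feat[complete, ]
  attr(out, "n_excluded") <- sum(!complete)
  attr(out, "lag_days") <- lag_days
  out
}

feature_cols <- function(features) setdiff(names(features), c("date", "value"))

# Dummy-encode the feature frame; tree and linear models share the encoding.
feature_matrix <- function(features) {
  df <- as.data.frame(features[, feature_cols(features)])
  mm <- stats::model.matrix(~., df)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

# map a dummy column name back to its source feature
matrix_col_feature <- function(cols) {
  out <- cols
  out[grepl("^day_of_weekdow", cols)] <- "day_of_week"
  out
}

#' Fit a counterfactual concentration model
#'
#' Trains either an ordinary least-squares linear model or a gradient-boosted
#' ensemble of shallow regression trees (squared-error loss) on historical
#' feature rows. The validation mean absolute error (MAE) is computed on a
#' held-out random 20% of training days under the given seed; the returned
#' model is then refit on all rows.
#'
#' @param features Feature table from [build_features()] (training years).
#' @param targets Numeric target concentrations (ug/m3); defaults to the
#'   `value` column of `features`.
#' @param model_kind `"linear"` or `"gbr"`.
#' @param seed Integer seed controlling the validation split and the boosting
#'   row subsampling. Identical seed and inputs give identical fits.
#' @param holdout_frac Fraction of rows held out for the MAE.
#' @param params Gradient-boosting hyperparameters, see [gbr_params()].
#' @param min_rows Minimum number of training rows.
#' @return An object of class `counterfactual_fit`.
#' @export
fit_counterfactual <- function(features, targets = features$value,
                               model_kind = c("linear", "gbr"), seed = 1L,
                               holdout_frac = 0.2, params = gbr_params(),
                               min_rows = 365) {
  model_kind <- rlang::arg_match(model_kind)
  if (is.null(targets)) stop_validation("no targets supplied")
  X <- feature_matrix(features)
  y <- as.numeric(targets)
  if (length(y) != nrow(X)) stop_validation("targets length must match feature rows")
  if (nrow(X) < min_rows) {
    stop_validation(sprintf("too few training rows: %d < %d", nrow(X), min_rows))
  }
  params <- utils::modifyList(gbr_params(), params)

  fit_one <- function(Xa, ya) {
    if (model_kind == "linear") fit_linear(Xa, ya) else fit_gbr(Xa, ya, params, seed)
  }
  hold <- withr::with_seed(seed, sample.int(nrow(X), floor(holdout_frac * nrow(X))))
  mae <- if (length(hold) > 0) {
    part <- fit_one(X[-hold, , drop = FALSE], y[-hold])
    mean(abs(y[hold] - predict_matrix(part, model_kind, X[hold, , drop = FALSE])))
  } else {
    NA_real_
  }
  full <- fit_one(X, y)
  structure(
    list(
      model_kind = model_kind, model = full,
      feature_names = feature_cols(features), matrix_cols = colnames(X),
      mae = mae, n_train = nrow(X), params = params, seed = seed,
      lag_days = attr(features, "lag_days")
    ),
    class = "counterfactual_fit"
  )
}

fit_linear <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    warn("rank-deficient design; using pseudo-inverse solution")
    beta <- MASS::ginv(Xi) %*% y
  } else {
    beta <- qr.coef(qx, y)
  }
  setNames(as.numeric(beta), colnames(Xi))
}

fit_gbr <- function(X, y, params, seed) {
  dm <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = list(
      max_depth = params$max_depth, eta = params$eta,
      subsample = params$subsample, objective = "reg:squarederror",
      nthread = 1, seed = as.integer(seed)
    ),
    data = dm, nrounds = params$nrounds, verbose = 0
  )
}

predict_matrix <- function(model, model_kind, X) {
  if (model_kind == "linear") {
    as.numeric(cbind(1, X) %*% model)
  } else {
    stats::predict(model, xgboost::xgb.DMatrix(X))
  }
}

#' @export
print.counterfactual_fit <- function(x, ...) {
  cat(sprintf("<counterfactual_fit> %s, %d training rows, validation MAE %.3g ug/m3\n",
              x$model_kind, x$n_train, x$mae))
  invisible(x)
}

#' Predict counterfactual daily concentrations
#'
#' @param fit A [fit_counterfactual()] object.
#' @param features Feature table for the prediction period; columns must match
#'   the training feature set exactly.
#' @return Tibble with `date` and `value` (predictions floored at 0, since
#'   concentrations are non-negative).
#' @export
predict_counterfactual <- function(fit, features) {
  have <- feature_cols(features)
  missing <- setdiff(fit$feature_names, have)
  extra <- setdiff(have, fit$feature_names)
  if (length(missing) > 0 || length(extra) > 0) {
    stop_validation(sprintf(
      "feature columns do not match fit: missing [%s], unexpected [%s]",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")
    ))
  }
  X <- feature_matrix(features[, c("date", fit$feature_names)])
  if (!identical(colnames(X), fit$matrix_cols)) {
    stop_validation("encoded feature matrix columns do not match fit")
  }
  tibble::tibble(
    date = features$date,
    value = pmax(0, predict_matrix(fit$model, fit$model_kind, X))
  )
}

#' Annual anomaly of observed vs counterfactual concentrations
#'
#' Relative change of the observed mean against the predicted
#' (counterfactual) mean, with a 95% confidence interval from a moving-block
#' bootstrap of the daily observed-predicted pairs. Contiguous 7-day blocks
#' preserve the weekly autocorrelation of the residuals; the percentile method
#' is applied to the bootstrap distribution of the relative change.
#'
#' @param observed,predicted Tibbles with `date` and `value` covering the
#'   anomaly year; at least `min_coverage` of the spanned days must have both.
#' @param n_boot Number of bootstrap replicates.
#' @param block_days Block length in days.
#' @param seed Integer seed; identical seed and inputs give identical results.
#' @param min_coverage Required fraction of spanned days with both values.
#' @return Object of class `anomaly_result`: a list with `observed_mean`,
#'   `predicted_mean`, `relative_change` (%), `ci95` (low, high, %), `n_days`.
#' @export
compute_anomaly <- function(observed, predicted, n_boot = 1000, block_days = 7,
                            seed = 1L, min_coverage = 0.75) {
  joined <- dplyr::inner_join(
    dplyr::rename(observed[!is.na(observed$value), c("date", "value")], obs = "value"),
    dplyr::rename(predicted[!is.na(predicted$value), c("date", "value")], pred = "value"),
    by = "date"
  )
  joined <- dplyr::arrange(joined, .data$date)
  span <- length(date_span(predicted$date))
  cov <- nrow(joined) / span
  if (cov < min_coverage) {
    stop_coverage(sprintf("anomaly coverage %.0f%% below required %.0f%%",
                          100 * cov, 100 * min_coverage))
  }
  rc <- relative_change(mean(joined$obs), mean(joined$pred))
  n <- nrow(joined)
  L <- min(block_days, n)
  n_blocks <- ceiling(n / L)
  boot <- withr::with_seed(seed, {
    starts <- matrix(sample.int(n - L + 1, n_boot * n_blocks, replace = TRUE),
                     nrow = n_boot)
    apply(starts, 1, function(s) {
      idx <- as.vector(outer(0:(L - 1), s, `+`))[seq_len(n)]
      relative_change(mean(joined$obs[idx]), mean(joined$pred[idx]))
    })
  })
  ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  structure(
    list(
      observed_mean = mean(joined$obs), predicted_mean = mean(joined$pred),
      relative_change = rc, ci95 = ci, n_days = n,
      n_boot = n_boot, block_days = block_days, seed = seed
    ),
    class = "anomaly_result"
  )
}

#' @export
print.anomaly_result <- function(x, ...) {
  cat(sprintf(
    "<anomaly_result> observed %.2f vs predicted %.2f ug/m3: %+.1f%% (95%% CI %+.1f%% to %+.1f%%, %d days)\n",
    x$observed_mean, x$predicted_mean, x$relative_change, x$ci95[1], x$ci95[2], x$n_days
  ))
  invisible(x)
}

#' Impurity-based feature importances of a boosted fit
#'
#' Total gain attributed to each feature (day-of-week dummies pooled back to
#' one feature), normalised to sum to 1 and sorted descending. Only defined
#' for gradient-boosted fits.
#'
#' @param fit A [fit_counterfactual()] object with `model_kind = "gbr"`.
#' @return Tibble with columns `feature` and `weight`.
#' @export
feature_importance <- function(fit) {
  if (fit$model_kind != "gbr") {
    stop_unsupported("feature importances are only available for gbr fits")
  }
  imp <- xgboost::xgb.importance(model = fit$model)
  src <- matrix_col_feature(imp$Feature)
  agg <- tapply(imp$Gain, src, sum)
  all_feats <- unique(matrix_col_feature(fit$matrix_cols))
  w <- setNames(rep(0, length(all_feats)), all_feats)
  w[names(agg)] <- agg
  w <- w / sum(w)
  out <- tibble::tibble(feature = names(w), weight = unname(w))
  dplyr::arrange(out, dplyr::desc(.data$weight))
}
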