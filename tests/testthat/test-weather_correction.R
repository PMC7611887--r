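flat_weather <- function(n, start = "2016-01-01") {
  dates <- seq(as.Date(start) - 7, by = "day", length.out = n + 7)
  withr::with_seed(9, tibble::tibble(
    city = "X", date = dates,
    temperature = 10 + 8 * sin(2 * pi * seq_along(dates) / 365) + rnorm(length(dates)),
    precipitation = pmax(0, rnorm(length(dates), 1, 1)),
    wind_speed = pmax(0.1, rnorm(length(dates), 4, 1.5))
  ))
}

test_that("feature rows are complete, lagged correctly and drop absent variables", {
  wx <- flat_weather(30)
  dates <- seq(as.Date("2016-01-01"), by = "day", length.out = 10)
  # weather starts 7 days before, so lag-3 is available for all 10 days
  f <- build_features(weather = wx, dates = dates, lag_days = 3)
  expect_equal(nrow(f), 10)
  expect_equal(f$temperature_lag3,
               wx$temperature[match(f$date - 3, wx$date)])

  # boundary loss: weather starting at the first date loses `lag` rows
  wx2 <- wx[wx$date >= dates[1], ]
  f2 <- build_features(weather = wx2, dates = dates, lag_days = 3)
  expect_equal(nrow(f2), 7)
  expect_equal(attr(f2, "n_excluded"), 3)

  # lag 0: lagged columns equal unlagged
  f0 <- build_features(weather = wx, dates = dates, lag_days = 0)
  expect_equal(f0$temperature_lag0, f0$temperature)

  # temperature-only city: no precip/wind columns at all
  f3 <- build_features(weather = wx[, c("city", "date", "temperature")],
                       dates = dates)
  expect_false(any(grepl("precipitation|wind", names(f3))))
  expect_true(all(c("temperature", "temperature_lag3") %in% names(f3)))

  expect_error(build_features(weather = wx, dates = dates, lag_days = -1),
               "non-negative")
})

test_that("linear fit interpolates exactly linear targets and GBR fits constants", {
  wx <- flat_weather(800)
  dates <- seq(as.Date("2016-01-01"), by = "day", length.out = 800)
  f <- build_features(weather = wx, dates = dates)
  # pure linear function of features, zero noise
  y <- 30 + 2 * f$temperature - 1.5 * f$wind_speed + 0.5 * f$temperature_lag3 +
    0.2 * f$year_index
  fit <- fit_counterfactual(f, y, model_kind = "linear", seed = 1)
  expect_lt(fit$mae, 1e-8)

  # constant target: both models predict ~ the constant
  fitc_l <- fit_counterfactual(f, rep(12, nrow(f)), "linear", seed = 1)
  fitc_g <- fit_counterfactual(f, rep(12, nrow(f)), "gbr", seed = 1,
                               params = list(nrounds = 150))
  pl <- predict_counterfactual(fitc_l, f)
  pg <- predict_counterfactual(fitc_g, f)
  expect_equal(pl$value, rep(12, nrow(f)), tolerance = 1e-6)
  expect_equal(pg$value, rep(12, nrow(f)), tolerance = 1e-2)
})

test_that("validation MAE matches the closed form for pure Gaussian noise", {
  wx <- flat_weather(1500)
  dates <- seq(as.Date("2016-01-01"), by = "day", length.out = 1500)
  f <- build_features(weather = wx, dates = dates)
  # target = constant + N(0, 4): best possible MAE is sigma * sqrt(2/pi) ~ 3.19
  y <- withr::with_seed(4, 30 + rnorm(nrow(f), 0, 4))
  fit <- fit_counterfactual(f, y, model_kind = "linear", seed = 2)
  expect_equal(fit$mae, 4 * sqrt(2 / pi), tolerance = 0.2)
})

test_that("fits are deterministic under a fixed seed and error on too few rows", {
  wx <- flat_weather(600)
  dates <- seq(as.Date("2016-01-01"), by = "day", length.out = 600)
  f <- build_features(weather = wx, dates = dates)
  y <- withr::with_seed(5, 20 + f$temperature + rnorm(nrow(f)))
  fit1 <- fit_counterfactual(f, y, "gbr", seed = 42, params = list(nrounds = 120))
  fit2 <- fit_counterfactual(f, y, "gbr", seed = 42, params = list(nrounds = 120))
  expect_identical(fit1$mae, fit2$mae)
  expect_identical(predict_counterfactual(fit1, f)$value,
                   predict_counterfactual(fit2, f)$value)

  expect_error(fit_counterfactual(f[1:100, ], y[1:100], "linear", seed = 1),
               "too few", class = "airshift_validation_error")
})

test_that("prediction validates feature columns and floors at zero", {
  wx <- flat_weather(600)
  dates <- seq(as.Date("2016-01-01"), by = "day", length.out = 600)
  f <- build_features(weather = wx, dates = dates)
  y <- 5 - 0.5 * f$wind_speed # can go negative at high wind
  fit <- fit_counterfactual(f, y, "linear", seed = 1)
  f_bad <- f[, setdiff(names(f), "wind_speed_lag3")]
  expect_error(predict_counterfactual(fit, f_bad), "wind_speed_lag3",
               class = "airshift_validation_error")
  wx_high <- dplyr::mutate(wx, wind_speed = 20)
  f_high <- build_features(weather = wx_high, dates = dates)
  p <- predict_counterfactual(fit, f_high)
  expect_true(all(p$value >= 0))
})

test_that("anomaly arithmetic, bootstrap CI and degenerate scaling behave", {
  obs <- daily_series("2020-01-01", rep(20, 366))
  pred <- daily_series("2020-01-01", rep(20, 366))
  a0 <- compute_anomaly(obs, pred, seed = 1)
  expect_equal(a0$relative_change, 0)
  expect_true(a0$ci95[1] <= 0 && a0$ci95[2] >= 0)

  # observed = 0.8 x predicted everywhere: -20% with zero-width CI
  pred2 <- daily_series("2020-01-01", 20 + sin(1:366 / 10))
  obs2 <- dplyr::mutate(pred2, value = 0.8 * value)
  a2 <- compute_anomaly(obs2, pred2, seed = 1)
  expect_equal(a2$relative_change, -20)
  expect_equal(unname(a2$ci95), c(-20, -20), tolerance = 1e-12)

  # worked cell: observed mean 25.3 vs predicted 31.9 -> -21% rounded
  a3 <- compute_anomaly(daily_series("2020-01-01", rep(25.3, 366)),
                        daily_series("2020-01-01", rep(31.9, 366)), seed = 1)
  expect_equal(round_percent(a3$relative_change), -21)

  # determinism: identical seed + inputs -> bit-identical result
  obs4 <- daily_series("2020-01-01", withr::with_seed(8, rnorm(366, 25, 3)))
  pred4 <- daily_series("2020-01-01", withr::with_seed(9, rnorm(366, 28, 3)))
  expect_identical(compute_anomaly(obs4, pred4, seed = 3),
                   compute_anomaly(obs4, pred4, seed = 3))

  # CI bounds bracket the point estimate
  a4 <- compute_anomaly(obs4, pred4, seed = 3)
  expect_true(a4$ci95[1] <= a4$relative_change &&
                a4$relative_change <= a4$ci95[2])

  expect_error(compute_anomaly(obs[1:100, ], pred, seed = 1), "coverage",
               class = "airshift_coverage_error")
})

test_that("feature importances identify the driving variable and sum to one", {
  wx <- flat_weather(1200)
  dates <- seq(as.Date("2016-01-01"), by = "day", length.out = 1200)
  f <- build_features(weather = wx, dates = dates)
  # target depends only on temperature
  y <- withr::with_seed(6, 3 * f$temperature + rnorm(nrow(f), 0, 0.3))
  fit <- fit_counterfactual(f, y, "gbr", seed = 1, params = list(nrounds = 200))
  imp <- feature_importance(fit)
  expect_equal(sum(imp$weight), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "temperature")
  expect_gt(imp$weight[1], 0.9)

  # all-noise target: no feature dominates
  y2 <- withr::with_seed(7, rnorm(nrow(f)))
  fit2 <- fit_counterfactual(f, y2, "gbr", seed = 1, params = list(nrounds = 200))
  expect_lt(max(feature_importance(fit2)$weight), 0.5)

  fitl <- fit_counterfactual(f, y, "linear", seed = 1)
  expect_error(feature_importance(fitl), "gbr",
               class = "airshift_unsupported_error")
})

test_that("GBR beats the linear model when the temperature response has a threshold", {
  sc <- test_scenario(seed = 31)
  sc$pollutants$NO2$cold_coef <- 2.5 # pronounced nonlinearity
  dat <- gen_city_data(sc)
  res_g <- anomaly_pipeline(dat$stations, dat$weather, "NO2",
                            station_scope = "urban_background",
                            model_kind = "gbr", seed = 31)
  res_l <- anomaly_pipeline(dat$stations, dat$weather, "NO2",
                            station_scope = "urban_background",
                            model_kind = "linear", seed = 31)
  expect_lte(res_g$fit$mae, res_l$fit$mae)
})
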