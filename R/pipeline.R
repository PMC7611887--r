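# Orchestration: validate a run configuration, then execute the full
# analysis -- normalise mobility, aggregate stations, fit counterfactuals,
# compute anomalies, correlate, assess health impact -- writing a result
# bundle (anomalies.csv, correlations.csv, af_table.csv, metadata.yaml).

#' Build and validate a run configuration
#'
#' Fills defaults and validates the configuration before any stage runs
#' (missing inputs, unknown model kinds or scopes, and beta coverage for the
#' requested pollutants are all rejected up front).
#'
#' @param paths Named list with `mobility`, `stations`, `weather` input CSVs
#'   and `outdir`.
#' @param baseline Character vector `c(start, end)` of the pre-Covid window.
#' @param train_years Years used to train the counterfactual models.
#' @param anomaly_year Year whose anomaly is assessed.
#' @param health_years Years of the attributable-fraction table.
#' @param station_scope Scope for the anomaly series (`"all"` or
#'   `"urban_background"`); the health stage always uses urban background.
#' @param model_kind `"gbr"` or `"linear"`.
#' @param gbr Gradient-boosting hyperparameters (see [gbr_params()]).
#' @param betas_path Optional path to a beta YAML (default: shipped table).
#' @param pollutants Pollutants to analyse.
#' @param modes Transport modes to correlate against.
#' @param seed Integer seed for all stochastic steps.
#' @return Validated configuration list of class `run_config`.
#' @export
run_config <- function(paths,
                       baseline = c("2020-01-13", "2020-03-14"),
                       train_years = 2015:2019,
                       anomaly_year = 2020,
                       health_years = 2010:2020,
                       station_scope = c("all", "urban_background"),
                       model_kind = c("gbr", "linear"),
                       gbr = gbr_params(),
                       betas_path = NULL,
                       pollutants = c("NO2", "PM2.5"),
                       modes = c("driving", "transit"),
                       seed = 1L) {
  station_scope <- rlang::arg_match(station_scope)
  model_kind <- rlang::arg_match(model_kind)
  for (f in c("mobility", "stations", "weather", "outdir")) {
    if (is.null(paths[[f]])) {
      stop_validation(sprintf("config error: paths$%s is required", f))
    }
  }
  for (f in c("mobility", "stations", "weather")) {
    if (!file.exists(paths[[f]])) {
      stop_validation(sprintf("config error: input file '%s' not found", paths[[f]]))
    }
  }
  bad_pol <- setdiff(pollutants, POLLUTANTS)
  if (length(bad_pol) > 0) {
    stop_validation(sprintf("config error: unknown pollutant '%s'", bad_pol[1]))
  }
  betas <- default_betas(betas_path)
  missing_beta <- setdiff(pollutants, betas$pollutant)
  if (length(missing_beta) > 0) {
    stop_validation(sprintf(
      "config error: no beta coefficient for pollutant '%s'", missing_beta[1]
    ))
  }
  structure(list(
    paths = paths, baseline = baseline, train_years = train_years,
    anomaly_year = anomaly_year, health_years = health_years,
    station_scope = station_scope, model_kind = model_kind, gbr = gbr,
    betas = betas, pollutants = pollutants, modes = modes,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return Validated configuration (see [run_config()]).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  if (!is.null(args$train_years)) args$train_years <- as.integer(args$train_years)
  if (!is.null(args$health_years)) args$health_years <- as.integer(args$health_years)
  do.call(run_config, args)
}

run_stage <- function(name, verbose, expr) {
  if (verbose) inform(sprintf("[airshift] stage: %s", name))
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = c("airshift_stage_error", "airshift_error"), parent = e)
  })
}

#' Weather-corrected anomaly for one city and pollutant
#'
#' Convenience wrapper over the modelling steps for a single city x
#' pollutant: aggregate stations to a city series, build features, train the
#' counterfactual on the training years, predict the anomaly year and compute
#' the annual anomaly plus the weekly anomaly series.
#'
#' @param stations Station table (one city).
#' @param weather Weather tibble (same city).
#' @param pollutant Pollutant to model.
#' @param station_scope Scope for the city series.
#' @param model_kind `"gbr"` or `"linear"`.
#' @param train_years Training years.
#' @param anomaly_year Year whose anomaly is computed.
#' @param seed Seed for split, boosting and bootstrap.
#' @param params Gradient-boosting hyperparameters.
#' @return List with `fit`, `observed`, `predicted`, `anomaly` (an
#'   `anomaly_result`) and `weekly` (weekly anomaly series).
#' @export
anomaly_pipeline <- function(stations, weather, pollutant,
                             station_scope = c("all", "urban_background"),
                             model_kind = c("gbr", "linear"),
                             train_years = 2015:2019, anomaly_year = 2020,
                             seed = 1L, params = gbr_params()) {
  station_scope <- rlang::arg_match(station_scope)
  model_kind <- rlang::arg_match(model_kind)
  series <- city_daily_mean(stations, station_scope)
  s <- series[series$pollutant == pollutant, ]
  if (nrow(s) == 0) stop_validation(sprintf("no data for pollutant '%s'", pollutant))
  hist <- s[lubridate::year(s$date) %in% train_years, ]
  train <- build_features(tibble::tibble(date = hist$date, value = hist$value), weather)
  fit <- fit_counterfactual(train, model_kind = model_kind, seed = seed,
                            params = params)
  target_days <- seq(lubridate::ymd(sprintf("%d-01-01", anomaly_year)),
                     lubridate::ymd(sprintf("%d-12-31", anomaly_year)), by = "day")
  pred <- predict_counterfactual(fit, build_features(weather = weather,
                                                     dates = target_days))
  obs <- s[lubridate::year(s$date) == anomaly_year, c("date", "value")]
  anom <- compute_anomaly(obs, pred, seed = seed)
  list(fit = fit, observed = obs, predicted = pred, anomaly = anom,
       weekly = weekly_anomaly(obs, pred))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order and writes the result bundle into
#' `config$paths$outdir`: `anomalies.csv` (annual observed vs counterfactual
#' means with bootstrap CIs), `correlations.csv` (weekly Spearman
#' correlations), `af_table.csv` (attributable fractions per year) and
#' `metadata.yaml` (config hash, seed, spans). Identical configuration and
#' seed give byte-identical result CSVs.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress?
#' @return Invisibly, a list with the three result tables and output paths.
#' @export
full_run <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$paths$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  mobility <- run_stage("read mobility", verbose,
                        read_mobility_csv(config$paths$mobility))
  stations <- run_stage("read stations", verbose,
                        read_station_csv(config$paths$stations))
  weather <- run_stage("read weather", verbose,
                       read_weather_csv(config$paths$weather))

  window <- baseline_window(config$baseline[1], config$baseline[2])
  panel <- run_stage("normalize mobility", verbose, mobility_panel(mobility, window))

  series <- run_stage("aggregate stations", verbose,
                      city_daily_mean(stations, config$station_scope))
  cities <- unique(series$city)

  anomalies <- list()
  correlations <- list()
  for (city in cities) {
    wx <- weather[weather$city == city, ]
    for (pol in intersect(config$pollutants, unique(series$pollutant))) {
      label <- sprintf("counterfactual %s %s", city, pol)
      res <- run_stage(label, verbose, anomaly_pipeline(
        stations[stations$city == city, ], wx, pol,
        station_scope = config$station_scope, model_kind = config$model_kind,
        train_years = config$train_years, anomaly_year = config$anomaly_year,
        seed = config$seed, params = config$gbr
      ))
      anomalies[[label]] <- tibble::tibble(
        city = city, pollutant = pol, model_kind = config$model_kind,
        observed_mean = res$anomaly$observed_mean,
        predicted_mean = res$anomaly$predicted_mean,
        relative_change = res$anomaly$relative_change,
        ci_low = res$anomaly$ci95[1], ci_high = res$anomaly$ci95[2],
        mae = res$fit$mae, n_days = res$anomaly$n_days
      )
      wk <- res$weekly
      kind <- if (config$model_kind == "gbr") "gbr_anomaly" else "lr_anomaly"
      for (mode in config$modes) {
        correlations[[paste(label, mode)]] <- run_stage(
          sprintf("correlate %s %s %s", city, pol, mode), verbose,
          dplyr::mutate(
            correlate_city(panel[panel$city == city, ], wk, mode, kind),
            pollutant = pol, .after = "city"
          )
        )
      }
    }
  }

  af <- run_stage("health impact", verbose, {
    means <- annual_urban_background_means(stations, config$health_years)
    af_table(means[means$pollutant %in% config$pollutants, ], config$betas)
  })

  anomalies <- purrr::list_rbind(unname(anomalies))
  correlations <- purrr::list_rbind(unname(correlations))
  meta <- list(config = unclass(config)[setdiff(names(config), "betas")],
               seed = config$seed)
  run_stage("write outputs", verbose, {
    write_result_csv(anomalies, file.path(outdir, "anomalies.csv"), meta)
    write_result_csv(correlations, file.path(outdir, "correlations.csv"), meta)
    write_result_csv(af, file.path(outdir, "af_table.csv"), meta)
    yaml::write_yaml(list(
      config_hash = rlang::hash(meta), seed = config$seed,
      cities = as.list(cities), pollutants = as.list(config$pollutants),
      anomaly_year = config$anomaly_year
    ), file.path(outdir, "metadata.yaml"))
  })
  invisible(list(anomalies = anomalies, correlations = correlations, af = af,
                 outdir = outdir))
}
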