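# City-level aggregation of station concentrations and baseline-relative
# change arithmetic: unweighted station means, period means with coverage
# rules, multi-year (day-of-year and period) baselines, weekly aggregation and
# the relative-change statistic used throughout the reported tables.

#' Aggregate station series to a city daily-mean series
#'
#' Per-date unweighted mean across all stations reporting that date. With
#' `scope = "urban_background"` only urban background stations (the class most
#' representative of population exposure) are used, as required by the health
#' impact assessment.
#'
#' @param stations Tibble as returned by [read_station_csv()].
#' @param scope `"all"` or `"urban_background"`.
#' @return Tibble with columns `city`, `pollutant`, `station_scope`, `date`,
#'   `value` (ug/m3).
#' @export
city_daily_mean <- function(stations, scope = c("all", "urban_background")) {
  scope <- rlang::arg_match(scope)
  sel <- if (scope == "urban_background") {
    stations[stations$category == "urban background", ]
  } else {
    stations
  }
  if (nrow(sel) == 0) {
    stop_validation(sprintf("no stations in scope '%s'", scope))
  }
  out <- dplyr::summarise(
    dplyr::group_by(sel, .data$city, .data$pollutant, .data$date),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop"
  )
  out$value[is.nan(out$value)] <- NA_real_
  out$station_scope <- scope
  dplyr::relocate(out, "city", "pollutant", "station_scope", "date", "value")
}

#' Mean concentration over a period
#'
#' @param series Tibble with `date` and `value` columns.
#' @param window Window object (see [baseline_window()]) or anything accepted
#'   by the mobility window coercion.
#' @param min_coverage Minimum fraction of window days with values.
#' @return Mean concentration (ug/m3).
#' @export
period_mean <- function(series, window, min_coverage = 0.75) {
  window <- as_window(window)
  vals <- series$value[series$date >= window$start & series$date <= window$end]
  vals <- vals[!is.na(vals)]
  cov <- length(vals) / window$n_days
  if (cov < min_coverage) {
    stop_coverage(sprintf("period coverage %.0f%% below required %.0f%%",
                          100 * cov, 100 * min_coverage))
  }
  mean(vals)
}

#' Relative change of an observed mean against a reference mean
#'
#' `100 * (observed - reference) / reference`; negative values are reductions.
#'
#' @param observed_mean,reference_mean Mean concentrations (ug/m3); the
#'   reference must be strictly positive.
#' @return Change in percent at full precision.
#' @examples
#' round_percent(relative_change(25.3, 31.9)) # -21
#' @export
relative_change <- function(observed_mean, reference_mean) {
  if (any(reference_mean <= 0)) {
    stop_validation("reference mean must be strictly positive")
  }
  100 * (observed_mean - reference_mean) / reference_mean
}

mmdd_key <- function(dates) {
  key <- format(dates, "%m-%d")
  # pool 29 Feb with 28 Feb so every year contributes to the same slot
  key[key == "02-29"] <- "02-28"
  key
}

#' Multi-year baseline of a pollutant series
#'
#' With `window = NULL`, returns the day-of-year baseline: for each calendar
#' day the mean concentration across the requested years (29 February pooled
#' with 28 February in non-leap years). With a window, returns the mean across
#' years of the same-calendar-window period means, i.e. the scalar baseline a
#' 2020 period mean is compared against.
#'
#' @param series Tibble with `date` and `value` covering several years.
#' @param years Integer vector of years to use (e.g. `2010:2019`).
#' @param window Optional window given by month-day endpoints of any year; the
#'   same calendar window is applied within each year.
#' @param min_coverage Per-year coverage required for a period mean; years
#'   failing it are skipped (at least one year must remain).
#' @return A tibble (`mmdd`, `value`, `n_years`) or a scalar mean.
#' @export
multi_year_baseline <- function(series, years, window = NULL, min_coverage = 0.75) {
  sel <- series[lubridate::year(series$date) %in% years & !is.na(series$value), ]
  if (nrow(sel) == 0) stop_coverage("no usable data in baseline years")
  if (is.null(window)) {
    out <- dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(mmdd = mmdd_key(sel$date),
                       year = lubridate::year(sel$date), value = sel$value),
        .data$mmdd
      ),
      value = mean(.data$value), n_years = dplyr::n_distinct(.data$year),
      .groups = "drop"
    )
    return(dplyr::arrange(out, .data$mmdd))
  }
  window <- as_window(window)
  per_year <- purrr::map_dbl(years, function(y) {
    win_y <- shift_window_to_year(window, y)
    tryCatch(period_mean(sel, win_y, min_coverage),
             airshift_coverage_error = function(e) NA_real_)
  })
  per_year <- per_year[!is.na(per_year)]
  if (length(per_year) == 0) {
    stop_coverage("no baseline year meets the coverage requirement")
  }
  mean(per_year)
}

# Apply a window's month-day endpoints within another year; 29 Feb endpoints
# fall back to 28 Feb in non-leap years.
shift_window_to_year <- function(window, year) {
  shift_one <- function(d) {
    md <- format(d, "%m-%d")
    if (md == "02-29" && !lubridate::leap_year(year)) md <- "02-28"
    lubridate::ymd(sprintf("%d-%s", year, md))
  }
  baseline_window(shift_one(window$start), shift_one(window$end))
}

#' Aggregate a daily series to calendar-week means
#'
#' Weeks start on Monday; weeks with fewer than `min_days` present days are
#' dropped, which smooths the series without letting fragmentary weeks distort
#' it.
#'
#' @param series Tibble with `date` and `value` columns.
#' @param min_days Minimum number of non-missing days per week.
#' @return Tibble with columns `week_start` and `value`.
#' @export
weekly_aggregate <- function(series, min_days = 4) {
  sel <- series[!is.na(series$value), ]
  out <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(
        week_start = lubridate::floor_date(sel$date, "week", week_start = 1),
        value = sel$value
      ),
      .data$week_start
    ),
    n = dplyr::n(), value = mean(.data$value), .groups = "drop"
  )
  out <- out[out$n >= min_days, c("week_start", "value")]
  dplyr::arrange(out, .data$week_start)
}

#' Five-year comparison level from annual means
#'
#' The recent-history comparison line: either the plain mean of the five
#' annual means or an ordinary least-squares linear trend through them
#' extrapolated to `target_year` (used where a city's series shows a clear
#' monotone trend).
#'
#' @param annual_means Tibble with columns `year` and `value` (5 rows typical).
#' @param method `"mean"` or `"trend"`.
#' @param target_year Year the trend is extrapolated to.
#' @return Scalar comparison level (ug/m3).
#' @export
five_year_reference <- function(annual_means, method = c("mean", "trend"),
                                target_year = 2020) {
  method <- rlang::arg_match(method)
  if (method == "mean") return(mean(annual_means$value))
  fit <- lm(value ~ year, data = annual_means)
  unname(predict(fit, newdata = data.frame(year = target_year)))
}

#' @importFrom stats predict
NULL
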