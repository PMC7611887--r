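# Re-normalisation of provider mobility indices against a pre-pandemic
# baseline window, and summaries of the resulting reductions over lockdown
# windows. The provider scales its index to 1.0 on a single reference day;
# because that day is atypical, indices are re-centred so the *mean* over the
# pre-Covid window is zero:
#
#   m_norm(d) = m0(d) / m_pc - 1,   m_pc = mean of m0 over the baseline window.

#' Baseline (pre-Covid) window
#'
#' Both endpoints inclusive. The default is the 62-day pre-Covid window
#' 2020-01-13 to 2020-03-14 used to zero-centre 2020 mobility indices.
#'
#' @param start,end Dates (or ISO strings), inclusive.
#' @return A list with `start`, `end` and `n_days`, class `baseline_window`.
#' @examples
#' baseline_window()$n_days # 62
#' @export
baseline_window <- function(start = "2020-01-13", end = "2020-03-14") {
  start <- as_iso_date(start, "window start")
  end <- as_iso_date(end, "window end")
  if (start > end) stop_validation("window start must not be after end")
  structure(
    list(start = start, end = end, n_days = as.integer(end - start) + 1L),
    class = "baseline_window"
  )
}

window_days <- function(window) seq(window$start, window$end, by = "day")

#' UK 2020 lockdown windows
#'
#' The first national lockdown (23 March to 10 May 2020) applied to all four
#' cities; the second was set locally. `"year"` denotes the span of the 2020
#' mobility record (13 January to 30 December).
#'
#' @return Tibble with columns `city`, `label`, `start`, `end`.
#' @export
uk_lockdown_windows <- function() {
  cities <- c("Greater London", "Cardiff", "Edinburgh", "Belfast")
  second <- tibble::tibble(
    city = cities,
    label = "second",
    start = lubridate::ymd(c("2020-11-05", "2020-10-23", "2020-11-20", "2020-11-27")),
    end = lubridate::ymd(c("2020-12-02", "2020-11-09", "2020-12-11", "2020-12-11"))
  )
  first <- tibble::tibble(
    city = cities, label = "first",
    start = lubridate::ymd("2020-03-23"), end = lubridate::ymd("2020-05-10")
  )
  year <- tibble::tibble(
    city = cities, label = "year",
    start = lubridate::ymd("2020-01-13"), end = lubridate::ymd("2020-12-30")
  )
  dplyr::arrange(dplyr::bind_rows(first, second, year), .data$city, .data$label)
}

coverage_fraction <- function(dates_present, window) {
  days <- window_days(window)
  sum(days %in% dates_present) / length(days)
}

#' Pre-Covid mean of a raw mobility series
#'
#' Arithmetic mean of the raw index over the days of the baseline window that
#' are present in the series; at least 90% of the window days must carry data.
#'
#' @param raw Tibble with columns `date` and `index` for one region x mode.
#' @param window A [baseline_window()].
#' @param min_coverage Minimum fraction of window days with data.
#' @return List with `m_pc` (the mean), `n_pc` (days actually used) and
#'   `n_window` (window length in days).
#' @export
precovid_mean <- function(raw, window = baseline_window(), min_coverage = 0.9) {
  in_win <- raw[!is.na(raw$index) & raw$date >= window$start & raw$date <= window$end, ]
  cov <- nrow(in_win) / window$n_days
  if (cov < min_coverage) {
    stop_coverage(sprintf(
      "baseline coverage %.0f%% below required %.0f%% (%d of %d days)",
      100 * cov, 100 * min_coverage, nrow(in_win), window$n_days
    ))
  }
  list(m_pc = mean(in_win$index), n_pc = nrow(in_win), n_window = window$n_days)
}

#' Normalise a raw mobility series to zero pre-Covid mean
#'
#' @inheritParams precovid_mean
#' @return Tibble with columns `date` and `m_norm`; missing raw days stay
#'   missing.
#' @export
normalize_mobility <- function(raw, window = baseline_window(), min_coverage = 0.9) {
  pc <- precovid_mean(raw, window, min_coverage)
  if (pc$m_pc == 0) {
    stop_validation("degenerate baseline: pre-Covid mean mobility is zero")
  }
  tibble::tibble(date = raw$date, m_norm = raw$index / pc$m_pc - 1)
}

#' Build a normalised mobility panel for several regions and modes
#'
#' Applies [normalize_mobility()] per (region, mode) group of a raw mobility
#' table.
#'
#' @param mobility Tibble as returned by [read_mobility_csv()].
#' @inheritParams precovid_mean
#' @return Tibble with columns `city`, `mode`, `date`, `raw`, `normalized`.
#' @export
mobility_panel <- function(mobility, window = baseline_window(), min_coverage = 0.9) {
  groups <- dplyr::group_split(dplyr::group_by(mobility, .data$region, .data$mode))
  purrr::list_rbind(purrr::map(groups, function(g) {
    norm <- normalize_mobility(
      tibble::tibble(date = g$date, index = g$index), window, min_coverage
    )
    tibble::tibble(
      city = g$region[1], mode = g$mode[1], date = g$date,
      raw = g$index, normalized = norm$m_norm
    )
  }))
}

panel_window_values <- function(panel, window) {
  panel[!is.na(panel$normalized) &
          panel$date >= window$start & panel$date <= window$end, ]
}

#' Average mobility reduction over a window
#'
#' Mean of the normalised series over a (lockdown) window, as a percentage;
#' negative values are reductions. Requires 75% coverage of the window.
#'
#' @param panel Tibble with `date` and `normalized` columns (one city x mode).
#' @param window A window object with `start` and `end` (e.g. a row of
#'   [uk_lockdown_windows()] passed through [baseline_window()]), or a
#'   `baseline_window`.
#' @param min_coverage Minimum fraction of window days with values.
#' @return Mean change in percent (full precision; see [round_percent()]).
#' @export
average_reduction <- function(panel, window, min_coverage = 0.75) {
  window <- as_window(window)
  vals <- panel_window_values(panel, window)
  cov <- nrow(vals) / window$n_days
  if (cov < min_coverage) {
    stop_coverage(sprintf("window coverage %.0f%% below required %.0f%%",
                          100 * cov, 100 * min_coverage))
  }
  100 * mean(vals$normalized)
}

#' Deepest daily mobility drop in a window
#'
#' Returns the most negative daily normalised value and its date; ties are
#' broken by the earlier date so reports are deterministic.
#'
#' @inheritParams average_reduction
#' @return List with `date` and `percent`.
#' @export
minimum_mobility <- function(panel, window) {
  window <- as_window(window)
  vals <- panel_window_values(panel, window)
  if (nrow(vals) == 0) stop_coverage("no mobility values in window")
  vals <- dplyr::arrange(vals, .data$date)
  i <- which.min(vals$normalized) # which.min returns the first (earliest) tie
  list(date = vals$date[i], percent = 100 * vals$normalized[i])
}

# Accept baseline_window objects, single-row window tibbles, or two-element
# date lists.
as_window <- function(window) {
  if (inherits(window, "baseline_window")) return(window)
  if (is.data.frame(window)) {
    stopifnot(nrow(window) == 1)
    return(baseline_window(window$start, window$end))
  }
  if (is.list(window) && all(c("start", "end") %in% names(window))) {
    return(baseline_window(window$start, window$end))
  }
  stop_validation("cannot interpret window object")
}
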