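# Spearman rank-order correlation between weekly mobility reduction and
# weekly pollutant change series. The correlation is computed from mid-ranks;
# p-values are exact (full permutation enumeration) for small n, and use the
# t approximation otherwise. No multiple-testing correction is applied: each
# city x pollutant x mode cell is reported raw.

# all permutations of 1..n as a matrix (n! rows); n is capped by the exact-p
# cutoff so this stays small
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}

#' Spearman rank-order correlation with exact small-sample p-value
#'
#' Computes r_s as the Pearson correlation of the mid-rank vectors (ties get
#' average ranks). Two-sided p-value: for n >= 10 via the t statistic
#' `t = r_s * sqrt((n - 2) / (1 - r_s^2))`; for n < 10 by exact enumeration of
#' all n! orderings (or, with `exact = FALSE`, by seeded Monte-Carlo
#' permutations). Paired missing values are dropped first.
#'
#' @param x,y Numeric vectors of equal length (n >= 3 after dropping pairs
#'   with missing values).
#' @param exact Use exact enumeration for n < 10? Default `TRUE`.
#' @param n_mc Number of Monte-Carlo permutations when `exact = FALSE`.
#' @param seed Seed for the Monte-Carlo p-value.
#' @return List with `r_s`, `p_value`, `n` and `method`.
#' @examples
#' spearman(1:5, c(2, 1, 4, 3, 5)) # r_s = 0.8
#' @export
spearman <- function(x, y, exact = TRUE, n_mc = 10000, seed = 1L) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop_validation("need at least 3 complete pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop_validation("undefined correlation: zero rank variance (all values tied)")
  }
  r_s <- cor(rx, ry)
  if (n >= 10) {
    tt <- r_s * sqrt((n - 2) / max(1 - r_s^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  } else if (exact) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(r_perm) >= abs(r_s) - 1e-12)
    method <- "exact permutation"
  } else {
    r_perm <- withr::with_seed(seed, {
      replicate(n_mc, cor(rx, sample(ry)))
    })
    p <- (1 + sum(abs(r_perm) >= abs(r_s) - 1e-12)) / (n_mc + 1)
    method <- "Monte-Carlo permutation"
  }
  list(r_s = unname(r_s), p_value = min(p, 1), n = n, method = method)
}

#' Weekly anomaly series (observed vs counterfactual)
#'
#' Aggregates observed and predicted daily series to Monday-start weekly means
#' and returns the weekly relative change (%) of observed against predicted.
#'
#' @param observed,predicted Tibbles with `date` and `value`.
#' @param min_days Minimum days per week (see [weekly_aggregate()]).
#' @return Tibble with `week_start` and `value` (weekly relative change, %).
#' @export
weekly_anomaly <- function(observed, predicted, min_days = 4) {
  wo <- dplyr::rename(weekly_aggregate(observed, min_days), obs = "value")
  wp <- dplyr::rename(weekly_aggregate(predicted, min_days), pred = "value")
  j <- dplyr::inner_join(wo, wp, by = "week_start")
  tibble::tibble(week_start = j$week_start,
                 value = relative_change(j$obs, j$pred))
}

#' Weekly change against a multi-year same-week baseline
#'
#' For each Monday-start week of the target year, the relative change of the
#' weekly mean against the mean of the same calendar week across the baseline
#' years.
#'
#' @param series Daily series covering the target year.
#' @param baseline_daily Day-of-year baseline from [multi_year_baseline()]
#'   (`window = NULL`), or a daily series covering the baseline years from
#'   which week means are formed on the target year's calendar.
#' @param year Target year.
#' @param min_days Minimum days per week.
#' @return Tibble with `week_start` and `value` (%).
#' @export
weekly_baseline_change <- function(series, baseline_daily, year = 2020, min_days = 4) {
  target <- series[lubridate::year(series$date) == year, ]
  wk <- weekly_aggregate(target, min_days)
  # expand the day-of-year baseline onto the target year's calendar
  days <- seq(lubridate::ymd(sprintf("%d-01-01", year)),
              lubridate::ymd(sprintf("%d-12-31", year)), by = "day")
  base <- tibble::tibble(
    date = days,
    value = baseline_daily$value[match(mmdd_key(days), baseline_daily$mmdd)]
  )
  wb <- dplyr::rename(weekly_aggregate(base, min_days), base = "value")
  j <- dplyr::inner_join(wk, wb, by = "week_start")
  tibble::tibble(week_start = j$week_start,
                 value = relative_change(j$value, j$base))
}

#' Correlate weekly mobility reduction with a weekly pollution-change series
#'
#' Aggregates the normalised mobility panel for one transport mode to weekly
#' means on the same Monday-start week keys as the pollution series, then
#' applies [spearman()].
#'
#' @param panel Normalised mobility panel (one city; see [mobility_panel()]).
#' @param weekly_series Tibble with `week_start` and `value` (e.g. from
#'   [weekly_anomaly()] or [weekly_baseline_change()]).
#' @param mode Transport mode (`"driving"` or `"transit"`).
#' @param series_kind Label for the pollution series (`"five_year_mean"`,
#'   `"lr_anomaly"` or `"gbr_anomaly"`).
#' @param min_weeks Minimum number of overlapping weeks.
#' @return One-row tibble: `city`, `mode`, `series_kind`, `r_s`, `p_value`,
#'   `n_weeks`.
#' @export
correlate_city <- function(panel, weekly_series, mode,
                           series_kind = c("gbr_anomaly", "lr_anomaly", "five_year_mean"),
                           min_weeks = 8) {
  series_kind <- rlang::arg_match(series_kind)
  sel <- panel[panel$mode == mode, ]
  if (nrow(sel) == 0) stop_validation(sprintf("no mobility data for mode '%s'", mode))
  wm <- weekly_aggregate(
    tibble::tibble(date = sel$date, value = sel$normalized)
  )
  j <- dplyr::inner_join(dplyr::rename(wm, mobility = "value"),
                         dplyr::rename(weekly_series, pollution = "value"),
                         by = "week_start")
  if (nrow(j) < min_weeks) {
    stop_coverage(sprintf("only %d overlapping weeks; need at least %d",
                          nrow(j), min_weeks))
  }
  sp <- spearman(j$mobility, j$pollution)
  tibble::tibble(
    city = sel$city[1], mode = mode, series_kind = series_kind,
    r_s = sp$r_s, p_value = sp$p_value, n_weeks = sp$n
  )
}
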