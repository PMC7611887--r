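# Attributable-fraction health impact assessment. Long-term exposure at
# annual mean concentration x maps to a relative risk through the log-linear
# concentration-response model RR = beta^(x/10), with beta the relative risk
# per 10 ug/m3 increment, and to the attributable fraction of all-cause
# mortality AF = 100 * (RR - 1) / RR. Because both maps are strictly monotone
# in beta, confidence intervals for AF follow exactly by propagating the
# endpoints of beta's interval.

#' Concentration-response coefficients
#'
#' Relative risks per 10 ug/m3 with 95% confidence intervals, read from the
#' versioned YAML data file shipped with the package (COMEAP-recommended
#' values: NO2 1.023, 95% CI 1.008-1.037; PM2.5 1.060, 95% CI 1.04-1.08).
#'
#' @param path Optional path to an alternative YAML beta table.
#' @return Tibble with columns `pollutant`, `beta`, `beta_low`, `beta_high`.
#' @export
default_betas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "betas.yaml", package = "airshift")
  }
  raw <- yaml::read_yaml(path)
  out <- purrr::list_rbind(purrr::imap(raw$betas, function(b, pol) {
    tibble::tibble(pollutant = pol, beta = b$beta,
                   beta_low = b$ci95[1], beta_high = b$ci95[2])
  }))
  bad <- out$beta <= 1 | out$beta_low > out$beta | out$beta < out$beta_low |
    out$beta > out$beta_high
  if (any(bad)) stop_validation("beta table violates beta > 1 or CI ordering")
  out
}

#' Relative risk at an annual mean concentration
#'
#' `RR = beta^(x/10)` with `beta` the relative risk per 10 ug/m3.
#'
#' @param beta Concentration-response coefficient (> 0).
#' @param x Annual mean concentration, ug/m3 (>= 0).
#' @return Relative risk (dimensionless).
#' @examples
#' relative_risk(1.023, 10) # 1.023
#' @export
relative_risk <- function(beta, x) {
  if (any(beta <= 0)) stop_validation("beta must be positive")
  if (any(x < 0, na.rm = TRUE)) stop_validation("concentration must be non-negative")
  beta^(x / 10)
}

#' Attributable fraction of all-cause mortality
#'
#' `AF = 100 * (RR - 1) / RR`, in percent.
#'
#' @param rr Relative risk (> 0).
#' @return Attributable fraction, %.
#' @examples
#' attributable_fraction(2) # 50
#' @export
attributable_fraction <- function(rr) {
  if (any(rr <= 0, na.rm = TRUE)) stop_validation("relative risk must be positive")
  100 * (rr - 1) / rr
}

#' @describeIn attributable_fraction Attributable fraction directly from a
#'   concentration: `attributable_fraction(relative_risk(beta, x))`.
#' @inheritParams relative_risk
#' @export
af_from_concentration <- function(beta, x) {
  attributable_fraction(relative_risk(beta, x))
}

#' Invert an attributable fraction to a concentration
#'
#' Solves `AF = 100 * (RR - 1) / RR`, `RR = beta^(x/10)` for x; the exact
#' inverse of [af_from_concentration()] (used for round-trip checks and for
#' reading concentrations back out of reported AF tables).
#'
#' @param af Attributable fraction, % (0 <= af < 100).
#' @param beta Concentration-response coefficient (> 1).
#' @return Concentration, ug/m3.
#' @export
concentration_from_af <- function(af, beta) {
  if (any(af < 0 | af >= 100, na.rm = TRUE)) {
    stop_validation("attributable fraction must be in [0, 100)")
  }
  rr <- 1 / (1 - af / 100)
  10 * log(rr) / log(beta)
}

#' Attributable-fraction table per city, pollutant and year
#'
#' Computes AF (with the beta-endpoint confidence interval) for each annual
#' mean concentration. Years with missing annual means (e.g. failing the
#' station coverage rule) are emitted as missing rather than dropped, so the
#' output table keeps one row per requested cell.
#'
#' @param annual_means Tibble with columns `city`, `pollutant`, `year`,
#'   `mean` (annual mean concentration ug/m3 at urban-background scope;
#'   `NA` allowed).
#' @param betas Beta table as from [default_betas()].
#' @return Tibble with `city`, `pollutant`, `year`, `annual_mean`, `rr`,
#'   `af_percent`, `af_low`, `af_high`.
#' @export
af_table <- function(annual_means, betas = default_betas()) {
  missing_pol <- setdiff(unique(annual_means$pollutant), betas$pollutant)
  if (length(missing_pol) > 0) {
    stop_validation(sprintf("no beta coefficient for pollutant '%s'", missing_pol[1]))
  }
  j <- dplyr::inner_join(annual_means, betas, by = "pollutant")
  rr <- ifelse(is.na(j$mean), NA_real_, relative_risk(j$beta, pmax(j$mean, 0)))
  out <- tibble::tibble(
    city = j$city, pollutant = j$pollutant, year = j$year,
    annual_mean = j$mean,
    rr = rr,
    af_percent = ifelse(is.na(rr), NA_real_, attributable_fraction(rr)),
    af_low = ifelse(is.na(j$mean), NA_real_,
                    af_from_concentration(j$beta_low, pmax(j$mean, 0))),
    af_high = ifelse(is.na(j$mean), NA_real_,
                     af_from_concentration(j$beta_high, pmax(j$mean, 0)))
  )
  dplyr::arrange(out, .data$pollutant, .data$city, .data$year)
}

#' Annual urban-background mean concentrations
#'
#' Convenience wrapper: aggregates stations at urban-background scope and
#' computes each year's annual mean under the period coverage rule; years
#' failing coverage yield `NA` (kept as blank cells downstream).
#'
#' @param stations Station table (see [read_station_csv()]).
#' @param years Years to compute.
#' @param min_coverage Required fraction of the year's days with data.
#' @return Tibble with `city`, `pollutant`, `year`, `mean`.
#' @export
annual_urban_background_means <- function(stations, years, min_coverage = 0.75) {
  series <- city_daily_mean(stations, scope = "urban_background")
  combos <- dplyr::distinct(series, .data$city, .data$pollutant)
  purrr::list_rbind(purrr::map(seq_len(nrow(combos)), function(i) {
    s <- series[series$city == combos$city[i] & series$pollutant == combos$pollutant[i], ]
    tibble::tibble(
      city = combos$city[i], pollutant = combos$pollutant[i], year = years,
      mean = purrr::map_dbl(years, function(y) {
        win <- baseline_window(sprintf("%d-01-01", y), sprintf("%d-12-31", y))
        tryCatch(period_mean(s, win, min_coverage),
                 airshift_coverage_error = function(e) NA_real_)
      })
    )
  }))
}
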