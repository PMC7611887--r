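# Synthetic city-data generator. Emulates the statistical structure the
# pipeline assumes -- seasonal autocorrelated weather; multi-year daily
# pollutant series with a weekday cycle, an early-decade declining trend,
# same-day and 3-day-lagged weather dependence; and a 2020 mobility record
# with two lockdown dips -- while recording the injected ground truth exactly,
# so every stage can be validated against known answers without downloads.
#
# Suppression of 2020 concentrations is multiplicative (the natural scale for
# a relative-change analysis and guaranteed non-negative):
#   mobility mode:  obs_d = cf_d * (1 - s * w_d),  w_d = mean driving/transit
#                   reduction magnitude on day d
#   uniform mode:   obs_d = cf_d * (1 - s) on every 2020 day, so the injected
#                   annual suppression is exactly -100 * s.

#' Default synthetic city scenario
#'
#' Parameter bundle describing one synthetic city: weather process, pollutant
#' processes (NO2 strongly coupled to mobility, PM2.5 weakly coupled plus an
#' uncoupled regional background), and the 2020 mobility profile with two
#' lockdown dips. Defaults emulate a mid-size UK city; see the methods
#' vignette for the rationale behind each value.
#'
#' @param city City name.
#' @param years Years covered by weather and pollutant series.
#' @param seed Default seed used by the generator functions.
#' @param suppression_mode `"mobility"` (daily suppression follows the
#'   driving/transit reduction) or `"uniform"` (constant factor `1 - s` across
#'   all 2020 days, making the injected annual suppression exactly `-100 s`).
#' @param no2_coupling,pm25_coupling Suppression fractions s in `[0, 1)`.
#' @return A list of class `city_scenario`.
#' @export
city_scenario <- function(city = "Avonford", years = 2010:2020, seed = 2020L,
                          suppression_mode = c("mobility", "uniform"),
                          no2_coupling = 0.25, pm25_coupling = 0.05) {
  suppression_mode <- rlang::arg_match(suppression_mode)
  stopifnot(no2_coupling >= 0, no2_coupling < 1,
            pm25_coupling >= 0, pm25_coupling < 1)
  structure(list(
    city = city,
    years = years,
    seed = as.integer(seed),
    suppression_mode = suppression_mode,
    weather = list(
      temp_mean = 10.5, temp_amplitude = 6.5, # deg C; peak late July
      temp_ar = 0.75, temp_sd = 2.8,          # AR(1) anomaly, stationary sd
      precip_prob = 0.45, precip_scale = 2.8, # Bernoulli occurrence x Exp(mm)
      wind_shape = 2.2, wind_scale = 2.0      # Gamma, mean ~4.4
    ),
    pollutants = list(
      NO2 = list(
        base = 33, trend = -1.0, trend_end_year = 2015, # ug/m3, ug/m3/yr
        weekday_amp = 0.12,
        coef = c(temperature = -0.35, precipitation = -0.15, wind_speed = -1.1),
        coef_lag3 = c(temperature = -0.12, precipitation = -0.05, wind_speed = -0.35),
        cold_coef = 0.8, cold_threshold = 5, # inversion-like excess below 5 C
        noise_sd = 2.5, noise_ar = 0.5,
        background_sd = 0, background_ar = 0,
        coupling = no2_coupling
      ),
      PM2.5 = list(
        base = 13, trend = -0.6, trend_end_year = 2015,
        weekday_amp = 0.06,
        coef = c(temperature = -0.1, precipitation = -0.25, wind_speed = -0.45),
        coef_lag3 = c(temperature = -0.05, precipitation = -0.08, wind_speed = -0.15),
        cold_coef = 0.2, cold_threshold = 5,
        noise_sd = 1.2, noise_ar = 0.6,
        background_sd = 2.2, background_ar = 0.8, # uncoupled regional term
        coupling = pm25_coupling
      )
    ),
    traffic_station = list(level_factor = 1.5, coupling_factor = 1.25),
    mobility = list(
      start = "2020-01-13", end = "2020-12-31",
      weekday_amp = 0.05, noise_sd = 0.02,
      lockdown1 = list(start = "2020-03-23", end = "2020-05-10"),
      lockdown2 = list(start = "2020-11-05", end = "2020-12-02"),
      # average depths during each lockdown, per mode
      depth1 = c(driving = 0.69, transit = 0.86, walking = 0.78),
      depth2 = c(driving = 0.36, transit = 0.58, walking = 0.59),
      # fraction of the dip recovered after each lockdown
      recovery1 = c(driving = 0.95, transit = 0.45, walking = 0.85),
      recovery2 = c(driving = 0.50, transit = 0.30, walking = 0.50),
      tau1 = 45, tau2 = 30 # recovery time constants, days
    )
  ), class = "city_scenario")
}

ar1_series <- function(n, phi, sd_stat) {
  if (sd_stat == 0) return(rep(0, n))
  if (phi == 0) return(rnorm(n, 0, sd_stat))
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sd_stat)
  innov <- rnorm(n - 1, 0, sd_stat * sqrt(1 - phi^2))
  for (t in 2:n) e[t] <- phi * e[t - 1] + innov[t - 1]
  e
}

#' Generate daily weather for a scenario
#'
#' Temperature is a seasonal sinusoid plus AR(1) anomalies; precipitation is
#' Bernoulli occurrence times exponential amounts; wind speed is gamma
#' distributed. A small lead-in before the first year is generated so lagged
#' features are available from 1 January.
#'
#' @param scenario A [city_scenario()].
#' @param seed Seed; defaults to the scenario seed. Same seed, same table.
#' @return Weather tibble (`city`, `date`, `temperature`, `precipitation`,
#'   `wind_speed`).
#' @export
gen_weather <- function(scenario, seed = scenario$seed) {
  w <- scenario$weather
  dates <- seq(lubridate::ymd(sprintf("%d-01-01", min(scenario$years))) - 7,
               lubridate::ymd(sprintf("%d-12-31", max(scenario$years))), by = "day")
  n <- length(dates)
  withr::with_seed(seed, {
    seasonal <- w$temp_mean +
      w$temp_amplitude * cos(2 * pi * (lubridate::yday(dates) - 205) / 365.25)
    temperature <- seasonal + ar1_series(n, w$temp_ar, w$temp_sd)
    precipitation <- rbinom(n, 1, w$precip_prob) * rexp(n, 1 / w$precip_scale)
    wind_speed <- rgamma(n, shape = w$wind_shape, scale = w$wind_scale)
    tibble::tibble(city = scenario$city, date = dates,
                   temperature = temperature,
                   precipitation = precipitation, wind_speed = wind_speed)
  })
}

# True (noise-free) reduction profile per mode over the 2020 mobility dates.
# Logistic descent into each lockdown, plateau at the configured depth,
# exponential partial recovery afterwards.
mobility_profile <- function(scenario) {
  m <- scenario$mobility
  dates <- seq(as_iso_date(m$start), as_iso_date(m$end), by = "day")
  t <- as.numeric(dates)
  l1s <- as.numeric(as_iso_date(m$lockdown1$start))
  l1e <- as.numeric(as_iso_date(m$lockdown1$end))
  l2s <- as.numeric(as_iso_date(m$lockdown2$start))
  l2e <- as.numeric(as_iso_date(m$lockdown2$end))
  if (l2s <= l1e) stop_validation("lockdown windows must not overlap")
  out <- purrr::map(MOBILITY_MODES, function(mode) {
    d1 <- m$depth1[[mode]]; d2 <- m$depth2[[mode]]
    p1 <- d1 * (1 - m$recovery1[[mode]])
    p2 <- d2 * (1 - m$recovery2[[mode]])
    # descent centred 5 days before the lockdown start, ~1 week wide, so the
    # configured depth is (nearly) the window average
    r <- -d1 / (1 + exp(-(t - (l1s - 5)) / 1.8))
    rec <- t > l1e
    r[rec] <- -(p1 + (d1 - p1) * exp(-(t[rec] - l1e) / m$tau1))
    pre2 <- -(p1 + (d1 - p1) * exp(-(l2s - l1e) / m$tau1))
    ramp2 <- t > (l2s - 7) & t <= l2s
    r[ramp2] <- pre2 + (-d2 - pre2) * (t[ramp2] - (l2s - 7)) / 7
    hold2 <- t > l2s & t <= l2e
    r[hold2] <- -d2
    rec2 <- t > l2e
    r[rec2] <- -(p2 + (d2 - p2) * exp(-(t[rec2] - l2e) / m$tau2))
    tibble::tibble(mode = mode, date = dates, reduction = r)
  })
  purrr::list_rbind(out)
}

# daily suppression weight from the true driving/transit reduction profiles
coupling_weights <- function(profile) {
  sel <- profile[profile$mode %in% c("driving", "transit"), ]
  w <- dplyr::summarise(dplyr::group_by(sel, .data$date),
                        w = mean(-.data$reduction), .groups = "drop")
  w$w <- pmin(1, pmax(0, w$w))
  w
}

#' Generate the 2020 mobility record for a scenario
#'
#' Raw indices are the true reduction profile times a weekday texture and
#' small multiplicative noise, scaled to ~1 over the pre-Covid window (the
#' provider's reference-day convention).
#'
#' @inheritParams gen_weather
#' @return Tibble in the layout of [read_mobility_csv()] (`region`, `mode`,
#'   `date`, `index`), with the true profile as attribute `"profile"`.
#' @export
gen_mobility <- function(scenario, seed = scenario$seed) {
  m <- scenario$mobility
  prof <- mobility_profile(scenario)
  withr::with_seed(seed + 1L, {
    wd_effect <- c(-0.2, 0.05, 0.1, 0.1, 0.15, 0.25, -0.45) # Mon..Sun, sums ~0
    out <- dplyr::mutate(
      prof,
      index = (1 + .data$reduction) *
        (1 + m$weekday_amp * wd_effect[lubridate::wday(.data$date, week_start = 1)]) *
        exp(rnorm(dplyr::n(), 0, m$noise_sd))
    )
    res <- tibble::tibble(region = scenario$city, mode = out$mode,
                          date = out$date, index = out$index)
    attr(res, "profile") <- prof
    res
  })
}

pollutant_level <- function(p, year) {
  p$base + p$trend * (pmin(year, p$trend_end_year) - 2010)
}

#' Generate station pollutant series for a scenario
#'
#' Two stations per city: one urban background and one urban traffic station
#' (higher levels, amplified mobility coupling). Daily concentration is
#' trend-and-weekday level, plus centred same-day and lag-3 weather terms,
#' AR(1) noise and (for PM2.5) an uncoupled regional background; 2020 values
#' are multiplied by the suppression factor and floored at 0.
#'
#' @inheritParams gen_weather
#' @param weather Weather tibble from [gen_weather()].
#' @param mobility Mobility tibble from [gen_mobility()] (used for the
#'   suppression weights); may be `NULL` only if all couplings are zero or
#'   suppression is uniform.
#' @return Station tibble in the layout of [read_station_csv()]; attribute
#'   `"ground_truth"` records couplings, suppression mode and the realised
#'   annual 2020 suppression (%) per pollutant and station, computed exactly
#'   from the counterfactual series. Attribute `"counterfactual"` holds the
#'   unsuppressed 2020 series.
#' @export
gen_pollution <- function(scenario, weather, mobility = NULL,
                          seed = scenario$seed) {
  dates <- seq(lubridate::ymd(sprintf("%d-01-01", min(scenario$years))),
               lubridate::ymd(sprintf("%d-12-31", max(scenario$years))), by = "day")
  n <- length(dates)
  year <- lubridate::year(dates)
  wd <- lubridate::wday(dates, week_start = 1)
  wd_effect <- c(0.6, 0.9, 1.0, 1.0, 0.9, -1.4, -2.0) # Mon..Sun, mean 0
  wd_effect <- wd_effect - mean(wd_effect)

  i_now <- match(dates, weather$date)
  i_lag <- match(dates - 3, weather$date)
  met <- list(
    temperature = weather$temperature,
    precipitation = weather$precipitation,
    wind_speed = weather$wind_speed
  )
  met_mean <- list(
    temperature = scenario$weather$temp_mean,
    precipitation = scenario$weather$precip_prob * scenario$weather$precip_scale,
    wind_speed = scenario$weather$wind_shape * scenario$weather$wind_scale
  )

  # suppression weights per day (2020 only)
  if (scenario$suppression_mode == "uniform") {
    w_day <- as.numeric(year == 2020)
  } else {
    w_day <- numeric(n)
    if (!is.null(mobility)) {
      prof <- attr(mobility, "profile")
      if (is.null(prof)) stop_validation("mobility table lacks the 'profile' attribute")
      cw <- coupling_weights(prof)
      idx <- match(dates, cw$date)
      w_day[!is.na(idx)] <- cw$w[idx[!is.na(idx)]]
    } else if (any(purrr::map_dbl(scenario$pollutants, "coupling") > 0)) {
      stop_validation("mobility-coupled suppression requires a mobility table")
    }
  }

  stations <- tibble::tibble(
    station_id = paste0(toupper(substr(scenario$city, 1, 3)), c("_UB1", "_TR1")),
    category = c("urban background", "urban traffic")
  )
  truth <- list(suppression_mode = scenario$suppression_mode, coupling = list(),
                realized_annual_suppression = list())
  cf_all <- list()
  rows <- list()
  k <- 0L
  for (pol in names(scenario$pollutants)) {
    p <- scenario$pollutants[[pol]]
    truth$coupling[[pol]] <- p$coupling
    for (si in seq_len(nrow(stations))) {
      k <- k + 1L
      is_traffic <- stations$category[si] == "urban traffic"
      lf <- if (is_traffic) scenario$traffic_station$level_factor else 1
      s_eff <- p$coupling *
        if (is_traffic) scenario$traffic_station$coupling_factor else 1
      cf <- withr::with_seed(seed + 10L * k, {
        level <- lf * pollutant_level(p, year) * (1 + p$weekday_amp * wd_effect[wd])
        met_term <- 0
        for (v in names(p$coef)) {
          met_term <- met_term +
            p$coef[[v]] * (met[[v]][i_now] - met_mean[[v]]) +
            p$coef_lag3[[v]] * (met[[v]][i_lag] - met_mean[[v]])
        }
        # threshold response: stagnation/inversion excess on cold days
        met_term <- met_term +
          p$cold_coef * pmax(0, p$cold_threshold - met$temperature[i_now])
        level + met_term + ar1_series(n, p$noise_ar, p$noise_sd) +
          ar1_series(n, p$background_ar, p$background_sd)
      })
      factor_d <- pmax(0, 1 - pmin(s_eff * w_day, 0.95))
      obs <- pmax(0, cf * factor_d)
      in20 <- year == 2020
      realized <- relative_change(mean(obs[in20]), mean(cf[in20]))
      truth$realized_annual_suppression[[pol]][[stations$station_id[si]]] <- realized
      cf_all[[paste(pol, stations$station_id[si])]] <-
        tibble::tibble(station_id = stations$station_id[si], pollutant = pol,
                       date = dates[in20], value = cf[in20])
      rows[[k]] <- tibble::tibble(
        station_id = stations$station_id[si], city = scenario$city,
        category = stations$category[si], pollutant = pol,
        date = dates, value = obs
      )
    }
  }
  out <- purrr::list_rbind(rows)
  attr(out, "ground_truth") <- truth
  attr(out, "counterfactual") <- purrr::list_rbind(cf_all)
  out
}

#' Generate a complete synthetic city dataset
#'
#' Convenience wrapper running [gen_weather()], [gen_mobility()] and
#' [gen_pollution()] under one seed.
#'
#' @inheritParams gen_weather
#' @return List with `weather`, `mobility`, `stations` and `truth` (the
#'   injected ground truth: couplings, suppression mode, realised annual 2020
#'   suppression per pollutant and station, and mobility dip depths).
#' @export
gen_city_data <- function(scenario, seed = scenario$seed) {
  weather <- gen_weather(scenario, seed)
  mobility <- gen_mobility(scenario, seed)
  stations <- gen_pollution(scenario, weather, mobility, seed)
  truth <- attr(stations, "ground_truth")
  truth$mobility_depths <- list(first = as.list(scenario$mobility$depth1),
                                second = as.list(scenario$mobility$depth2))
  list(weather = weather, mobility = mobility, stations = stations,
       counterfactual = attr(stations, "counterfactual"), truth = truth)
}

#' Write a synthetic scenario to fixture files
#'
#' Emits the three CSV dialects the readers understand plus a
#' `ground_truth.yaml` with the injected truth, so a written scenario is a
#' self-contained, reproducible test fixture.
#'
#' @inheritParams gen_weather
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_scenario <- function(scenario, outdir, seed = scenario$seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dat <- gen_city_data(scenario, seed)
  paths <- list(
    mobility = file.path(outdir, "mobility.csv"),
    stations = file.path(outdir, "stations.csv"),
    weather = file.path(outdir, "weather.csv"),
    truth = file.path(outdir, "ground_truth.yaml")
  )
  write_mobility_csv(dat$mobility, paths$mobility)
  write_station_csv(dat$stations, paths$stations)
  write_weather_csv(dat$weather, paths$weather)
  yaml::write_yaml(c(dat$truth, list(seed = seed, city = scenario$city)),
                   paths$truth)
  invisible(paths)
}
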