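test_that("weather generation is seeded, seasonal and AR-correlated", {
  sc <- city_scenario(seed = 71)
  w1 <- gen_weather(sc)
  w2 <- gen_weather(sc)
  expect_identical(w1, w2) # determinism under the scenario seed
  expect_true(all(w1$precipitation >= 0))
  expect_true(all(w1$wind_speed >= 0))

  # zero-noise scenario gives the pure seasonal sinusoid
  sc0 <- city_scenario(seed = 71)
  sc0$weather$temp_sd <- 0
  w0 <- gen_weather(sc0)
  expect_equal(
    w0$temperature,
    sc0$weather$temp_mean + sc0$weather$temp_amplitude *
      cos(2 * pi * (lubridate::yday(w0$date) - 205) / 365.25)
  )

  # lag-1 autocorrelation of the temperature anomaly ~ the AR coefficient
  anom <- w1$temperature - w0$temperature
  expect_equal(cor(anom[-1], anom[-length(anom)]), sc$weather$temp_ar,
               tolerance = 0.05)
})

test_that("mobility generation hits configured dips and normalises to ~0 baseline", {
  sc <- city_scenario(seed = 72)
  mob <- gen_mobility(sc)
  expect_identical(mob, gen_mobility(sc)) # same seed -> identical
  panel <- mobility_panel(mob)
  w1 <- baseline_window("2020-03-23", "2020-05-10")
  for (m in c("driving", "transit", "walking")) {
    got <- average_reduction(panel[panel$mode == m, ], w1)
    expect_equal(got, -100 * sc$mobility$depth1[[m]], tolerance = 2.5)
  }
  # transit recovers least after the first lockdown
  post <- baseline_window("2020-08-01", "2020-10-15")
  post_means <- purrr::map_dbl(c("driving", "transit", "walking"), function(m)
    average_reduction(panel[panel$mode == m, ], post))
  expect_equal(which.min(post_means), 2)

  # no lockdowns: normalised series stays near zero all year
  sc0 <- city_scenario(seed = 72)
  sc0$mobility$depth1[] <- 0
  sc0$mobility$depth2[] <- 0
  panel0 <- mobility_panel(gen_mobility(sc0))
  yr <- baseline_window("2020-01-13", "2020-12-30")
  for (m in c("driving", "transit", "walking")) {
    expect_lt(abs(average_reduction(panel0[panel0$mode == m, ], yr)), 2)
  }

  # injected synthetic dip is recovered by minimum_mobility
  sc2 <- city_scenario(seed = 73)
  sc2$mobility$depth1[] <- 0.83
  sc2$mobility$noise_sd <- 0
  sc2$mobility$weekday_amp <- 0
  p2 <- mobility_panel(gen_mobility(sc2))
  mm <- minimum_mobility(p2[p2$mode == "driving", ], yr)
  expect_equal(mm$percent, -83, tolerance = 1)

  # overlapping lockdown windows are a configuration error
  sc3 <- city_scenario(seed = 74)
  sc3$mobility$lockdown2 <- list(start = "2020-05-01", end = "2020-06-01")
  expect_error(gen_mobility(sc3), "overlap")
})

test_that("pollution generation records exact ground truth and respects coupling", {
  sc <- test_scenario(seed = 75)
  dat <- gen_city_data(sc)
  truth <- dat$truth
  st <- dat$stations
  expect_setequal(unique(st$category), c("urban background", "urban traffic"))
  expect_true(all(st$value >= 0))

  # realized suppression equals the observed/counterfactual contrast exactly
  cf <- dat$counterfactual
  for (pol in c("NO2", "PM2.5")) {
    ub <- st[st$pollutant == pol & st$category == "urban background" &
               lubridate::year(st$date) == 2020, ]
    cfub <- cf[cf$pollutant == pol & grepl("UB", cf$station_id), ]
    expect_equal(relative_change(mean(ub$value), mean(cfub$value)),
                 truth$realized_annual_suppression[[pol]][[ub$station_id[1]]])
  }
  # NO2 is suppressed more than PM2.5 (stronger coupling), traffic more than background
  s_no2 <- unlist(truth$realized_annual_suppression$NO2)
  s_pm <- unlist(truth$realized_annual_suppression$PM2.5)
  expect_lt(mean(s_no2), mean(s_pm))
  expect_lt(s_no2[grep("TR", names(s_no2))], s_no2[grep("UB", names(s_no2))])

  # zero coupling: 2020 equals the counterfactual continuation exactly
  sc0 <- test_scenario(seed = 75, no2_coupling = 0, pm25_coupling = 0)
  dat0 <- gen_city_data(sc0)
  expect_true(all(abs(unlist(dat0$truth$realized_annual_suppression)) < 1e-10))

  # uniform mode: realized annual suppression is exactly -100 * s
  scu <- test_scenario(seed = 76, suppression_mode = "uniform",
                       no2_coupling = 0.3)
  datu <- gen_city_data(scu)
  expect_equal(datu$truth$realized_annual_suppression$NO2[[1]], -30,
               tolerance = 1e-10)
})

test_that("written scenarios round-trip through the readers with ground truth", {
  dir <- withr::local_tempdir()
  sc <- test_scenario(seed = 77)
  paths <- write_scenario(sc, dir)
  expect_true(all(file.exists(unlist(paths))))

  dat <- gen_city_data(sc)
  mob <- read_mobility_csv(paths$mobility)
  expect_equal(mob$index, dplyr::arrange(dat$mobility, region, mode, date)$index)
  st <- read_station_csv(paths$stations)
  expect_equal(nrow(st), nrow(dat$stations))
  wx <- read_weather_csv(paths$weather)
  expect_equal(wx$temperature, dat$weather$temperature)

  gt <- yaml::read_yaml(paths$truth)
  expect_equal(gt$coupling$NO2, 0.25)
  expect_equal(gt$seed, 77)
  expect_true(!is.null(gt$realized_annual_suppression$NO2))
})
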