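make_stations <- function(values_by_station, start = "2020-01-01",
                          categories = NULL) {
  if (is.null(categories)) {
    categories <- setNames(rep("urban background", length(values_by_station)),
                           names(values_by_station))
  }
  purrr::list_rbind(purrr::imap(values_by_station, function(v, id) {
    tibble::tibble(station_id = id, city = "X", category = categories[[id]],
                   pollutant = "NO2",
                   date = seq(as.Date(start), by = "day", length.out = length(v)),
                   value = v)
  }))
}

test_that("city daily mean averages stations available on each date", {
  st <- make_stations(list(S1 = c(10, 10), S2 = c(20, NA)))
  s <- city_daily_mean(st, "all")
  expect_equal(s$value, c(15, 10)) # available-case mean on day 2

  # single station in scope equals that station's series
  st2 <- make_stations(list(S1 = runif(5, 10, 30)))
  expect_equal(city_daily_mean(st2, "all")$value, st2$value)

  # no station in urban-background scope
  st3 <- make_stations(list(S1 = 1:3), categories = c(S1 = "urban traffic"))
  expect_error(city_daily_mean(st3, "urban_background"), "scope")
})

test_that("period means respect windows and coverage", {
  s <- daily_series("2020-01-01", rep(25.3, 366))
  expect_equal(period_mean(s, baseline_window("2020-01-01", "2020-12-31")), 25.3)
  expect_equal(period_mean(daily_series("2020-01-01", c(4, 6)),
                           baseline_window("2020-01-01", "2020-01-02")), 5)
  expect_error(period_mean(s, baseline_window("2021-01-01", "2021-01-10")),
               "coverage", class = "airshift_coverage_error")
})

test_that("relative change reproduces reported-table arithmetic and identities", {
  expect_equal(round_percent(relative_change(25.3, 31.9)), -21)
  expect_equal(round_percent(relative_change(9.2, 8.6)), 7)
  expect_equal(relative_change(10, 10), 0)
  expect_error(relative_change(10, 0), "positive")

  # sign antisymmetry with the exact rescaling rc(a,b) = -rc(b,a) * a / b
  withr::with_seed(1, {
    a <- runif(50, 1, 50)
    b <- runif(50, 1, 50)
    expect_equal(relative_change(a, b), -relative_change(b, a) * a / b)
  })
})

test_that("percent rounding is half away from zero", {
  expect_equal(round_percent(c(-20.5, 20.5, -0.4, 0.4, -0.5)), c(-21, 21, 0, 0, -1))
})

test_that("multi-year baselines average period means across years", {
  # 10 identical years at 30
  years <- 2010:2019
  s <- purrr::list_rbind(purrr::map(years, function(y) {
    daily_series(sprintf("%d-01-01", y),
                 rep(30, ifelse(lubridate::leap_year(y), 366, 365)))
  }))
  win <- baseline_window("2020-03-23", "2020-05-10")
  expect_equal(multi_year_baseline(s, years, win), 30)

  # 2 years at 20 and 40
  s2 <- dplyr::bind_rows(
    daily_series("2018-01-01", rep(20, 365)),
    daily_series("2019-01-01", rep(40, 365))
  )
  expect_equal(multi_year_baseline(s2, 2018:2019, win), 30)

  # declining trend -1 ug/m3/yr: baseline equals value at the midpoint year
  s3 <- purrr::list_rbind(purrr::map(years, function(y) {
    daily_series(sprintf("%d-01-01", y),
                 rep(30 - (y - 2010), ifelse(lubridate::leap_year(y), 366, 365)))
  }))
  expect_equal(multi_year_baseline(s3, years, win), 30 - 4.5)

  expect_error(multi_year_baseline(s3, 1990:1991, win), "baseline",
               class = "airshift_coverage_error")
})

test_that("day-of-year baseline pools 29 February with 28 February", {
  s <- dplyr::bind_rows(
    daily_series("2019-01-01", rep(10, 365)), # non-leap
    daily_series("2020-01-01", rep(20, 366))  # leap
  )
  b <- multi_year_baseline(s, 2019:2020)
  expect_false("02-29" %in% b$mmdd)
  feb28 <- b$value[b$mmdd == "02-28"]
  expect_equal(feb28, 50 / 3) # (10 from 2019) + (20 + 20 from 2020) over 3 days
  expect_equal(b$value[b$mmdd == "03-01"], 15)
})

test_that("weekly aggregation uses Monday weeks and drops sparse weeks", {
  s <- daily_series("2020-01-06", rep(5, 28)) # starts a Monday
  w <- weekly_aggregate(s)
  expect_equal(w$value, rep(5, 4))
  expect_true(all(lubridate::wday(w$week_start, week_start = 1) == 1))

  # 7 days 1..7 -> mean 4
  expect_equal(weekly_aggregate(daily_series("2020-01-06", 1:7))$value, 4)

  # a week with only 3 present days is dropped
  s2 <- daily_series("2020-01-06", c(1, 2, 3, rep(NA, 4), rep(5, 7)))
  w2 <- weekly_aggregate(s2)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$value, 5)
})

test_that("five-year reference supports plain mean and extrapolated trend", {
  am <- tibble::tibble(year = 2015:2019, value = c(40, 38, 36, 34, 32))
  expect_equal(five_year_reference(am, "mean"), 36)
  expect_equal(five_year_reference(am, "trend"), 30) # exact linear continuation
})
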