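# Shared fixtures, built in code at test time.

# A compact scenario for unit tests: fewer years, same structure.
test_scenario <- function(seed = 101, ...) {
  sc <- city_scenario(seed = seed, ...)
  sc$years <- 2015:2020
  sc
}

# Write a minimal wide mobility CSV and return its path.
write_mobility_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                   values = NULL, dates = NULL) {
  if (is.null(dates)) dates <- as.character(seq(as.Date("2020-01-13"), by = "day", length.out = 5))
  if (is.null(values)) {
    values <- matrix(c(1, 1.1, 1.2, 1.05, 0.95,
                       1, 0.9, 0.95, 1.0, 1.05,
                       1, 1.0, 1.1, 1.15, 0.9), nrow = 3, byrow = TRUE)
  }
  df <- data.frame(region = "Testville",
                   transportation_type = c("driving", "transit", "walking"),
                   check.names = FALSE)
  for (j in seq_along(dates)) df[[dates[j]]] <- values[, j]
  path <- file.path(dir, "mobility.csv")
  readr::write_csv(df, path, na = "")
  path
}

# Long station CSV fixture.
write_station_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                  rows = NULL) {
  if (is.null(rows)) {
    dates <- as.character(seq(as.Date("2020-01-01"), by = "day", length.out = 10))
    rows <- rbind(
      data.frame(station_id = "S1", city = "Testville", category = "urban background",
                 pollutant = "NO2", date = dates, value = 20 + seq_along(dates)),
      data.frame(station_id = "S2", city = "Testville", category = "urban traffic",
                 pollutant = "NO2", date = dates, value = 30 + seq_along(dates))
    )
  }
  path <- file.path(dir, "stations.csv")
  readr::write_csv(rows, path, na = "")
  path
}

# Daily series tibble helper.
daily_series <- function(start, values) {
  tibble::tibble(date = seq(as.Date(start), by = "day", length.out = length(values)),
                 value = values)
}

# Raw mobility series helper (date + index).
raw_series <- function(start, index) {
  tibble::tibble(date = seq(as.Date(start), by = "day", length.out = length(index)),
                 index = index)
}
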