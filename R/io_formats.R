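# Readers and writers for the three tabular dialects the pipeline touches:
# wide provider mobility CSVs, long monitoring-station CSVs and daily weather
# CSVs, plus result tables with a YAML metadata sidecar.

MOBILITY_MODES <- c("driving", "transit", "walking")

STATION_CATEGORIES <- c(
  "rural background", "suburban background", "suburban industrial",
  "urban background", "urban industrial", "urban traffic"
)

POLLUTANTS <- c("NO2", "PM2.5")

WEATHER_VARS <- c("temperature", "precipitation", "wind_speed")

is_date_col <- function(x) grepl("^\\d{4}-\\d{2}-\\d{2}$", x)

parse_numeric_cells <- function(x, rows, col, path) {
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop_parse(sprintf(
      "non-numeric cell in '%s': row %d, column '%s' (value '%s')",
      path, rows[bad[1]], col, x[bad[1]]
    ))
  }
  out
}

#' Read a wide provider-style mobility CSV
#'
#' Parses the wide dialect used by public mobility snapshots: one row per
#' region and transportation type, leading metadata columns, then one column
#' per ISO date holding a dimensionless direction-request index (1.0 on the
#' provider's reference day). Snapshots exist both on the unit scale and as
#' percentages of the reference day; `scale = "percent"` divides by 100 so
#' stored indices are always on the unit scale.
#'
#' @param path Path to the CSV file.
#' @param scale Either `"unit"` (default; values stored as-is) or `"percent"`
#'   (values divided by 100).
#' @return A tibble with columns `region`, `mode`, `date`, `index`, one row per
#'   region x mode x day. Empty cells become `NA` (a warning reports how many).
#' @export
read_mobility_csv <- function(path, scale = c("unit", "percent")) {
  scale <- rlang::arg_match(scale)
  if (!file.exists(path)) stop_format(sprintf("file not found: '%s'", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  for (col in c("region", "transportation_type")) {
    if (!col %in% names(raw)) {
      stop_format(sprintf("malformed mobility header in '%s': missing column '%s'", path, col))
    }
  }
  date_cols <- names(raw)[is_date_col(names(raw))]
  if (length(date_cols) == 0) {
    stop_format(sprintf("malformed mobility header in '%s': no ISO date columns", path))
  }
  bad_mode <- setdiff(unique(raw$transportation_type), MOBILITY_MODES)
  if (length(bad_mode) > 0) {
    stop_validation(sprintf(
      "unknown transportation_type '%s'; allowed: %s",
      bad_mode[1], paste(MOBILITY_MODES, collapse = ", ")
    ))
  }
  long <- tidyr::pivot_longer(raw[, c("region", "transportation_type", date_cols)],
                              cols = dplyr::all_of(date_cols),
                              names_to = "date", values_to = "index")
  idx <- parse_numeric_cells(long$index, seq_len(nrow(long)), "index", path)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    warn(sprintf("'%s': %d empty mobility cell(s) stored as missing", path, n_missing))
  }
  if (scale == "percent") idx <- idx / 100
  if (any(idx <= 0, na.rm = TRUE)) {
    stop_validation("mobility indices must be strictly positive where present")
  }
  out <- tibble::tibble(
    region = long$region,
    mode = long$transportation_type,
    date = as_iso_date(long$date),
    index = idx
  )
  dplyr::arrange(out, .data$region, .data$mode, .data$date)
}

#' Write a mobility table back to the wide provider dialect
#'
#' @param x Tibble as returned by [read_mobility_csv()].
#' @param path Output path.
#' @param scale `"unit"` or `"percent"` (multiplies by 100 on write).
#' @return `path`, invisibly.
#' @export
write_mobility_csv <- function(x, path, scale = c("unit", "percent")) {
  scale <- rlang::arg_match(scale)
  vals <- if (scale == "percent") x$index * 100 else x$index
  wide <- tidyr::pivot_wider(
    tibble::tibble(region = x$region, transportation_type = x$mode,
                   date = as.character(x$date), index = vals),
    names_from = "date", values_from = "index"
  )
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' Read a long monitoring-station CSV
#'
#' Long dialect with columns `station_id`, `city`, `category`, `pollutant`,
#' `date`, `value` (daily mean concentration in ug/m3). Station categories must
#' come from the six monitoring-network classes; duplicate (station, pollutant,
#' date) rows and negative concentrations are rejected.
#'
#' @param path Path to the CSV file.
#' @return Tibble with one row per station x pollutant x day, sorted.
#' @export
read_station_csv <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: '%s'", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  required <- c("station_id", "city", "category", "pollutant", "date", "value")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_format(sprintf("malformed station header in '%s': missing column '%s'",
                        path, missing[1]))
  }
  bad_cat <- setdiff(unique(raw$category), STATION_CATEGORIES)
  if (length(bad_cat) > 0) {
    stop_validation(sprintf(
      "unknown station category '%s'; allowed categories: %s",
      bad_cat[1], paste(STATION_CATEGORIES, collapse = ", ")
    ))
  }
  bad_pol <- setdiff(unique(raw$pollutant), POLLUTANTS)
  if (length(bad_pol) > 0) {
    stop_validation(sprintf("unknown pollutant '%s'; allowed: %s",
                            bad_pol[1], paste(POLLUTANTS, collapse = ", ")))
  }
  value <- parse_numeric_cells(raw$value, seq_len(nrow(raw)), "value", path)
  if (any(value < 0, na.rm = TRUE)) {
    i <- which(value < 0)[1]
    stop_validation(sprintf("negative concentration (%g) at row %d of '%s'",
                            value[i], i, path))
  }
  out <- tibble::tibble(
    station_id = raw$station_id, city = raw$city, category = raw$category,
    pollutant = raw$pollutant, date = as_iso_date(raw$date), value = value
  )
  key <- paste(out$station_id, out$pollutant, out$date)
  if (anyDuplicated(key)) {
    stop_validation(sprintf("duplicate (station, pollutant, date) rows for key '%s'",
                            key[duplicated(key)][1]))
  }
  dplyr::arrange(out, .data$station_id, .data$pollutant, .data$date)
}

#' @rdname read_station_csv
#' @param x Tibble as returned by [read_station_csv()].
#' @param path Output path.
#' @export
write_station_csv <- function(x, path) {
  out <- dplyr::mutate(x, date = as.character(.data$date))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a daily weather CSV
#'
#' Long dialect with columns `city`, `date`, `temperature` (deg C) and,
#' optionally, `precipitation` (mm) and `wind_speed`. A city-wide absent
#' meteorological variable (a column missing entirely) is permitted; the
#' downstream counterfactual feature set then shrinks accordingly.
#'
#' @param path Path to the CSV file.
#' @return Tibble with one row per city x day; attribute `"absent_vars"` lists
#'   weather variables not present in the file.
#' @export
read_weather_csv <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: '%s'", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  for (col in c("city", "date", "temperature")) {
    if (!col %in% names(raw)) {
      stop_format(sprintf("malformed weather header in '%s': missing column '%s'", path, col))
    }
  }
  present <- intersect(WEATHER_VARS, names(raw))
  absent <- setdiff(WEATHER_VARS, present)
  out <- tibble::tibble(city = raw$city, date = as_iso_date(raw$date))
  for (v in present) {
    out[[v]] <- parse_numeric_cells(raw[[v]], seq_len(nrow(raw)), v, path)
  }
  if (any(!is.finite(out$temperature) & !is.na(out$temperature))) {
    stop_validation("temperature must be finite where present")
  }
  for (v in intersect(c("precipitation", "wind_speed"), present)) {
    if (any(out[[v]] < 0, na.rm = TRUE)) {
      stop_validation(sprintf("%s must be non-negative", v))
    }
  }
  out <- dplyr::arrange(out, .data$city, .data$date)
  attr(out, "absent_vars") <- absent
  out
}

#' @rdname read_weather_csv
#' @param x Tibble as returned by [read_weather_csv()].
#' @param path Output path.
#' @export
write_weather_csv <- function(x, path) {
  out <- dplyr::mutate(x, date = as.character(.data$date))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write a result table with a YAML metadata sidecar
#'
#' Result CSVs are accompanied by `<path>.meta.yaml` recording a content hash
#' of the configuration, the seed and the date range covered, so every output
#' can be traced back to the run that produced it.
#'
#' @param x Data frame to write.
#' @param path Output CSV path.
#' @param meta Named list of run metadata (e.g. `config`, `seed`).
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path, meta = list()) {
  readr::write_csv(dplyr::mutate(x, dplyr::across(dplyr::where(
    function(col) inherits(col, "Date")), as.character)), path, na = "")
  side <- list(
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rows = nrow(x),
    config_hash = rlang::hash(meta)
  )
  side <- c(side, meta)
  if ("date" %in% names(x) && nrow(x) > 0) {
    side$date_range <- as.character(range(x$date))
  }
  yaml::write_yaml(side, paste0(path, ".meta.yaml"))
  invisible(path)
}
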