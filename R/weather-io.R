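# Reading, validating, writing and simulating daily weather series.
#
# The on-disk dialect follows SILO patched-point exports: one row per
# location-day with minimum/maximum temperature (degC), solar radiation
# (MJ m-2 day-1) and, optionally, rain (mm) and vapour pressure (hPa).

WEATHER_CANONICAL <- c("date", "tmin", "tmax", "radiation", "rain", "vp")
WEATHER_MANDATORY <- c("date", "tmin", "tmax", "radiation")

#' Construct and validate a daily weather series
#'
#' A `weather_series` is a tibble with one row per day and columns `date`
#' (class `Date`), `tmin`, `tmax` (degC), `radiation` (MJ m-2 day-1) and
#' optionally `rain` (mm) and `vapour_pressure` (hPa), carrying its
#' `location_id` as an attribute. Validation enforces strictly increasing,
#' gap-free dates, `tmin <= tmax` on every day, non-negative radiation and
#' rain, and strictly positive vapour pressure where present.
#'
#' @param data Data frame with at least `date`, `tmin`, `tmax`, `radiation`;
#'   optionally `rain` and `vapour_pressure`.
#' @param location_id Single string naming the station/site.
#' @return A validated `weather_series` tibble.
#' @examples
#' wx <- weather_series(
#'   data.frame(date = as.Date("2021-01-01") + 0:2,
#'              tmin = c(20, 21, 22), tmax = c(30, 31, 32),
#'              radiation = c(25, 24, 26)),
#'   location_id = "gatton")
#' location_id(wx)
#' @export
weather_series <- function(data, location_id = "unknown") {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing_cols <- setdiff(WEATHER_MANDATORY, names(data))
  if (length(missing_cols)) {
    abort(sprintf("weather data lacks mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(data[intersect(
    c("date", "tmin", "tmax", "radiation", "rain", "vapour_pressure"),
    names(data))])
  out$date <- as.Date(out$date)
  attr(out, "location_id") <- as.character(location_id)
  class(out) <- c("weather_series", class(tibble::tibble()))
  validate_weather_series(out)
}

#' @rdname weather_series
#' @param x A `weather_series`.
#' @export
location_id <- function(x) attr(x, "location_id")

#' Validate weather-series invariants
#'
#' @param x A `weather_series` (or coercible data frame).
#' @return `x` invisibly on success; aborts with a descriptive message on
#'   the first violated invariant.
#' @export
validate_weather_series <- function(x) {
  if (nrow(x) > 0) {
    if (anyNA(x$date)) abort("weather series contains missing dates.")
    d <- diff(as.integer(x$date))
    if (any(d <= 0)) {
      abort("weather series dates must be strictly increasing with no duplicates.")
    }
    if (any(d > 1)) {
      gap_after <- x$date[which(d > 1)]
      abort(sprintf("weather series has date gap(s) after: %s",
                    paste(format(gap_after), collapse = ", ")))
    }
    bad <- !is.na(x$tmin) & !is.na(x$tmax) & x$tmin > x$tmax
    if (any(bad)) {
      abort(sprintf("tmin > tmax on: %s",
                    paste(format(x$date[bad]), collapse = ", ")))
    }
    if (any(x$radiation < 0, na.rm = TRUE)) {
      abort("radiation must be >= 0.")
    }
    if ("rain" %in% names(x) && any(x$rain < 0, na.rm = TRUE)) {
      abort("rain must be >= 0 when present.")
    }
    if ("vapour_pressure" %in% names(x) &&
        any(x$vapour_pressure <= 0, na.rm = TRUE)) {
      abort("vapour_pressure must be > 0 when present.")
    }
  }
  invisible(x)
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> location '%s', %d day(s)", location_id(x),
              nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf(", %s to %s", format(x$date[1]), format(x$date[nrow(x)])))
  }
  cat("\n")
  NextMethod()
}

# Parse a character date column in either ISO (2021-02-19) or SILO compact
# (20210219) form; the two dialects may not be mixed within one file.
parse_weather_dates <- function(raw) {
  raw <- trimws(as.character(raw))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", raw)
  silo <- grepl("^\\d{8}$", raw)
  if (any(iso) && any(silo)) {
    abort("mixed date dialects (ISO and YYYYMMDD) within one file.")
  }
  fmt <- if (all(silo) && length(raw) > 0) "%Y%m%d" else "%Y-%m-%d"
  parsed <- as.Date(raw, format = fmt)
  if (anyNA(parsed)) {
    lines <- which(is.na(parsed)) + 1L  # +1 for the header row
    abort(sprintf("unparsable date(s) at file line(s): %s",
                  paste(lines, collapse = ", ")))
  }
  parsed
}

#' Read a daily weather CSV in a SILO-like dialect
#'
#' Mandatory columns are `date`, `tmin`, `tmax` and `radiation`; `rain` and
#' `vp` (vapour pressure) are optional. Other columns (SILO quality codes,
#' evaporation, ...) are ignored. Column names in the file may differ from
#' the canonical ones via `dialect`, a named character map from canonical
#' name to file column name, e.g. `c(tmin = "min_temp")`. Dates may be ISO
#' `YYYY-MM-DD` or SILO compact `YYYYMMDD` (auto-detected per file; mixing
#' the two is an error).
#'
#' @param path CSV file path.
#' @param dialect Named character vector remapping canonical column names to
#'   the file's column names; omitted entries default to the canonical name.
#' @param location_id Station identifier to attach; defaults to the file
#'   name without extension.
#' @return A validated [weather_series()].
#' @seealso [write_weather_csv()], [simulate_weather()]
#' @export
read_weather_csv <- function(path, dialect = NULL, location_id = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  location_id <- location_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  lookup <- setNames(WEATHER_CANONICAL, WEATHER_CANONICAL)
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), WEATHER_CANONICAL)
    if (length(unknown)) {
      abort(sprintf("dialect maps unknown canonical column(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    lookup[names(dialect)] <- dialect
  }
  missing_cols <- WEATHER_MANDATORY[!lookup[WEATHER_MANDATORY] %in% names(raw)]
  if (length(missing_cols)) {
    abort(sprintf("weather CSV is missing mandatory column(s): %s",
                  paste(lookup[missing_cols], collapse = ", ")))
  }
  out <- data.frame(date = parse_weather_dates(raw[[lookup[["date"]]]]))
  for (col in c("tmin", "tmax", "radiation")) {
    out[[col]] <- as.numeric(raw[[lookup[[col]]]])
  }
  if (lookup[["rain"]] %in% names(raw)) {
    out$rain <- as.numeric(raw[[lookup[["rain"]]]])
  }
  if (lookup[["vp"]] %in% names(raw)) {
    out$vapour_pressure <- as.numeric(raw[[lookup[["vp"]]]])
  }
  if (anyNA(out[c("tmin", "tmax", "radiation")])) {
    abort("missing daily values in tmin/tmax/radiation; gap-filling is not supported.")
  }
  weather_series(out, location_id = location_id)
}

#' Write a weather series to CSV with canonical columns
#'
#' Writes ISO dates and the canonical column names (`date`, `tmin`, `tmax`,
#' `radiation`, and `rain`/`vp` when populated), losslessly at full double
#' precision so [read_weather_csv()] round-trips the series.
#'
#' @param series A [weather_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(series, path) {
  validate_weather_series(series)
  out <- as.data.frame(series)
  out$date <- format(out$date, "%Y-%m-%d")
  if ("vapour_pressure" %in% names(out)) {
    names(out)[names(out) == "vapour_pressure"] <- "vp"
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort(sprintf("cannot write '%s': %s", path,
                                 conditionMessage(ok)))
  invisible(path)
}

#' Parameters of the synthetic Queensland-style weather generator
#'
#' Defaults emulate a subtropical south-east Queensland site: a sinusoidal
#' annual cycle peaking in mid-January (southern-hemisphere summer,
#' `peak_day_of_year = 15`) with daily Gaussian noise. Daily maxima average
#' 27 degC with +/- 6.5 degC seasonal swing, minima run about 10.5 degC
#' below maxima, and daily solar radiation averages 19 MJ m-2 with a
#' 7 MJ m-2 swing.
#'
#' @param mean_tmax Annual mean of daily maximum temperature (degC).
#' @param annual_amplitude Seasonal half-range of the temperature cycle (degC).
#' @param tmin_offset Mean gap between tmax and tmin (degC).
#' @param noise_sd Standard deviation of daily Gaussian noise (degC; also
#'   used, in MJ m-2, for radiation noise).
#' @param mean_radiation Annual mean daily solar radiation (MJ m-2).
#' @param radiation_amplitude Seasonal half-range of radiation (MJ m-2).
#' @param peak_day_of_year Day of year at which the cycles peak (1-366).
#' @param seed Integer RNG seed; identical parameters give identical series.
#' @return A `synthetic_weather_params` list.
#' @export
weather_params <- function(mean_tmax = 27, annual_amplitude = 6.5,
                           tmin_offset = 10.5, noise_sd = 2,
                           mean_radiation = 19, radiation_amplitude = 7,
                           peak_day_of_year = 15L, seed = 1L) {
  check_number(annual_amplitude, "annual_amplitude", lower = 0)
  check_number(radiation_amplitude, "radiation_amplitude", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(peak_day_of_year, "peak_day_of_year", lower = 1, upper = 366)
  check_number(mean_tmax, "mean_tmax")
  check_number(tmin_offset, "tmin_offset")
  check_number(mean_radiation, "mean_radiation")
  check_number(seed, "seed")
  structure(list(mean_tmax = mean_tmax, annual_amplitude = annual_amplitude,
                 tmin_offset = tmin_offset, noise_sd = noise_sd,
                 mean_radiation = mean_radiation,
                 radiation_amplitude = radiation_amplitude,
                 peak_day_of_year = as.integer(peak_day_of_year),
                 seed = as.integer(seed)),
            class = "synthetic_weather_params")
}

#' Simulate a synthetic daily weather series
#'
#' Generates `tmax(d) = mean_tmax + annual_amplitude * cos(2 * pi * (doy(d) -
#' peak_day_of_year) / 365.25) + e`, with `e ~ N(0, noise_sd^2)`;
#' `tmin = tmax - tmin_offset + e'` (independent noise), clamped so
#' `tmin <= tmax`; radiation follows the analogous sinusoid, clamped at
#' 0.1 MJ m-2. Vapour pressure is derived from tmin via the Magnus
#' saturation formula (treating the overnight minimum as a dew-point proxy)
#' and rain is an independent wet-day (30 percent) gamma process, so
#' feature building on vapour-pressure and rain windows can be exercised
#' offline. The function is pure: the caller's RNG state is untouched and
#' identical `(params, start, n_days)` give identical series.
#'
#' @param params A [weather_params()] object.
#' @param start First date of the series.
#' @param n_days Number of consecutive days (>= 1).
#' @param location_id Station identifier for the resulting series.
#' @return A validated [weather_series()] of `n_days` rows.
#' @examples
#' wx <- simulate_weather(weather_params(seed = 42),
#'                        start = as.Date("2015-07-01"), n_days = 30)
#' mean(wx$tmax)
#' @export
simulate_weather <- function(params = weather_params(),
                             start = as.Date("2012-07-01"),
                             n_days = 3650, location_id = "synthetic") {
  if (!inherits(params, "synthetic_weather_params")) {
    abort("`params` must come from weather_params().")
  }
  check_number(n_days, "n_days", lower = 1)
  start <- as_scalar_date(start, "start")
  n_days <- as.integer(n_days)
  dates <- start + 0:(n_days - 1L)
  doy <- as.integer(format(dates, "%j"))
  phase <- 2 * pi * (doy - params$peak_day_of_year) / 365.25
  with_local_seed(params$seed, {
    tmax <- params$mean_tmax + params$annual_amplitude * cos(phase) +
      rnorm(n_days, 0, params$noise_sd)
    tmin <- tmax - params$tmin_offset + rnorm(n_days, 0, params$noise_sd)
    tmin <- pmin(tmin, tmax)
    radiation <- pmax(0.1, params$mean_radiation +
                        params$radiation_amplitude * cos(phase) +
                        rnorm(n_days, 0, params$noise_sd))
    # Magnus saturation vapour pressure (hPa) at the dew-point proxy tmin.
    vp <- 6.112 * exp(17.62 * tmin / (243.12 + tmin))
    wet <- runif(n_days) < 0.3
    rain <- ifelse(wet, rgamma(n_days, shape = 0.8, scale = 12), 0)
    weather_series(
      data.frame(date = dates, tmin = tmin, tmax = tmax,
                 radiation = radiation, rain = rain,
                 vapour_pressure = pmax(vp, 0.1)),
      location_id = location_id)
  })
}
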