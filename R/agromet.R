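# Phenology-anchored agro-meteorological derivations: growing degree days,
# stress days and windowed weather statistics.

#' Degree-day truncation rule
#'
#' Thermal time is accumulated as growing degree days with a base
#' temperature below which no development is counted and a cap applied to
#' the daily maximum, the convention used for field-grown beans (base 5
#' degC, cap 30 degC). The daily maximum is capped *before* averaging with
#' the minimum; negative daily values truncate to zero; the minimum is not
#' floored at the base.
#'
#' @param t_base Base temperature (degC), default 5.
#' @param t_cap Cap applied to the daily maximum (degC), default 30.
#' @return A `degree_day_rule` list.
#' @export
degree_day_rule <- function(t_base = 5, t_cap = 30) {
  check_number(t_base, "t_base")
  check_number(t_cap, "t_cap")
  if (t_base >= t_cap) abort("`t_base` must be strictly below `t_cap`.")
  structure(list(t_base = t_base, t_cap = t_cap), class = "degree_day_rule")
}

#' Daily growing degree days
#'
#' `max(0, (min(tmax, t_cap) + tmin) / 2 - t_base)` per day (degC d).
#' Vectorised over `tmin`/`tmax`.
#'
#' @param tmin,tmax Daily minimum/maximum temperature (degC); `tmin <= tmax`.
#' @param rule A [degree_day_rule()].
#' @return Degree days (degC d), one value per day.
#' @examples
#' daily_degree_day(15, 35)  # capped at 30: (30 + 15)/2 - 5 = 17.5
#' @export
daily_degree_day <- function(tmin, tmax, rule = degree_day_rule()) {
  if (length(tmin) != length(tmax)) {
    abort("`tmin` and `tmax` must have equal length.")
  }
  if (any(tmin > tmax, na.rm = TRUE)) {
    abort("`tmin` must not exceed `tmax`.")
  }
  pmax(0, (pmin(tmax, rule$t_cap) + tmin) / 2 - rule$t_base)
}

#' An inclusive calendar date window
#'
#' @param start,end First and last date (both inclusive); `start <= end`.
#' @return A `date_window` list with `start`, `end` and `n_days`.
#' @export
date_window <- function(start, end) {
  start <- as_scalar_date(start, "start")
  end <- as_scalar_date(end, "end")
  if (start > end) {
    abort(sprintf("window start (%s) is after end (%s).",
                  format(start), format(end)))
  }
  structure(list(start = start, end = end,
                 n_days = as.integer(end - start) + 1L),
            class = "date_window")
}

# Rows of `series` inside `window`, erroring if any window day is absent.
window_rows <- function(series, window, context = "window") {
  wanted <- seq(window$start, window$end, by = "day")
  idx <- match(wanted, series$date)
  if (anyNA(idx)) {
    miss <- wanted[is.na(idx)]
    show <- paste(format(head(miss, 5)), collapse = ", ")
    if (length(miss) > 5) show <- paste0(show, ", ...")
    abort(sprintf("%s not covered by weather series '%s': missing %d day(s) (%s)",
                  context, location_id(series) %||% "?", length(miss), show))
  }
  series[idx, , drop = FALSE]
}

#' Growing degree days over a window
#'
#' Sum of [daily_degree_day()] over every day of the inclusive window.
#'
#' @param series A [weather_series()] covering the window.
#' @param window A [date_window()].
#' @param rule A [degree_day_rule()].
#' @return Accumulated thermal time (degC d).
#' @export
growing_degree_days <- function(series, window, rule = degree_day_rule()) {
  rows <- window_rows(series, window, "degree-day window")
  sum(daily_degree_day(rows$tmin, rows$tmax, rule))
}

#' Stress days above a temperature threshold
#'
#' Number of days in the window whose maximum temperature strictly exceeds
#' `threshold`. The thresholds associated with flower/pod abortion in beans
#' are 27.5 and 30 degC.
#'
#' @inheritParams growing_degree_days
#' @param threshold Temperature threshold (degC), strict `>` comparison.
#' @return Integer count of stress days.
#' @export
stress_days <- function(series, window, threshold) {
  check_number(threshold, "threshold")
  rows <- window_rows(series, window, "stress-day window")
  sum(rows$tmax > threshold)
}

#' Windowed statistic of a weather variable
#'
#' `tmean` is the day-wise `(tmin + tmax) / 2`; the statistic is then
#' applied over the days of the window.
#'
#' @inheritParams growing_degree_days
#' @param variable One of `"tmin"`, `"tmax"`, `"tmean"`, `"radiation"`,
#'   `"vapour_pressure"`.
#' @param statistic One of `"mean"`, `"sum"`, `"min"`, `"max"`.
#' @return The statistic, in the variable's units.
#' @export
window_stat <- function(series, window,
                        variable = c("tmin", "tmax", "tmean", "radiation",
                                     "vapour_pressure"),
                        statistic = c("mean", "sum", "min", "max")) {
  variable <- match.arg(variable)
  statistic <- match.arg(statistic)
  rows <- window_rows(series, window, sprintf("window for %s", variable))
  values <- if (variable == "tmean") {
    (rows$tmin + rows$tmax) / 2
  } else {
    if (!variable %in% names(rows)) {
      abort(sprintf("variable '%s' absent from weather series '%s'.",
                    variable, location_id(series) %||% "?"))
    }
    rows[[variable]]
  }
  if (anyNA(values)) {
    abort(sprintf("variable '%s' has missing values inside the window.",
                  variable))
  }
  switch(statistic,
         mean = mean(values), sum = sum(values),
         min = min(values), max = max(values))
}

#' Day of the Australian financial year
#'
#' Ordinal day with 1 July = 1, used to encode sowing date on a scale that
#' is continuous across the southern-hemisphere growing seasons. Range
#' 1..366 (366 only in financial years containing 29 February).
#'
#' @param d A `Date` vector.
#' @return Integer day-of-financial-year for each date.
#' @examples
#' day_of_financial_year(as.Date("2020-07-01"))  # 1
#' day_of_financial_year(as.Date("2021-02-19"))  # 234
#' @export
day_of_financial_year <- function(d) {
  d <- as.Date(d)
  yr <- as.integer(format(d, "%Y"))
  mo <- as.integer(format(d, "%m"))
  fy_start <- as.Date(sprintf("%d-07-01", ifelse(mo >= 7, yr, yr - 1L)))
  as.integer(d - fy_start) + 1L
}

#' Declarative phenology-anchored window specification
#'
#' Windows are anchored at a phenology date (`sowing`, `petal_fall` or
#' `harvest`) and either run to another anchor (`mode = "to_anchor"`) or
#' span a fixed number of days before/after the anchor
#' (`mode = "fixed_days"`). Anchor-to-anchor windows exclude the start
#' anchor day and include the end anchor day, so the window length equals
#' the plain date difference used for growth durations. Fixed windows
#' after an anchor span `[anchor + 1, anchor + n]`; before an anchor,
#' `[anchor - n, anchor - 1]`.
#'
#' @param anchor One of `"sowing"`, `"petal_fall"`, `"harvest"`.
#' @param mode `"to_anchor"` or `"fixed_days"`.
#' @param end_anchor End anchor for `mode = "to_anchor"`.
#' @param n Number of days for `mode = "fixed_days"` (>= 1).
#' @param direction `"after"` or `"before"` the anchor (fixed windows only).
#' @return A `window_spec` list.
#' @examples
#' window_spec("sowing", "to_anchor", end_anchor = "petal_fall")  # vegetative
#' window_spec("petal_fall", "fixed_days", n = 5)                 # early pod fill
#' @export
window_spec <- function(anchor = c("sowing", "petal_fall", "harvest"),
                        mode = c("to_anchor", "fixed_days"),
                        end_anchor = NULL, n = NULL,
                        direction = c("after", "before")) {
  anchor <- match.arg(anchor)
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  if (mode == "to_anchor") {
    if (is.null(end_anchor) ||
        !end_anchor %in% c("sowing", "petal_fall", "harvest")) {
      abort("`end_anchor` must name a phenology anchor for mode 'to_anchor'.")
    }
    n <- NULL
  } else {
    check_number(n, "n", lower = 1)
    n <- as.integer(n)
    end_anchor <- NULL
  }
  structure(list(anchor = anchor, mode = mode, end_anchor = end_anchor,
                 n = n, direction = direction), class = "window_spec")
}

#' Resolve a window specification against one sowing's phenology dates
#'
#' @param sowing Sowing date.
#' @param petal_fall,harvest Petal-fall and harvest dates, or `NA`/`NULL`
#'   when unobserved.
#' @param spec A [window_spec()].
#' @return A [date_window()].
#' @export
resolve_window <- function(sowing, petal_fall = NULL, harvest = NULL, spec) {
  if (!inherits(spec, "window_spec")) abort("`spec` must be a window_spec.")
  anchors <- list(sowing = sowing, petal_fall = petal_fall, harvest = harvest)
  get_anchor <- function(name) {
    value <- anchors[[name]]
    if (is.null(value) || length(value) == 0 || is.na(value)) {
      abort(sprintf("window spec requires anchor '%s', which is absent.", name))
    }
    as.Date(value)
  }
  a <- get_anchor(spec$anchor)
  if (spec$mode == "to_anchor") {
    b <- get_anchor(spec$end_anchor)
    if (b <= a) {
      abort(sprintf("end anchor '%s' (%s) is not after start anchor '%s' (%s).",
                    spec$end_anchor, format(b), spec$anchor, format(a)))
    }
    date_window(a + 1, b)
  } else if (spec$direction == "after") {
    date_window(a + 1, a + spec$n)
  } else {
    date_window(a - spec$n, a - 1)
  }
}
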