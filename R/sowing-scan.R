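# Multi-year sowing-date scans: derive agro-meteorological variables for a
# grid of hypothetical sowings and summarise them as medians and
# 20th/80th percentiles by season and growth period.

#' Derive features for a grid of hypothetical sowing dates
#'
#' Builds one hypothetical crop record per (location, sowing date) over the
#' inclusive date range with the given step, assigns petal fall and harvest
#' from fixed season-specific growth durations, and runs
#' [build_feature_table()] on the grid. Sowings whose windows run past the
#' weather coverage are dropped (their count is reported in attribute
#' `n_dropped`), as are sowings with any uncomputable feature.
#'
#' @param weather Named list of [weather_series()], keyed by location_id.
#' @param from,to First and last hypothetical sowing date (inclusive).
#' @param step Days between consecutive sowing dates, default 1.
#' @param durations Either `c(vegetative = , pod_fill = )` applied to every
#'   sowing, or a named list of such vectors keyed by season label for
#'   season-specific durations.
#' @param region Region label used for season classification (`"SEQ"` or
#'   `"NEQ"`), a single value or one per location.
#' @param features Feature catalogue, see [default_feature_spec()].
#' @param rule [degree_day_rule()] for thermal-time features.
#' @return Feature table tibble (see [build_feature_table()]) with
#'   attributes `n_dropped` (rows lost to coverage/missing features) and
#'   `n_grid` (size of the full grid).
#' @export
scan_sowings <- function(weather, from, to, step = 1,
                         durations = c(vegetative = 41, pod_fill = 21),
                         region = "SEQ",
                         features = default_feature_spec(),
                         rule = degree_day_rule()) {
  from <- as_scalar_date(from, "from")
  to <- as_scalar_date(to, "to")
  if (from > to) abort("`from` must not be after `to`.")
  check_number(step, "step", lower = 1)
  if (!is.list(weather) || is.null(names(weather))) {
    abort("`weather` must be a named list of weather_series keyed by location_id.")
  }
  locations <- names(weather)
  region <- rep_len(region, length(locations))
  sow_dates <- seq(from, to, by = as.integer(step))
  grid <- expand.grid(location_id = locations, sowing = sow_dates,
                      stringsAsFactors = FALSE)
  grid$region <- region[match(grid$location_id, locations)]
  grid$record_id <- sprintf("%s_%s", grid$location_id, format(grid$sowing))
  season <- classify_season(grid)
  dur_for <- function(season_label) {
    d <- if (is.list(durations)) {
      durations[[season_label]] %||%
        abort(sprintf("no durations supplied for season '%s'.", season_label))
    } else {
      durations
    }
    if (!all(c("vegetative", "pod_fill") %in% names(d)) ||
        any(d[c("vegetative", "pod_fill")] < 1)) {
      abort("durations need positive `vegetative` and `pod_fill` entries.")
    }
    d
  }
  veg <- vapply(season, function(s) dur_for(s)[["vegetative"]], numeric(1))
  pod <- vapply(season, function(s) dur_for(s)[["pod_fill"]], numeric(1))
  grid$petal_fall <- grid$sowing + veg
  grid$harvest <- grid$petal_fall + pod
  records <- crop_records(grid)
  table <- build_feature_table(records, weather, features = features,
                               rule = rule)
  problems <- attr(table, "problems")
  feature_names <- vapply(features, `[[`, character(1), "name")
  complete <- complete.cases(table[feature_names])
  out <- table[complete, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("no hypothetical sowing has full weather coverage.")
  }
  attr(out, "problems") <- problems
  attr(out, "n_dropped") <- sum(!complete)
  attr(out, "n_grid") <- nrow(table)
  out
}

#' Grouped median and 20th/80th percentile summaries
#'
#' Order-statistic quantiles with linear interpolation between closest
#' ranks (R's default type-7 convention), computed per group for each
#' requested variable.
#'
#' @param rows Feature table (data frame), e.g. from [scan_sowings()] or
#'   [build_feature_table()].
#' @param group_by Character vector of grouping columns (e.g. `"season"`).
#' @param variables Character vector of numeric columns to summarise.
#' @param probs Probabilities, default `c(0.2, 0.5, 0.8)`.
#' @return A tibble with the group keys, `variable`, `n`, and one column
#'   per probability (`p20`, `median`, `p80` for the defaults).
#' @export
percentile_summary <- function(rows, group_by = "season", variables,
                               probs = c(0.2, 0.5, 0.8)) {
  missing_cols <- setdiff(c(group_by, variables), names(rows))
  if (length(missing_cols)) {
    abort(sprintf("unknown column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(probs < 0 | probs > 1)) abort("`probs` must be in [0, 1].")
  prob_name <- function(p) {
    if (isTRUE(all.equal(p, 0.5))) "median" else sprintf("p%02d", round(p * 100))
  }
  long <- tidyr_pivot(rows, group_by, variables)
  keys <- c(group_by, "variable")
  groups <- split(long, long[keys], drop = TRUE)
  rows_out <- lapply(groups, function(g) {
    values <- g$value[!is.na(g$value)]
    if (!length(values)) {
      abort(sprintf("group (%s) has no non-missing values.",
                    paste(unlist(g[1, keys]), collapse = ", ")))
    }
    q <- quantile(values, probs = probs, type = 7, names = FALSE)
    out <- g[1, keys, drop = FALSE]
    out$n <- length(values)
    for (i in seq_along(probs)) out[[prob_name(probs[i])]] <- q[i]
    out
  })
  tibble::as_tibble(dplyr::bind_rows(rows_out))
}

# Minimal long-format pivot (group keys + variable/value) without a tidyr
# dependency.
tidyr_pivot <- function(rows, group_by, variables) {
  pieces <- lapply(variables, function(v) {
    out <- rows[group_by]
    out$variable <- v
    out$value <- as.numeric(rows[[v]])
    out
  })
  tibble::as_tibble(dplyr::bind_rows(pieces))
}
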