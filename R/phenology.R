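# Crop records, growth durations, season classification and the
# per-sowing agro-meteorological feature table.

#' Construct and validate crop records
#'
#' One row per commercial sowing: `record_id`, `location_id`, `region`
#' (`"SEQ"` south-east Queensland or `"NEQ"` north-east Queensland),
#' `sowing`, optional `petal_fall` and `harvest` dates, optional
#' `fresh_yield` (marketable kg/ha). Date ordering
#' `sowing < petal_fall < harvest` is enforced where the dates exist.
#'
#' @param data Data frame with the columns above (missing optional columns
#'   are added as `NA`).
#' @return A validated `crop_records` tibble.
#' @export
crop_records <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  needed <- c("record_id", "location_id", "region", "sowing")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(sprintf("crop records lack column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  for (col in c("petal_fall", "harvest")) {
    if (!col %in% names(out)) out[[col]] <- as.Date(NA)
  }
  if (!"fresh_yield" %in% names(out)) out$fresh_yield <- NA_real_
  out$record_id <- as.character(out$record_id)
  out$location_id <- as.character(out$location_id)
  out$region <- as.character(out$region)
  for (col in c("sowing", "petal_fall", "harvest")) {
    out[[col]] <- as.Date(out[[col]])
  }
  out$fresh_yield <- as.numeric(out$fresh_yield)
  if (anyDuplicated(out$record_id)) abort("duplicate record_id values.")
  if (anyNA(out$sowing)) abort("every record needs a sowing date.")
  bad_order <- record_order_problems(out)
  if (any(bad_order != "")) {
    abort(sprintf("date ordering violated for record(s): %s",
                  paste(out$record_id[bad_order != ""], collapse = ", ")))
  }
  if (any(out$fresh_yield < 0, na.rm = TRUE)) {
    abort("fresh_yield must be >= 0 when present.")
  }
  class(out) <- c("crop_records", class(tibble::tibble()))
  out
}

# "" when a row's dates are ordered, else a reason string.
record_order_problems <- function(df) {
  reason <- character(nrow(df))
  pf_bad <- !is.na(df$petal_fall) & df$petal_fall <= df$sowing
  hv_bad <- (!is.na(df$harvest) & !is.na(df$petal_fall) &
               df$harvest <= df$petal_fall) |
    (!is.na(df$harvest) & df$harvest <= df$sowing)
  reason[pf_bad] <- "date ordering: petal_fall not after sowing"
  reason[hv_bad] <- "date ordering: harvest not after earlier stages"
  reason
}

#' Load crop records from CSV, collecting row-level validation problems
#'
#' Expects columns `record_id`, `location_id`, `region`, `sowing`,
#' `petal_fall`, `harvest`, `fresh_yield` (ISO dates). Rows violating the
#' date ordering `sowing < petal_fall < harvest` are rejected rather than
#' aborting the load; reasons are returned in a validation report attached
#' as the `"problems"` attribute (a tibble of `record_id`, `reason`).
#'
#' @param path CSV file path.
#' @return A `crop_records` tibble of the accepted rows, with attribute
#'   `problems`.
#' @export
load_crop_records <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) {
                    abort(sprintf("malformed crop CSV '%s': %s", path,
                                  conditionMessage(e)))
                  })
  needed <- c("record_id", "location_id", "region", "sowing")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("crop CSV is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in c("petal_fall", "harvest")) {
    if (!col %in% names(raw)) raw[[col]] <- NA
  }
  if (!"fresh_yield" %in% names(raw)) raw$fresh_yield <- NA_real_
  raw$sowing <- as.Date(as.character(raw$sowing))
  for (col in c("petal_fall", "harvest")) {
    raw[[col]] <- as.Date(as.character(raw[[col]]))
  }
  reason <- character(nrow(raw))
  reason[is.na(raw$sowing)] <- "missing or unparsable sowing date"
  ord <- record_order_problems(raw)
  reason[reason == "" & ord != ""] <- ord[reason == "" & ord != ""]
  problems <- tibble::tibble(record_id = as.character(raw$record_id)[reason != ""],
                             reason = reason[reason != ""])
  accepted <- raw[reason == "", , drop = FALSE]
  out <- crop_records(accepted)
  attr(out, "problems") <- problems
  out
}

#' Growth-period durations from phenology dates
#'
#' Plain date differences in days: vegetative = petal fall - sowing,
#' pod fill = harvest - petal fall, total = harvest - sowing. A duration
#' whose endpoint is unobserved is `NA`, never zero.
#'
#' @param records A `crop_records` tibble (or data frame with `record_id`,
#'   `sowing`, `petal_fall`, `harvest`).
#' @return A tibble with `record_id`, `vegetative`, `pod_fill`, `total`
#'   (days).
#' @examples
#' recs <- crop_records(data.frame(
#'   record_id = "a", location_id = "gatton", region = "SEQ",
#'   sowing = "2021-02-19", petal_fall = "2021-04-01",
#'   harvest = "2021-04-22"))
#' crop_durations(recs)  # vegetative 41, pod fill 21, total 62
#' @export
crop_durations <- function(records) {
  tibble::tibble(
    record_id = records$record_id,
    vegetative = as.numeric(records$petal_fall - records$sowing),
    pod_fill = as.numeric(records$harvest - records$petal_fall),
    total = as.numeric(records$harvest - records$sowing))
}

#' Default sowing-month to season map
#'
#' `NEQ` sowings are all `Middle` season. For `SEQ` the two sowing seasons
#' are split so that every calendar month classifies: January-July sowings
#' are `Autumn`, August-December are `Spring`. (Published descriptions of
#' the season boundaries differ between the narrative, Oct-Dec vs Jan-May,
#' and the observed sowing months, Aug-Nov vs Mar-May; the default map
#' covers all twelve months and is overridable.)
#'
#' @return Named character vector of length 12 mapping SEQ sowing month
#'   number to season label.
#' @export
default_season_map <- function() {
  setNames(c(rep("Autumn", 7), rep("Spring", 5)), 1:12)
}

#' Classify each sowing into a growing season
#'
#' @param records A `crop_records` tibble.
#' @param seq_month_map Month-to-season map for SEQ sowings; see
#'   [default_season_map()].
#' @return Character vector of season labels (`"Autumn"`, `"Spring"`,
#'   `"Middle"`), one per record.
#' @export
classify_season <- function(records, seq_month_map = default_season_map()) {
  region <- records$region
  unknown <- setdiff(unique(region), c("SEQ", "NEQ"))
  if (length(unknown)) {
    abort(sprintf("unknown region(s): %s", paste(unknown, collapse = ", ")))
  }
  month <- as.integer(format(records$sowing, "%m"))
  ifelse(region == "NEQ", "Middle", unname(seq_month_map[month]))
}

#' The default agro-meteorological feature catalogue
#'
#' One entry per derived variable, each a list with `name`, `kind`
#' (`"degree_days"`, `"stress"` with `threshold`, or `"stat"` with
#' `variable`/`statistic`) and a window description consumed by
#' [window_spec()]. The catalogue covers the candidate predictors used in
#' duration and yield modelling: thermal time, mean/cumulative radiation,
#' mean temperatures and vapour pressure over the vegetative, pod-fill and
#' total windows; stress-day counts above 27.5 and 30 degC (whole windows
#' and 5/15 days post petal fall); and first-7/14/28-day post-sowing
#' statistics.
#'
#' The same catalogue ships as `inst/extdata/features.yaml` and can be
#' edited and reloaded with [read_feature_spec()].
#'
#' @return A list of feature definitions.
#' @export
default_feature_spec <- function() {
  veg <- list(anchor = "sowing", mode = "to_anchor", end_anchor = "petal_fall")
  pod <- list(anchor = "petal_fall", mode = "to_anchor", end_anchor = "harvest")
  tot <- list(anchor = "sowing", mode = "to_anchor", end_anchor = "harvest")
  post_sow <- function(n) list(anchor = "sowing", mode = "fixed_days", n = n,
                               direction = "after")
  post_pf <- function(n) list(anchor = "petal_fall", mode = "fixed_days",
                              n = n, direction = "after")
  gdd <- function(name, window) list(name = name, kind = "degree_days",
                                     window = window)
  stress <- function(name, threshold, window) {
    list(name = name, kind = "stress", threshold = threshold, window = window)
  }
  stat <- function(name, variable, statistic, window) {
    list(name = name, kind = "stat", variable = variable,
         statistic = statistic, window = window)
  }
  c(
    list(gdd("thermal_time_veg", veg),
         gdd("thermal_time_pod", pod),
         gdd("thermal_time_total", tot)),
    list(
      stat("cum_radiation_veg", "radiation", "sum", veg),
      stat("avg_radiation_veg", "radiation", "mean", veg),
      stat("cum_radiation_pod", "radiation", "sum", pod),
      stat("avg_radiation_pod", "radiation", "mean", pod),
      stat("avg_tmin_veg", "tmin", "mean", veg),
      stat("avg_tmax_veg", "tmax", "mean", veg),
      stat("avg_tmean_veg", "tmean", "mean", veg),
      stat("avg_tmin_pod", "tmin", "mean", pod),
      stat("avg_tmax_pod", "tmax", "mean", pod),
      stat("avg_tmean_pod", "tmean", "mean", pod),
      stat("avg_tmin_total", "tmin", "mean", tot),
      stat("avg_vp_veg", "vapour_pressure", "mean", veg),
      stat("avg_vp_pod", "vapour_pressure", "mean", pod),
      stress("stress275_veg", 27.5, veg),
      stress("stress30_veg", 30, veg),
      stress("stress275_pod", 27.5, pod),
      stress("stress30_pod", 30, pod),
      stress("stress30_5d_pf", 30, post_pf(5)),
      stress("stress30_15d_pf", 30, post_pf(15)),
      stress("stress275_15d_pf", 27.5, post_pf(15)),
      stat("avg_radiation_7d_sow", "radiation", "mean", post_sow(7)),
      stat("avg_radiation_28d_sow", "radiation", "mean", post_sow(28)),
      stat("avg_tmax_14d_sow", "tmax", "mean", post_sow(14)),
      stat("avg_tmin_14d_sow", "tmin", "mean", post_sow(14)),
      stat("avg_tmax_28d_sow", "tmax", "mean", post_sow(28)),
      stat("avg_tmin_28d_sow", "tmin", "mean", post_sow(28)),
      stat("avg_vp_28d_sow", "vapour_pressure", "mean", post_sow(28))
    ))
}

#' Read a feature catalogue from YAML
#'
#' @param path YAML file with a top-level `features:` list matching the
#'   structure of [default_feature_spec()].
#' @return A list of feature definitions.
#' @export
read_feature_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  spec <- yaml::read_yaml(path)
  features <- spec$features %||% spec
  for (f in features) {
    if (is.null(f$name) || is.null(f$kind) || is.null(f$window)) {
      abort("each feature needs `name`, `kind` and `window` entries.")
    }
  }
  features
}

feature_window_spec <- function(window) {
  window_spec(anchor = window$anchor, mode = window$mode,
              end_anchor = window$end_anchor, n = window$n,
              direction = window$direction %||% "after")
}

compute_feature <- function(feature, series, sowing, petal_fall, harvest,
                            rule) {
  win <- resolve_window(sowing, petal_fall, harvest,
                        feature_window_spec(feature$window))
  switch(feature$kind,
         degree_days = growing_degree_days(series, win, rule),
         stress = stress_days(series, win, feature$threshold),
         stat = window_stat(series, win, feature$variable,
                            feature$statistic),
         abort(sprintf("unknown feature kind '%s'.", feature$kind)))
}

#' Build the per-sowing agro-meteorological feature table
#'
#' Joins each crop record to its location's weather series and computes
#' every feature in the catalogue over its phenology-anchored window. A
#' feature whose window cannot be resolved (missing anchor) or is not
#' covered by the weather is recorded as `NA` — never silently zero — with
#' the reason collected in the `"problems"` attribute, so downstream model
#' fitting can drop incomplete rows reproducibly.
#'
#' @param records A `crop_records` tibble.
#' @param weather Named list of [weather_series()], keyed by `location_id`.
#' @param features Feature catalogue; see [default_feature_spec()].
#' @param rule [degree_day_rule()] used for thermal-time features.
#' @param seq_month_map Season map passed to [classify_season()].
#' @return A tibble with one row per record: `record_id`, `location_id`,
#'   `region`, `season`, `sowing_day_fy`, `fresh_yield`, the three
#'   durations, and one column per feature. Attribute `problems` is a
#'   tibble of `record_id`, `feature`, `reason`.
#' @export
build_feature_table <- function(records, weather,
                                features = default_feature_spec(),
                                rule = degree_day_rule(),
                                seq_month_map = default_season_map()) {
  if (!is.list(weather) || is.null(names(weather))) {
    abort("`weather` must be a named list of weather_series keyed by location_id.")
  }
  missing_loc <- setdiff(unique(records$location_id), names(weather))
  if (length(missing_loc)) {
    ids <- records$record_id[records$location_id %in% missing_loc]
    abort(sprintf("no weather series for location(s) %s (record(s): %s)",
                  paste(missing_loc, collapse = ", "),
                  paste(ids, collapse = ", ")))
  }
  durs <- crop_durations(records)
  base <- tibble::tibble(
    record_id = records$record_id,
    location_id = records$location_id,
    region = records$region,
    season = classify_season(records, seq_month_map),
    sowing_day_fy = day_of_financial_year(records$sowing),
    fresh_yield = records$fresh_yield,
    duration_veg = durs$vegetative,
    duration_pod = durs$pod_fill,
    duration_total = durs$total)
  feature_names <- vapply(features, `[[`, character(1), "name")
  if (anyDuplicated(feature_names)) abort("duplicate feature names.")
  values <- matrix(NA_real_, nrow = nrow(records),
                   ncol = length(features),
                   dimnames = list(NULL, feature_names))
  problems <- list()
  for (i in seq_len(nrow(records))) {
    series <- weather[[records$location_id[i]]]
    for (j in seq_along(features)) {
      res <- tryCatch(
        compute_feature(features[[j]], series, records$sowing[i],
                        records$petal_fall[i], records$harvest[i], rule),
        error = function(e) e)
      if (inherits(res, "error")) {
        problems[[length(problems) + 1L]] <- tibble::tibble(
          record_id = records$record_id[i],
          feature = feature_names[j],
          reason = conditionMessage(res))
      } else {
        values[i, j] <- res
      }
    }
  }
  out <- dplyr::bind_cols(base, tibble::as_tibble(values))
  attr(out, "problems") <- if (length(problems)) {
    dplyr::bind_rows(problems)
  } else {
    tibble::tibble(record_id = character(), feature = character(),
                   reason = character())
  }
  out
}
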