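# Crop records, durations, season classification and the feature table.

test_that("crop CSV loading accepts ordered rows and reports bad ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "record_id,location_id,region,sowing,petal_fall,harvest,fresh_yield",
    "ok,loc1,SEQ,2021-02-19,2021-04-01,2021-04-22,12092",
    "bad,loc1,SEQ,2021-02-19,2021-04-10,2021-04-05,1000"), path)
  recs <- load_crop_records(path)
  expect_equal(recs$record_id, "ok")
  problems <- attr(recs, "problems")
  expect_equal(problems$record_id, "bad")
  expect_match(problems$reason, "date ordering")
})

test_that("an empty crop CSV gives an empty result and empty report", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    "record_id,location_id,region,sowing,petal_fall,harvest,fresh_yield",
    path)
  recs <- load_crop_records(path)
  expect_equal(nrow(recs), 0)
  expect_equal(nrow(attr(recs, "problems")), 0)
})

test_that("durations are plain date differences, absent when endpoints are", {
  recs <- crop_records(data.frame(
    record_id = c("a", "b"), location_id = "x", region = "SEQ",
    sowing = c("2021-02-19", "2021-02-27"),
    petal_fall = c("2021-04-01", "2021-04-08"),
    harvest = c("2021-04-22", "2021-04-28")))
  d <- crop_durations(recs)
  expect_equal(d$vegetative, c(41, 40))
  expect_equal(d$pod_fill, c(21, 20))
  expect_equal(d$total, c(62, 60))

  partial <- crop_records(data.frame(
    record_id = "c", location_id = "x", region = "SEQ",
    sowing = "2021-02-19", petal_fall = NA, harvest = NA))
  dp <- crop_durations(partial)
  expect_true(is.na(dp$vegetative) && is.na(dp$pod_fill) && is.na(dp$total))
})

test_that("season classification follows region and sowing month", {
  recs <- crop_records(data.frame(
    record_id = c("a", "b", "c", "d"),
    location_id = "x",
    region = c("SEQ", "SEQ", "NEQ", "SEQ"),
    sowing = c("2021-02-19", "2020-10-15", "2020-07-01", "2021-07-31")))
  expect_equal(classify_season(recs),
               c("Autumn", "Spring", "Middle", "Autumn"))
  bad <- recs; bad$region[1] <- "VIC"
  expect_error(classify_season(bad), "unknown region")
  # the month map is overridable
  map <- default_season_map(); map["7"] <- "Spring"
  expect_equal(classify_season(recs, map)[4], "Spring")
})

test_that("feature table under constant weather matches closed forms", {
  wx <- constant_weather(15, 25, start = as.Date("2021-01-01"),
                         n_days = 150)
  recs <- crop_records(example_crop_frame())
  ft <- build_feature_table(recs, list(const = wx))
  # 41 vegetative days x 15 degC d/day
  expect_equal(ft$thermal_time_veg, 41 * 15)
  expect_equal(ft$thermal_time_pod, 21 * 15)
  expect_equal(ft$thermal_time_total, 62 * 15)
  expect_equal(ft$avg_tmax_28d_sow, 25)
  expect_equal(ft$cum_radiation_veg, 41 * 20)
  expect_equal(ft$stress275_pod, 0)
  expect_equal(ft$duration_total, ft$duration_veg + ft$duration_pod)
  expect_equal(ft$season, "Autumn")
  expect_equal(ft$sowing_day_fy, 234L)
})

test_that("records missing harvest keep vegetative features, drop pod ones", {
  wx <- constant_weather(15, 25, n_days = 150)
  frame <- example_crop_frame(); frame$harvest <- NA
  recs <- crop_records(frame)
  ft <- build_feature_table(recs, list(const = wx))
  expect_false(is.na(ft$thermal_time_veg))
  expect_true(is.na(ft$thermal_time_pod))
  problems <- attr(ft, "problems")
  expect_true("thermal_time_pod" %in% problems$feature)
  expect_match(problems$reason[problems$feature == "thermal_time_pod"],
               "harvest")
})

test_that("identical records give identical rows and order does not matter", {
  wx <- random_weather(n_days = 150, seed = 8,
                       start = as.Date("2021-01-01"), location_id = "const")
  f1 <- example_crop_frame()
  f2 <- example_crop_frame(); f2$record_id <- "s2"
  f3 <- example_crop_frame(); f3$record_id <- "s0"; f3$sowing <- "2021-01-20"
  f3$petal_fall <- "2021-03-01"; f3$harvest <- "2021-03-20"
  fwd <- build_feature_table(crop_records(rbind(f1, f2, f3)),
                             list(const = wx))
  rev <- build_feature_table(crop_records(rbind(f3, f2, f1)),
                             list(const = wx))
  expect_equal(fwd[fwd$record_id == "s1", -1], fwd[fwd$record_id == "s2", -1])
  expect_equal(fwd[order(fwd$record_id), ], rev[order(rev$record_id), ],
               ignore_attr = TRUE)
})

test_that("a record at an unknown location is a concordance error", {
  recs <- crop_records(example_crop_frame())
  expect_error(build_feature_table(recs, list(elsewhere = constant_weather(15, 25))),
               "s1")
})

test_that("the shipped YAML catalogue matches the built-in one", {
  path <- system.file("extdata", "features.yaml", package = "cropclock")
  expect_true(nzchar(path))
  from_yaml <- read_feature_spec(path)
  builtin <- default_feature_spec()
  expect_equal(vapply(from_yaml, `[[`, character(1), "name"),
               vapply(builtin, `[[`, character(1), "name"))
  wx <- constant_weather(15, 25, n_days = 150)
  recs <- crop_records(example_crop_frame())
  expect_equal(
    build_feature_table(recs, list(const = wx), features = from_yaml),
    build_feature_table(recs, list(const = wx), features = builtin),
    ignore_attr = TRUE)
})
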