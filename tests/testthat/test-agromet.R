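# Degree days, stress days, windowed statistics and window resolution.

test_that("daily degree days follow the capped-average formula", {
  expect_equal(daily_degree_day(15, 35), 17.5)  # cap 30: (30+15)/2 - 5
  expect_equal(daily_degree_day(2, 4), 0)       # negative truncated
  expect_equal(daily_degree_day(5, 5), 0)       # boundary at base
  expect_error(daily_degree_day(10, 5), "tmin")
  expect_error(degree_day_rule(t_base = 30, t_cap = 30), "strictly below")
})

test_that("windowed degree days sum the daily values", {
  wx <- constant_weather(15, 25, n_days = 10)
  win <- date_window(wx$date[1], wx$date[3])
  expect_equal(growing_degree_days(wx, win), 45)  # 3 x 15
  one <- date_window(wx$date[4], wx$date[4])
  expect_equal(growing_degree_days(wx, one),
               daily_degree_day(wx$tmin[4], wx$tmax[4]))
  past <- date_window(wx$date[1], wx$date[10] + 5)
  expect_error(growing_degree_days(wx, past), "missing 5 day")
})

test_that("windowed operations agree with a brute-force day loop", {
  # independent oracle: explicit loop over days, no shared code path
  oracle_gdd <- function(wx, from, to, base = 5, cap = 30) {
    total <- 0
    for (d in seq(from, to, by = "day")) {
      row <- wx[wx$date == d, ]
      total <- total + max(0, (min(row$tmax, cap) + row$tmin) / 2 - base)
    }
    total
  }
  oracle_stat <- function(wx, from, to, var, fun) {
    vals <- c()
    for (d in seq(from, to, by = "day")) {
      row <- wx[wx$date == d, ]
      vals <- c(vals, if (var == "tmean") (row$tmin + row$tmax) / 2
                else row[[var]])
    }
    fun(vals)
  }
  withr::with_seed(42, {
    for (rep in 1:200) {
      wx <- random_weather(n_days = 30, seed = rep)
      i <- sample(1:30, 1); j <- i + sample.int(30 - i + 1, 1) - 1L
      win <- date_window(wx$date[i], wx$date[j])
      expect_equal(growing_degree_days(wx, win),
                   oracle_gdd(wx, win$start, win$end))
      thr <- runif(1, 15, 35)
      expect_equal(stress_days(wx, win, thr), sum(wx$tmax[i:j] > thr))
      expect_equal(window_stat(wx, win, "radiation", "mean"),
                   oracle_stat(wx, win$start, win$end, "radiation", mean))
      expect_equal(window_stat(wx, win, "tmean", "sum"),
                   oracle_stat(wx, win$start, win$end, "tmean", sum))
    }
  })
})

test_that("degree days are additive over adjacent windows", {
  wx <- random_weather(n_days = 40, seed = 3)
  a <- date_window(wx$date[1], wx$date[15])
  b <- date_window(wx$date[16], wx$date[40])
  whole <- date_window(wx$date[1], wx$date[40])
  expect_equal(growing_degree_days(wx, a) + growing_degree_days(wx, b),
               growing_degree_days(wx, whole))
})

test_that("monotonicity: thresholds, window length and base temperature", {
  wx <- random_weather(n_days = 50, seed = 5)
  win <- date_window(wx$date[5], wx$date[45])
  thresholds <- seq(15, 38, by = 0.5)
  counts <- vapply(thresholds, function(t) stress_days(wx, win, t), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(stress_days(wx, win, -100), win$n_days)  # saturation

  lens <- vapply(10:45, function(j) {
    growing_degree_days(wx, date_window(wx$date[5], wx$date[j]))
  }, numeric(1))
  expect_true(all(diff(lens) >= 0))

  bases <- seq(0, 15, by = 1)
  gdd_by_base <- vapply(bases, function(b) {
    growing_degree_days(wx, win, degree_day_rule(t_base = b))
  }, numeric(1))
  expect_true(all(diff(gdd_by_base) <= 0))
})

test_that("raising tmax above the cap leaves degree days unchanged", {
  for (tmax in c(30, 31, 35, 45)) {
    expect_equal(daily_degree_day(18, tmax), daily_degree_day(18, 30))
  }
})

test_that("window statistics validate variable availability", {
  wx <- constant_weather(15, 25, n_days = 5)
  no_vp <- weather_series(
    data.frame(date = wx$date, tmin = wx$tmin, tmax = wx$tmax,
               radiation = wx$radiation), location_id = "novp")
  win <- date_window(wx$date[1], wx$date[3])
  expect_error(window_stat(no_vp, win, "vapour_pressure", "mean"), "absent")
  expect_equal(window_stat(wx, win, "radiation", "sum"), 60)
  expect_equal(window_stat(wx, win, "radiation", "mean"), 20)
})

test_that("day of financial year follows the 1 July convention", {
  expect_equal(day_of_financial_year(as.Date("2020-07-01")), 1L)
  expect_equal(day_of_financial_year(as.Date("1999-07-01")), 1L)
  expect_equal(day_of_financial_year(as.Date("2021-06-30")), 365L)
  expect_equal(day_of_financial_year(as.Date("2021-02-19")), 234L)
  # leap-February financial years reach 366
  expect_equal(day_of_financial_year(as.Date("2020-06-30")), 366L)
})

test_that("window resolution matches the duration conventions", {
  sowing <- as.Date("2021-02-19")
  petal_fall <- as.Date("2021-04-01")
  veg <- resolve_window(sowing, petal_fall, NULL,
                        window_spec("sowing", "to_anchor",
                                    end_anchor = "petal_fall"))
  expect_equal(veg$n_days, 41L)        # equals the vegetative duration
  expect_equal(veg$end, petal_fall)
  expect_equal(veg$start, sowing + 1)

  after <- resolve_window(sowing, NULL, NULL,
                          window_spec("sowing", "fixed_days", n = 7))
  expect_equal(after$start, as.Date("2021-02-20"))
  expect_equal(after$end, as.Date("2021-02-26"))

  before <- resolve_window(sowing, NULL, NULL,
                           window_spec("sowing", "fixed_days", n = 5,
                                       direction = "before"))
  expect_equal(before$start, sowing - 5)
  expect_equal(before$end, sowing - 1)

  expect_error(
    resolve_window(sowing, sowing - 10, NULL,
                   window_spec("sowing", "to_anchor",
                               end_anchor = "petal_fall")),
    "not after")
  expect_error(
    resolve_window(sowing, NULL, NULL,
                   window_spec("petal_fall", "fixed_days", n = 5)),
    "absent")
})
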