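# Shared fixture builders: all synthetic, generated in code at test time.

# Constant weather: the same tmin/tmax/radiation every day.
constant_weather <- function(tmin, tmax, radiation = 20,
                             start = as.Date("2021-01-01"), n_days = 120,
                             location_id = "const", vp = 18) {
  weather_series(
    data.frame(date = start + 0:(n_days - 1), tmin = tmin, tmax = tmax,
               radiation = radiation, rain = 0, vapour_pressure = vp),
    location_id = location_id)
}

# A random valid weather series (uniform noise, no seasonal structure).
random_weather <- function(n_days = 60, seed = 1,
                           start = as.Date("2020-01-01"),
                           location_id = "rand") {
  withr::with_seed(seed, {
    tmax <- runif(n_days, 18, 36)
    tmin <- tmax - runif(n_days, 2, 14)
    weather_series(
      data.frame(date = start + 0:(n_days - 1), tmin = tmin, tmax = tmax,
                 radiation = runif(n_days, 5, 30),
                 rain = round(runif(n_days, 0, 20), 1),
                 vapour_pressure = runif(n_days, 5, 30)),
      location_id = location_id)
  })
}

# One valid crop record frame (dates of the first sampled sowing).
example_crop_frame <- function() {
  data.frame(record_id = "s1", location_id = "const", region = "SEQ",
             sowing = "2021-02-19", petal_fall = "2021-04-01",
             harvest = "2021-04-22", fresh_yield = 12092,
             stringsAsFactors = FALSE)
}

# Simulate a two-season grouped logistic data set from given truth.
simulate_grouped_logistic <- function(seed, n_per_group = 500, noise_sd = 800,
                                      truth = list(
                                        Autumn = c(asym = 6064, xmid = 876),
                                        Spring = c(asym = 6371, xmid = 836)),
                                      scal = 22,
                                      x_range = c(700, 1080)) {
  withr::with_seed(seed, {
    pieces <- lapply(names(truth), function(season) {
      x <- runif(n_per_group, x_range[1], x_range[2])
      mu <- logistic_value(x, truth[[season]][["asym"]],
                           truth[[season]][["xmid"]], scal)
      data.frame(x = x, y = mu + rnorm(n_per_group, 0, noise_sd),
                 season = season)
    })
    do.call(rbind, pieces)
  })
}
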