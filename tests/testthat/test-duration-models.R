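# Collinearity screening, OLS, backward stepwise AIC and prediction
# intervals.

# k independent standard-normal candidate columns; caller controls the seed
make_design <- function(n, k) {
  as.data.frame(setNames(lapply(seq_len(k), function(i) rnorm(n)),
                         paste0("x", seq_len(k))))
}

test_that("perfectly collinear and constant candidates are dropped", {
  d <- withr::with_seed(1, make_design(50, 2))
  d$x3 <- 2 * d$x1
  d$x4 <- 5
  res <- collinearity_filter(d, c("x1", "x2", "x3", "x4"))
  expect_equal(res$retained, c("x1", "x2"))
  expect_setequal(res$dropped$variable, c("x3", "x4"))
  expect_equal(res$dropped$reason[res$dropped$variable == "x4"], "constant")
})

test_that("independent candidates pass the collinearity screen", {
  d <- withr::with_seed(2, make_design(200, 6))
  res <- collinearity_filter(d, names(d))
  expect_equal(res$retained, names(d))
  expect_equal(nrow(res$dropped), 0)
})

test_that("OLS matches the normal-equations oracle on random designs", {
  for (seed in 1:100) {
    d <- withr::with_seed(seed, {
      out <- make_design(40, 3)
      out$y <- 1 + 2 * out$x1 - out$x2 + 0.5 * out$x3 + rnorm(40)
      out
    })
    model <- fit_ols(d, "y", c("x1", "x2", "x3"))
    X <- cbind(1, as.matrix(d[c("x1", "x2", "x3")]))
    beta <- solve(t(X) %*% X, t(X) %*% d$y)  # independent oracle
    expect_equal(unname(model$coefficients$estimate), c(beta),
                 tolerance = 1e-10)
  }
})

test_that("exact linear data recovers coefficients; AIC sentinel is -Inf", {
  d <- data.frame(x = 1:20)
  d$y <- 2 + 3 * d$x
  model <- suppressWarnings(fit_ols(d, "y", "x"))  # summary.lm on exact fit
  expect_equal(unname(model$coefficients$estimate), c(2, 3), tolerance = 1e-10)
  expect_identical(model$aic, -Inf)
})

test_that("intercept-only AIC follows the closed form", {
  withr::with_seed(3, {
    d <- data.frame(y = rnorm(30, 10, 2))
  })
  model <- fit_ols(d, "y", character())
  n <- 30
  expect_equal(model$aic, n * log(sum((d$y - mean(d$y))^2) / n) + 4)
})

test_that("rank-deficient designs raise a named error", {
  d <- withr::with_seed(4, make_design(30, 2))
  d$x3 <- d$x1 + d$x2
  d$y <- withr::with_seed(44, rnorm(30))
  expect_error(fit_ols(d, "y", c("x1", "x2", "x3")), "x3")
})

test_that("backward stepwise never raises AIC and beats the full model", {
  withr::with_seed(11, {
    d <- make_design(120, 6)
    d$y <- 5 + 3 * d$x1 + rnorm(120, 0, 3)
  })
  model <- backward_stepwise(d, "y", names(d)[names(d) != "y"])
  expect_true(all(diff(model$trace$aic) <= 0))
  full <- fit_ols(d, "y", paste0("x", 1:6))
  expect_lte(model$aic, full$aic)
  expect_true("x1" %in% model$candidates)
})

test_that("stepwise keeps the real signal and prunes noise candidates", {
  keep_rate <- matrix(NA, 100, 6,
                      dimnames = list(NULL, c("gdd", paste0("noise", 1:5))))
  for (rep in 1:100) {
    d <- withr::with_seed(rep, {
      out <- data.frame(gdd = runif(300, 500, 900))
      for (i in 1:5) out[[paste0("noise", i)]] <- rnorm(300)
      out$y <- 40 + 0.02 * out$gdd + rnorm(300, 0, 1)
      out
    })
    model <- backward_stepwise(d, "y", colnames(keep_rate))
    keep_rate[rep, ] <- colnames(keep_rate) %in% model$candidates
  }
  expect_equal(mean(keep_rate[, "gdd"]), 1)
  for (v in paste0("noise", 1:5)) {
    expect_lt(mean(keep_rate[, v]), 0.5)
  }
})

test_that("stepwise selection agrees with the MASS::stepAIC cross-check", {
  withr::with_seed(77, {
    d <- make_design(150, 5)
    d$y <- 2 + 1.5 * d$x1 - 2 * d$x3 + rnorm(150)
  })
  ours <- backward_stepwise(d, "y", paste0("x", 1:5))
  ref <- MASS::stepAIC(lm(y ~ x1 + x2 + x3 + x4 + x5, data = d),
                       direction = "backward", trace = 0)
  expect_setequal(ours$candidates,
                  setdiff(all.vars(stats::formula(ref)), "y"))
})

test_that("prediction intervals are monotone in level and leverage", {
  withr::with_seed(8, {
    d <- data.frame(x = runif(100, -2, 2))
    d$y <- 1 + 2 * d$x + rnorm(100)
  })
  model <- fit_ols(d, "y", "x")
  newd <- data.frame(x = c(mean(d$x), -2, 2, 0.5))
  p80 <- predict_with_interval(model, newd, level = 0.80)
  p9999 <- predict_with_interval(model, newd, level = 0.9999)
  expect_true(all(p9999$upr - p9999$lwr > p80$upr - p80$lwr))
  widths <- p80$upr - p80$lwr
  expect_equal(which.min(widths), 1)  # training mean has minimum leverage
  # symmetric about the point prediction
  expect_equal(p80$fit - p80$lwr, p80$upr - p80$fit)
  expect_error(predict_with_interval(model, data.frame(z = 1)), "x")
})

test_that("80% prediction intervals cover about 80% of new observations", {
  withr::with_seed(19, {
    train <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
    train$y <- 3 + 2 * train$x1 - train$x2 + rnorm(200, 0, 1.5)
    test <- data.frame(x1 = rnorm(2000), x2 = rnorm(2000))
    test$y <- 3 + 2 * test$x1 - test$x2 + rnorm(2000, 0, 1.5)
  })
  model <- fit_ols(train, "y", c("x1", "x2"))
  pred <- predict_with_interval(model, test, level = 0.80)
  coverage <- mean(test$y >= pred$lwr & test$y <= pred$upr)
  expect_gte(coverage, 0.77)
  expect_lte(coverage, 0.83)
})

test_that("a duration model trained on synthetic sowings predicts held-out
          durations within 1.5 d mean absolute error", {
  withr::with_seed(23, {
    n <- 400
    d <- data.frame(sowing_day_fy = sample(1:365, n, TRUE),
                    thermal_time_veg = runif(n, 600, 850),
                    avg_radiation_veg = runif(n, 10, 25))
    # known mechanism: duration driven by thermal time and radiation
    d$duration_veg <- 90 - 0.06 * d$thermal_time_veg -
      0.3 * d$avg_radiation_veg + rnorm(n, 0, 1)
    train_idx <- 1:300
  })
  model <- backward_stepwise(d[train_idx, ], "duration_veg",
                             c("sowing_day_fy", "thermal_time_veg",
                               "avg_radiation_veg"))
  pred <- predict_with_interval(model, d[-train_idx, ])
  mae <- mean(abs(pred$fit - d$duration_veg[-train_idx]))
  expect_lt(mae, 1.5)
})
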