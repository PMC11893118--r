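# Linear modelling of growth-period durations from agro-meteorological
# predictors: collinearity screening, backward stepwise AIC selection, and
# t-based prediction intervals.

#' Screen candidate predictors for collinearity
#'
#' Iterates over candidate pairs in the listed order and, whenever the
#' absolute Pearson correlation (on complete cases) reaches `r_max`, drops
#' the later-listed variable; constant (zero-variance) candidates are
#' dropped with reason `"constant"`. Deterministic given the candidate
#' order.
#'
#' @param data Feature table (data frame).
#' @param candidates Ordered character vector of candidate column names.
#' @param r_max Absolute-correlation threshold at or above which the later
#'   variable is dropped; default 0.95.
#' @return List with `retained` (character vector) and `dropped` (tibble of
#'   `variable`, `reason`).
#' @export
collinearity_filter <- function(data, candidates, r_max = 0.95) {
  check_number(r_max, "r_max", lower = 0, upper = 1)
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols)) {
    abort(sprintf("candidate(s) not in data: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  cc <- data[complete.cases(data[candidates]), candidates, drop = FALSE]
  if (nrow(cc) < 2) abort("need at least 2 complete rows.")
  dropped <- tibble::tibble(variable = character(), reason = character())
  retained <- character()
  for (v in candidates) {
    if (sd(cc[[v]]) == 0) {
      dropped <- dplyr::bind_rows(dropped,
                                  tibble::tibble(variable = v,
                                                 reason = "constant"))
      next
    }
    clash <- NULL
    for (kept in retained) {
      r <- cor(cc[[kept]], cc[[v]])
      if (is.finite(r) && abs(r) >= r_max) { clash <- c(kept, r); break }
    }
    if (is.null(clash)) {
      retained <- c(retained, v)
    } else {
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        variable = v,
        reason = sprintf("|r| = %.3f with %s", abs(as.numeric(clash[2])),
                         clash[1])))
    }
  }
  list(retained = retained, dropped = dropped)
}


#' Fit an ordinary least squares duration model
#'
#' OLS of `response` on the candidate columns (complete cases), reporting
#' the package's RSS-based AIC convention `n * log(RSS/n) + 2 * (p + 1)`
#' (additive constants dropped; offset by a constant from `stats::AIC`,
#' which cancels in comparisons). An exact fit (RSS = 0) reports AIC
#' `-Inf`.
#'
#' @param data Feature table.
#' @param response Response column name (a duration in days).
#' @param candidates Character vector of predictor column names; empty for
#'   an intercept-only model.
#' @return A `duration_model` list: `fit` (the `lm`), `coefficients` tibble
#'   (estimate, se), `response`, `candidates`, `n`, `rss`, `sigma2`, `aic`,
#'   and an empty selection `trace`.
#' @export
fit_ols <- function(data, response, candidates) {
  if (!response %in% names(data)) {
    abort(sprintf("response '%s' not in data.", response))
  }
  if (response %in% candidates) {
    abort("`response` must not be among `candidates`.")
  }
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols)) {
    abort(sprintf("candidate(s) not in data: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  cols <- c(response, candidates)
  cc <- data[complete.cases(data[cols]), cols, drop = FALSE]
  p <- length(candidates) + 1L
  if (nrow(cc) < p + 2) {
    abort(sprintf("need at least %d complete rows for %d coefficient(s), have %d.",
                  p + 2, p, nrow(cc)))
  }
  fml <- if (length(candidates)) {
    stats::reformulate(candidates, response)
  } else {
    stats::reformulate("1", response)
  }
  fit <- lm(fml, data = cc)
  if (anyNA(coef(fit))) {
    abort(sprintf("rank-deficient design; aliased: %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  smry <- summary(fit)
  n <- nrow(cc)
  rss <- sum(residuals(fit)^2)
  # an (effectively) exact fit reports the documented -Inf AIC sentinel
  tss <- sum((cc[[response]] - mean(cc[[response]]))^2)
  if (rss <= 1e-12 * max(tss, .Machine$double.xmin)) rss <- 0
  structure(list(
    fit = fit,
    coefficients = tibble::tibble(term = rownames(smry$coefficients),
                                  estimate = smry$coefficients[, 1],
                                  se = smry$coefficients[, 2]),
    response = response, candidates = candidates, n = n, rss = rss,
    sigma2 = rss / fit$df.residual, aic = aic_rss(rss, n, length(coef(fit))),
    trace = tibble::tibble(step = integer(), dropped = character(),
                           aic = numeric())),
    class = "duration_model")
}

#' Backward stepwise selection by AIC
#'
#' Starts from the full model on all candidates and repeatedly removes the
#' single variable whose removal most lowers the RSS-based AIC, stopping
#' when no removal lowers it. A removal that leaves AIC unchanged is
#' accepted (parsimony: equal fit with fewer variables), and ties between
#' competing removals go to the later-listed variable. Complete cases are
#' fixed at the full-candidate set so AIC is comparable across steps.
#'
#' @inheritParams fit_ols
#' @return A `duration_model` for the selected variable set; `trace`
#'   records each accepted drop and the AIC after it (step 0 = full model).
#' @export
backward_stepwise <- function(data, response, candidates) {
  cols <- c(response, candidates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("column(s) not in data: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  cc <- data[complete.cases(data[cols]), cols, drop = FALSE]
  current <- candidates
  model <- fit_ols(cc, response, current)
  trace <- tibble::tibble(step = 0L, dropped = NA_character_,
                          aic = model$aic)
  step <- 0L
  repeat {
    if (!length(current)) break
    trial_aic <- vapply(seq_along(current), function(i) {
      fit_ols(cc, response, current[-i])$aic
    }, numeric(1))
    best <- max(which(trial_aic == min(trial_aic)))  # tie -> later-listed
    if (trial_aic[best] > model$aic) break
    step <- step + 1L
    dropped_var <- current[best]
    current <- current[-best]
    model <- fit_ols(cc, response, current)
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step, dropped = dropped_var, aic = model$aic))
  }
  model$trace <- trace
  model
}

#' Point predictions with t-based prediction intervals
#'
#' Intervals account for both residual variance and estimation variance
#' (the leverage term), are symmetric about the point prediction, and
#' default to the 80 percent level used for harvest-window planning.
#'
#' @param model A `duration_model`.
#' @param new_data Data frame containing every model variable.
#' @param level Coverage level in `(0, 1)`, default 0.80.
#' @return A tibble with `fit`, `lwr`, `upr` per row of `new_data`.
#' @export
predict_with_interval <- function(model, new_data, level = 0.80) {
  if (!inherits(model, "duration_model")) {
    abort("`model` must be a duration_model.")
  }
  check_number(level, "level")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  missing_cols <- setdiff(model$candidates, names(new_data))
  if (length(missing_cols)) {
    abort(sprintf("new data lacks model variable(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  pred <- predict(model$fit, newdata = new_data, interval = "prediction",
                  level = level)
  tibble::as_tibble(as.data.frame(pred))
}

#' @export
print.duration_model <- function(x, ...) {
  cat(sprintf("Duration model: %s ~ %s\n", x$response,
              if (length(x$candidates)) paste(x$candidates, collapse = " + ")
              else "1"))
  cat(sprintf("n = %d, AIC = %.2f, residual sd = %.2f d\n", x$n, x$aic,
              sqrt(x$sigma2)))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  if (nrow(x$trace) > 1) {
    cat("\nSelection trace:\n")
    print(as.data.frame(x$trace), row.names = FALSE)
  }
  invisible(x)
}
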