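# Radiation-budget indices and the season-grouped three-parameter logistic
# model of fresh pod weight against thermal time after petal fall.

#' Primary production from intercepted radiation
#'
#' `P_n = S_t * epsilon_i * epsilon_c / k`: above-ground biomass (g m-2)
#' over a growing period as a function of incident solar radiation, the
#' efficiencies of interception and of conversion into biomass, and the
#' energy content of plant mass.
#'
#' @param s_t Incident solar radiation over the period (MJ m-2).
#' @param epsilon_i Radiation interception efficiency, in `[0, 1]`.
#' @param epsilon_c Conversion efficiency into biomass, in `[0, 1]`.
#' @param k Energy content of plant mass (MJ g-1), > 0.
#' @return Primary production `P_n` (g m-2).
#' @export
primary_production <- function(s_t, epsilon_i, epsilon_c, k) {
  check_number(s_t, "s_t", lower = 0)
  check_number(epsilon_i, "epsilon_i", lower = 0, upper = 1)
  check_number(epsilon_c, "epsilon_c", lower = 0, upper = 1)
  check_number(k, "k")
  if (k <= 0) abort("`k` must be > 0.")
  s_t * epsilon_i * epsilon_c / k
}

#' Yield potential from primary production and harvest index
#'
#' `Y_p = eta * P_n`, the fraction of biomass partitioned into the
#' harvested product under non-limiting conditions.
#'
#' @param p_n Primary production (g m-2).
#' @param eta Harvest index, in `(0, 1]`.
#' @return Yield potential `Y_p` (g m-2).
#' @export
yield_potential <- function(p_n, eta) {
  check_number(p_n, "p_n", lower = 0)
  check_number(eta, "eta")
  if (eta <= 0 || eta > 1) abort("`eta` must be in (0, 1].")
  eta * p_n
}

#' Photothermal productivity index
#'
#' Growth index `I_g = R_i / (T_i - T_b) * RIX`: potential growth per unit
#' of crop development, from mean daily radiation `R_i`, mean daily
#' temperature `T_i` above the base `T_b`, scaled by the radiation
#' interception factor `RIX` (1 under full leaf cover, LAI above about
#' 2-3). Specialised to the vegetative and pod-fill periods it gives
#' `I_veg` and `I_pod`. The quotient reading (a photothermal quotient) is
#' the default; `form = "product"` gives the alternative
#' `R_i * (T_i - T_b) * RIX` reading.
#'
#' @param r_i Mean daily radiation over the period (MJ m-2).
#' @param t_i Mean daily temperature over the period (degC); must exceed
#'   `t_b` or the index is undefined.
#' @param t_b Base temperature (degC), default 5.
#' @param rix Radiation interception factor in `(0, 1]`, default 1
#'   (adequate leaf cover assumed).
#' @param form `"quotient"` (default) or `"product"`.
#' @return The index value.
#' @examples
#' productivity_index(r_i = 20, t_i = 25)  # 20 / (25 - 5) = 1
#' @export
productivity_index <- function(r_i, t_i, t_b = 5, rix = 1,
                               form = c("quotient", "product")) {
  form <- match.arg(form)
  check_number(r_i, "r_i", lower = 0)
  check_number(t_i, "t_i")
  check_number(t_b, "t_b")
  check_number(rix, "rix")
  if (rix <= 0 || rix > 1) abort("`rix` must be in (0, 1].")
  if (t_i <= t_b) {
    abort(sprintf(
      "productivity index undefined: mean temperature (%s) must exceed base (%s).",
      format(t_i), format(t_b)))
  }
  if (form == "quotient") r_i / (t_i - t_b) * rix else r_i * (t_i - t_b) * rix
}

#' Three-parameter logistic growth curve
#'
#' `Asym / (1 + exp((xmid - x) / scal))`: the standard increasing growth
#' curve with upper asymptote `Asym`, inflection point `xmid` (here in
#' degC d thermal time) and input-axis scale `scal` (positive for
#' increasing curves; in the slope parameterisation `scal = -1/b`).
#'
#' @param x Thermal time (degC d); vectorised.
#' @param asym Upper asymptote (response units), > 0.
#' @param xmid Inflection point (degC d).
#' @param scal Scale (degC d), non-zero.
#' @return Fitted response at each `x`.
#' @examples
#' logistic_value(876, asym = 6064, xmid = 876, scal = 22)  # Asym / 2
#' @export
logistic_value <- function(x, asym, xmid, scal) {
  check_number(asym, "asym")
  check_number(xmid, "xmid")
  check_number(scal, "scal")
  if (asym <= 0) abort("`asym` must be > 0.")
  if (scal == 0) abort("`scal` must be non-zero.")
  asym / (1 + exp((xmid - x) / scal))
}

# Self-start for the logistic: Asym0 = 1.05 * max(y); regress
# logit(y / Asym0) on x, giving slope 1/scal and intercept -xmid/scal.
logistic_start <- function(x, y) {
  asym0 <- 1.05 * max(y)
  p <- pmin(pmax(y / asym0, 1e-3), 1 - 1e-3)
  z <- log(p / (1 - p))
  fit <- lm(z ~ x)
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope == 0) slope <- 1 / diff(range(x))
  scal0 <- 1 / slope
  xmid0 <- -coef(fit)[[1]] * scal0
  list(Asym = asym0, xmid = xmid0, scal = scal0)
}

# Logistic mean function with analytic gradient, for nls.
logistic_grad <- deriv(~ Asym / (1 + exp((xmid - x) / scal)),
                       c("Asym", "xmid", "scal"),
                       function(x, Asym, xmid, scal) {})

# Gauss-Newton nls with the package's convergence settings; scaleOffset
# keeps the relative-offset criterion defined on zero-residual (noise-free)
# data. If Gauss-Newton fails, retries with the bounded port algorithm
# (positivity of Asym and scal for increasing growth curves). Returns the
# nls fit or the last error object.
nls_with_fallback <- function(formula, data, start) {
  ctrl <- nls.control(maxiter = 200, tol = 1e-8, minFactor = 1 / 4096,
                      scaleOffset = 1, warnOnly = FALSE)
  fit <- tryCatch(nls(formula, data = data, start = start, control = ctrl),
                  error = function(e) e)
  if (!inherits(fit, "error")) return(fit)
  lower <- unlist(lapply(names(start), function(nm) {
    rep(if (nm == "xmid") -Inf else 1e-8, length(start[[nm]]))
  }))
  tryCatch(
    suppressWarnings(nls(formula, data = data, start = start, control = ctrl,
                         algorithm = "port", lower = lower)),
    error = function(e) e)
}

# RSS-based AIC used for both linear and nonlinear fits in this package:
# n * log(RSS / n) + 2 * (p + 1), additive constants dropped. Comparable
# across models fitted to the same data, offset by a constant from
# stats::AIC. RSS of 0 gives -Inf (documented sentinel).
aic_rss <- function(rss, n, p) {
  if (rss <= 0) return(-Inf)
  n * log(rss / n) + 2 * (p + 1)
}

#' Fit a three-parameter logistic by nonlinear least squares
#'
#' Initialises with the scaled-logit self-start (`Asym0 = 1.05 * max(y)`;
#' logit of `y / Asym0` regressed on `x` for `xmid` and `scal`) and refines
#' by Gauss-Newton least squares with the analytic Jacobian of the logistic
#' (relative-offset tolerance 1e-8, at most 200 iterations).
#'
#' @param x Thermal time values (degC d), not constant; length >= 5.
#' @param y Responses (fresh weight, response units) with positive spread.
#' @return A `logistic_fit` list: `estimate` and `se` (named `Asym`,
#'   `xmid`, `scal`), `rss`, `sigma`, `n`, `aic`, `fit` (the underlying
#'   `nls` object) and `convergence` info.
#' @export
fit_logistic <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) abort("need at least 5 complete (x, y) points.")
  if (sd(x) == 0) abort("`x` must not be constant.")
  if (sd(y) == 0 || max(y) <= 0) {
    abort("`y` is degenerate: needs positive spread and a positive maximum.")
  }
  start <- logistic_start(x, y)
  dat <- data.frame(x = x, y = y)
  fit <- nls_with_fallback(y ~ logistic_grad(x, Asym, xmid, scal), dat,
                           start)
  if (inherits(fit, "error")) {
    abort(sprintf("logistic fit did not converge: %s (self-start: Asym %.4g, xmid %.4g, scal %.4g)",
                  conditionMessage(fit), start$Asym, start$xmid, start$scal))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  rss <- sum(residuals(fit)^2)
  n <- length(x)
  structure(list(estimate = est, se = se, rss = rss,
                 sigma = sqrt(rss / (n - 3)), n = n,
                 aic = aic_rss(rss, n, 3), fit = fit,
                 convergence = fit$convInfo), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Three-parameter logistic fit (n =", x$n, ")\n")
  print(round(rbind(estimate = x$estimate, se = x$se), 3))
  invisible(x)
}

grouped_structures <- c("all_shared", "shared_scal", "all_separate")

fit_one_structure <- function(x, y, g, structure_name, starts) {
  dat <- data.frame(x = x, y = y, g = g)
  n_groups <- nlevels(g)
  formula_start <- switch(
    structure_name,
    all_shared = list(
      y ~ Asym / (1 + exp((xmid - x) / scal)),
      list(Asym = mean(starts$Asym), xmid = mean(starts$xmid),
           scal = mean(starts$scal))),
    shared_scal = list(
      y ~ Asym[g] / (1 + exp((xmid[g] - x) / scal)),
      list(Asym = starts$Asym, xmid = starts$xmid,
           scal = mean(starts$scal))),
    all_separate = list(
      y ~ Asym[g] / (1 + exp((xmid[g] - x) / scal[g])),
      list(Asym = starts$Asym, xmid = starts$xmid, scal = starts$scal)))
  fit <- nls_with_fallback(formula_start[[1]], dat, formula_start[[2]])
  if (inherits(fit, "error")) {
    abort(sprintf("structure '%s' did not converge: %s", structure_name,
                  conditionMessage(fit)))
  }
  p <- switch(structure_name, all_shared = 3,
              shared_scal = 2 * n_groups + 1, all_separate = 3 * n_groups)
  rss <- sum(residuals(fit)^2)
  list(structure = structure_name, fit = fit, p = p, rss = rss,
       aic = aic_rss(rss, length(x), p))
}

#' Fit season-grouped logistic curves and select the sharing structure
#'
#' Filters to thermal times strictly below `max_x` (past about 1080 degC d
#' pods turn stringy and fresh weight is past its optimum), then fits three
#' nested parameter-sharing structures across the season groups:
#' all parameters shared (`all_shared`), separate asymptote and inflection
#' with a common scale (`shared_scal`), and all separate (`all_separate`).
#' Selection follows the principle of parsimony: starting from the fully
#' shared structure, a more complex structure is adopted only when it both
#' lowers the RSS-based AIC and is significantly better by the
#' extra-sum-of-squares F test (`select = "parsimonious"`, default, with
#' significance level `alpha`), so a simpler model with fewer parameters is
#' favoured unless the data clearly demand more. `select = "aic"` instead
#' takes the lowest AIC outright, with ties broken toward fewer
#' parameters. The F tests for all nested pairs are reported either way.
#'
#' @param x Thermal time after petal fall (degC d).
#' @param y Fresh pod weight (response units).
#' @param group Season labels (coerced to factor); at least 2 groups with
#'   at least 5 points each after filtering.
#' @param max_x Strict upper thermal-time cutoff (degC d), default 1080.
#' @param select Structure-selection rule: `"parsimonious"` (default) or
#'   `"aic"`.
#' @param alpha Significance level of the F gate for `"parsimonious"`
#'   selection, default 0.05.
#' @return A `grouped_logistic_fit` list: `structure` (selected),
#'   `estimate`/`se` (named vectors, group-indexed names such as
#'   `Asym.Autumn`), `comparison` (per-structure tibble of p, RSS, AIC),
#'   `anova` (nested F tests), `n` (points used after the filter),
#'   `n_dropped`, `groups`, `rss`, `sigma`, and `fit`.
#' @export
fit_grouped_logistic <- function(x, y, group, max_x = 1080,
                                 select = c("parsimonious", "aic"),
                                 alpha = 0.05) {
  select <- match.arg(select)
  check_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (length(x) != length(y) || length(x) != length(group)) {
    abort("`x`, `y` and `group` must have equal length.")
  }
  check_number(max_x, "max_x")
  keep <- is.finite(x) & is.finite(y) & !is.na(group) & x < max_x
  x <- x[keep]; y <- y[keep]
  g <- droplevels(factor(group[keep]))
  if (nlevels(g) < 2) {
    abort("need at least 2 season groups after the thermal-time filter.")
  }
  counts <- table(g)
  if (any(counts < 5)) {
    abort(sprintf("group(s) too small after filtering: %s",
                  paste(names(counts)[counts < 5], collapse = ", ")))
  }
  per_group <- lapply(levels(g), function(lv) {
    fit <- tryCatch(fit_logistic(x[g == lv], y[g == lv]),
                    error = function(e) {
                      abort(sprintf("group '%s': %s", lv, conditionMessage(e)))
                    })
    fit$estimate
  })
  starts <- list(Asym = vapply(per_group, `[[`, numeric(1), "Asym"),
                 xmid = vapply(per_group, `[[`, numeric(1), "xmid"),
                 scal = vapply(per_group, `[[`, numeric(1), "scal"))
  fits <- lapply(grouped_structures, function(s) {
    tryCatch(fit_one_structure(x, y, g, s, starts), error = function(e) NULL)
  })
  names(fits) <- grouped_structures
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) abort("no grouped structure converged.")
  comparison <- dplyr::bind_rows(lapply(fits[ok], function(f) {
    tibble::tibble(structure = f$structure, p = f$p, rss = f$rss,
                   aic = f$aic)
  }))
  n <- length(x)
  anova_tbl <- nested_f_tests(fits, n)
  best_name <- select_structure(comparison, anova_tbl, select, alpha)
  best <- fits[[best_name]]
  est <- coef(best$fit)
  se <- sqrt(diag(vcov(best$fit)))
  names(est) <- names(se) <- grouped_param_names(best_name, levels(g))
  structure(list(structure = best_name, estimate = est, se = se,
                 comparison = comparison, anova = anova_tbl,
                 n = n, n_dropped = sum(!keep), groups = levels(g),
                 rss = best$rss, sigma = sqrt(best$rss / (n - best$p)),
                 aic = best$aic, fit = best$fit),
            class = "grouped_logistic_fit")
}

# Walk up the nesting chain; under "parsimonious" a step to a more complex
# structure must both lower AIC and pass the F gate.
select_structure <- function(comparison, anova_tbl, select, alpha) {
  present <- comparison$structure
  if (select == "aic") {
    ord <- order(comparison$aic, comparison$p)
    return(comparison$structure[ord[1]])
  }
  current <- grouped_structures[grouped_structures %in% present][1]
  for (candidate in grouped_structures[grouped_structures %in% present][-1]) {
    step <- anova_tbl[anova_tbl$reduced == current &
                        anova_tbl$full == candidate, ]
    if (nrow(step) != 1) next
    aic_cur <- comparison$aic[comparison$structure == current]
    aic_new <- comparison$aic[comparison$structure == candidate]
    if (aic_new < aic_cur && step$p_value < alpha) current <- candidate
  }
  current
}

grouped_param_names <- function(structure_name, group_levels) {
  switch(structure_name,
         all_shared = c("Asym", "xmid", "scal"),
         shared_scal = c(paste0("Asym.", group_levels),
                         paste0("xmid.", group_levels), "scal"),
         all_separate = c(paste0("Asym.", group_levels),
                          paste0("xmid.", group_levels),
                          paste0("scal.", group_levels)))
}

# Extra-sum-of-squares F tests between each nested structure pair.
nested_f_tests <- function(fits, n) {
  pairs <- list(c("all_shared", "shared_scal"),
                c("shared_scal", "all_separate"),
                c("all_shared", "all_separate"))
  rows <- lapply(pairs, function(pr) {
    small <- fits[[pr[1]]]; big <- fits[[pr[2]]]
    if (is.null(small) || is.null(big)) return(NULL)
    df1 <- big$p - small$p
    df2 <- n - big$p
    f <- ((small$rss - big$rss) / df1) / (big$rss / df2)
    tibble::tibble(reduced = pr[1], full = pr[2], df1 = df1, df2 = df2,
                   f = f, p_value = pf(f, df1, df2, lower.tail = FALSE))
  })
  dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
}

#' @export
print.grouped_logistic_fit <- function(x, ...) {
  cat("Grouped logistic fit:", x$structure,
      sprintf("(n = %d, %d filtered out)\n", x$n, x$n_dropped))
  print(round(rbind(estimate = x$estimate, se = x$se), 3))
  cat("\nStructure comparison:\n")
  print(as.data.frame(x$comparison), row.names = FALSE)
  invisible(x)
}
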