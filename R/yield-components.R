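# Yield-component estimation from field quadrat samples: per-sample fresh
# yield, the product-of-means estimator with delta-method errors, maturity
# proportions, and the sample-size rule.

#' Per-sample fresh yield, scaled to kg/ha
#'
#' Each sample's pod mass over the sampled area is scaled to kg/ha as
#' `grams * 10000 / area_m2 / 1000`; the estimate is the mean across
#' samples with the standard error of the mean.
#'
#' @param pod_mass_g Vector of per-sample total pod fresh mass (g); >= 2
#'   samples.
#' @param area_m2 Sampled area per sample (m2), a single value (e.g. 0.5625
#'   for a 0.75 m row) or one per sample.
#' @return List with `mean` and `se` (kg/ha) and `n`.
#' @examples
#' per_sample_yield(c(52.1, 52.1), area_m2 = 0.5625)  # 926.2 kg/ha, se 0
#' @export
per_sample_yield <- function(pod_mass_g, area_m2) {
  if (length(pod_mass_g) < 2) {
    abort("need >= 2 samples for a standard error.")
  }
  if (any(pod_mass_g < 0) || any(area_m2 <= 0)) {
    abort("pod mass must be >= 0 and area > 0.")
  }
  yields <- pod_mass_g * 10000 / area_m2 / 1000
  list(mean = mean(yields), se = sd(yields) / sqrt(length(yields)),
       n = length(yields))
}

#' Yield from the product of component means, with delta-method error
#'
#' Fresh weight yield = plants per area x pods per plant x pod weight.
#' With density in plants/ha and pod weight in grams the product is
#' divided by 1000 to give kg/ha. The standard error uses the first-order
#' delta method for a product of independent estimates:
#' `mean * sqrt(sum((se_i / mean_i)^2))`.
#'
#' @param density `c(mean, se)` of plant density (plants/ha).
#' @param pods `c(mean, se)` of pods per plant.
#' @param pod_weight `c(mean, se)` of pod fresh weight (g).
#' @return List with `mean` and `se` (kg/ha).
#' @examples
#' product_of_means_yield(c(234077, 0), c(5.28, 0.52), c(0.92, 0.05))
#' @export
product_of_means_yield <- function(density, pods, pod_weight) {
  comps <- list(density = density, pods = pods, pod_weight = pod_weight)
  for (nm in names(comps)) {
    v <- comps[[nm]]
    if (length(v) != 2 || anyNA(v)) {
      abort(sprintf("`%s` must be c(mean, se).", nm))
    }
    if (v[1] <= 0) abort(sprintf("`%s` mean must be > 0.", nm))
    if (v[2] < 0) abort(sprintf("`%s` se must be >= 0.", nm))
  }
  m <- density[1] * pods[1] * pod_weight[1] / 1000
  cv2 <- (density[2] / density[1])^2 + (pods[2] / pods[1])^2 +
    (pod_weight[2] / pod_weight[1])^2
  list(mean = m, se = m * sqrt(cv2))
}

#' Pod maturity proportions
#'
#' Two ratios describing how far a sampled crop is from harvest maturity:
#' current mean pod weight against the mature marketable pod weight
#' (default 4.91 g from commercial packet weighings; the rounded 4.9 g is
#' available via `mature_pod_weight`), and sampled yield against final
#' marketable yield. Reported to 3 decimals.
#'
#' @param current_pod_weight Mean pod weight at sampling (g).
#' @param sampled_yield Fresh pod yield at sampling (kg/ha).
#' @param final_yield Final marketable yield (kg/ha).
#' @param mature_pod_weight Mature pod reference weight (g), default 4.91.
#' @return List with `weight_proportion` and `yield_proportion`.
#' @examples
#' maturity_proportions(0.92, 1166, 10578)  # 0.187 and 0.110
#' @export
maturity_proportions <- function(current_pod_weight, sampled_yield,
                                 final_yield, mature_pod_weight = 4.91) {
  check_number(current_pod_weight, "current_pod_weight", lower = 0)
  check_number(sampled_yield, "sampled_yield", lower = 0)
  if (mature_pod_weight <= 0 || final_yield <= 0) {
    abort("reference pod weight and final yield must be > 0.")
  }
  list(weight_proportion = round(current_pod_weight / mature_pod_weight, 3),
       yield_proportion = round(sampled_yield / final_yield, 3))
}

#' Required sample size to estimate a mean within a relative error
#'
#' From an observed mean, standard error and sample count, the coefficient
#' of variation is `CV = se * sqrt(n_observed) / mean` and the required
#' size under simple random sampling is `n = ceiling((z * CV /
#' rel_error)^2)` with `z` the two-sided standard-normal quantile, floored
#' at 1.
#'
#' @param mean Observed mean (> 0).
#' @param se Observed standard error of the mean (> 0).
#' @param n_observed Number of samples behind `mean`/`se` (>= 2).
#' @param rel_error Target relative error, default 0.10.
#' @param confidence Two-sided confidence level, default 0.95.
#' @return Minimum number of samples (integer >= 1).
#' @examples
#' required_sample_size(15.58, 0.83, 11)  # 12
#' @export
required_sample_size <- function(mean, se, n_observed, rel_error = 0.10,
                                 confidence = 0.95) {
  check_number(mean, "mean")
  if (mean <= 0) abort("`mean` must be > 0.")
  check_number(se, "se", lower = 0)
  check_number(n_observed, "n_observed", lower = 2)
  check_number(rel_error, "rel_error")
  if (rel_error <= 0) abort("`rel_error` must be > 0.")
  check_number(confidence, "confidence")
  if (confidence <= 0 || confidence >= 1) {
    abort("`confidence` must be in (0, 1).")
  }
  cv <- se * sqrt(n_observed) / mean
  z <- qnorm(1 - (1 - confidence) / 2)
  max(1L, as.integer(ceiling((z * cv / rel_error)^2)))
}
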