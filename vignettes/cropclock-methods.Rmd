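---
title: "Agro-meteorological derivation and modelling of green bean phenology and yield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agro-meteorological derivation and modelling of green bean phenology and yield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropclock)
```

## The problem

Fresh-market green beans (*Phaseolus vulgaris* L.) in subtropical Queensland
are sown across staggered dates in two or three regional seasons and
harvested mechanically inside a narrow optimum-quality window. Agronomists
need to predict, from the sowing date and routinely available daily weather,
(i) how long the vegetative period (sowing to petal fall) and the pod-fill
period (petal fall to harvest) will last, and (ii) how fresh pod yield
responds to accumulated heat and to days of high-temperature stress.
`cropclock` provides the full chain: daily weather ingestion, derivation of
phenology-anchored agro-meteorological variables, and the statistical models
— season-grouped logistic growth curves, stepwise-AIC duration regressions
with prediction intervals, yield-component estimation, and sowing-date
percentile scans.

Because fresh pods are about 90% water, process-based dry-matter simulators
are a poor fit for marketable fresh weight; the approach here is empirical
statistical modelling on derived weather variables instead.

## Thermal time and windowed variables

Development is clocked in growing degree days. For a day with minimum and
maximum temperatures $T_{\min}, T_{\max}$, base $T_b$ and cap $T_c$:

$$\mathrm{GDD} = \max\!\left(0,\; \frac{\min(T_{\max}, T_c) + T_{\min}}{2} - T_b\right)$$

with defaults $T_b = 5\,^\circ$C and $T_c = 30\,^\circ$C, the convention
used for field-grown beans on daily data. Two conventions had to be fixed
where common usage varies:

* the cap is applied to $T_{\max}$ **before** averaging, and $T_{\min}$ is
  **not** floored at the base. This is the "capped-Tmax, averaging" variant;
  it is isolated behind `degree_day_rule()` so the flooring variant is a
  one-line change if ever needed;
* stress days count days with $T_{\max}$ **strictly** above the threshold
  (27.5 or 30 °C, the levels associated with flower and pod abortion).
  Whether the original tally used ≥ or > is not documented; strict `>` is
  the package's fixed choice.

Windows are anchored at phenology dates. An anchor-to-anchor window (e.g.
vegetative: sowing → petal fall) spans `[start + 1, end]`, so its length in
days equals the plain date difference used for the growth durations — a
sowing of 19 Feb 2021 with petal fall on 1 Apr 2021 gives a 41-day
vegetative duration and a 41-day weather window, consistently. Fixed
windows after an anchor span `[anchor + 1, anchor + n]`; before an anchor,
`[anchor - n, anchor - 1]`. Sowing dates are additionally encoded as day of
the Australian financial year (1 July = day 1), which makes the sowing-day
covariate continuous across the southern-hemisphere season span.

The default feature catalogue (`default_feature_spec()`, also shipped as
`extdata/features.yaml`) covers thermal time, cumulative and mean radiation,
mean temperatures and vapour pressure per growth window, stress-day counts
(whole windows plus 5 and 15 days post petal fall), and first-7/14/28-day
post-sowing statistics. Missing anchors or uncovered windows yield explicit
`NA`s plus a problems report — never a silent zero — so complete-case
modelling is reproducible.

## Season classification

South-east Queensland (SEQ) has Autumn- and Spring-season sowings; Bowen in
north Queensland (NEQ) has a single "Middle" winter season. Published
descriptions of the SEQ boundaries conflict (narrative: Spring = Oct–Dec,
Autumn = Jan–May; observed sowing months: Spring Aug–Nov, Autumn Mar–May).
So that every calendar date classifies, the default map assigns SEQ sowings
in Jan–Jul to Autumn and Aug–Dec to Spring, and is overridable month by
month (`default_season_map()`).

## Productivity indices

Potential biomass follows the radiation-budget identities
$P_n = S_t\,\epsilon_i\,\epsilon_c / k$ and $Y_p = \eta P_n$. The growth
index implemented by `productivity_index()` is read as a photothermal
quotient,

$$I_g = \frac{R_i}{T_i - T_b}\cdot RIX,$$

mean daily radiation per unit of development above the base temperature,
scaled by the radiation-interception factor ($RIX = 1$ under full canopy,
LAI ≳ 2–3). The typeset source formula is ambiguous between this quotient
and a product; the quotient is adopted because season contrasts are
interpreted as a "radiation to temperature balance", which only the ratio
expresses. The product reading remains available via `form = "product"`.
The index is undefined when $T_i \le T_b$ and the function errors rather
than returning an infinity.

## Grouped logistic growth of fresh pod weight

Fresh pod weight $y$ against thermal time after petal fall $x$ follows a
three-parameter logistic

$$y = \frac{\mathrm{Asym}}{1 + \exp\!\big((\mathrm{xmid} - x)/\mathrm{scal}\big)},$$

fitted by nonlinear least squares. Initialisation is the classic scaled
logit self-start: $\mathrm{Asym}_0 = 1.05\max(y)$, then
$\mathrm{logit}(y/\mathrm{Asym}_0)$ regressed on $x$ gives starting `xmid`
and `scal`. Gauss–Newton iterations use the analytic Jacobian of the
logistic (via `deriv()`), relative-offset tolerance $10^{-8}$, at most 200
iterations, and a `scaleOffset` so the criterion stays defined on
noise-free data; if Gauss–Newton fails the bounded `port` algorithm is
retried with positivity constraints on `Asym` and `scal`. Grouped fits use
factor-indexed parameters, for which analytic differentiation is not
available, so they rely on `nls`'s numeric derivatives.

Only observations with $x < 1080$ °C d enter the fit (strict inequality):
past that thermal time pods turn stringy and fresh weight is beyond its
marketable optimum.

Three nested sharing structures are fitted across seasons: all parameters
common; separate `Asym` and `xmid` with common `scal`; all separate.
Selection follows the principle of parsimony: a more complex structure is
adopted only when it both lowers the RSS-based AIC *and* is significantly
better by the extra-sum-of-squares F test (default $\alpha = 0.05$). Raw
lowest-AIC selection (ties to fewer parameters) is available via
`select = "aic"`, but note that when the simpler structure is true, raw AIC
still promotes the extra parameter with asymptotic probability
$P(\chi^2_1 > 2) \approx 0.16$; the F gate keeps that error near $\alpha$,
which is why it is the default. The full AIC comparison and the nested F
tests are always returned.

AIC here (and in the duration models) is the RSS form
$n\ln(\mathrm{RSS}/n) + 2(p + 1)$ with additive constants dropped — offset
by a constant from `stats::AIC`, which cancels in any within-data
comparison.

## Duration models

Growth durations (days) are modelled by ordinary least squares on the
derived variables, after two screens:

* `collinearity_filter()` walks candidate pairs in their listed order and
  drops the later-listed one whenever $|r| \ge 0.95$ (constants are dropped
  as such) — deterministic given the ordering;
* `backward_stepwise()` starts from all remaining candidates and repeatedly
  removes the variable whose removal most lowers AIC, accepting removals
  that leave AIC unchanged (equal fit, fewer variables) and breaking ties
  between removals toward the later-listed variable. The AIC trace is
  returned and is non-increasing by construction. Complete cases are fixed
  at the full candidate set so AIC is comparable across steps. An exact fit
  reports the documented $-\infty$ AIC sentinel (an RSS below
  $10^{-12}\times$ total sum of squares is treated as zero).

Predictions carry t-based prediction intervals (residual plus estimation
variance, i.e. the leverage term), defaulting to the 80% level used for
harvest-window planning. Rows with missing features are dropped
(complete-case analysis); no imputation rule is applied.

## Yield components and sampling

Fresh yield decomposes as plants per area × pods per plant × pod weight.
Quadrat samples (e.g. 0.5625 m², a 0.75 m row segment) scale to kg/ha as
$\mathrm{g} \times 10^4 / \mathrm{area}_{m^2} / 10^3$ — fixed and
unit-tested against the classic factor-of-ten slip. The product-of-means
estimator propagates error by the first-order delta method assuming
independent components (no covariances are available):
$\mathrm{se} = \hat\mu\sqrt{\sum_i (\mathrm{se}_i/\hat\mu_i)^2}$, valid for
component CVs up to ~0.15 (verified against Monte Carlo within 10%).
Maturity is tracked as the ratio of current to mature pod weight (reference
4.91 g, with the rounded 4.9 g available) and of sampled to final yield.
The sample-size rule is z-based: $n = \lceil (z\,\mathrm{CV}/e)^2 \rceil$
with relative error $e = 0.10$ and 95% confidence, floored at 1; applied to
an observed pods-per-plant run (mean 15.58, se 0.83, n = 11) it returns 12,
the low end of the 12–15 samples needed to estimate the mean within 10%.

## Sowing-date scans

`scan_sowings()` builds a grid of hypothetical sowings (locations × dates,
configurable step), assigns petal fall and harvest from fixed
season-specific durations (default 41 + 21 days; model-predicted durations
are deliberately *not* the default to avoid circularity between the scan
and the duration models), derives the full feature set per sowing, and
drops sowings whose windows overrun the weather coverage (counted, never
silent). `percentile_summary()` reports the median and 20th/80th
percentiles per season × variable using R's default type-7
linear-interpolation quantiles — stated explicitly because published
summary tables cannot adjudicate between quantile conventions without the
raw data.

## Synthetic weather

No weather or crop data ship with the package; `simulate_weather()` stands
in for station exports so everything runs offline. It emulates a
subtropical Queensland site: sinusoidal annual cycles in daily maximum
temperature and radiation peaking in mid-January (southern-hemisphere
summer, `peak_day_of_year = 15`), daily Gaussian noise, minima offset below
maxima and clamped to `tmin <= tmax`, radiation clamped at 0.1 MJ m⁻².
Defaults (mean tmax 27 °C, amplitude 6.5 °C, tmin offset 10.5 °C, noise sd
2 °C, mean radiation 19 MJ m⁻², amplitude 7 MJ m⁻²) are typical of
south-east Queensland bean districts. Vapour pressure is derived from the
overnight minimum via the Magnus saturation formula (tmin as a dew-point
proxy) and rain is an independent wet-day gamma process, so the full
feature catalogue can be exercised. The generator is a pure function of
(parameters, start, length): it neither reads nor perturbs the caller's
RNG state.

What the generator does **not** emulate: autocorrelated synoptic weather
(fronts, heat waves arrive as independent daily draws), rain–temperature
and rain–radiation dependence, inter-annual drift, and site-specific
topographic effects. Passing tests therefore demonstrate correctness of the
derivations and estimators under controlled conditions, not forecast skill
on real station data.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen so each check is
informative yet quick: 200 randomised windows for the degree-day property
checks; 100 random designs for the OLS/normal-equations comparison; 2000
held-out draws for prediction-interval coverage (empirical coverage
required within ±0.03 of the nominal 80%); $10^5$ Monte-Carlo draws for the
delta-method comparison; and 100 replicates of the grouped-logistic
recovery simulation (two seasons of 500 points each, thermal time uniform
on 700–1080 °C d, noise sd 800, generating parameters Asym 6064/6371, xmid
876/836, common scal 22). Recovery is judged within 3 estimated standard
errors, and structure recovery as the fraction of replicates selecting the
common-`scal` structure.

## Known limitations

* Missing daily weather values are hard errors; no gap-filling or QA of
  observational records is attempted.
* Phenology dates are calendar dates; no time-of-day or timezone handling.
* The delta method assumes independent yield components; with correlated
  components its se is biased.
* The duration models are purely empirical; extrapolation outside the
  fitted covariate ranges (e.g. far warmer climates) is unguarded.
* Single-curve logistic fits use an analytic Jacobian; grouped fits use
  numeric derivatives (factor-indexed parameters are outside `deriv()`'s
  reach), which is slightly slower but numerically equivalent at the
  reported tolerances.
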