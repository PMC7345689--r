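---
title: "Methods: time-stratified case-crossover analysis of air pollution and ED visits"
author: "ccair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-stratified case-crossover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The design and the model

ccair estimates short-term associations between daily ambient air-pollution
concentrations and daily counts of emergency department (ED) visits. The
inferential engine is the *time-stratified case-crossover* design: each day is
compared only with the other days sharing its year, month and day-of-week.
Because referents are drawn from the same month and weekday, all confounders
that are constant within a month — long-term trends, seasonality, and
day-of-week patterns — are controlled by design rather than by modelling.

With daily counts rather than individual events, the design is fitted as a
**conditional Poisson regression**. Let $y_{si}$ be the count on day $i$ of
stratum $s$, and

$$\log \mu_{si} = \alpha_s + \beta\, x_{si} + f(t_{si}),$$

where $x_{si}$ is the pollutant concentration at the chosen lag, $t_{si}$ the
ambient temperature at the same lag, and $f$ a natural cubic spline with 3
degrees of freedom. Conditioning on the stratum totals $Y_s = \sum_i y_{si}$
eliminates every $\alpha_s$: the conditional likelihood of stratum $s$ is
multinomial with cell probabilities

$$p_{si} = \frac{e^{\beta x_{si} + f(t_{si})}}{\sum_j e^{\beta x_{sj} + f(t_{sj})}},$$

so the thousands of stratum intercepts are never estimated. For event-level
data this conditional likelihood coincides with conditional logistic
regression on the case-crossover referent sets; the test suite verifies this
equivalence numerically against `survival::coxph` on expanded event data and
against a brute-force one-dimensional maximisation.

Counts of ED visits are typically overdispersed. Estimation keeps the Poisson
mean structure and scales the variance by the **Pearson dispersion**

$$\hat\phi = \frac{1}{n - S - p} \sum_{si} \frac{(y_{si} - \hat\mu_{si})^2}{\hat\mu_{si}},$$

where $S$ is the number of informative strata (the eliminated intercepts
count as estimated parameters) and $p$ the number of regression columns.
Fitted means distribute each stratum's observed total over its days by the
fitted multinomial probabilities, so they conserve the stratum totals exactly.
All standard errors, intervals and p-values use the $\hat\phi$-scaled
variance.

Results are reported as the **relative risk per interquartile range**,
$RR = e^{\hat\beta \cdot IQR}$ with 95% interval
$e^{(\hat\beta \pm 1.96\,\hat{se}) \cdot IQR}$, the conventional reporting
scale in this literature.

## Exposure metrics

* **Daily mean across monitors.** The data model is hourly concentrations
  from several fixed monitors. Within each hour the monitors reporting are
  averaged first, and the daily value is the mean over hours; this order is
  robust to monitors with different missingness patterns. A day requires at
  least 75% of its 24 hours (18 h) to be observed — a standard regulatory
  convention; below that the day is missing.
* **Daily maximum 8-h ozone.** The maximum over the 17 same-day windows
  starting at hours 0–16 of the 8-h window mean; a window needs at least 6
  observed hours. Windows do not cross midnight.
* **AQHI.** Canada's Air Quality Health Index,
  $\tfrac{1000}{10.4}\,(e^{0.000871\,NO_2} + e^{0.000537\,O_3} +
  e^{0.000487\,PM_{2.5}} - 3)$, with fixed published coefficients. It is
  computed from the same daily metrics as the single-pollutant models (daily
  mean NO₂, max-8h O₃, daily mean PM₂.₅), since no alternative input metric
  is defined for it. It is zero exactly at the origin (implemented with
  `expm1`) and strictly increasing in each pollutant.
* **Lags.** Exposure at lag $k$ is the concentration $k$ days before the
  outcome day, $k = 0,\dots,5$ by default; temperature is lagged by the same
  number of days, so every model adjusts for the exposure-day temperature.
* **IQR.** Quartiles use linear interpolation between order statistics
  (R's default "type 7"). Published IQRs computed under other conventions
  can differ in the last digit, so the convention is recorded in the
  `scaling_spec` object. The IQR is computed once per pollutant from the
  unlagged daily series over the analysis period, so all lags of a pollutant
  share one scale.

## The spline basis

`nsb()` implements the natural cubic spline basis from first principles
(Cox–de Boor recursion plus a QR projection onto the zero-second-derivative
constraint at the boundary knots) and follows the most common regression
convention: `df` columns without intercept place `df − 1` internal knots at
equally spaced quantiles of the covariate — for `df = 3`, at the 33.3rd and
66.7th percentiles — with boundary knots at the observed range and linear
extrapolation beyond. The tests require agreement with the reference
`splines::ns()` basis to 10⁻⁸. Knot quantiles are period-wide quantiles of
the lag-matched temperature series (not per-subgroup), computed from the
non-missing values before degenerate-stratum exclusions; the fit is refit per
lag, so each lag's basis is built from its own lagged series.

## Numerical choices

* Newton–Raphson on the conditional log-likelihood with analytic gradient and
  Hessian and step-halving; convergence requires a relative log-likelihood
  change below 10⁻¹⁰ *and* every score component below 10⁻⁸ relative to its
  natural magnitude (`1 + Σᵢ |xᵢⱼ| μᵢ` for column j). The relative form
  matters: with ~84,000 events the floating-point floor of the absolute score
  is above 10⁻⁸, while for small datasets the criterion is effectively
  absolute.
* Log-sum-exp stabilisation per stratum (subtracting the stratum maximum of
  the linear predictor) prevents overflow.
* Rows with missing response, exposure, temperature or stratum are excluded
  and counted; strata reduced to fewer than 2 days, or with zero total count,
  carry no conditional information and are dropped and counted.
* A covariate with no within-stratum variation anywhere makes its coefficient
  inestimable; this is detected before iteration and raised as an error
  (the analysis grid records it as a failed cell rather than stopping).
* In saturated fits with non-positive residual degrees of freedom the
  dispersion falls back to 1 (model-based variance); the strict accessor
  `pearson_dispersion()` still errors there.
* 95% intervals use the conventional 1.96 (not `qnorm(0.975)`), matching how
  such results are reported; other levels use exact normal quantiles.
* Significance in the qualitative map is *strictly* `rr_low > 1`; a lower
  limit exactly at 1 is classified 0.

## The analysis grid and sensitivity analyses

`run_grid()` fits every combination of subgroup (all patients, each sex, sex
× age group, and disorder category × all/male/female by default), pollutant
(NO₂, max-8h O₃, PM₂.₅) and lag (0–5). "All patients" rows aggregate the
subgroup counts day by day before fitting — they are single fits on summed
counts, not pooled estimates. Failed cells are reported with their reason,
never silently dropped, and a re-run on the same inputs is bit-identical.
**No multiple-testing adjustment is applied across the grid**: each cell
carries its own unadjusted 95% interval, and the significance map must be
read with that in mind.

Two sensitivity analyses mirror common practice: halving the study period at
a calendar boundary (strata are rebuilt independently within each half, so no
stratum spans the cut) and replacing the single pollutant with the AQHI to
represent the pollutant mixture, scaled per AQHI IQR.

The default study period runs 1 April 2004 – 31 December 2015 (4292 days).
Reference summaries are ambiguous about a January versus April 2004 start;
the April start is the one consistent with the 4292-day count and is used
throughout, with the discrepancy documented rather than resolved.

The default ICD-10 mapping assigns the standard chapter blocks to the seven
categories (F00–F09 organic, F10–F19 substance-related, F20–F29 schizophrenic
and psychotic, F30–F39 mood, F40–F48 anxiety, F60–F69 personality; remaining
F-chapter codes and the self-harm codes X60–X84 to "other"). The published
appendix listing the exact codes is hosted outside the article, so the map is
a documented default, replaceable by any table with the same columns.

## The synthetic world

Real inputs (ED visit records, monitoring-network concentrations) are
confidential or external, so the package ships a generator whose defaults
*are* the reference study's marginal conditions:

* Pollutants and temperature are seasonal Gaussian AR(1) series; pollutants
  are clipped at zero. Levels, amplitudes and noise scales are calibrated so
  that simulated medians sit near the published daily summaries (NO₂
  ≈ 16 ppb, max-8h O₃ ≈ 31.5 ppb, PM₂.₅ ≈ 6–7 µg/m³, temperature quartiles
  ≈ 1.7/18.4 °C, AQHI IQR ≈ 1). Clipping (rather than a log-normal) keeps
  the stated marginal scales directly interpretable; it is configurable.
* Counts follow the model the analysis assumes:
  $\log \mu_d = \alpha_{s(d)} + \beta\,x_{d-\ell} + f(t_{d-\ell})$ with
  stratum effects $\alpha_s \sim N(0, 0.05)$, a mild quadratic temperature
  effect, an average of ≈ 19.6 visits/day (83,985 visits / 4292 days), and
  negative-binomial noise with variance $\phi\mu$ ($\phi = 1.3$ by default).
  Quasi-Poisson is an estimation device, not a generative family, so a
  concrete overdispersed family had to be chosen; the negative binomial with
  a variance factor is the natural one.
* Subgroup tables split each day's total multinomially with shares
  proportional to the published sex × age × category totals.

What the generator does **not** emulate: spatial monitor structure, the
right skew of real PM₂.₅, pollution–temperature dependence beyond shared
seasonality, holiday effects, and any real diagnostic-coding behaviour. A
green test therefore establishes that the estimator recovers known effects
with nominal coverage *under the assumed model* — it cannot validate the
substantive findings of any particular city, which require the confidential
registry data.

Validation uses this world end to end: 200-replicate parameter recovery at a
true RR of 1.02 per IQR over 4292 days with $\phi = 1.3$ (CI coverage
required in 93–97%, mean bias of $\hat\beta$ under 10%), type-I control of
the significance map under a null effect (≤ 5% of cells flagged per lag),
and Pearson-dispersion calibration under Poisson and variance-doubled
simulation.

## Limitations

Exposure is a city-wide average, so individual exposure misclassification is
non-differential and biases toward the null; the design controls slow
confounders but not fast ones that co-vary within a month (e.g. influenza
waves); the Wald intervals rely on large-sample normality, which is adequate
at thousands of events but not for the very sparse category × sex × age
cells, where the grid reports wide intervals or explained failures.
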