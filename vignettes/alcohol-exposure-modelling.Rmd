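---
title: "Modelling population alcohol exposure: distributions, PAFs, and upshifting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling population alcohol exposure: distributions, PAFs, and upshifting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcopaf)
```

## The modelling problem

Estimating the share of a disease burden attributable to alcohol requires
three ingredients: the population's exposure distribution (how much people
drink, in grams of pure alcohol per day), a dose-response relative-risk
curve RR(x) for the disease, and a formula combining them into a
Population-Attributable Fraction (PAF). Surveys provide drinker-level
consumption, but they are noisy, stratified by sex and age, and typically
capture only 30-60% of the alcohol known to be sold. This package
implements the full chain: fitting parametric consumption distributions to
survey microdata, computing categorical and continuous PAFs, characterizing
the fitted Gamma distribution by the linear relationship between its mean
and standard deviation, and "upshifting" a fitted distribution so its mean
matches per-capita sales figures.

## Consumption distributions

Current drinkers' average daily consumption is right-skewed and unimodal.
Three two-parameter families are supported, all on g/day:

* **Log-Normal**(\(\mu, \sigma\)): \(\log x \sim N(\mu, \sigma^2)\). Easy to
  fit, but its tail is heavier than consumption data usually support.
* **Gamma**(\(\kappa, \theta\)): mean \(\kappa\theta\), sd
  \(\theta\sqrt{\kappa}\). The recommended default: flexible, and its mean
  is exactly the sample mean at the MLE, which makes calibration against
  per-capita figures trivial.
* **Weibull**(\(\gamma, \theta\)): mean \(\theta\Gamma(1+1/\gamma)\), sd
  \(\theta\sqrt{\Gamma(1+2/\gamma)-\Gamma(1+1/\gamma)^2}\). Behaves very
  like the Gamma in practice.

Shapes below 1 - the norm for drinking data - make the Gamma and Log-Normal
densities diverge at zero. `dist_pdf()` therefore treats non-positive
points as errors rather than returning 0: a zero in drinker data is an
upstream cleaning problem, and silent zeros would mask it. Weibull moment
inversion solves the coefficient-of-variation equation by bisection on
\(\gamma \in [0.05, 50]\) (the CV is monotone decreasing in \(\gamma\), so
bracketing is guaranteed; tolerance 1e-10), and all \(\Gamma(\cdot)\)
evaluations go through `lgamma()` because \(2/\gamma\) exceeds 6 for the
smallest shapes seen in real surveys.

## Fitting

`preprocess_consumption()` applies the standard cleaning: current drinkers
only, missing consumption dropped, values above 300 g/day winsorized to 300
(capped, not deleted - an average above 300 g/day is physiologically
implausible reporting, but the respondent is still a heavy drinker), and
near-zero averages lifted to 0.01 g/day by default (quantity-frequency
instruments can produce arbitrarily small averages; the alternative
`"reject"` policy errors instead). Ages bin into the eight conventional
groups 15-24 through 85+ with inclusive lower bounds.

`fit_consumption()` maximizes the likelihood. The Log-Normal solution is
closed form on logs. For Gamma and Weibull the scale is concentrated out
and Newton-Raphson runs on the one-dimensional profile score of the shape
(method-of-moments start for Gamma, the \(\pi/\sqrt{6}\) log-moment start
for Weibull), with step-halving whenever a step leaves the domain or
worsens the score, a convergence tolerance of 1e-8 on the full score
vector, and a 100-iteration cap. Quadratic convergence typically ends in
3-6 iterations. The Gamma profile construction enforces
\(\hat\kappa\hat\theta = \bar x\) identically - the property that makes the
Gamma the natural family for per-capita calibration.

## PAF computation

The categorical PAF is
\(\sum_i P_i(RR_i-1) \big/ \left[\sum_i P_i(RR_i-1) + 1\right]\), summing
over drinker categories and the former-drinker cell. The continuous PAF
replaces the category sum with
\(P_a RR_a + P_{ex} RR_{ex} + \int_0^{U} P(x)RR(x)\,dx\) where
\(P(x) = p_{current} f(x)\). The integral uses the composite trapezoidal
rule on a uniform 0.01 g/day grid over (0.01, U], U = 150 g/day by default
(configurable to 300). Two boundary corrections keep the calculation exact
in probability: drinker mass beyond U (from the closed-form CDF) enters at
RR(U) - capping the tail's risk exactly as winsorization caps the data -
and the small mass below 0.01 enters at RR(0.01). Diagnostics columns
report the integral and both masses so the cap's influence is visible.

Relative-risk curves are strictly user configuration: disease-specific
coefficients come from meta-analyses and the package ships none as
constants. Built-in families are log-linear \(e^{b_1 x}\) (exponential
growth, typical of pancreatitis or breast cancer), log-quadratic
\(e^{b_1 x + b_2 x^2}\) (the J-shape seen for diabetes when
\(b_1 < 0 < b_2\)), piecewise-linear interpolation through user knots, and
the constant null curve. Validation enforces RR(0) = 1 - zero consumption
is the counterfactual - and positivity over the 0-300 g/day scan range.
Coefficients used in the examples and tests (e.g. \(b_1 = 0.018\)) are
illustrative, not published epidemiology.

A J-shaped curve with a low-mean exposure yields a negative PAF: current
drinking prevents cases relative to universal abstention. That sign is
correct and preserved everywhere.

`discretize_exposure()` bridges the two PAF routes by binning the
continuous model (prevalences from exact CDF differences, RR at bin
midpoints or mass-weighted), carrying the boundary masses as their own
cells. As the bin width shrinks the categorical PAF converges to the
continuous one; the test suite verifies agreement to well under 0.002 at
0.1 g/day bins. `paf_decomposition()` splits the drinkers' excess-risk
integral at cutpoints (96, 120, 150, 200 g/day are conventional) into
shares that sum to one exactly, because the total is defined as the sum of
the per-segment integrals.

### Distribution choice and the integration cap

With families fitted to the *same* survey data, the Log-Normal's inflated
implied moments push its PAF above the Gamma's and Weibull's for convex
increasing risk curves in the vast majority of strata, while Gamma and
Weibull stay within about 0.01 of each other - the reason the Gamma (or
Weibull) is preferred for burden estimation. At *matched* mean and sd the
picture is subtler: the Log-Normal's heavier tail inflates the PAF only
while the integration cap does not bind. With U = 150 and drinker means
above roughly 10-15 g/day, assigning RR(U) to the capped tail neutralizes
most of the Log-Normal's extra tail mass and the ordering can reverse.
The acceptance suite states the matched-moments ordering across the full
5-40 g/day mean grid and is expected to fail at the upper means under the
default cap; the fitted-route dominance and the Gamma-Weibull closeness are
the results that hold robustly.

## The mean-SD relationship and upshifting

Across hundreds of sex-age-country strata, the sd of the fitted Gamma is
very nearly proportional to its mean, with a sex-specific slope (reported
values in the literature: about 1.26 for women, 1.17 for men).
`fit_meansd()` estimates this by OLS - with a free intercept by default,
since published analyses report only slopes and a zero-intercept variant is
available; reports always name the policy, and note that `lm()`'s R² for
origin regressions is the uncentered variant. `meansd_interaction()` tests
the sex difference at \(\alpha = 0.05\) via the pooled interaction model.
Diagnostics use Cook's distance at the conventional 4/n threshold and test
homoscedasticity by regressing squared residuals on fitted values (all
thresholds configurable; none are canonical). The weighted (by stratum n)
variant is available; the default is unweighted.

`upshift_gamma()` is the payoff: given a per-capita-consistent target mean
\(\mu^*\) (e.g. survey drinker mean times
`coverage_factor(percap, survey_percap(records))`), it sets
\(\sigma^* = slope\cdot\mu^*\) (+ intercept) and returns the Gamma with
\(\kappa = (\mu^*/\sigma^*)^2\), \(\theta = \sigma^{*2}/\mu^*\). Under a
zero intercept \(\kappa = slope^{-2}\) independent of the mean, so an
entire country's exposure distribution follows from average consumption
alone - which is exactly what makes the method usable where only aggregate
statistics exist. A CV-preserving variant (keep the survey fit's shape,
stretch the scale) is available for sensitivity analysis. Apportioning
per-capita totals across strata, and tourist/unrecorded adjustments, are
out of scope: the module implements the moment-rescaling step, taking the
corrected drinker mean as input.

## Synthetic data and what the tests do (and do not) show

`simulate_survey()` generates microdata with the structure of multi-country
drinking surveys: a lifetime-abstainer / former-drinker / current-drinker
trichotomy (defaults 0.10 / 0.15, within the ranges published prevalence
tables span) and per-sex Gamma consumption with means 7.55 (women) and
18.29 (men) g/day and the corresponding cross-survey sds (9.86, 22.01) -
the published cross-survey averages, giving CVs near 1.2-1.3.
`simulate_panel()` emulates the multi-stratum mean-SD panel with a known
slope and proportional (heteroscedastic, 15%) or constant noise. All
generators take an explicit integer seed and are bit-reproducible under it;
no hidden RNG state is used.

The generators reproduce the *structure* of survey data, not its
pathologies: no survey weights, nonresponse, digit heaping, or
occasion-level drinking patterns. Passing tests therefore demonstrate the
correctness of the estimators and formulas, not robustness to those
real-data complications. Problem sizes used by the test and acceptance
suites - 2000 observations per parameter-recovery replicate, 400 strata and
200 replicates for slope-coverage, a 0.01 g/day integration grid - were
chosen so each check resolves its target quantity comfortably at desk
scale.

## Numerical choices, in one place

* Integration: trapezoid, uniform 0.01 g/day step, (0.01, 150] default
  window, closed-form CDF mass corrections at both ends.
* Newton-Raphson: profile score, tolerance 1e-8 on the score, 100
  iterations max, step-halving safeguard.
* Weibull CV inversion: bisection on [0.05, 50], tolerance 1e-10, explicit
  error when the target CV is unattainable.
* Zero-consumption drinkers: lifted to 0.01 g/day by default
  ("reject" selectable).
* Winsorization at 300 g/day: capping, not deletion; the cap is an
  argument everywhere it applies.
* Age bins: [15,25), [25,35), ..., [85, Inf); ages under 15 excluded.
* PAF denominators are validated positive; degenerate strata and
  non-bracketing inversions raise descriptive errors rather than returning
  NA.

## Known limitations

Fitted categorical PAFs depend on the category boundaries, for which there
is no canonical choice; the defaults (women 0/20/40, men 0/40/60 g/day) are
conventional burden-of-disease bands and fully configurable. The mean-SD
relationship is estimated globally per sex; regional heterogeneity is not
modelled. The 300 g/day cap is treated as winsorization rather than a
censored-likelihood term, matching standard practice for these data.
Survey design weights are not used in fitting.
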