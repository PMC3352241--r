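# alcopaf

Population-level alcohol exposure distributions and attributable fractions.

Burden-of-disease work needs the *distribution* of alcohol consumption in a
population, not just its average: for most alcohol-related diseases the
dose-response curve RR(x) is nonlinear, so the Population-Attributable
Fraction (PAF)

```
        P_a RR_a + P_ex RR_ex + ∫₀ᵁ P(x) RR(x) dx − 1
PAF = ──────────────────────────────────────────────────
        P_a RR_a + P_ex RR_ex + ∫₀ᵁ P(x) RR(x) dx
```

depends on how consumption is spread across drinkers (P_a, P_ex: prevalence
of lifetime abstainers and former drinkers; P(x): population density of
consuming x grams of pure alcohol per day). `alcopaf` provides, in
tidyverse style (tibbles in and out, `tidy()`/`glance()` methods,
`autoplot()` figures):

* maximum-likelihood fitting of **Log-Normal, Gamma and Weibull**
  consumption distributions to drinker-level survey microdata
  (Newton-Raphson on the profile likelihood; closed form for the
  Log-Normal), with the standard cleaning: missing values excluded, values
  above 300 g/day winsorized, sex and eight age-group strata;
* **categorical and continuous PAFs** under pluggable relative-risk curves
  (log-linear, J-shaped log-quadratic, piecewise; coefficients are user
  configuration, never package constants), their difference, a
  cutpoint decomposition of the excess-risk integral, and a discretizer
  linking the two routes;
* the **mean-SD characterization** of the Gamma distribution: OLS of the
  stratum Gamma sd on its mean by sex, with interaction test, Cook's
  distance influence and homoscedasticity diagnostics — across many
  surveyed strata sd ≈ slope × mean with sex-specific slopes near 1.26
  (women) and 1.17 (men);
* **upshifting**: rescaling a fitted Gamma so its mean matches per-capita
  sales figures, with sd from the mean-SD slope; under a zero intercept the
  shape is `slope^-2` regardless of the mean, so a whole exposure
  distribution follows from average consumption alone;
* a **synthetic survey generator** (abstainer/former/current mixture,
  right-skewed drinker consumption, explicit seeding) so every stage is
  testable without restricted survey data.

## Worked example

```r
library(alcopaf)

records <- simulate_survey(5000, seed = 1)      # survey-like microdata
x <- preprocess_consumption(records, sex = "M") # drinkers, cleaned, capped
fit <- fit_consumption(x, "gamma")
fit
#> <alc_fit> gamma fit to n = 1820 drinkers | loglik = -6927.1715 | converged in 3 iteration(s)
#> <alc_dist> gamma(shape = 0.708237, scale = 24.4394)
#>   mean = 17.31 g/day, sd = 20.57 g/day
```

The fitted Gamma mean equals the sample mean exactly (an MLE identity for
this family). Combine it with status prevalences and an illustrative
exponential risk curve:

```r
rr <- rr_spec("log_linear", coef = 0.018, rr_former = 1.2)
ex <- exposure_model(p_abstainer = 0.10, p_former = 0.15, dist = fit$dist)
paf_continuous(ex, rr)
#> # A tibble: 1 × 8
#>     paf method     family integral tail_mass lower_mass upper  step
#>   <dbl> <chr>      <chr>     <dbl>     <dbl>      <dbl> <dbl> <dbl>
#> 1 0.287 continuous gamma      1.11  0.000713    0.00328   150  0.01
```

28.7% of this disease's burden is attributable to current drinking in the
simulated population; the diagnostics show the risk-weighted integral and
the (small) probability mass handled outside the integration window. A
0.1 g/day categorical discretization agrees to 3e-5. The mean-SD
characterization and an upshift to a doubled (per-capita-consistent) mean:

```r
panel <- simulate_panel(400, slope = 1.25, noise = 0.15, seed = 2)
glance(fit_meansd(panel, sex = "F"))
#> # A tibble: 1 × 8
#>   sex   slope conf.low conf.high intercept r.squared     n intercept_policy
#> 1 F      1.26     1.24      1.29    0.0795     0.956   400 free

up <- upshift_gamma(2 * dist_moments(fit$dist)$mean, sd_model = 1.171)
up
#> <alc_dist> gamma(shape = 0.729266, scale = 47.4694)
#>   mean = 34.62 g/day, sd = 40.54 g/day
paf_continuous(exposure_model(0.10, 0.15, up), rr)$paf
#> [1] 0.5275605
```

Correcting the survey's undercoverage nearly doubles the estimated
attributable fraction — the reason upshifting matters.

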