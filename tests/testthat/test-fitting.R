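test_that("preprocessing filters status, drops missing, winsorizes, and errors on empty strata", {
  rec <- make_records(
    list("F", "30", "abstainer", ""),
    list("F", "40", "former", ""),
    list("F", "35", "drinker", "10"),
    list("F", "50", "drinker", ""),
    list("F", "22", "drinker", "310"),
    list("M", "60", "drinker", "5")
  )
  expect_equal(sort(preprocess_consumption(rec, sex = "F")), c(10, 300))
  expect_equal(preprocess_consumption(rec, sex = "F", cap = 100), c(10, 100))
  expect_equal(preprocess_consumption(rec, sex = "M"), 5)
  expect_equal(preprocess_consumption(rec, sex = "F", age_group = "35-44"), 10)
  expect_error(preprocess_consumption(rec, sex = "M", age_group = "15-24"), "Empty stratum")

  zero <- make_records(list("F", "30", "drinker", "0"), list("F", "31", "drinker", "2"))
  expect_equal(preprocess_consumption(zero), c(0.01, 2))
  expect_error(preprocess_consumption(zero, zero_policy = "reject"), "0.01 g/day")
})

test_that("age grouping uses inclusive lower bounds and excludes minors", {
  expect_equal(
    as.character(age_group(c(15, 24, 25, 84, 85, 99))),
    c("15-24", "15-24", "25-34", "75-84", "85+", "85+")
  )
  expect_true(is.na(age_group(14)))
})

test_that("log-normal fit is the closed form on logs", {
  x <- c(1, exp(1), exp(2))
  f <- fit_consumption(x, "lognormal", min_n = 3)
  expect_equal(f$dist$params[["meanlog"]], 1, tolerance = 1e-12)
  expect_equal(f$dist$params[["sdlog"]], sqrt(2 / 3), tolerance = 1e-12)
  expect_true(f$converged)
})

test_that("the fitted Gamma mean equals the sample mean", {
  set.seed(5)
  for (r in 1:20) {
    x <- rgamma(sample(50:500, 1), shape = runif(1, 0.4, 2), scale = runif(1, 2, 30))
    f <- fit_consumption(x, "gamma")
    expect_equal(f$dist$params[["shape"]] * f$dist$params[["scale"]], mean(x),
      tolerance = 1e-6
    )
  }
})

test_that("fits are stationary maxima that dominate the method-of-moments start", {
  set.seed(8)
  x <- rgamma(2000, shape = 0.7, scale = 15)
  for (fam in c("gamma", "weibull")) {
    f <- fit_consumption(x, fam)
    expect_true(f$converged)
    expect_lt(max(abs(f$gradient)), 1e-6 * max(1, abs(f$loglik)))
    # moment-matched start never beats the optimum
    mm <- dist_from_moments(fam, mean(x), sd(x))
    ll_mm <- sum(log(dist_pdf(mm, x)))
    expect_gte(f$loglik, ll_mm)
  }
})

test_that("maximum-likelihood estimates match an independent fitter", {
  skip_if_not_installed("fitdistrplus")
  set.seed(13)
  x <- rgamma(1500, shape = 0.8, scale = 12)
  for (fam in c("gamma", "weibull", "lognormal")) {
    f <- fit_consumption(x, fam)
    ref <- fitdistrplus::fitdist(x, switch(fam,
      gamma = "gamma", weibull = "weibull", lognormal = "lnorm"
    ))
    est <- ref$estimate
    mine <- f$dist$params
    if (fam == "gamma") {
      # oracle tolerance: fitdistrplus stops at optim precision, not machine
      expect_equal(mine[["shape"]], unname(est["shape"]), tolerance = 1e-3)
      expect_equal(mine[["scale"]], 1 / unname(est["rate"]), tolerance = 1e-3)
    } else if (fam == "weibull") {
      expect_equal(mine[["shape"]], unname(est["shape"]), tolerance = 1e-3)
      expect_equal(mine[["scale"]], unname(est["scale"]), tolerance = 1e-3)
    } else {
      expect_equal(mine[["meanlog"]], unname(est["meanlog"]), tolerance = 1e-6)
      # reference uses the same ML (n-denominator) variant
      expect_equal(mine[["sdlog"]], unname(est["sdlog"]), tolerance = 1e-3)
    }
  }
})

test_that("replicated fits recover the generating parameters within 3 standard errors", {
  truth <- list(
    gamma = dist_gamma(0.7, 15),
    weibull = dist_weibull(0.85, 12),
    lognormal = dist_lognormal(1.0, 1.2)
  )
  set.seed(31)
  for (fam in names(truth)) {
    hits <- 0L
    for (r in 1:10) {
      x <- dist_rand(truth[[fam]], 2000)
      f <- fit_consumption_se(x, fam)
      se <- sqrt(diag(vcov(f)))
      ok <- all(abs(f$dist$params - truth[[fam]]$params) <= 3 * se)
      hits <- hits + ok
    }
    expect_gte(hits, 9L)
  }
})

test_that("winsorization can only pull the fitted Gamma mean down", {
  set.seed(17)
  x <- rgamma(3000, shape = 0.5, scale = 60) # long tail, some values beyond 300
  f <- fit_consumption(pmin(x, 300), "gamma")
  expect_lte(f$dist$params[["shape"]] * f$dist$params[["scale"]], mean(x) + 1e-9)
})

test_that("stratified fitting returns one row per stratum and family, with failures recorded", {
  set.seed(23)
  rec <- simulate_survey(800, seed = 23)
  tab <- fit_strata(rec, families = c("gamma", "weibull"))
  expect_equal(nrow(tab), 2 * 2) # 2 sexes x 2 families, pooled ages
  expect_true(all(tab$converged))
  # pooled n equals the sum over age groups
  tab_age <- fit_strata(rec, families = "gamma", by_age = TRUE, min_n = 1)
  fitted_rows <- tab_age[!is.na(tab_age$n), ]
  pooled <- fit_strata(rec, families = "gamma")
  for (s in c("F", "M")) {
    expect_equal(
      sum(fitted_rows$n[fitted_rows$sex == s]),
      pooled$n[pooled$sex == s]
    )
  }
  # an empty stratum is reported, not fatal
  rec_f <- rec[rec$sex == "F", ]
  tab_f <- fit_strata(rec_f, families = "gamma")
  expect_true(all(is.na(tab_f$n[tab_f$sex == "M"]) | tab_f$sex == "F"))

  g <- glance(tab$fit[[1]])
  expect_named(g, c("family", "n", "logLik", "mean", "sd", "converged", "iterations"))
  td <- tidy(tab$fit[[1]])
  expect_equal(nrow(td), 2)
})
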