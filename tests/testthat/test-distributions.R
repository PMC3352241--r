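test_that("densities match hand-computable special cases and reject out-of-support input", {
  # shape 1 reduces Gamma and Weibull to the exponential
  expect_equal(dist_pdf(dist_gamma(1, 2), 0.5), 0.5 * exp(-0.25), tolerance = 1e-12)
  expect_equal(dist_pdf(dist_weibull(1, 5), 0), 0.2, tolerance = 1e-12)
  expect_equal(dist_pdf(dist_lognormal(0, 1), 1), 1 / sqrt(2 * pi), tolerance = 1e-12)

  # out-of-support points are errors, not zeros
  expect_error(dist_pdf(dist_gamma(0.7, 10), 0), "support")
  expect_error(dist_pdf(dist_lognormal(0, 1), c(1, -2)), "support")
  expect_error(dist_pdf(dist_weibull(1, 5), -0.1), "support")
  # Weibull support includes the origin
  expect_silent(dist_pdf(dist_weibull(1.2, 5), 0))

  # parameter domain
  expect_error(dist_gamma(-1, 2), "> 0")
  expect_error(dist_weibull(1, 0), "> 0")
  expect_error(dist_lognormal(0, -1), "> 0")
})

test_that("gamma log-likelihood matches the exponential special case and per-point densities", {
  expect_equal(gamma_loglik(1, 1, 1), -1, tolerance = 1e-12)
  expect_equal(gamma_loglik(c(2, 3), 1, 2), -2 * log(2) - 5 / 2, tolerance = 1e-12)

  # independent oracle: sum of pointwise log densities
  x <- c(0.5, 1.5, 4.0)
  expect_equal(
    gamma_loglik(x, 0.8, 3),
    sum(log(dist_pdf(dist_gamma(0.8, 3), x))),
    tolerance = 1e-9
  )
  set.seed(11)
  for (r in 1:10) {
    x <- rgamma(50, 1.4, scale = 8) + 0.01
    k <- runif(1, 0.3, 3)
    th <- runif(1, 1, 30)
    expect_equal(gamma_loglik(x, k, th),
      sum(dgamma(x, shape = k, scale = th, log = TRUE)),
      tolerance = 1e-9
    )
  }
  expect_error(gamma_loglik(c(1, 0), 1, 1), "> 0")
})

test_that("closed-form moments agree with published parameter/moment pairs", {
  # published multi-country reference fits, 2-dp rounded parameters
  expect_equal(dist_moments(dist_gamma(1.33, 19.72))$mean, 26.23, tolerance = 0.01)
  expect_equal(dist_moments(dist_weibull(0.60, 2.92))$mean, 4.39, tolerance = 0.01)
  # exponential: mean = sd = scale
  m <- dist_moments(dist_weibull(1, 5))
  expect_equal(c(m$mean, m$sd), c(5, 5), tolerance = 1e-12)
})

test_that("moment inversion round-trips for all families and hits the exponential at CV = 1", {
  g <- dist_from_moments("gamma", mean = 20, sd = 23.42)
  expect_equal(g$params[["shape"]], (20 / 23.42)^2, tolerance = 1e-12)
  expect_equal(g$params[["scale"]], 23.42^2 / 20, tolerance = 1e-12)

  e1 <- dist_from_moments("gamma", mean = 5, sd = 5)
  expect_equal(unname(e1$params), c(1, 5), tolerance = 1e-9)
  e2 <- dist_from_moments("weibull", mean = 5, sd = 5)
  expect_equal(unname(e2$params), c(1, 5), tolerance = 1e-7)

  set.seed(7)
  for (fam in c("lognormal", "gamma", "weibull")) {
    for (r in 1:10) {
      d <- random_dist(fam)
      m <- dist_moments(d)
      back <- dist_from_moments(fam, m$mean, m$sd)
      expect_equal(unname(back$params), unname(d$params), tolerance = 1e-6)
      m2 <- dist_moments(back)
      expect_equal(c(m2$mean, m2$sd), c(m$mean, m$sd), tolerance = 1e-8)
    }
  }
  # unattainably small Weibull CV errors rather than silently extrapolating
  expect_error(dist_from_moments("weibull", mean = 1, sd = 0.005), "inversion failed")
})

test_that("trapezoid is the composite rule and errors on malformed grids", {
  expect_equal(trapezoid(c(0, 0.5, 1), c(0, 0.5, 1)), 0.5, tolerance = 1e-12)
  g <- seq(0, 150, by = 1)
  expect_equal(trapezoid(rep(1, length(g)), g), 150, tolerance = 1e-12)
  # normalization oracle: the grid misses the sub-0.01 spike of shape < 1
  g2 <- seq(0.01, 300, by = 0.01)
  d <- dist_gamma(0.7, 10)
  v <- trapezoid(dist_pdf(d, g2), g2)
  expect_gte(v, 0.98)
  expect_lte(v, 1 + 1e-9)
  expect_equal(v + dist_cdf(d, 0.01) + (1 - dist_cdf(d, 300)), 1, tolerance = 1e-3)
  expect_error(trapezoid(1:3, 1:4), "length")
  expect_error(trapezoid(1:3, c(1, 3, 2)), "increasing")
})

test_that("densities integrate to one over the survey range, tail mass accounting for the deficit", {
  x <- seq(0.01, 300, by = 0.01)
  set.seed(21)
  for (fam in c("lognormal", "gamma", "weibull")) {
    for (r in 1:5) {
      d <- random_dist(fam)
      v <- trapezoid(dist_pdf(d, x), x)
      expect_gte(v, 0.98)
      expect_lte(v, 1 + 1e-6)
      # adding back the mass outside (0.01, 300] recovers 1
      total <- v + (1 - dist_cdf(d, 300)) + dist_cdf(d, 0.01)
      expect_equal(total, 1, tolerance = 5e-3)
    }
  }
})

test_that("Monte-Carlo moments agree with the closed forms within 3 standard errors", {
  set.seed(99)
  n <- 1e6
  cases <- list(
    dist_gamma(0.7, 15), dist_weibull(0.85, 12), dist_lognormal(1.5, 1.0)
  )
  for (d in cases) {
    m <- dist_moments(d)
    x <- dist_rand(d, n)
    se_mean <- m$sd / sqrt(n)
    expect_lt(abs(mean(x) - m$mean), 3 * se_mean)
    # conservative SE for the sd via the fourth moment
    se_sd <- sd((x - mean(x))^2) / (2 * m$sd * sqrt(n))
    expect_lt(abs(sd(x) - m$sd), 3 * se_sd)
  }
})
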