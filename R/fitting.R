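#' @importFrom dplyr mutate filter select group_by ungroup summarise arrange
#'   bind_rows bind_cols across all_of left_join if_else n
#' @importFrom purrr map map_dbl map2 pmap
#' @importFrom stats digamma trigamma lgamma optimHess
NULL

AGE_BREAKS <- c(15, 25, 35, 45, 55, 65, 75, 85, Inf)
AGE_LABELS <- c("15-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75-84", "85+")

#' Assign survey respondents to standard age groups
#'
#' Bins age in years into the eight conventional groups 15-24, 25-34, ...,
#' 75-84, 85+ (inclusive lower bound, exclusive upper). Ages below 15 return
#' `NA` and are excluded from stratified analyses.
#'
#' @param age Integer ages in years.
#' @return A factor with the eight age-group levels.
#' @export
age_group <- function(age) {
  cut(age, breaks = AGE_BREAKS, labels = AGE_LABELS, right = FALSE)
}

#' Extract the positive consumption vector for one stratum
#'
#' Applies the standard pre-fitting cleaning to drinker-level microdata:
#' keeps current drinkers in the requested sex/age stratum, drops records
#' with missing grams-per-day, winsorizes values above `cap` (reported
#' averages above 300 g/day are replaced by 300, not deleted), and handles
#' zero or near-zero averages according to `zero_policy`: `"lift"` (default)
#' raises values below 0.01 g/day to 0.01 so the log-likelihoods remain
#' defined, while `"reject"` errors on them.
#'
#' @param records A data frame of consumption records with columns `sex`,
#'   `age`, `status` (one of `"abstainer"`, `"former"`, `"drinker"`), and
#'   `grams_per_day`.
#' @param sex Optional filter, `"F"` or `"M"`.
#' @param age_group Optional age-group label filter (see [age_group()]).
#' @param cap Winsorization point, g/day.
#' @param zero_policy `"lift"` or `"reject"`.
#' @return A numeric vector of positive g/day values.
#' @export
preprocess_consumption <- function(records, sex = NULL, age_group = NULL,
                                   cap = 300, zero_policy = c("lift", "reject")) {
  zero_policy <- arg_match(zero_policy)
  records <- validate_records(records)
  if (!is.null(sex)) records <- records[records$sex %in% sex, , drop = FALSE]
  if (!is.null(age_group)) {
    grp <- age_group
    records <- records[!is.na(records$age_group) & records$age_group %in% grp, , drop = FALSE]
  }
  x <- records$grams_per_day[records$status == "drinker"]
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    abort("Empty stratum: no current drinkers with observed consumption after filtering.")
  }
  x <- pmin(x, cap)
  tiny <- x < 0.01
  if (any(tiny)) {
    if (zero_policy == "reject") {
      abort(sprintf(
        "%d drinker record(s) report < 0.01 g/day; rerun with zero_policy = \"lift\" or clean upstream.",
        sum(tiny)
      ))
    }
    x[tiny] <- 0.01
  }
  x
}

validate_records <- function(records) {
  needed <- c("sex", "age", "status", "grams_per_day")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("`records` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  records <- as_tibble(records)
  bad <- !records$status %in% c("abstainer", "former", "drinker")
  if (any(bad)) {
    abort(sprintf("Unknown drinking status %s.", records$status[bad][1]))
  }
  records$age_group <- age_group(records$age)
  records
}

#' Fit a consumption distribution by maximum likelihood
#'
#' Fits one of the three families to a positive consumption vector. The
#' Log-Normal solution is closed form (mean and ML standard deviation of the
#' logs). Gamma and Weibull are fitted by Newton-Raphson on the profile
#' score of the shape parameter, with the scale concentrated out
#' (\eqn{\hat\theta = \bar x/\hat\kappa} for Gamma,
#' \eqn{\hat\theta = (\overline{x^{\hat\gamma}})^{1/\hat\gamma}} for
#' Weibull). Starting values are method-of-moments (Gamma) or the log-moment
#' approximation (Weibull); steps are halved whenever they leave the
#' parameter domain or decrease the likelihood.
#'
#' @param x Positive consumption values, g/day (see
#'   [preprocess_consumption()]).
#' @param family `"lognormal"`, `"gamma"`, or `"weibull"`.
#' @param min_n Minimum sample size accepted.
#' @param tol Convergence tolerance on the score of the full log-likelihood.
#' @param max_iter Iteration cap for Newton-Raphson.
#' @return An object of class `alc_fit`: a list with elements `family`,
#'   `dist` (the fitted [`alc_dist`]), `n`, `loglik`, `converged`,
#'   `iterations`, and `gradient` (score vector at the optimum).
#' @examples
#' x <- rgamma(500, shape = 0.8, scale = 12)
#' fit <- fit_consumption(x, "gamma")
#' tidy(fit)
#' @export
fit_consumption <- function(x, family = c("gamma", "lognormal", "weibull"),
                            min_n = 5, tol = 1e-8, max_iter = 100) {
  family <- arg_match(family)
  if (!is.numeric(x) || anyNA(x)) abort("`x` must be numeric with no missing values.")
  if (any(x <= 0)) abort("`x` must be strictly positive; see `preprocess_consumption()`.")
  if (length(x) < min_n) {
    abort(sprintf("Need at least %d observations to fit (got %d).", min_n, length(x)))
  }
  fit <- switch(family,
    lognormal = fit_lognormal(x),
    gamma = fit_gamma_nr(x, tol = tol, max_iter = max_iter),
    weibull = fit_weibull_nr(x, tol = tol, max_iter = max_iter)
  )
  structure(
    c(list(family = family, n = length(x)), fit, list(data_mean = mean(x), data_sd = sd(x))),
    class = "alc_fit"
  )
}

fit_lognormal <- function(x) {
  lx <- log(x)
  mu <- mean(lx)
  sg <- sqrt(mean((lx - mu)^2)) # ML variant, n denominator
  dist <- dist_lognormal(mu, sg)
  list(
    dist = dist,
    loglik = sum(log(dist_pdf(dist, x))),
    converged = TRUE, iterations = 0L, gradient = c(meanlog = 0, sdlog = 0)
  )
}

# Profile score for the Gamma shape: with theta = xbar/kappa concentrated
# out, the ML shape solves log(kappa) - digamma(kappa) = log(xbar) - mean(log x).
fit_gamma_nr <- function(x, tol, max_iter) {
  n <- length(x)
  xbar <- mean(x)
  c0 <- log(xbar) - mean(log(x))
  # method-of-moments start
  k <- max(xbar^2 / max(var(x), .Machine$double.eps), 1e-3)
  f <- function(k) log(k) - digamma(k) - c0
  it <- 0L
  repeat {
    it <- it + 1L
    fk <- f(k)
    dk <- 1 / k - trigamma(k) # < 0 for all k > 0
    step <- fk / dk
    k_new <- k - step
    halvings <- 0L
    while ((k_new <= 0 || abs(f(k_new)) > abs(fk)) && halvings < 60L) {
      step <- step / 2
      k_new <- k - step
      halvings <- halvings + 1L
    }
    k <- k_new
    if (abs(f(k)) < 1e-13 || it >= max_iter) break
  }
  theta <- xbar / k
  dist <- dist_gamma(shape = k, scale = theta)
  grad <- c(
    shape = sum(log(x)) - n * log(theta) - n * digamma(k),
    scale = sum(x) / theta^2 - n * k / theta
  )
  ll <- gamma_loglik(x, k, theta)
  conv <- max(abs(grad)) <= max(tol, tol * abs(ll))
  if (!conv && it >= max_iter) {
    abort(sprintf(
      "Gamma Newton-Raphson did not converge after %d iterations (last shape %.6g, score %.3g).",
      it, k, max(abs(grad))
    ))
  }
  list(dist = dist, loglik = ll, converged = conv, iterations = it, gradient = grad)
}

# Weibull profile score: g(gamma) = sum(x^g log x)/sum(x^g) - 1/g - mean(log x)
fit_weibull_nr <- function(x, tol, max_iter) {
  n <- length(x)
  lx <- log(x)
  lbar <- mean(lx)
  g <- 1.2826 / max(sd(lx), .Machine$double.eps) # pi/sqrt(6) log-moment start
  score <- function(g) {
    w <- x^g
    sum(w * lx) / sum(w) - 1 / g - lbar
  }
  dscore <- function(g) {
    w <- x^g
    sw <- sum(w)
    a <- sum(w * lx) / sw
    sum(w * lx^2) / sw - a^2 + 1 / g^2
  }
  it <- 0L
  repeat {
    it <- it + 1L
    fg <- score(g)
    step <- fg / dscore(g)
    g_new <- g - step
    halvings <- 0L
    while ((g_new <= 0 || abs(score(g_new)) > abs(fg)) && halvings < 60L) {
      step <- step / 2
      g_new <- g - step
      halvings <- halvings + 1L
    }
    g <- g_new
    if (abs(score(g)) < 1e-13 || it >= max_iter) break
  }
  theta <- mean(x^g)^(1 / g)
  dist <- dist_weibull(shape = g, scale = theta)
  z <- (x / theta)^g
  grad <- c(
    shape = n / g + sum(lx) - n * log(theta) - sum(z * (lx - log(theta))),
    scale = (g / theta) * (sum(z) - n)
  )
  ll <- sum(log(dist_pdf(dist, x)))
  conv <- max(abs(grad)) <= max(tol, tol * abs(ll))
  if (!conv && it >= max_iter) {
    abort(sprintf(
      "Weibull Newton-Raphson did not converge after %d iterations (last shape %.6g, score %.3g).",
      it, g, max(abs(grad))
    ))
  }
  list(dist = dist, loglik = ll, converged = conv, iterations = it, gradient = grad)
}

#' @export
print.alc_fit <- function(x, ...) {
  cat(sprintf(
    "<alc_fit> %s fit to n = %d drinkers | loglik = %.4f | %s in %d iteration(s)\n",
    x$family, x$n, x$loglik,
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  print(x$dist)
  invisible(x)
}

#' @export
logLik.alc_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' Asymptotic covariance of a fitted consumption distribution
#'
#' Inverse observed information at the optimum, from a numerically
#' differentiated Hessian of the log-likelihood.
#'
#' @param object An [`alc_fit`].
#' @param ... Unused.
#' @return A 2x2 covariance matrix in the family's native parameterization.
#' @export
vcov.alc_fit <- function(object, ...) {
  p <- object$dist$params
  nll <- switch(object$family,
    lognormal = NULL,
    gamma = function(q) -gamma_loglik(object$.x, q[1], q[2]),
    weibull = function(q) -sum(log(dist_pdf(dist_weibull(q[1], q[2]), object$.x)))
  )
  if (object$family == "lognormal") {
    # closed-form Fisher information
    s2 <- p[["sdlog"]]^2
    v <- diag(c(s2 / object$n, s2 / (2 * object$n)))
    dimnames(v) <- list(names(p), names(p))
    return(v)
  }
  if (is.null(object$.x)) {
    abort("Fit does not carry its data; refit with `keep_data = TRUE` via `fit_consumption_se()`.")
  }
  h <- optimHess(unname(p), nll)
  v <- solve(h)
  dimnames(v) <- list(names(p), names(p))
  v
}

#' Fit with standard errors
#'
#' Convenience wrapper around [fit_consumption()] that retains the data so
#' [vcov()] can evaluate the observed information.
#'
#' @inheritParams fit_consumption
#' @param ... Passed to [fit_consumption()].
#' @return An `alc_fit` carrying its data.
#' @export
fit_consumption_se <- function(x, family, ...) {
  fit <- fit_consumption(x, family, ...)
  fit$.x <- x
  fit
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.alc_fit <- function(x, ...) {
  se <- tryCatch(sqrt(diag(vcov(x))), error = function(e) rep(NA_real_, 2))
  tibble(
    term = names(x$dist$params),
    estimate = unname(x$dist$params),
    std.error = unname(se)
  )
}

#' @exportS3Method generics::glance
glance.alc_fit <- function(x, ...) {
  m <- dist_moments(x$dist)
  tibble(
    family = x$family, n = x$n, logLik = x$loglik,
    mean = m$mean, sd = m$sd,
    converged = x$converged, iterations = x$iterations
  )
}

#' Fit every sex/age stratum of a survey
#'
#' Applies [preprocess_consumption()] and [fit_consumption()] to each
#' requested stratum and family. Strata that are empty or fail to converge
#' are reported in the output, not fatal.
#'
#' @param records Microdata records (see [preprocess_consumption()]).
#' @param families Families to fit.
#' @param by_age If `TRUE`, stratify by the eight age groups within sex;
#'   otherwise pool all ages per sex.
#' @param cap,zero_policy,min_n Passed to the per-stratum steps.
#' @return A tibble with one row per (sex, age_group, family): columns `sex`,
#'   `age_group` (`"all"` when pooled), `family`, `n`, parameter columns
#'   `par1`/`par2` (named per family in `term1`/`term2`), `mean`, `sd`,
#'   `loglik`, `converged`, `error`, and a list-column `fit`.
#' @export
fit_strata <- function(records, families = c("lognormal", "gamma", "weibull"),
                       by_age = FALSE, cap = 300, zero_policy = "lift", min_n = 5) {
  records <- validate_records(records)
  sexes <- sort(unique(records$sex))
  groups <- if (by_age) AGE_LABELS else "all"
  grid <- tidyr::expand_grid(sex = sexes, age_group = groups, family = families)
  rows <- pmap(grid, function(sex, age_group, family) {
    out <- tibble(
      sex = sex, age_group = age_group, family = family,
      n = NA_integer_, term1 = NA_character_, par1 = NA_real_,
      term2 = NA_character_, par2 = NA_real_,
      mean = NA_real_, sd = NA_real_, loglik = NA_real_,
      converged = FALSE, error = NA_character_, fit = list(NULL)
    )
    res <- tryCatch(
      {
        x <- preprocess_consumption(
          records,
          sex = sex,
          age_group = if (age_group == "all") NULL else age_group,
          cap = cap, zero_policy = zero_policy
        )
        fit_consumption(x, family, min_n = min_n)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
      return(out)
    }
    m <- dist_moments(res$dist)
    out$n <- res$n
    out$term1 <- names(res$dist$params)[1]
    out$par1 <- res$dist$params[[1]]
    out$term2 <- names(res$dist$params)[2]
    out$par2 <- res$dist$params[[2]]
    out$mean <- m$mean
    out$sd <- m$sd
    out$loglik <- res$loglik
    out$converged <- res$converged
    out$fit <- list(res)
    out
  })
  bind_rows(rows)
}
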