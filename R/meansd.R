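#' @importFrom stats lm coef confint cooks.distance fitted resid pf qt
NULL

#' Regress the Gamma standard deviation on the Gamma mean
#'
#' Across many survey strata the standard deviation of the fitted Gamma
#' consumption distribution is very nearly proportional to its mean, and the
#' proportionality differs by sex. This fits that relationship by ordinary
#' least squares on a panel of stratum summaries, one sex at a time.
#'
#' @param summaries A data frame with one row per stratum and columns
#'   `sex`, `gamma_mean`, `gamma_sd` (g/day), optionally `n` when
#'   `weighted = TRUE`.
#' @param sex Which sex to fit (`"F"` or `"M"`); required when both are
#'   present.
#' @param intercept `"free"` (standard OLS, default) or `"zero"` (regression
#'   through the origin). Reports name the policy used; note that the
#'   zero-intercept R-squared is the uncentered variant `lm()` reports for
#'   origin regressions.
#' @param weighted If `TRUE`, weight strata by their respondent count `n`.
#' @param conf_level Confidence level for the slope interval.
#' @return An object of class `meansd_fit` wrapping the `lm`, with elements
#'   `sex`, `slope`, `slope_ci`, `intercept` (NA under the zero policy),
#'   `r_squared`, `n`, `intercept_policy`, `model`.
#' @examples
#' panel <- simulate_panel(100, slope = 1.25, seed = 1)
#' fit <- fit_meansd(panel, sex = "F")
#' glance(fit)
#' @export
fit_meansd <- function(summaries, sex = NULL, intercept = c("free", "zero"),
                       weighted = FALSE, conf_level = 0.95) {
  intercept <- arg_match(intercept)
  d <- as_tibble(summaries)
  if (!all(c("gamma_mean", "gamma_sd") %in% names(d))) {
    abort("`summaries` needs columns gamma_mean and gamma_sd.")
  }
  if (!is.null(sex)) {
    d <- d[d$sex == sex, , drop = FALSE]
  } else if ("sex" %in% names(d) && length(unique(d$sex)) > 1) {
    abort("Both sexes present: pass `sex`, or use `meansd_interaction()` for the pooled test.")
  }
  if (nrow(d) < 3) abort(sprintf("Need at least 3 strata (got %d).", nrow(d)))
  if (sd(d$gamma_mean) == 0) abort("Degenerate design: all stratum means are identical.")
  w <- if (weighted) {
    if (!"n" %in% names(d)) abort("`weighted = TRUE` needs an `n` column.")
    d$n
  } else {
    NULL
  }
  form <- if (intercept == "free") gamma_sd ~ gamma_mean else gamma_sd ~ gamma_mean - 1
  m <- lm(form, data = d, weights = w)
  sl <- coef(m)[["gamma_mean"]]
  ci <- confint(m, "gamma_mean", level = conf_level)
  structure(
    list(
      sex = if (is.null(sex)) NA_character_ else sex,
      slope = sl, slope_ci = c(ci[1], ci[2]),
      intercept = if (intercept == "free") coef(m)[["(Intercept)"]] else NA_real_,
      r_squared = summary(m)$r.squared,
      n = nrow(d), intercept_policy = intercept,
      conf_level = conf_level, weighted = weighted,
      model = m, data = d
    ),
    class = "meansd_fit"
  )
}

#' @export
print.meansd_fit <- function(x, ...) {
  cat(sprintf(
    "<meansd_fit> sex %s | n = %d strata | intercept policy: %s%s\n",
    x$sex, x$n, x$intercept_policy, if (x$weighted) " (n-weighted)" else ""
  ))
  cat(sprintf(
    "  slope %.4f (%.0f%% CI %.4f to %.4f), R^2 = %.4f\n",
    x$slope, 100 * x$conf_level, x$slope_ci[1], x$slope_ci[2], x$r_squared
  ))
  if (!is.na(x$intercept)) cat(sprintf("  intercept %.4f g/day\n", x$intercept))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.meansd_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(
    term = rownames(s), estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @exportS3Method generics::glance
glance.meansd_fit <- function(x, ...) {
  tibble(
    sex = x$sex, slope = x$slope,
    conf.low = x$slope_ci[1], conf.high = x$slope_ci[2],
    intercept = x$intercept, r.squared = x$r_squared,
    n = x$n, intercept_policy = x$intercept_policy
  )
}

#' Test for a sex interaction in the mean-SD relationship
#'
#' Fits the pooled model `gamma_sd ~ gamma_mean * sex` and tests the
#' interaction coefficient. When the interaction is significant at `alpha`,
#' the relationship should be modeled separately by sex.
#'
#' @param summaries Stratum summaries with both sexes present.
#' @param alpha Decision threshold.
#' @inheritParams fit_meansd
#' @return A one-row tibble: `estimate` (slope difference), `statistic`,
#'   `p.value`, `alpha`, `fit_separately`.
#' @export
meansd_interaction <- function(summaries, alpha = 0.05, weighted = FALSE) {
  d <- as_tibble(summaries)
  if (!"sex" %in% names(d) || length(unique(d$sex)) < 2) {
    abort("Interaction test needs strata from both sexes.")
  }
  w <- if (weighted) d$n else NULL
  m <- lm(gamma_sd ~ gamma_mean * sex, data = d, weights = w)
  s <- summary(m)$coefficients
  row <- grep("^gamma_mean:sex", rownames(s))
  tibble(
    estimate = s[row, 1], statistic = s[row, 3], p.value = s[row, 4],
    alpha = alpha, fit_separately = s[row, 4] < alpha
  )
}

#' Regression diagnostics for a mean-SD fit
#'
#' Influence by Cook's distance (default threshold 4/n) and a
#' homoscedasticity check by the auxiliary regression of squared residuals
#' on fitted values (an F test on its slope; small p indicates
#' heteroscedasticity).
#'
#' @param fit A [`meansd_fit`].
#' @param cooks_threshold Flagging threshold for Cook's distance.
#' @return A list with `influential` (tibble of flagged strata: row id,
#'   Cook's distance, mean, sd), `cooks` (all distances), and
#'   `homoscedasticity_p`.
#' @export
meansd_diagnostics <- function(fit, cooks_threshold = NULL) {
  if (!inherits(fit, "meansd_fit")) abort("Expected a `meansd_fit`.")
  cd <- cooks.distance(fit$model)
  if (is.null(cooks_threshold)) cooks_threshold <- 4 / fit$n
  flagged <- which(cd > cooks_threshold)
  aux <- lm(resid(fit$model)^2 ~ fitted(fit$model))
  fstat <- summary(aux)$fstatistic
  p_hom <- if (is.null(fstat)) NA_real_ else unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  list(
    influential = tibble(
      stratum = flagged,
      cooks_distance = unname(cd[flagged]),
      gamma_mean = fit$data$gamma_mean[flagged],
      gamma_sd = fit$data$gamma_sd[flagged]
    ),
    cooks = unname(cd),
    cooks_threshold = cooks_threshold,
    homoscedasticity_p = p_hom
  )
}

#' Predict the Gamma standard deviation from the mean
#'
#' Applies the fitted (or fixed) sex-specific linear relationship:
#' `slope * mean` plus the intercept when one was fitted. Non-positive
#' predictions are floored at a small positive value with a warning, since a
#' Gamma distribution needs sd > 0.
#'
#' @param object A [`meansd_fit`] or a bare numeric slope.
#' @param mean Consumption mean(s), g/day, `> 0`.
#' @param intercept Intercept used when `object` is a bare slope.
#' @param floor Lower bound for the returned sd.
#' @return Predicted standard deviation(s), g/day.
#' @examples
#' predict_sd(1.171, 20) # men's slope, zero intercept
#' @export
predict_sd <- function(object, mean, intercept = 0, floor = 1e-6) {
  if (any(mean <= 0)) abort("`mean` must be > 0 g/day.")
  if (inherits(object, "meansd_fit")) {
    slope <- object$slope
    intercept <- if (is.na(object$intercept)) 0 else object$intercept
  } else {
    slope <- object
    check_number(slope, "slope")
  }
  out <- slope * mean + intercept
  if (any(out <= 0)) {
    warn("Predicted sd was not positive; flooring at a small positive value.")
    out <- pmax(out, floor)
  }
  out
}
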