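#' Undercoverage factor of a survey relative to per-capita figures
#'
#' Surveys typically capture only 30-60% of the alcohol sold; the
#' undercoverage factor is the ratio of the per-capita consumption figure to
#' the per-capita consumption implied by the survey.
#'
#' @param percap Per-capita consumption from sales/taxation statistics,
#'   g/day per adult, `> 0`.
#' @param survey_implied Survey-implied per-capita consumption, g/day per
#'   adult (see [survey_percap()]), `> 0`.
#' @return The multiplicative factor.
#' @export
coverage_factor <- function(percap, survey_implied) {
  check_number(percap, "percap", positive = TRUE)
  if (!is.numeric(survey_implied) || length(survey_implied) != 1 || survey_implied <= 0) {
    abort("`survey_implied` must be > 0; a survey with zero reported consumption cannot be calibrated.")
  }
  percap / survey_implied
}

#' Survey-implied per-capita consumption
#'
#' The mean of grams/day over all respondents, with lifetime abstainers and
#' former drinkers contributing zero and drinkers their reported average.
#' Drinkers with missing consumption are excluded from numerator and
#' denominator alike.
#'
#' @param records Microdata records (see [preprocess_consumption()]).
#' @return Per-capita g/day implied by the survey.
#' @export
survey_percap <- function(records) {
  records <- validate_records(records)
  x <- ifelse(records$status == "drinker", records$grams_per_day, 0)
  mean(x, na.rm = TRUE)
}

#' Upshift a Gamma exposure distribution to a corrected mean
#'
#' Rescales a survey-fitted Gamma consumption distribution so that its mean
#' matches a per-capita-consistent target, with the standard deviation set
#' from the mean through the sex-specific linear relationship (see
#' [fit_meansd()]). With target mean \eqn{\mu^*} and predicted
#' \eqn{\sigma^* = slope\cdot\mu^* (+ intercept)}, the result is the Gamma
#' with \eqn{\kappa = (\mu^*/\sigma^*)^2}, \eqn{\theta = \sigma^{*2}/\mu^*}.
#' Under a zero intercept \eqn{\kappa = slope^{-2}} regardless of the mean:
#' upshifting then stretches the scale only. This is also the route to an
#' exposure distribution for countries with no survey at all - only an
#' abstention prevalence and per-capita mean are needed.
#'
#' @param target_mean Corrected drinker mean \eqn{\mu^*}, g/day, `> 0`.
#'   Typically `survey drinker mean * coverage_factor(...)`.
#' @param sd_model A [`meansd_fit`] or a bare numeric slope.
#' @param intercept Intercept when `sd_model` is a bare slope.
#' @param preserve_cv If `TRUE`, ignore `sd_model` and keep the coefficient
#'   of variation of `survey_dist` instead (requires `survey_dist`).
#' @param survey_dist Optional survey-fitted [`alc_dist`], used only with
#'   `preserve_cv = TRUE`.
#' @return The upshifted Gamma [`alc_dist`].
#' @examples
#' upshift_gamma(20, sd_model = 1.171) # kappa = 1.171^-2, theta = sd^2/mean
#' @export
upshift_gamma <- function(target_mean, sd_model, intercept = 0,
                          preserve_cv = FALSE, survey_dist = NULL) {
  check_number(target_mean, "target_mean", positive = TRUE)
  if (preserve_cv) {
    if (is.null(survey_dist)) abort("`preserve_cv = TRUE` needs `survey_dist`.")
    m <- dist_moments(survey_dist)
    sd_star <- target_mean * m$sd / m$mean
  } else {
    sd_star <- predict_sd(sd_model, target_mean, intercept = intercept)
  }
  dist_from_moments("gamma", mean = target_mean, sd = sd_star)
}
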