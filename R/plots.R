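#' @importFrom ggplot2 ggplot aes geom_histogram geom_line geom_point
#'   geom_abline labs theme_minimal autoplot after_stat
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted consumption distribution over the data
#'
#' Histogram of the positive consumption values with the fitted density
#' superimposed, the standard visual check of how well a family tracks the
#' empirical consumption distribution.
#'
#' @param object An [`alc_fit`] from [fit_consumption_se()] (the fit must
#'   carry its data) or an [`alc_dist`] plus explicit `x`.
#' @param x Consumption data when `object` is a bare distribution.
#' @param binwidth Histogram bin width, g/day.
#' @param xmax Right edge of the plotted range.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.alc_fit <- function(object, x = object$.x, binwidth = 2, xmax = NULL, ...) {
  if (is.null(x)) {
    abort("Fit does not carry its data; use `fit_consumption_se()` or pass `x`.")
  }
  xmax <- xmax %||% stats::quantile(x, 0.99)
  grid <- seq(max(0.01, binwidth / 100), xmax, length.out = 400)
  dens <- tibble(x = grid, density = dist_pdf(object$dist, grid))
  ggplot(tibble(x = x), aes(x = x)) +
    geom_histogram(aes(y = after_stat(density)),
      binwidth = binwidth,
      boundary = 0, fill = "grey80", colour = "grey50"
    ) +
    geom_line(data = dens, aes(x = x, y = density), colour = "firebrick", linewidth = 0.8) +
    labs(
      x = "Average consumption (g/day pure alcohol)", y = "Density",
      title = sprintf("%s fit (n = %d)", object$family, object$n)
    ) +
    theme_minimal()
}

#' Plot the mean-SD relationship of a stratum panel
#'
#' Scatter of stratum Gamma standard deviations against means with the
#' fitted line, mirroring the standard presentation of the sex-specific
#' proportionality between the two.
#'
#' @param object A [`meansd_fit`].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.meansd_fit <- function(object, ...) {
  icpt <- if (is.na(object$intercept)) 0 else object$intercept
  ggplot(object$data, aes(x = gamma_mean, y = gamma_sd)) +
    geom_point(alpha = 0.5) +
    geom_abline(slope = object$slope, intercept = icpt, colour = "firebrick") +
    labs(
      x = "Gamma mean (g/day)", y = "Gamma standard deviation (g/day)",
      title = sprintf(
        "sd = %.3f mean%s  (R² = %.3f, n = %d)",
        object$slope,
        if (is.na(object$intercept)) "" else sprintf(" + %.3f", object$intercept),
        object$r_squared, object$n
      )
    ) +
    theme_minimal()
}

#' Plot a relative-risk curve
#'
#' @param object An [`rr_spec`].
#' @param upper Right edge of the plotted range, g/day.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rr_spec <- function(object, upper = 150, ...) {
  grid <- seq(0, upper, length.out = 400)
  ggplot(tibble(x = grid, rr = rr_eval(object, grid)), aes(x = x, y = rr)) +
    geom_line(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    labs(
      x = "Average consumption (g/day)", y = "Relative risk",
      title = if (nzchar(object$disease)) object$disease else object$family
    ) +
    theme_minimal()
}
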