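#' Relative-risk curve specifications
#'
#' Builds a pluggable dose-response curve RR(x) for average daily alcohol
#' consumption, together with the discrete relative risks for lifetime
#' abstainers (`rr_abstainer`, the counterfactual reference, 1 by default)
#' and former drinkers (`rr_former`). Coefficients are user configuration:
#' they come from disease-specific meta-analyses and are not shipped as
#' package constants; the examples below are illustrative only.
#'
#' Families:
#' * `constant` - RR(x) = 1 everywhere (null curve).
#' * `log_linear` - RR(x) = exp(b1 x); exponential risk growth, the typical
#'   shape for pancreatitis or breast cancer.
#' * `log_quadratic` - RR(x) = exp(b1 x + b2 x^2); with b1 < 0 < b2 this is
#'   the J-shaped curve seen for diabetes (protective at moderate intake,
#'   harmful beyond the nadir).
#' * `piecewise` - linear interpolation through user-supplied `(x, rr)`
#'   knots, which must start at (0, 1); constant beyond the last knot.
#'
#' @param family Curve family (see above).
#' @param coef Numeric coefficients: `b1` for `log_linear`, `c(b1, b2)` for
#'   `log_quadratic`, ignored for `constant`.
#' @param knots For `piecewise`, a data frame with columns `x` and `rr`.
#' @param rr_abstainer,rr_former Discrete relative risks, `> 0`.
#' @param disease Label carried through to outputs.
#' @return An object of class `rr_spec`.
#' @examples
#' rr <- rr_spec("log_linear", coef = 0.018, rr_former = 1.2, disease = "pancreatitis-like")
#' rr_eval(rr, c(0, 20, 60))
#' @export
rr_spec <- function(family = c("constant", "log_linear", "log_quadratic", "piecewise"),
                    coef = NULL, knots = NULL,
                    rr_abstainer = 1, rr_former = 1, disease = "") {
  family <- arg_match(family)
  check_number(rr_abstainer, "rr_abstainer", positive = TRUE)
  check_number(rr_former, "rr_former", positive = TRUE)
  spec <- structure(
    list(
      family = family, coef = coef, knots = knots,
      rr_abstainer = rr_abstainer, rr_former = rr_former, disease = disease
    ),
    class = "rr_spec"
  )
  validate_rr(spec)
}

#' Validate a relative-risk specification
#'
#' Checks the structural requirements of the curve: RR(0) = 1 (zero
#' consumption is the counterfactual reference), positivity on a scan grid
#' over 0-300 g/day, and well-formed coefficients or knots.
#'
#' @param spec An [`rr_spec`].
#' @return The validated spec, invisibly usable in pipelines.
#' @export
validate_rr <- function(spec) {
  if (!inherits(spec, "rr_spec")) abort("Expected an `rr_spec` object.")
  n_coef <- c(constant = 0L, log_linear = 1L, log_quadratic = 2L, piecewise = 0L)[[spec$family]]
  if (n_coef > 0) {
    if (!is.numeric(spec$coef) || length(spec$coef) != n_coef || anyNA(spec$coef)) {
      abort(sprintf("`%s` needs %d numeric coefficient(s).", spec$family, n_coef))
    }
  }
  if (spec$family == "piecewise") {
    k <- spec$knots
    if (is.null(k) || !all(c("x", "rr") %in% names(k)) || nrow(k) < 2) {
      abort("`piecewise` needs a `knots` data frame with columns `x`, `rr` and >= 2 rows.")
    }
    if (is.unsorted(k$x, strictly = TRUE)) abort("Piecewise knots must have strictly increasing `x`.")
    if (abs(k$x[1]) > 1e-12 || abs(k$rr[1] - 1) > 1e-9) {
      abort("Piecewise knots must start at (0, 1): zero consumption is the reference.")
    }
    if (any(k$rr <= 0)) abort("Piecewise knot relative risks must be > 0.")
  }
  scan <- rr_eval(spec, seq(0, 300, by = 1))
  if (abs(scan[1] - 1) > 1e-9) abort("RR(0) must equal 1.")
  if (any(scan <= 0) || any(!is.finite(scan))) {
    abort("RR(x) must be positive and finite over [0, 300] g/day.")
  }
  spec
}

#' Evaluate a relative-risk curve
#'
#' @param spec An [`rr_spec`].
#' @param x Consumption, g/day, `>= 0`.
#' @return Relative risks (dimensionless, positive).
#' @export
rr_eval <- function(spec, x) {
  if (!inherits(spec, "rr_spec")) abort("Expected an `rr_spec` object.")
  if (any(x < 0)) abort("`x` must be >= 0 g/day.")
  switch(spec$family,
    constant = rep(1, length(x)),
    log_linear = exp(spec$coef[1] * x),
    log_quadratic = exp(spec$coef[1] * x + spec$coef[2] * x^2),
    piecewise = {
      k <- spec$knots
      stats::approx(k$x, k$rr, xout = pmin(x, max(k$x)), rule = 2)$y
    }
  )
}

#' @export
print.rr_spec <- function(x, ...) {
  cat(sprintf(
    "<rr_spec> %s%s | RR_abstainer = %g, RR_former = %g\n",
    x$family,
    if (nzchar(x$disease)) paste0(" [", x$disease, "]") else "",
    x$rr_abstainer, x$rr_former
  ))
  if (!is.null(x$coef)) cat("  coef:", paste(signif(x$coef, 6), collapse = ", "), "\n")
  invisible(x)
}
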