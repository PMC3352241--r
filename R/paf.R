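#' Continuous exposure model for a population
#'
#' Bundles the drinking-status prevalences with the fitted consumption
#' distribution of current drinkers. The population density of consumption is
#' `p_current * dist_pdf(dist, x)`; lifetime abstainers and former drinkers
#' enter the PAF through their own prevalences and discrete relative risks.
#'
#' @param p_abstainer,p_former Prevalences of lifetime abstainers and former
#'   drinkers, in `[0, 1]` and summing with `p_current` to 1.
#' @param dist The drinkers' consumption distribution, an [`alc_dist`].
#' @param p_current Prevalence of current drinkers; defaults to the
#'   complement of the other two.
#' @return An object of class `exposure_model`.
#' @examples
#' exposure_model(0.1, 0.15, dist_gamma(0.7, 15))
#' @export
exposure_model <- function(p_abstainer, p_former, dist,
                           p_current = 1 - p_abstainer - p_former) {
  for (p in list(p_abstainer, p_former, p_current)) {
    if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
      abort("Prevalences must be single numbers in [0, 1].")
    }
  }
  if (abs(p_abstainer + p_former + p_current - 1) > 1e-9) {
    abort("Prevalences must sum to 1.")
  }
  check_dist(dist)
  structure(
    list(
      p_abstainer = p_abstainer, p_former = p_former,
      p_current = p_current, dist = dist
    ),
    class = "exposure_model"
  )
}

#' @export
print.exposure_model <- function(x, ...) {
  cat(sprintf(
    "<exposure_model> abstainers %.3f | former %.3f | current %.3f\n",
    x$p_abstainer, x$p_former, x$p_current
  ))
  print(x$dist)
  invisible(x)
}

#' Categorical exposure for the category-based PAF
#'
#' The traditional exposure representation: ordered consumption categories
#' with prevalences and category relative risks, plus the abstainer and
#' former-drinker cells. Prevalences (including abstainers and former
#' drinkers) must sum to 1.
#'
#' @param categories A data frame with columns `lower`, `upper` (g/day,
#'   disjoint increasing intervals; `upper` may be `Inf`), `prevalence`, and
#'   `rr`.
#' @param p_abstainer,p_former Prevalences of the two non-drinking statuses.
#' @param rr_abstainer,rr_former Their relative risks.
#' @return An object of class `categorical_exposure`.
#' @export
categorical_exposure <- function(categories, p_abstainer = 0, p_former = 0,
                                 rr_abstainer = 1, rr_former = 1) {
  needed <- c("lower", "upper", "prevalence", "rr")
  if (!all(needed %in% names(categories))) {
    abort("`categories` needs columns lower, upper, prevalence, rr.")
  }
  categories <- as_tibble(categories)[needed]
  if (any(categories$upper <= categories$lower)) abort("Category intervals must have upper > lower.")
  if (is.unsorted(categories$lower, strictly = TRUE) ||
    any(categories$lower[-1] < categories$upper[-nrow(categories)] - 1e-12)) {
    abort("Categories must be disjoint and increasing.")
  }
  if (any(categories$prevalence < 0) || p_abstainer < 0 || p_former < 0) {
    abort("Prevalences must be non-negative.")
  }
  tot <- sum(categories$prevalence) + p_abstainer + p_former
  if (abs(tot - 1) > 1e-6) {
    abort(sprintf("Prevalences must sum to 1 (got %.8f).", tot))
  }
  structure(
    list(
      categories = categories,
      p_abstainer = p_abstainer, p_former = p_former,
      rr_abstainer = rr_abstainer, rr_former = rr_former
    ),
    class = "categorical_exposure"
  )
}

#' Category-based population-attributable fraction
#'
#' The classical categorical PAF
#' \deqn{PAF = \frac{\sum_i P_i (RR_i - 1)}{\sum_i P_i (RR_i - 1) + 1}}
#' where the sum runs over the drinker categories, the former-drinker cell,
#' and (when its relative risk is not the reference 1) the abstainer cell.
#'
#' @param exposure A [`categorical_exposure`].
#' @return A one-row tibble: `paf`, `method`, `excess` (the summed
#'   \eqn{P_i(RR_i-1)} term), and `n_categories`.
#' @export
paf_categorical <- function(exposure) {
  if (!inherits(exposure, "categorical_exposure")) {
    abort("Expected a `categorical_exposure`; see `categorical_exposure()` or `discretize_exposure()`.")
  }
  excess <- sum(exposure$categories$prevalence * (exposure$categories$rr - 1)) +
    exposure$p_former * (exposure$rr_former - 1) +
    exposure$p_abstainer * (exposure$rr_abstainer - 1)
  denom <- excess + 1
  if (denom <= 0) {
    abort("Pathological relative risks: the PAF denominator is not positive.")
  }
  tibble(
    paf = excess / denom, method = "categorical",
    excess = excess, n_categories = nrow(exposure$categories)
  )
}

#' Continuous population-attributable fraction
#'
#' The distribution-based PAF
#' \deqn{PAF = \frac{P_a RR_a + P_{ex} RR_{ex} + \int_0^{U} P(x)RR(x)dx - 1}
#'   {P_a RR_a + P_{ex} RR_{ex} + \int_0^{U} P(x)RR(x)dx}}
#' with \eqn{P(x) = p_{current} f(x)} the population consumption density.
#' The integral is evaluated by the composite trapezoidal rule on a uniform
#' grid over `(lower, upper]`. Drinker probability mass beyond `upper` is
#' retained and assigned RR(`upper`) - capping the tail's risk exactly as
#' winsorization caps the data - and the small mass below `lower` is
#' assigned RR(`lower`).
#'
#' @param exposure An [`exposure_model`].
#' @param rr An [`rr_spec`].
#' @param upper Integration upper bound U, g/day. Default 150; set 300 to
#'   integrate across the full fitted (winsorized) range.
#' @param lower Integration lower bound, g/day; keeps the grid away from the
#'   shape < 1 density singularity at 0.
#' @param step Uniform grid step, g/day.
#' @return A one-row tibble: `paf`, `method`, `family`, `integral` (the
#'   trapezoid value of \eqn{P(x)RR(x)}), `tail_mass` (drinker mass beyond
#'   `upper`), `lower_mass`, `upper`, `step`.
#' @examples
#' ex <- exposure_model(0.1, 0.15, dist_gamma(0.7, 15))
#' rr <- rr_spec("log_linear", coef = 0.018, rr_former = 1.2)
#' paf_continuous(ex, rr)
#' @export
paf_continuous <- function(exposure, rr, upper = 150, lower = 0.01, step = 0.01) {
  if (!inherits(exposure, "exposure_model")) abort("Expected an `exposure_model`.")
  if (!inherits(rr, "rr_spec")) abort("Expected an `rr_spec`.")
  if (upper <= lower) abort("`upper` must exceed `lower`.")
  if (step <= 0) abort("`step` must be > 0.")
  grid <- seq(lower, upper, by = step)
  if (grid[length(grid)] < upper) grid <- c(grid, upper)
  dens <- exposure$p_current * dist_pdf(exposure$dist, grid)
  rrx <- rr_eval(rr, grid)
  integral <- trapezoid(dens * rrx, grid)
  tail_mass <- exposure$p_current * (1 - dist_cdf(exposure$dist, upper))
  lower_mass <- exposure$p_current * dist_cdf(exposure$dist, lower)
  total <- exposure$p_abstainer * rr$rr_abstainer +
    exposure$p_former * rr$rr_former +
    integral +
    tail_mass * rr_eval(rr, upper) +
    lower_mass * rr_eval(rr, lower)
  tibble(
    paf = (total - 1) / total, method = "continuous",
    family = exposure$dist$family, integral = integral,
    tail_mass = tail_mass, lower_mass = lower_mass,
    upper = upper, step = step
  )
}

#' Difference between categorical and continuous PAF estimates
#'
#' The sensitivity-analysis contrast: categorical minus continuous, sign
#' preserved (either may be negative for net-protective exposure).
#'
#' @param categorical,continuous PAF result rows (or bare numbers).
#' @return The signed difference.
#' @export
paf_difference <- function(categorical, continuous) {
  pull_paf <- function(p) if (is.data.frame(p)) p$paf else p
  pull_paf(categorical) - pull_paf(continuous)
}

#' Decompose the drinker excess-risk term at consumption cutpoints
#'
#' Splits the drinkers' excess-risk integral
#' \eqn{\int p_{current} f(x)(RR(x)-1)dx} into the segments defined by the
#' cutpoints (e.g. at 96, 120, 150, or 200 g/day), reporting each segment's
#' contribution and its share of the total. Mass beyond `upper` is assigned
#' `RR(upper) - 1` and counted in the last segment; shares sum to 1.
#'
#' @param exposure An [`exposure_model`].
#' @param rr An [`rr_spec`].
#' @param cutpoints Increasing cutpoints inside `(lower, upper)`.
#' @inheritParams paf_continuous
#' @return A tibble with one row per segment: `lower`, `upper`,
#'   `contribution`, `share`.
#' @export
paf_decomposition <- function(exposure, rr, cutpoints,
                              upper = 150, lower = 0.01, step = 0.01) {
  if (is.unsorted(cutpoints, strictly = TRUE)) abort("`cutpoints` must be strictly increasing.")
  if (any(cutpoints <= lower) || any(cutpoints >= upper)) {
    abort("`cutpoints` must lie strictly inside (lower, upper).")
  }
  edges <- c(lower, cutpoints, upper)
  seg <- function(a, b) {
    g <- seq(a, b, by = step)
    if (g[length(g)] < b) g <- c(g, b)
    dens <- exposure$p_current * dist_pdf(exposure$dist, g)
    trapezoid(dens * (rr_eval(rr, g) - 1), g)
  }
  contrib <- purrr::map2_dbl(edges[-length(edges)], edges[-1], seg)
  # mass outside the integration window, at capped RR
  contrib[1] <- contrib[1] +
    exposure$p_current * dist_cdf(exposure$dist, lower) * (rr_eval(rr, lower) - 1)
  contrib[length(contrib)] <- contrib[length(contrib)] +
    exposure$p_current * (1 - dist_cdf(exposure$dist, upper)) * (rr_eval(rr, upper) - 1)
  total <- sum(contrib)
  tibble(
    lower = edges[-length(edges)], upper = edges[-1],
    contribution = contrib,
    share = if (abs(total) > 0) contrib / total else rep(NA_real_, length(contrib))
  )
}

#' Discretize a continuous exposure into consumption categories
#'
#' Bridges the continuous model to the categorical PAF: bins the drinkers'
#' distribution on `(lower, upper]` at the given width (prevalences from
#' exact CDF differences), assigns each bin the RR at its midpoint (or the
#' mass-weighted mean RR), and carries the below-`lower` and beyond-`upper`
#' masses as boundary categories at RR(`lower`) and RR(`upper`), mirroring
#' [paf_continuous()]'s tail handling. As `width` shrinks, the categorical
#' PAF of the result converges to the continuous PAF.
#'
#' @param exposure An [`exposure_model`].
#' @param rr An [`rr_spec`].
#' @param width Bin width, g/day.
#' @param rr_policy `"midpoint"` or `"mass_weighted"`.
#' @inheritParams paf_continuous
#' @return A [`categorical_exposure`].
#' @export
discretize_exposure <- function(exposure, rr, width = 1,
                                rr_policy = c("midpoint", "mass_weighted"),
                                upper = 150, lower = 0.01) {
  rr_policy <- arg_match(rr_policy)
  if (width <= 0) abort("`width` must be > 0.")
  edges <- unique(c(seq(lower, upper, by = width), upper))
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  prev <- exposure$p_current * (dist_cdf(exposure$dist, hi) - dist_cdf(exposure$dist, lo))
  rr_bin <- switch(rr_policy,
    midpoint = rr_eval(rr, (lo + hi) / 2),
    mass_weighted = purrr::map2_dbl(lo, hi, function(a, b) {
      g <- seq(a, b, length.out = 21)
      w <- dist_pdf(exposure$dist, g)
      sum(w * rr_eval(rr, g)) / sum(w)
    })
  )
  cats <- tibble(lower = lo, upper = hi, prevalence = prev, rr = rr_bin)
  # boundary cells mirroring the continuous tail treatment
  below <- exposure$p_current * dist_cdf(exposure$dist, lower)
  beyond <- exposure$p_current * (1 - dist_cdf(exposure$dist, upper))
  rr_lo <- rr_eval(rr, lower)
  rr_hi <- rr_eval(rr, upper)
  cats <- bind_rows(
    tibble(lower = 0, upper = !!lower, prevalence = below, rr = rr_lo),
    cats,
    tibble(lower = !!upper, upper = Inf, prevalence = beyond, rr = rr_hi)
  )
  categorical_exposure(
    cats,
    p_abstainer = exposure$p_abstainer, p_former = exposure$p_former,
    rr_abstainer = rr$rr_abstainer, rr_former = rr$rr_former
  )
}

#' Conventional drinker categories
#'
#' The default consumption bands for the standalone categorical model:
#' women (0, 20], (20, 40], (40, Inf); men (0, 40], (40, 60], (60, Inf)
#' g/day - conventional burden-of-disease bands, fully overridable.
#'
#' @param sex `"F"` or `"M"`.
#' @return A tibble with columns `lower` and `upper`.
#' @export
default_categories <- function(sex = c("F", "M")) {
  sex <- arg_match(sex)
  if (sex == "F") {
    tibble(lower = c(0, 20, 40), upper = c(20, 40, Inf))
  } else {
    tibble(lower = c(0, 40, 60), upper = c(40, 60, Inf))
  }
}
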