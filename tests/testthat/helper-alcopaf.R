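# small record builder used across files
make_records <- function(...) {
  rows <- list(...)
  tibble::tibble(
    sex = vapply(rows, `[[`, "", 1),
    age = as.integer(vapply(rows, `[[`, "", 2)),
    status = vapply(rows, `[[`, "", 3),
    grams_per_day = suppressWarnings(as.numeric(vapply(rows, `[[`, "", 4)))
  )
}

# random valid parameters in the range seen across real surveys
random_dist <- function(family) {
  switch(family,
    gamma = dist_gamma(runif(1, 0.6, 2), runif(1, 3, 40)),
    weibull = dist_weibull(runif(1, 0.6, 2), runif(1, 2, 35)),
    lognormal = dist_lognormal(runif(1, -0.5, 2.5), runif(1, 0.5, 1.6))
  )
}
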