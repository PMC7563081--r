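# broom-style accessors for the package's result objects

#' Tidy a radiograph measurement
#'
#' @param x A `cc_measurement` from [measure_radiograph()].
#' @param ... Unused.
#' @return `tidy()`: one row per polynomial term (`term`, `estimate`);
#'   `glance()`: the one-row summary (`coefficient`, `angle`, `label`,
#'   `rms_residual`, `n_points`).
#' @export
tidy.cc_measurement <- function(x, ...) {
  tibble(
    term = c("(Intercept)", "x", "x^2"),
    estimate = c(x$a, x$b, x$c)
  )
}

#' @rdname tidy.cc_measurement
#' @export
glance.cc_measurement <- function(x, ...) {
  as_tibble(x)[, c("coefficient", "angle", "label", "rms_residual", "n_points")]
}

#' Tidy a trend-analysis result
#'
#' `cc_trend` objects are already tidy tables; `tidy()` strips the class,
#' `glance()` reports the model type and data size.
#'
#' @param x A `cc_trend` from [linear_trend()], [multinomial_trend()] or
#'   [mixed_trend()].
#' @param ... Unused.
#' @export
tidy.cc_trend <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.cc_trend
#' @export
glance.cc_trend <- function(x, ...) {
  tibble(model = attr(x, "model"), n_obs = attr(x, "n_obs"), n_terms = nrow(x))
}

#' Tidy a prevalence table
#'
#' @param x A `cc_prevalence` from [estimate_prevalence()].
#' @param ... Unused.
#' @export
tidy.cc_prevalence <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}

#' Format a prevalence table at the reporting precision
#'
#' Percentages and interval bounds to one decimal, as in the published
#' annual-trend tables.
#'
#' @param prevalence A `cc_prevalence` tibble.
#' @return A tibble with a formatted `prevalence` column,
#'   `"p.p (lo to hi)"` in percent.
#' @export
format_prevalence <- function(prevalence) {
  mutate(tidy(prevalence),
    prevalence = sprintf(
      "%.1f (%.1f to %.1f)",
      100 * .data$proportion, 100 * .data$conf.low, 100 * .data$conf.high
    )
  )
}
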