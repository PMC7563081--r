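# ggplot2 views of the package's result types

#' Plot a measured radiograph
#'
#' Standardized points with the fitted second-order polynomial overlaid.
#'
#' @param object A `cc_measurement` from [measure_radiograph()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cc_measurement <- function(object, ...) {
  curve <- attr(object, "standardized")
  grid <- tibble(x = seq(min(curve$x), max(curve$x), length.out = 200))
  grid$y <- object$a + object$b * grid$x + object$c * grid$x^2
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(
      x = "standardized x", y = "standardized y",
      title = sprintf(
        "coefficient %.2f (%s), angle %.1f°",
        object$coefficient, as.character(object$label), object$angle
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot prevalence trends
#'
#' Prevalence by year with Wald confidence ribbons, one line per class,
#' faceted over any remaining grouping columns.
#'
#' @param object A `cc_prevalence` from
#'   [estimate_prevalence()] grouped by at least `year`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cc_prevalence <- function(object, ...) {
  df <- tidy(object)
  stopifnot("year" %in% names(df))
  facet_cols <- setdiff(
    names(df),
    c("year", "label", "n", "count", "proportion", "conf.low", "conf.high")
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$year, y = 100 * .data$proportion,
    colour = .data$label, fill = .data$label
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 100 * .data$conf.low, ymax = 100 * .data$conf.high),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "year", y = "prevalence (%)", colour = "class", fill = "class") +
    ggplot2::theme_minimal()
  if (length(facet_cols) > 0) {
    p <- p + ggplot2::facet_wrap(facet_cols)
  }
  p
}

#' Plot a cohort's yearly mean coefficient
#'
#' Yearly mean curvature coefficient with +/- 1 SE bars and the OLS trend
#' line, optionally split by sex.
#'
#' @param object A cohort tibble of class `cc_cohort`.
#' @param by Optional grouping column (e.g. `"sex"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cc_cohort <- function(object, by = NULL, ...) {
  keys <- c("year", by)
  df <- summarise(
    group_by(as_tibble(object), across(all_of(keys))),
    mean = mean(.data$coefficient),
    se = sd(.data$coefficient) / sqrt(n()),
    .groups = "drop"
  )
  aes_base <- if (is.null(by)) {
    ggplot2::aes(x = .data$year, y = .data$mean)
  } else {
    ggplot2::aes(x = .data$year, y = .data$mean, colour = .data[[by]])
  }
  ggplot2::ggplot(df, aes_base) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$se,
      ymax = .data$mean + .data$se
    )) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.5) +
    ggplot2::labs(x = "year", y = "mean curvature coefficient") +
    ggplot2::theme_minimal()
}
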