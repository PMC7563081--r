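#' Default standardized half-chord length
#'
#' Digitized polylines arrive in arbitrary pixel units, so before fitting
#' the quadratic the chord through the endpoints is rescaled to a fixed
#' half-length h0. The default is the unique h0 for which the coefficient
#' cutoff +/-0.8 corresponds exactly to the +/-4 degree global-angle cutoff
#' of the Harrison posterior tangent convention under the endpoint-tangent
#' model (see [coefficient_to_angle()]):
#' `h0 = tan(2 * pi / 180) / (2 * 8e-4)`, approximately 21.8255.
#'
#' @return A positive scalar.
#' @export
half_chord_default <- function() {
  tan(2 * pi / 180) / (2 * 8e-4)
}

#' Standardize a digitized vertebral polyline
#'
#' Maps the polyline into the fitting frame: the chord through the first
#' and last points becomes the x-axis with its midpoint at the origin, the
#' half-chord is scaled to `half_chord`, and the anatomically anterior side
#' (per the polyline's orientation flag) is mapped to positive y. The
#' transform is a rigid rotation + translation followed by a uniform
#' scaling, so the shape of the curve is preserved.
#'
#' @param polyline A [as_polyline()] object (or a data frame with `x`,`y`,
#'   coerced with anterior = "left").
#' @param half_chord Target standardized half-chord length; defaults to
#'   [half_chord_default()].
#' @return A tibble of class `cc_standardized` with columns `x`, `y` and
#'   attribute `half_chord`. The first and last points lie at
#'   `(-half_chord, 0)` and `(+half_chord, 0)`.
#' @export
#' @examples
#' pl <- as_polyline(data.frame(x = -6:6, y = 0.002 * (-6:6)^2))
#' standardize_curve(pl)
standardize_curve <- function(polyline, half_chord = half_chord_default()) {
  if (!inherits(polyline, "cc_polyline")) polyline <- as_polyline(polyline)
  stopifnot(is.numeric(half_chord), length(half_chord) == 1L, half_chord > 0)
  x <- polyline$x
  y <- polyline$y
  n <- length(x)
  chord <- c(x[n] - x[1], y[n] - y[1])
  len <- sqrt(sum(chord^2))
  if (len <= 0) cc_abort("invalid_geometry", "Polyline endpoints coincide.")
  mid <- c((x[1] + x[n]) / 2, (y[1] + y[n]) / 2)
  phi <- atan2(chord[2], chord[1])
  # rotate by -phi: chord direction -> +x; left of travel -> +y
  cs <- cos(phi)
  sn <- sin(phi)
  xs <- (x - mid[1]) * cs + (y - mid[2]) * sn
  ys <- -(x - mid[1]) * sn + (y - mid[2]) * cs
  s <- half_chord / (len / 2)
  xs <- xs * s
  ys <- ys * s
  if (polyline_anterior(polyline) == "right") ys <- -ys
  structure(
    tibble(x = xs, y = ys),
    half_chord = half_chord,
    class = c("cc_standardized", class(tibble()))
  )
}

#' Fit the second-order polynomial to a standardized curve
#'
#' Ordinary least squares of y on (1, x, x^2) over all points of the
#' standardized polyline. The curvature coefficient is the quadratic
#' coefficient scaled by 1000: positive for an anteriorly convex (lordotic)
#' curve, negative for kyphosis.
#'
#' @param curve A `cc_standardized` object from [standardize_curve()].
#' @return A one-row tibble of class `cc_fit`: `a`, `b`, `c` (polynomial
#'   coefficients), `coefficient` (`c * 1000`), `rms_residual`, `n_points`,
#'   with the `lm` fit in attribute `fit`.
#' @export
fit_curvature <- function(curve) {
  if (!inherits(curve, "cc_standardized")) {
    cc_abort("invalid_value", "`curve` must come from standardize_curve().")
  }
  if (nrow(curve) < 5) cc_abort("insufficient_points", "Need at least 5 points to fit.")
  x <- curve$x
  if (length(unique(x)) < 3) {
    cc_abort("singular_fit", "Design is rank deficient: fewer than 3 distinct x values.")
  }
  fit <- lm(y ~ x + I(x^2), data = data.frame(x = x, y = curve$y))
  cf <- unname(coef(fit))
  if (anyNA(cf)) cc_abort("singular_fit", "Quadratic fit is rank deficient.")
  res <- structure(
    tibble(
      a = cf[1], b = cf[2], c = cf[3],
      coefficient = cf[3] * 1000,
      rms_residual = sqrt(mean(resid(fit)^2)),
      n_points = nrow(curve)
    ),
    fit = fit,
    half_chord = attr(curve, "half_chord"),
    class = c("cc_fit", class(tibble()))
  )
  res
}

#' Classify a curvature coefficient
#'
#' Cutoffs follow the Harrison-angle-derived convention: coefficients in
#' the closed interval `[-cutoff, +cutoff]` are straight, above it lordotic
#' (normal anterior convexity), below it kyphotic (reversed curvature).
#'
#' @param coefficient Numeric vector of curvature coefficients (c x 1000).
#' @param cutoff Classification boundary (default 0.8).
#' @return A factor with levels `kyphotic`, `straight`, `lordotic`.
#' @export
#' @examples
#' classify_coefficient(c(-2, 0, 0.8, 1.76))
classify_coefficient <- function(coefficient, cutoff = 0.8) {
  if (!is.numeric(coefficient) || any(!is.finite(coefficient))) {
    cc_abort("invalid_value", "`coefficient` must be finite numeric.")
  }
  stopifnot(is.numeric(cutoff), cutoff > 0)
  out <- ifelse(coefficient < -cutoff, "kyphotic",
    ifelse(coefficient > cutoff, "lordotic", "straight")
  )
  factor(out, levels = c("kyphotic", "straight", "lordotic"))
}

curvature_levels <- function() c("kyphotic", "straight", "lordotic")

#' Global angle from the Harrison posterior tangent landmarks
#'
#' Signed angle, in degrees, between the tangent lines along the posterior
#' walls of the C2 and C7 vertebral bodies. Each wall is given by its
#' superior and inferior landmark; the angle is measured from the C2 wall
#' direction to the C7 wall direction (both taken superior to inferior),
#' with the sign convention that a lordotic alignment gives a negative
#' angle (lordosis < -4 degrees, kyphosis > +4 degrees).
#'
#' @param c2_superior,c2_inferior,c7_superior,c7_inferior Length-2 numeric
#'   vectors `(x, y)` in image-pixel coordinates.
#' @return Signed angle in degrees, magnitude in `[0, 180)`.
#' @export
harrison_angle <- function(c2_superior, c2_inferior, c7_superior, c7_inferior) {
  pt <- function(p, nm) {
    if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p))) {
      cc_abort("invalid_value", sprintf("`%s` must be a finite (x, y) pair.", nm))
    }
    p
  }
  u <- pt(c2_inferior, "c2_inferior") - pt(c2_superior, "c2_superior")
  v <- pt(c7_inferior, "c7_inferior") - pt(c7_superior, "c7_superior")
  if (all(u == 0) || all(v == 0)) {
    cc_abort("invalid_geometry", "Wall landmarks coincide; tangent direction undefined.")
  }
  atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)) * 180 / pi
}

#' Convert between the curvature coefficient and the global angle
#'
#' The standardized curve is a parabola `y = a + b x + c x^2` over
#' `[-h0, h0]`. Its endpoint tangents meet at the angle
#' `theta = -2 * atan(2 * (C / 1000) * h0)` (degrees), where `C` is the
#' curvature coefficient; this is the package's Harrison-equivalent global
#' angle. The mapping is strictly decreasing and exactly inverts: with the
#' default `half_chord`, coefficient 0.8 maps to -4 degrees, so the
#' published +/-4 degree angle cutoffs and +/-0.8 coefficient cutoffs
#' classify identically.
#'
#' @param coefficient Curvature coefficient(s), `c * 1000`.
#' @param theta Global angle(s) in signed degrees, `|theta| < 180`.
#' @param half_chord Standardized half-chord; defaults to
#'   [half_chord_default()].
#' @return Signed degrees (`coefficient_to_angle`) or coefficients
#'   (`angle_to_coefficient`).
#' @export
#' @examples
#' coefficient_to_angle(0.8) # -4
#' angle_to_coefficient(-4) # 0.8
coefficient_to_angle <- function(coefficient, half_chord = half_chord_default()) {
  if (!is.numeric(coefficient) || any(!is.finite(coefficient))) {
    cc_abort("invalid_value", "`coefficient` must be finite numeric.")
  }
  -2 * atan(2 * (coefficient / 1000) * half_chord) * 180 / pi
}

#' @rdname coefficient_to_angle
#' @export
angle_to_coefficient <- function(theta, half_chord = half_chord_default()) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    cc_abort("invalid_value", "`theta` must be finite numeric.")
  }
  if (any(abs(theta) >= 180)) {
    cc_abort("invalid_value", "|theta| must be < 180 degrees.")
  }
  tan(-theta / 2 * pi / 180) / (2 * half_chord) * 1000
}

#' Measure a radiograph polyline end to end
#'
#' Composition of [standardize_curve()], [fit_curvature()],
#' [coefficient_to_angle()] and [classify_coefficient()]: the one-call path
#' from a digitized anterior vertebral line to its curvature coefficient,
#' Harrison-equivalent global angle and class label.
#'
#' @inheritParams standardize_curve
#' @param cutoff Coefficient classification boundary (default 0.8).
#' @return A one-row tibble of class `cc_measurement` with columns `a`,
#'   `b`, `c`, `coefficient`, `angle`, `rms_residual`, `n_points`, `label`.
#'   The standardized curve and `lm` fit are kept in attributes.
#' @export
#' @examples
#' pl <- generate_spine_polyline(spine_spec(target_coefficient = 2.5, seed = 1))
#' measure_radiograph(pl)
measure_radiograph <- function(polyline, half_chord = half_chord_default(),
                               cutoff = 0.8) {
  curve <- standardize_curve(polyline, half_chord = half_chord)
  fit <- fit_curvature(curve)
  out <- mutate(
    as_tibble(fit),
    angle = coefficient_to_angle(.data$coefficient, half_chord = half_chord),
    label = classify_coefficient(.data$coefficient, cutoff = cutoff)
  )
  structure(
    out,
    standardized = curve,
    fit = attr(fit, "fit"),
    half_chord = half_chord,
    class = c("cc_measurement", class(tibble()))
  )
}
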