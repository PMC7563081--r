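test_that("polyline validation rejects degenerate inputs", {
  expect_error(as_polyline(data.frame(x = 1:3, y = 1:3)), class = "cervicurve_error_insufficient_points")
  expect_error(
    as_polyline(data.frame(x = c(0, 1, 1, 2, 3), y = c(0, 1, 1, 2, 3))),
    class = "cervicurve_error_invalid_geometry"
  )
  closed <- data.frame(x = c(0, 1, 2, 1, 0), y = c(0, 1, 0, -1, 0))
  expect_error(as_polyline(closed), class = "cervicurve_error_invalid_geometry")
  expect_error(as_polyline(data.frame(x = c(1:4, NA), y = 1:5)), class = "cervicurve_error_invalid_value")
})

test_that("standardization is the identity on an already-standard curve", {
  h0 <- half_chord_default()
  pl <- parabola_polyline(2.0, n = 13)
  std <- standardize_curve(pl)
  # endpoints at (-h0, 0), (h0, 0)
  expect_equal(std$x[c(1, 13)], c(-h0, h0), tolerance = 1e-12)
  expect_equal(std$y[c(1, 13)], c(0, 0), tolerance = 1e-12)
  # same parabola up to the chord shift: quadratic term preserved exactly
  expect_equal(fit_curvature(std)$coefficient, 2.0, tolerance = 1e-9)
})

test_that("standardization inverts a known rigid transform point-wise", {
  h0 <- half_chord_default()
  x <- seq(-h0, h0, length.out = 13)
  base <- tibble::tibble(x = x, y = 0.002 * x^2)
  moved <- apply_rigid(base, angle = 30 * pi / 180, translation = c(100, -50))
  std_base <- standardize_curve(as_polyline(base))
  std_moved <- standardize_curve(as_polyline(moved))
  expect_equal(std_moved$x, std_base$x, tolerance = 1e-9)
  expect_equal(std_moved$y, std_base$y, tolerance = 1e-9)
  expect_equal(fit_curvature(std_moved)$c, 0.002, tolerance = 1e-9)
})

test_that("collinear polylines standardize to zero y", {
  pl <- as_polyline(data.frame(x = 1:9, y = 2 * (1:9) + 3))
  std <- standardize_curve(pl)
  expect_true(all(abs(std$y) < 1e-9))
  expect_equal(fit_curvature(std)$coefficient, 0, tolerance = 1e-9)
})

test_that("anterior orientation flag controls the sign of the coefficient", {
  pl_left <- parabola_polyline(1.5)
  pl_right <- as_polyline(as.data.frame(pl_left[, c("x", "y")]), anterior = "right")
  expect_equal(measure_radiograph(pl_left)$coefficient, 1.5, tolerance = 1e-9)
  expect_equal(measure_radiograph(pl_right)$coefficient, -1.5, tolerance = 1e-9)
})

test_that("quadratic fit recovers noiseless polynomials exactly", {
  h0 <- half_chord_default()
  x <- seq(-h0, h0, length.out = 15)
  curve <- structure(tibble::tibble(x = x, y = 1 + 0.5 * x + 0.0008 * x^2),
    half_chord = h0, class = c("cc_standardized", class(tibble::tibble()))
  )
  fit <- fit_curvature(curve)
  expect_equal(c(fit$a, fit$b, fit$c), c(1, 0.5, 0.0008), tolerance = 1e-9)
  expect_equal(fit$coefficient, 0.8, tolerance = 1e-9)

  flat <- structure(tibble::tibble(x = x, y = rep(0, 15)),
    half_chord = h0, class = c("cc_standardized", class(tibble::tibble()))
  )
  fit0 <- fit_curvature(flat)
  expect_equal(fit0$coefficient, 0, tolerance = 1e-12)
  expect_equal(fit0$rms_residual, 0, tolerance = 1e-12)
})

test_that("noisy fit lands within 3 closed-form standard errors", {
  h0 <- half_chord_default()
  x <- seq(-h0, h0, length.out = 25)
  set.seed(11)
  y <- 0.00176 * x^2 + rnorm(25, 0, 0.05)
  curve <- structure(tibble::tibble(x = x, y = y),
    half_chord = h0, class = c("cc_standardized", class(tibble::tibble()))
  )
  se_c <- quadratic_se(x, 0.05) * 1000
  expect_lt(abs(fit_curvature(curve)$coefficient - 1.76), 3 * se_c)
})

test_that("OLS fit matches the independent normal-equations oracle", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    x <- sort(runif(n, -20, 20))
    y <- runif(1, -1, 1) + runif(1, -0.5, 0.5) * x + runif(1, -0.003, 0.003) * x^2 +
      rnorm(n, 0, 0.1)
    curve <- structure(tibble::tibble(x = x, y = y),
      half_chord = 20, class = c("cc_standardized", class(tibble::tibble()))
    )
    fit <- fit_curvature(curve)
    oracle <- normal_equations_quadratic(x, y)
    expect_equal(unname(c(fit$a, fit$b, fit$c)), unname(oracle), tolerance = 1e-9)
  }
})

test_that("rank-deficient designs raise a singular-fit error", {
  curve <- structure(tibble::tibble(x = rep(c(0, 1), c(3, 2)), y = rnorm(5)),
    half_chord = 1, class = c("cc_standardized", class(tibble::tibble()))
  )
  expect_error(fit_curvature(curve), class = "cervicurve_error_singular_fit")
})

test_that("coefficient classification follows the closed-interval cutoffs", {
  expect_equal(as.character(classify_coefficient(1.76)), "lordotic")
  expect_equal(as.character(classify_coefficient(0)), "straight")
  expect_equal(as.character(classify_coefficient(-0.8)), "straight")
  expect_equal(as.character(classify_coefficient(0.8)), "straight")
  expect_equal(as.character(classify_coefficient(-0.8000001)), "kyphotic")
  expect_equal(as.character(classify_coefficient(0.8000001)), "lordotic")
  expect_error(classify_coefficient(NaN), class = "cervicurve_error_invalid_value")
})

test_that("harrison angle matches the dot-product oracle and is antisymmetric", {
  # parallel walls
  expect_equal(harrison_angle(c(0, 0), c(0, 1), c(5, 0), c(5, 1)), 0, tolerance = 1e-12)
  # C7 wall rotated 10 degrees, lordotic orientation
  d10 <- c(sin(10 * pi / 180), cos(10 * pi / 180))
  a <- harrison_angle(c(0, 0), c(0, 1), c(5, 0), c(5, 0) + d10)
  expect_equal(a, -10, tolerance = 1e-9)
  # swapping the walls flips the sign
  b <- harrison_angle(c(5, 0), c(5, 0) + d10, c(0, 0), c(0, 1))
  expect_equal(b, 10, tolerance = 1e-9)
  expect_error(
    harrison_angle(c(0, 0), c(0, 0), c(1, 0), c(1, 1)),
    class = "cervicurve_error_invalid_geometry"
  )
})

test_that("coefficient/angle conversion anchors and inverse pair hold", {
  expect_equal(coefficient_to_angle(0), 0, tolerance = 1e-12)
  expect_equal(coefficient_to_angle(0.8), -4, tolerance = 1e-12)
  expect_equal(angle_to_coefficient(-4), 0.8, tolerance = 1e-12)
  expect_equal(angle_to_coefficient(4), -0.8, tolerance = 1e-12)
  for (x in c(-5, -0.8, 0, 0.8, 1.76, 5)) {
    expect_equal(angle_to_coefficient(coefficient_to_angle(x)), x, tolerance = 1e-12)
  }
  # strictly decreasing
  grid <- seq(-10, 10, by = 0.25)
  expect_true(all(diff(coefficient_to_angle(grid)) < 0))
  expect_error(angle_to_coefficient(180), class = "cervicurve_error_invalid_value")
})

test_that("classification by coefficient and by converted angle agree everywhere", {
  grid <- c(seq(-5, 5, by = 0.01), -0.8, 0.8, -0.8 - 1e-9, 0.8 + 1e-9)
  by_coef <- as.character(classify_coefficient(grid))
  theta <- coefficient_to_angle(grid)
  by_angle <- ifelse(theta < -4, "lordotic", ifelse(theta > 4, "kyphotic", "straight"))
  expect_equal(by_coef, by_angle)
})

test_that("measured coefficient is invariant to rigid transforms and scaling", {
  set.seed(21)
  pl <- generate_spine_polyline(spine_spec(1.3, noise_sd = 0.03, seed = 99))
  ref <- measure_radiograph(pl)$coefficient
  for (i in 1:8) {
    moved <- apply_rigid(pl,
      angle = runif(1, -pi, pi),
      translation = runif(2, -500, 500), scale = runif(1, 0.2, 8)
    )
    got <- measure_radiograph(as_polyline(moved))$coefficient
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("measure_radiograph composes standardize, fit and classify", {
  lord <- generate_spine_polyline(spine_spec(2.5, seed = 1))
  expect_equal(as.character(measure_radiograph(lord)$label), "lordotic")
  straight <- generate_spine_polyline(spine_spec(0, noise_sd = 0.02, seed = 2))
  expect_equal(as.character(measure_radiograph(straight)$label), "straight")
  kyph <- generate_spine_polyline(spine_spec(-2.0, seed = 3))
  m <- measure_radiograph(kyph)
  expect_equal(as.character(m$label), "kyphotic")
  # intermediates retained and consistent
  expect_equal(m$coefficient, m$c * 1000, tolerance = 1e-12)
  expect_equal(m$angle, coefficient_to_angle(m$coefficient), tolerance = 1e-12)
  expect_s3_class(attr(m, "standardized"), "cc_standardized")
})
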