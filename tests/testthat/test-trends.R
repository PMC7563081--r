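test_that("Wald prevalence intervals match the hand computation", {
  cohort <- tibble::tibble(
    label = factor(rep(c("straight", "lordotic"), c(104, 316)),
      levels = c("kyphotic", "straight", "lordotic")
    )
  )
  est <- estimate_prevalence(cohort, target_class = "straight")
  p <- 104 / 420
  se <- sqrt(p * (1 - p) / 420)
  expect_equal(est$proportion, p)
  expect_equal(est$conf.low, p - qnorm(0.975) * se)
  expect_equal(est$conf.high, p + qnorm(0.975) * se)
  # matches the published reporting precision for this cell
  expect_equal(
    format_prevalence(est)$prevalence, "24.8 (20.6 to 28.9)"
  )
})

test_that("prevalence intervals clip to [0, 1] at the extremes", {
  zero <- tibble::tibble(label = factor(rep("lordotic", 50), levels = c("kyphotic", "straight", "lordotic")))
  est0 <- estimate_prevalence(zero, target_class = "kyphotic")
  expect_equal(c(est0$proportion, est0$conf.low, est0$conf.high), c(0, 0, 0))
  all50 <- tibble::tibble(label = factor(rep("straight", 50), levels = c("kyphotic", "straight", "lordotic")))
  est1 <- estimate_prevalence(all50, target_class = "straight")
  expect_equal(c(est1$proportion, est1$conf.low, est1$conf.high), c(1, 1, 1))
})

test_that("class proportions sum to one within every stratum", {
  cohort <- simulate_cohort(default_quantile_strata("sex", years = c(2006, 2012)), seed = 3)
  est <- estimate_prevalence(cohort,
    target_class = c("kyphotic", "straight", "lordotic"),
    group_by = c("year", "sex")
  )
  sums <- dplyr::summarise(dplyr::group_by(tidy(est), year, sex), s = sum(proportion))
  expect_equal(sums$s, rep(1, nrow(sums)))
  empty <- cohort[0, ]
  expect_error(estimate_prevalence(empty), class = "cervicurve_error_empty_group")
})

test_that("linear trend is exact on noiseless data and matches the brute-force oracle", {
  years <- rep(2006:2018, each = 5)
  noiseless <- tibble::tibble(year = years, coefficient = 1.76 - 0.05 * (years - 2006))
  tr <- suppressWarnings(linear_trend(noiseless)) # perfect-fit warning
  expect_equal(tr$estimate, -0.05, tolerance = 1e-12)

  set.seed(41)
  cohort <- tibble::tibble(
    year = sample(2006:2018, 300, replace = TRUE),
    coefficient = rnorm(300, 1.5, 1.3)
  )
  tr2 <- linear_trend(cohort)
  X <- cbind(1, cohort$year - 2006)
  oracle <- solve(t(X) %*% X, t(X) %*% cohort$coefficient)[2, 1]
  expect_equal(tr2$estimate, oracle, tolerance = 1e-6)
})

test_that("linear trend recovers the generating female drift within 3 SE", {
  tc <- simulate_trend_cohort(beta = -0.05, n_per_year = 800, sex = "female", seed = 19)
  tr <- linear_trend(tc)
  expect_lt(abs(tr$estimate - (-0.05)), 3 * tr$std.error)
  expect_lt(tr$p.value, 0.05)
  expect_true(tr$conf.low <= tr$estimate && tr$estimate <= tr$conf.high)
})

test_that("stratified linear trends return one row per stratum", {
  tcf <- simulate_trend_cohort(beta = -0.05, n_per_year = 100, sex = "female", seed = 20)
  tcm <- simulate_trend_cohort(beta = -0.03, n_per_year = 100, sex = "male", seed = 21)
  tr <- linear_trend(dplyr::bind_rows(tcf, tcm), by = "sex")
  expect_equal(sort(tr$sex), c("female", "male"))
  expect_equal(tr$model, rep("ols", 2))
})

test_that("multinomial trend recovers a null year effect", {
  st <- dplyr::bind_rows(
    lapply(c(2006, 2010, 2014, 2018), function(y) {
      stratum_config(y, 1500, "quantile", p_kyphotic = 0.05, p_straight = 0.25)
    })
  )
  cohort <- simulate_cohort(st, seed = 8)
  tr <- multinomial_trend(cohort)
  yr <- dplyr::filter(tidy(tr), term == "year")
  expect_equal(nrow(yr), 2)
  expect_true(all(abs(yr$estimate) < 3 * yr$std.error))
})

test_that("multinomial trend recovers known generating coefficients within 3 SE", {
  beta_k <- c(-3.2, 0.10, 0.3, 0.005)
  beta_s <- c(-1.2, 0.05, -0.4, 0.002)
  cohort <- sample_multinomial_cohort(12000, beta_k, beta_s, seed = 14)
  tr <- tidy(multinomial_trend(cohort))
  # the model's dummy is sexmale (female = baseline), so the DGP's
  # female-indicator coefficient folds into the intercept and flips sign
  truth <- tibble::tibble(
    outcome = rep(c("kyphotic", "straight"), each = 4),
    term = rep(c("(Intercept)", "year", "sexmale", "age"), 2),
    true = c(
      beta_k[1] + beta_k[3], beta_k[2], -beta_k[3], beta_k[4],
      beta_s[1] + beta_s[3], beta_s[2], -beta_s[3], beta_s[4]
    )
  )
  joined <- dplyr::inner_join(tr, truth, by = c("outcome", "term"))
  expect_equal(nrow(joined), 8)
  expect_true(all(abs(joined$estimate - joined$true) < 3 * joined$std.error))
})

test_that("multinomial trend collapsed to two classes agrees with binary logistic", {
  set.seed(15)
  n <- 2000
  year <- sample(2006:2018, n, replace = TRUE)
  eta <- -1 + 0.08 * (year - 2006)
  lab <- ifelse(runif(n) < plogis(eta), "straight", "lordotic")
  cohort <- tibble::tibble(
    year = year,
    label = factor(lab, levels = c("kyphotic", "straight", "lordotic"))
  )
  # two observed classes is degenerate for the default three-class model
  expect_error(multinomial_trend(cohort), class = "cervicurve_error_degenerate_outcome")
  # collapsing to the two observed classes reduces the MLE to ordinary
  # logistic regression on the same data
  tr <- tidy(multinomial_trend(cohort,
    covariates = character(0),
    classes = c("lordotic", "straight")
  ))
  glm_fit <- glm(I(label == "straight") ~ I(year - 2006), data = cohort, family = binomial)
  got <- dplyr::filter(tr, outcome == "straight", term == "year")
  expect_lt(abs(got$estimate - unname(coef(glm_fit)[2])), 1e-6)
  expect_lt(abs(got$std.error - unname(sqrt(diag(vcov(glm_fit)))[2])), 1e-3)
})

test_that("type-I error of the linear trend is calibrated near 5 percent", {
  rejections <- vapply(1:200, function(s) {
    tc <- simulate_trend_cohort(beta = 0, n_per_year = 40, seed = 30000 + s)
    linear_trend(tc)$p.value < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("mixed model recovers the longitudinal fixed slope within 3 SE", {
  lg <- simulate_longitudinal(longitudinal_config(
    n_subjects = 500, beta = -0.06, tau = 0.03, sigma = 0.3, seed = 23
  ))
  tr <- mixed_trend(lg)
  expect_lt(abs(tr$estimate - (-0.06)), 3 * tr$std.error)
  expect_equal(tr$model, "lmm")
  expect_equal(tr$n_subjects, 500)
  expect_true(tr$p.value < 0.05)
})

test_that("mixed model survives boundary variance structure", {
  # mostly 2 visits with a minority of 3rd visits: just enough replication
  # for the random intercept + slope pair to stay identifiable
  lg <- simulate_longitudinal(longitudinal_config(
    n_subjects = 150, visits_min = 2, visits_max = 3,
    beta = -0.05, tau = 0.3, sigma = 0.02, seed = 25
  ))
  tr <- suppressWarnings(suppressMessages(mixed_trend(lg, covariates = character(0))))
  vc <- as.data.frame(lme4::VarCorr(attr(tr, "meta")$fit))
  # variance rows (var2 absent) must be nonnegative; the
  # intercept-slope covariance row may legitimately have either sign
  expect_true(all(vc$vcov[is.na(vc$var2)] >= 0))
  expect_true(is.finite(tr$estimate))
})

test_that("all-singleton subjects raise a no-repeats error", {
  cohort <- tibble::tibble(
    subject = as.character(1:30), year = rep(2006:2015, 3),
    coefficient = rnorm(30)
  )
  expect_error(mixed_trend(cohort), class = "cervicurve_error_no_repeats")
})
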