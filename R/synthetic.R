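# Synthetic stand-ins for the study inputs: single spine polylines with
# known curvature, yearly cross-sectional cohorts calibrated to the
# published means/prevalences, and longitudinal repeated measures with a
# per-subject random slope on year.

# run code under a temporary RNG state so generators are deterministic
# given their seed without clobbering the caller's stream
with_cc_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for one synthetic spine polyline
#'
#' Describes a parabola-like anterior vertebral line with a known target
#' curvature coefficient: the standardized parabola
#' `y = (target_coefficient / 1000) * x^2` sampled over the standardized
#' chord, plus Gaussian landmark noise, mapped into image coordinates by a
#' rigid transform and uniform scale.
#'
#' @param target_coefficient Curvature coefficient the polyline encodes.
#' @param n_points Number of digitized points (>= 5).
#' @param noise_sd SD of Gaussian y-noise in standardized units.
#' @param angle Rotation of the image frame, radians.
#' @param translation Length-2 translation in image pixels.
#' @param scale Uniform scale into image pixels (> 0).
#' @param half_chord Standardized half-chord (defaults to
#'   [half_chord_default()]).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list of class `cc_spine_spec`.
#' @export
spine_spec <- function(target_coefficient, n_points = 25L, noise_sd = 0.05,
                       angle = 0, translation = c(0, 0), scale = 1,
                       half_chord = half_chord_default(), seed = NULL) {
  if (!is.numeric(target_coefficient) || !is.finite(target_coefficient)) {
    cc_abort("config", "`target_coefficient` must be finite.")
  }
  if (n_points < 5) cc_abort("config", "`n_points` must be >= 5.")
  if (noise_sd < 0) cc_abort("config", "`noise_sd` must be >= 0.")
  if (scale <= 0) cc_abort("config", "`scale` must be > 0.")
  structure(
    list(
      target_coefficient = target_coefficient, n_points = as.integer(n_points),
      noise_sd = noise_sd, angle = angle, translation = translation,
      scale = scale, half_chord = half_chord, seed = seed
    ),
    class = "cc_spine_spec"
  )
}

#' Generate a synthetic spine polyline
#'
#' @param spec A [spine_spec()].
#' @return A [as_polyline()] object in image coordinates, anterior side
#'   `"left"`, deterministic given `spec$seed`.
#' @export
#' @examples
#' pl <- generate_spine_polyline(spine_spec(2.5, noise_sd = 0, seed = 1))
#' measure_radiograph(pl)$coefficient
generate_spine_polyline <- function(spec) {
  stopifnot(inherits(spec, "cc_spine_spec"))
  h0 <- spec$half_chord
  xs <- seq(-h0, h0, length.out = spec$n_points)
  ys <- (spec$target_coefficient / 1000) * xs^2
  with_cc_seed(spec$seed, {
    if (spec$noise_sd > 0) ys <- ys + rnorm(spec$n_points, 0, spec$noise_sd)
    cs <- cos(spec$angle)
    sn <- sin(spec$angle)
    px <- spec$scale * (xs * cs - ys * sn) + spec$translation[1]
    py <- spec$scale * (xs * sn + ys * cs) + spec$translation[2]
    as_polyline(tibble(x = px, y = py), anterior = "left")
  })
}

#' Calibrate a normal coefficient distribution to class prevalences
#'
#' Finds the unique Normal(mu, sigma) whose lower tail below `-cutoff`
#' equals the kyphotic prevalence and whose mass in `[-cutoff, cutoff]`
#' equals the straight prevalence, via the probit closed form:
#' `sigma = 2 * cutoff / (z2 - z1)`, `mu = -cutoff - sigma * z1` with
#' `z1 = qnorm(p_kyphotic)`, `z2 = qnorm(p_kyphotic + p_straight)`.
#'
#' @param p_kyphotic,p_straight Target class probabilities, both > 0 with
#'   sum < 1.
#' @param cutoff Classification boundary (default 0.8).
#' @return A named list `list(mu, sigma)`.
#' @export
#' @examples
#' calibrate_group_normal(0.029, 0.248) # male 2006 stratum
calibrate_group_normal <- function(p_kyphotic, p_straight, cutoff = 0.8) {
  if (!is.numeric(p_kyphotic) || !is.numeric(p_straight) ||
      p_kyphotic <= 0 || p_straight <= 0 || p_kyphotic + p_straight >= 1) {
    cc_abort(
      "config",
      "Need p_kyphotic > 0, p_straight > 0 and p_kyphotic + p_straight < 1."
    )
  }
  z1 <- qnorm(p_kyphotic)
  z2 <- qnorm(p_kyphotic + p_straight)
  sigma <- 2 * cutoff / (z2 - z1)
  list(mu = -cutoff - sigma * z1, sigma = sigma)
}

#' Build stratum configurations for the cohort simulator
#'
#' A stratum is one cell of the cohort design (year x sex and/or age
#' group) with either a moment-mode Normal model (`mean`, `sd` given
#' directly, matching published means) or a quantile-mode model (mu/sigma
#' derived from published kyphotic/straight prevalences through
#' [calibrate_group_normal()]).
#'
#' @param year Calendar year.
#' @param n Stratum size.
#' @param mode `"moment"` or `"quantile"`.
#' @param mean,sd Coefficient mean and SD (moment mode).
#' @param p_kyphotic,p_straight Class probabilities (quantile mode).
#' @param sex `"male"`, `"female"` or `NA` (assigned at simulation time).
#' @param age_group One of the study age groups or `NA`.
#' @return A one-row tibble.
#' @export
stratum_config <- function(year, n, mode = c("moment", "quantile"),
                           mean = NA_real_, sd = NA_real_,
                           p_kyphotic = NA_real_, p_straight = NA_real_,
                           sex = NA_character_, age_group = NA_character_) {
  mode <- match.arg(mode)
  if (n < 1) cc_abort("config", "`n` must be >= 1.")
  if (mode == "moment" && (!is.finite(mean) || !is.finite(sd) || sd <= 0)) {
    cc_abort("config", "Moment mode needs finite `mean` and `sd` > 0.")
  }
  if (mode == "quantile" && (!is.finite(p_kyphotic) || !is.finite(p_straight))) {
    cc_abort("config", "Quantile mode needs `p_kyphotic` and `p_straight`.")
  }
  if (!is.na(age_group) && !age_group %in% age_group_bounds()$age_group) {
    cc_abort("config", sprintf("Unknown age group '%s'.", age_group))
  }
  tibble(
    year = as.integer(year), n = as.integer(n), mode = mode,
    mean = mean, sd = sd, p_kyphotic = p_kyphotic, p_straight = p_straight,
    sex = sex, age_group = age_group
  )
}

#' Study-calibrated default strata
#'
#' `default_moment_strata()` returns the yearly overall strata in moment
#' mode (published/interpolated means, SD 1.37, published yearly n).
#' `default_quantile_strata()` returns per-year strata in quantile mode
#' from the published straight/kyphotic prevalences, either by sex (n
#' split by the published female fraction) or by age group (yearly n split
#' evenly across the six groups).
#'
#' @param years Years to include (default all, 2006-2018).
#' @param by `"sex"` or `"age_group"`.
#' @return A tibble of stratum configurations for [simulate_cohort()].
#' @export
default_moment_strata <- function(years = cc_years()) {
  ov <- filter(calibration_defaults()$overall, .data$year %in% years)
  purrr::pmap_dfr(ov, function(year, n, pct_female, mean, sd) {
    stratum_config(year, n, "moment", mean = mean, sd = sd)
  })
}

#' @rdname default_moment_strata
#' @export
default_quantile_strata <- function(by = c("sex", "age_group"), years = cc_years()) {
  by <- match.arg(by)
  cal <- calibration_defaults()
  prev <- filter(cal$prevalence, .data$stratum_type == by, .data$year %in% years)
  ov <- cal$overall
  purrr::pmap_dfr(prev, function(year, stratum_type, stratum, pct_straight, pct_kyphotic) {
    n_year <- ov$n[ov$year == year]
    pf <- ov$pct_female[ov$year == year] / 100
    n <- if (by == "sex") {
      round(n_year * if (stratum == "female") pf else 1 - pf)
    } else {
      round(n_year / 6)
    }
    stratum_config(
      year, max(1L, n), "quantile",
      p_kyphotic = pct_kyphotic / 100, p_straight = pct_straight / 100,
      sex = if (by == "sex") stratum else NA_character_,
      age_group = if (by == "age_group") stratum else NA_character_
    )
  })
}

# overall female share of the analytic sample, used when a stratum does
# not fix sex
cc_female_share <- function() 0.588

#' Simulate a cross-sectional cohort
#'
#' Draws per-stratum curvature coefficients from the stratum's Normal
#' model (quantile-mode strata are first calibrated with
#' [calibrate_group_normal()]), assigns ages uniformly within the age
#' group (18-90 when unset; the open >=70 group is capped at 90), assigns
#' unset sex by the study's overall female share, and classifies each
#' coefficient. The global seed expands to per-stratum child seeds as
#' `seed + stratum_index`, so adding strata does not perturb existing
#' ones.
#'
#' @param strata Tibble of stratum configurations ([stratum_config()] or
#'   the `default_*_strata()` builders).
#' @param seed Integer seed.
#' @param cutoff Classification boundary (default 0.8).
#' @return A cohort tibble: `subject`, `year`, `sex`, `age`, `age_group`,
#'   `coefficient`, `label`.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_moment_strata(years = 2006), seed = 1)
#' mean(cohort$coefficient)
simulate_cohort <- function(strata, seed, cutoff = 0.8) {
  stopifnot(is.data.frame(strata), nrow(strata) >= 1)
  bounds <- age_group_bounds()
  out <- purrr::map_dfr(seq_len(nrow(strata)), function(i) {
    st <- strata[i, ]
    if (st$mode == "quantile") {
      ms <- calibrate_group_normal(st$p_kyphotic, st$p_straight, cutoff = cutoff)
    } else {
      ms <- list(mu = st$mean, sigma = st$sd)
    }
    with_cc_seed(seed + i, {
      coefs <- rnorm(st$n, ms$mu, ms$sigma)
      if (is.na(st$age_group)) {
        age <- round(runif(st$n, 18, 90))
      } else {
        b <- bounds[bounds$age_group == st$age_group, ]
        age <- round(runif(st$n, b$lo, b$hi))
      }
      sex <- if (is.na(st$sex)) {
        ifelse(runif(st$n) < cc_female_share(), "female", "male")
      } else {
        rep(st$sex, st$n)
      }
      tibble(
        subject = sprintf("s%03d_%05d", i, seq_len(st$n)),
        year = st$year,
        sex = sex,
        age = age,
        age_group = as.character(cc_age_group(age)),
        coefficient = coefs,
        label = classify_coefficient(coefs, cutoff = cutoff)
      )
    })
  })
  structure(out, class = c("cc_cohort", class(tibble())))
}

#' Simulate a cohort with a linear drift in the yearly mean
#'
#' The year-y stratum mean is `mu0 + beta * (y - 2006)` with constant SD;
#' everything else follows [simulate_cohort()]. This is the
#' data-generating process behind the cross-sectional trend analyses.
#'
#' @param mu0 Baseline (2006) mean coefficient.
#' @param sd Within-year SD.
#' @param beta Per-year drift of the mean.
#' @param years Calendar years (default 2006-2018).
#' @param n_per_year Stratum size per year.
#' @param sex Optional sex for all strata.
#' @param seed Integer seed.
#' @return A cohort tibble as in [simulate_cohort()].
#' @export
simulate_trend_cohort <- function(mu0 = 1.76, sd = 1.37, beta, years = cc_years(),
                                  n_per_year, sex = NA_character_, seed) {
  if (!is.numeric(beta) || !is.finite(beta)) cc_abort("config", "`beta` must be finite.")
  strata <- purrr::map_dfr(years, function(y) {
    stratum_config(y, n_per_year, "moment",
      mean = mu0 + beta * (y - 2006), sd = sd, sex = sex
    )
  })
  simulate_cohort(strata, seed = seed)
}

#' Configuration for the longitudinal generator
#'
#' Repeated measures with a per-subject random slope on year:
#' `coefficient_ij = mu0 + (beta + b_i) * t_ij + e_ij`, with
#' `b_i ~ N(0, tau^2)`, `e_ij ~ N(0, sigma^2)` and `t = year - 2006`.
#' First visits are uniform over 2006-2017 and follow-up gaps uniform over
#' 1-4 years, with 2 or 3 visits per subject (matching the study's mean of
#' about 2.1 follow-up images).
#'
#' @param n_subjects Number of subjects.
#' @param visits_min,visits_max Visits per subject (both >= 2).
#' @param mu0 Baseline mean coefficient at 2006.
#' @param beta Population (fixed) slope per year.
#' @param tau SD of the per-subject random slope.
#' @param sigma Residual SD.
#' @param sex Optional common sex; `NA` assigns by the overall female share.
#' @param seed Integer seed.
#' @return A list of class `cc_longitudinal_config`.
#' @export
longitudinal_config <- function(n_subjects = 500L, visits_min = 2L, visits_max = 3L,
                                mu0 = 1.76, beta = -0.06, tau = 0.03, sigma = 0.3,
                                sex = NA_character_, seed = NULL) {
  if (visits_min < 2) cc_abort("config", "Longitudinal data needs >= 2 visits per subject.")
  if (visits_max < visits_min) cc_abort("config", "`visits_max` must be >= `visits_min`.")
  if (tau < 0 || sigma < 0) cc_abort("config", "`tau` and `sigma` must be >= 0.")
  if (n_subjects < 1) cc_abort("config", "`n_subjects` must be >= 1.")
  structure(
    list(
      n_subjects = as.integer(n_subjects), visits_min = as.integer(visits_min),
      visits_max = as.integer(visits_max), mu0 = mu0, beta = beta, tau = tau,
      sigma = sigma, sex = sex, seed = seed
    ),
    class = "cc_longitudinal_config"
  )
}

#' Simulate longitudinal repeated measures
#'
#' @param config A [longitudinal_config()].
#' @return A cohort tibble with one row per visit: `subject`, `year`
#'   (continuous visit time), `visit`, `sex`, `age`, `age_group`,
#'   `coefficient`, `label`. Deterministic given `config$seed`.
#' @export
simulate_longitudinal <- function(config) {
  stopifnot(inherits(config, "cc_longitudinal_config"))
  with_cc_seed(config$seed, {
    rows <- purrr::map_dfr(seq_len(config$n_subjects), function(i) {
      n_vis <- if (config$visits_min == config$visits_max) {
        config$visits_min
      } else {
        sample(config$visits_min:config$visits_max, 1)
      }
      t0 <- runif(1, 2006, 2017)
      gaps <- runif(n_vis - 1, 1, 4)
      times <- t0 + c(0, cumsum(gaps))
      b_i <- rnorm(1, 0, config$tau)
      e <- rnorm(n_vis, 0, config$sigma)
      age0 <- round(runif(1, 18, 87))
      sex <- if (is.na(config$sex)) {
        if (runif(1) < cc_female_share()) "female" else "male"
      } else {
        config$sex
      }
      coefs <- config$mu0 + (config$beta + b_i) * (times - 2006) + e
      tibble(
        subject = sprintf("p%05d", i),
        year = times,
        visit = seq_len(n_vis),
        sex = sex,
        age = age0 + round(times - times[1]),
        coefficient = coefs
      )
    })
    rows <- mutate(rows,
      age_group = as.character(cc_age_group(.data$age)),
      label = classify_coefficient(.data$coefficient)
    )
    structure(
      rows[, c("subject", "year", "visit", "sex", "age", "age_group", "coefficient", "label")],
      class = c("cc_cohort", class(tibble()))
    )
  })
}
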