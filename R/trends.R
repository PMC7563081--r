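# Statistical stage: prevalence estimates with Wald intervals, per-stratum
# linear trends of the mean coefficient, multinomial prevalence trends, and
# the linear mixed-effects longitudinal model.

cc_trend_result <- function(df, model, n_obs, extra = list()) {
  structure(
    df,
    model = model, n_obs = n_obs, meta = extra,
    class = c("cc_trend", class(tibble()))
  )
}

#' Estimate class prevalence with Wald confidence intervals
#'
#' Per group, the proportion of subjects in each target class with the
#' normal-approximation interval `p +/- 1.96 * sqrt(p (1 - p) / n)`,
#' clipped to `[0, 1]`.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()]) with a `label`
#'   column.
#' @param target_class Classes to report (default kyphotic and straight).
#' @param group_by Character vector of grouping columns (e.g.
#'   `c("year", "sex")`); `NULL` for a single overall group.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of class `cc_prevalence`: grouping columns, `label`,
#'   `n`, `count`, `proportion`, `conf.low`, `conf.high`.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_quantile_strata("sex", years = 2006), seed = 1)
#' estimate_prevalence(cohort, group_by = "sex")
estimate_prevalence <- function(cohort, target_class = c("kyphotic", "straight"),
                                group_by = NULL, conf_level = 0.95) {
  stopifnot(is.data.frame(cohort), "label" %in% names(cohort))
  if (nrow(cohort) == 0) cc_abort("empty_group", "Cohort is empty.")
  z <- qnorm(1 - (1 - conf_level) / 2)
  grouped <- if (is.null(group_by)) cohort else group_by(cohort, across(all_of(group_by)))
  counts <- summarise(grouped, n = n(),
    !!!setNames(
      purrr::map(target_class, function(cl) rlang::quo(sum(.data$label == !!cl))),
      target_class
    ),
    .groups = "drop"
  )
  if (any(counts$n == 0)) cc_abort("empty_group", "A group has no observations.")
  long <- tidyr::pivot_longer(counts, all_of(target_class),
    names_to = "label", values_to = "count"
  )
  out <- mutate(long,
    proportion = .data$count / .data$n,
    conf.low = pmax(0, .data$proportion - z * sqrt(.data$proportion * (1 - .data$proportion) / .data$n)),
    conf.high = pmin(1, .data$proportion + z * sqrt(.data$proportion * (1 - .data$proportion) / .data$n))
  )
  structure(out, class = c("cc_prevalence", class(tibble())))
}

#' Linear trend of the mean curvature coefficient over calendar year
#'
#' Ordinary least squares of the individual coefficient on calendar year
#' (centered at 2006), fitted within each stratum defined by `by`. The
#' slope is the per-year change in mean coefficient, with Wald 95\% CI and
#' two-sided p from the t distribution.
#'
#' @param cohort A cohort tibble; filter it first to restrict the stratum.
#' @param by Optional character vector of stratification columns; one fit
#'   per stratum.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of class `cc_trend`, one row per stratum: stratification
#'   columns, `term` (`"year"`), `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `p.value`, `n`, `model` (`"ols"`).
#' @export
linear_trend <- function(cohort, by = NULL, conf_level = 0.95) {
  stopifnot(is.data.frame(cohort), all(c("year", "coefficient") %in% names(cohort)))
  fit_one <- function(df) {
    if (length(unique(df$year)) < 2) {
      cc_abort("rank", "Need >= 2 distinct years to fit a trend.")
    }
    fit <- lm(coefficient ~ I(year - 2006), data = df)
    sm <- summary(fit)$coefficients
    est <- sm[2, 1]
    se <- sm[2, 2]
    z <- qnorm(1 - (1 - conf_level) / 2)
    tibble(
      term = "year", estimate = est, std.error = se,
      conf.low = est - z * se, conf.high = est + z * se,
      p.value = sm[2, 4], n = nrow(df), model = "ols"
    )
  }
  out <- if (is.null(by)) {
    fit_one(cohort)
  } else {
    grouped <- group_by(cohort, across(all_of(by)))
    dplyr::group_modify(grouped, function(df, key) fit_one(df)) |> ungroup()
  }
  cc_trend_result(out, model = "ols", n_obs = nrow(cohort))
}

#' Multinomial logistic trend of curvature class prevalence
#'
#' Three-category outcome (lordotic as reference, so coefficients describe
#' the kyphotic-vs-lordotic and straight-vs-lordotic log-odds), with
#' linear predictors in year (centered at 2006), sex and age in years,
#' fitted by maximum likelihood. Wald CIs and two-sided p-values from the
#' estimated covariance.
#'
#' @param cohort A cohort tibble with `label`, `year`, and any of the
#'   requested covariates.
#' @param covariates Model terms besides year (default `c("sex", "age")`;
#'   terms absent or constant in the data are dropped).
#' @param reference Reference outcome class (default `"lordotic"`).
#' @param classes Outcome classes to model (default all three). Every
#'   listed class must be observed; with the default, a cohort missing a
#'   class is a degenerate outcome. Passing two classes collapses the
#'   model to ordinary logistic regression on those classes.
#' @param conf_level Confidence level.
#' @return A tibble of class `cc_trend`: `outcome`, `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`, `p.value`, `model`
#'   (`"multinomial"`).
#' @export
multinomial_trend <- function(cohort, covariates = c("sex", "age"),
                              reference = "lordotic",
                              classes = curvature_levels(), conf_level = 0.95) {
  stopifnot(is.data.frame(cohort), all(c("label", "year") %in% names(cohort)))
  stopifnot(length(classes) >= 2, reference %in% classes)
  cohort <- filter(cohort, as.character(.data$label) %in% classes)
  present <- unique(as.character(cohort$label))
  if (length(present) < length(classes)) {
    cc_abort(
      "degenerate_outcome",
      sprintf(
        "Modelled curvature classes must all be present; missing: %s.",
        paste(setdiff(classes, present), collapse = ", ")
      )
    )
  }
  if (length(unique(cohort$year)) < 2) cc_abort("rank", "Need >= 2 distinct years.")
  covariates <- covariates[covariates %in% names(cohort)]
  covariates <- covariates[vapply(covariates, function(v) length(unique(cohort[[v]])) > 1, logical(1))]
  dat <- mutate(cohort,
    .label = stats::relevel(factor(as.character(.data$label), levels = classes),
      ref = reference
    ),
    year_c = .data$year - 2006
  )
  rhs <- paste(c("year_c", covariates), collapse = " + ")
  fit <- nnet::multinom(
    stats::as.formula(paste(".label ~", rhs)),
    data = dat, trace = FALSE, maxit = 500, reltol = 1e-12
  )
  if (fit$convergence != 0) {
    cc_abort("convergence", "Multinomial fit did not converge (possible separation).")
  }
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1, dimnames = list(fit$lev[2], names(cf)))
  vc <- vcov(fit)
  se <- matrix(sqrt(diag(vc)), nrow = nrow(cf), byrow = TRUE, dimnames = dimnames(cf))
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- purrr::map_dfr(rownames(cf), function(oc) {
    est <- unname(cf[oc, ])
    s <- unname(se[oc, ])
    tibble(
      outcome = oc,
      term = sub("^year_c$", "year", colnames(cf)),
      estimate = est,
      std.error = s,
      conf.low = est - z * s,
      conf.high = est + z * s,
      p.value = 2 * pnorm(-abs(est / s)),
      model = "multinomial"
    )
  })
  cc_trend_result(out, model = "multinomial", n_obs = nrow(dat), extra = list(fit = fit))
}

#' Linear mixed-effects trend for longitudinal measurements
#'
#' REML fit of the individual coefficient on year (centered at 2006) plus
#' optional sex and age fixed effects, with a per-subject random intercept
#' and random slope on year (unstructured covariance). The reported row is
#' the fixed year slope with its Wald CI and Satterthwaite p-value.
#'
#' @param cohort A longitudinal cohort tibble (repeated `subject` rows; see
#'   [simulate_longitudinal()]).
#' @param covariates Fixed-effect terms besides year (default
#'   `c("sex", "age")`; absent or constant terms are dropped).
#' @param conf_level Confidence level.
#' @return A tibble of class `cc_trend` with the `year` fixed-effect row:
#'   `term`, `estimate`, `std.error`, `conf.low`, `conf.high`, `p.value`,
#'   `n`, `n_subjects`, `model` (`"lmm"`). The `lmerMod` fit is in
#'   `attr(, "meta")$fit`.
#' @export
mixed_trend <- function(cohort, covariates = c("sex", "age"), conf_level = 0.95) {
  stopifnot(is.data.frame(cohort), all(c("subject", "year", "coefficient") %in% names(cohort)))
  visits <- table(cohort$subject)
  if (sum(visits >= 2) < 10) {
    cc_abort("no_repeats", "Need >= 2 visits for at least 10 subjects.")
  }
  covariates <- covariates[covariates %in% names(cohort)]
  covariates <- covariates[vapply(covariates, function(v) length(unique(cohort[[v]])) > 1, logical(1))]
  dat <- mutate(cohort, year_c = .data$year - 2006)
  rhs <- paste(c("year_c", covariates, "(1 + year_c | subject)"), collapse = " + ")
  fit <- lmerTest::lmer(
    stats::as.formula(paste("coefficient ~", rhs)),
    data = dat, REML = TRUE,
    control = lme4::lmerControl(
      optimizer = "bobyqa",
      check.conv.singular = lme4::.makeCC("ignore", tol = 1e-4)
    )
  )
  sm <- summary(fit)$coefficients
  est <- sm["year_c", "Estimate"]
  se <- sm["year_c", "Std. Error"]
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble(
    term = "year", estimate = est, std.error = se,
    conf.low = est - z * se, conf.high = est + z * se,
    p.value = sm["year_c", "Pr(>|t|)"],
    n = nrow(dat), n_subjects = length(visits), model = "lmm"
  )
  cc_trend_result(out,
    model = "lmm", n_obs = nrow(dat),
    extra = list(fit = fit)
  )
}
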