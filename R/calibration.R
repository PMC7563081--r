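# Published calibration anchors for the synthetic cohort generator.
# All numbers are the printed study values: yearly sample sizes and female
# fractions, the 2006/2018 overall coefficient mean (SD), per-year
# straight/kyphotic prevalences by sex and 10-year age group, and the
# fitted per-year trend slopes. Everything else the generator needs is
# derived from these (means by linear interpolation, normal (mu, sigma)
# per stratum by quantile calibration).

cc_years <- function() 2006:2018

#' Study-calibrated defaults for the synthetic cohort generator
#'
#' Returns the calibration tables the generator defaults are built from:
#'
#' * `overall`: per year, sample size `n`, percent female, and the overall
#'   coefficient mean/SD. Only the 2006 mean 1.76 (SD 1.37) and 2018 mean
#'   1.24 (SD 1.37) were published; intermediate yearly means are linear
#'   interpolation between them and the SD is held at 1.37.
#' * `prevalence`: per year and stratum (sex and 10-year age group), the
#'   published percentage of straight and kyphotic curvature. Zero cells
#'   are floored at 0.05\% so quantile calibration (which needs strictly
#'   positive tail probabilities) stays defined.
#' * `trend`: published per-year slopes of mean coefficient on calendar
#'   year from the cross-sectional linear fit (`beta_ols`) and the
#'   longitudinal mixed model (`beta_lmm`), by sex.
#'
#' @return A list of tibbles `overall`, `prevalence`, `trend`.
#' @export
#' @examples
#' calibration_defaults()$trend
calibration_defaults <- function() {
  years <- cc_years()
  overall <- tibble(
    year = years,
    n = c(970L, 1239L, 1038L, 899L, 621L, 473L, 973L, 990L, 980L, 1408L, 1243L, 1655L, 1202L),
    pct_female = c(56.7, 57.0, 55.5, 57.8, 56.5, 63.2, 58.7, 58.1, 56.7, 61.7, 62.8, 59.3, 59.6),
    mean = seq(1.76, 1.24, length.out = length(years)),
    sd = 1.37
  )

  sex_rows <- function(stratum, straight, kyphotic) {
    tibble(
      year = years, stratum_type = "sex", stratum = stratum,
      pct_straight = straight, pct_kyphotic = kyphotic
    )
  }
  age_rows <- function(stratum, straight, kyphotic) {
    tibble(
      year = years, stratum_type = "age_group", stratum = stratum,
      pct_straight = straight, pct_kyphotic = kyphotic
    )
  }
  prevalence <- bind_rows(
    sex_rows(
      "male",
      c(24.8, 25.3, 28.0, 26.2, 30.3, 30.2, 25.0, 27.8, 31.5, 27.7, 33.0, 35.0, 32.0),
      c(2.9, 4.5, 5.3, 2.8, 3.3, 4.9, 4.5, 3.6, 5.6, 4.2, 4.8, 6.8, 4.7)
    ),
    sex_rows(
      "female",
      c(16.5, 18.7, 20.8, 22.5, 20.2, 20.7, 25.8, 24.8, 26.5, 24.6, 28.9, 28.8, 26.9),
      c(2.7, 2.7, 3.6, 1.9, 5.3, 4.7, 4.2, 4.7, 6.3, 3.8, 4.8, 6.0, 7.8)
    ),
    age_rows(
      "18-29",
      c(34.8, 37.9, 37.2, 42.7, 43.3, 35.9, 41.5, 42.3, 50.7, 41.2, 48.1, 45.4, 45.5),
      c(4.5, 6.8, 10.1, 7.3, 13.4, 12.8, 9.6, 13.0, 14.2, 12.2, 12.4, 14.6, 16.7)
    ),
    age_rows(
      "30-39",
      c(26.3, 22.6, 36.4, 35.1, 32.1, 39.0, 33.1, 37.7, 37.4, 37.8, 40.6, 42.1, 40.6),
      c(3.0, 6.2, 8.4, 2.2, 6.2, 10.2, 7.6, 6.8, 12.3, 7.4, 8.2, 12.3, 11.9)
    ),
    age_rows(
      "40-49",
      c(21.5, 26.2, 23.4, 26.7, 27.7, 34.5, 29.9, 27.1, 32.8, 27.3, 38.6, 35.0, 36.0),
      c(3.1, 1.9, 1.9, 5.0, 3.8, 2.4, 5.2, 5.4, 6.2, 3.3, 4.5, 8.3, 6.6)
    ),
    age_rows(
      "50-59",
      c(17.3, 17.0, 22.1, 18.7, 17.5, 19.9, 21.1, 19.4, 21.4, 20.7, 28.1, 29.1, 25.7),
      c(2.4, 1.6, 3.1, 0.0, 2.3, 1.9, 2.2, 1.1, 1.5, 2.0, 3.2, 2.9, 3.0)
    ),
    age_rows(
      "60-69",
      c(12.4, 13.4, 16.5, 9.6, 21.4, 13.0, 14.7, 16.7, 16.0, 19.8, 22.6, 23.7, 18.4),
      c(2.2, 3.3, 2.3, 0.7, 2.3, 6.5, 0.6, 0.6, 3.2, 1.1, 2.0, 2.4, 3.7)
    ),
    age_rows(
      ">=70",
      c(10.7, 14.8, 9.8, 14.7, 11.1, 15.7, 13.6, 15.9, 16.7, 13.3, 9.7, 17.7, 13.5),
      c(1.3, 3.4, 4.9, 0.0, 4.4, 2.0, 2.3, 0.0, 1.0, 2.1, 2.8, 2.6, 2.0)
    )
  )
  # quantile calibration needs P(kyphotic) > 0 and P(straight) > 0
  prevalence <- mutate(
    prevalence,
    pct_straight = pmax(.data$pct_straight, 0.05),
    pct_kyphotic = pmax(.data$pct_kyphotic, 0.05)
  )

  trend <- tibble(
    sex = c("female", "male"),
    beta_ols = c(-0.05, -0.03),
    beta_lmm = c(-0.06, -0.04)
  )

  list(overall = overall, prevalence = prevalence, trend = trend)
}

#' Age-group bounds
#'
#' The study's 10-year age groups: 18-29, 30-39, 40-49, 50-59, 60-69 and
#' >=70 (the open top group is capped at 90 for simulation).
#'
#' @return A tibble with columns `age_group`, `lo`, `hi`.
#' @export
age_group_bounds <- function() {
  tibble(
    age_group = c("18-29", "30-39", "40-49", "50-59", "60-69", ">=70"),
    lo = c(18, 30, 40, 50, 60, 70),
    hi = c(29, 39, 49, 59, 69, 90)
  )
}

cc_age_group <- function(age) {
  b <- age_group_bounds()
  cut(age,
    breaks = c(b$lo, Inf), labels = b$age_group,
    right = FALSE, include.lowest = TRUE
  )
}
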