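# Independent oracles and small generators used across the suite.

# quadratic OLS via the normal equations, independent of lm()
normal_equations_quadratic <- function(x, y) {
  X <- cbind(1, x, x^2)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# closed-form OLS standard error of the quadratic coefficient at a fixed
# design and known noise sd
quadratic_se <- function(x, sigma) {
  X <- cbind(1, x, x^2)
  sqrt(sigma^2 * solve(t(X) %*% X)[3, 3])
}

# rigid transform + uniform scale applied to a polyline's points
apply_rigid <- function(pts, angle = 0, translation = c(0, 0), scale = 1) {
  cs <- cos(angle)
  sn <- sin(angle)
  tibble::tibble(
    x = scale * (pts$x * cs - pts$y * sn) + translation[1],
    y = scale * (pts$x * sn + pts$y * cs) + translation[2]
  )
}

# noiseless parabola polyline on the standardized abscissae
parabola_polyline <- function(coefficient, n = 13, h0 = half_chord_default()) {
  x <- seq(-h0, h0, length.out = n)
  as_polyline(tibble::tibble(x = x, y = (coefficient / 1000) * x^2))
}

# sample a cohort from a known multinomial-logit DGP
# (reference = lordotic; intercepts/slopes per outcome)
sample_multinomial_cohort <- function(n, beta_kyph, beta_straight, seed) {
  # beta_*: c(intercept, year_c, sexfemale, age)
  set.seed(seed)
  year <- sample(2006:2018, n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  age <- round(runif(n, 18, 90))
  X <- cbind(1, year - 2006, as.numeric(sex == "female"), age)
  eta_k <- X %*% beta_kyph
  eta_s <- X %*% beta_straight
  den <- 1 + exp(eta_k) + exp(eta_s)
  u <- runif(n)
  p_k <- exp(eta_k) / den
  p_s <- exp(eta_s) / den
  label <- ifelse(u < p_k, "kyphotic", ifelse(u < p_k + p_s, "straight", "lordotic"))
  tibble::tibble(
    subject = as.character(seq_len(n)), year = year, sex = sex, age = age,
    coefficient = NA_real_,
    label = factor(label, levels = c("kyphotic", "straight", "lordotic"))
  )
}
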