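---
title: "Quantifying cervical curvature and its population trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cervical curvature and its population trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervicurve)
library(dplyr)
```

## The measurement model

On a lateral cervical radiograph the anterior margins of the vertebral
bodies trace a gently curved line: convex anteriorly in the normal
(lordotic) neck, flat when the lordosis is lost, and concave when the
curvature has reversed (kyphosis). cervicurve quantifies that shape from a
digitized polyline of the anterior vertebral line.

The polyline is first **standardized**: the chord through its first
(cranial) and last (caudal) points becomes the x-axis, the chord midpoint
the origin, and the half-chord is rescaled to a fixed length $h_0$. The
anatomically anterior side — carried on the polyline as an orientation
flag — maps to positive $y$. A second-order polynomial
$y = a + bx + cx^2$ is then fitted by ordinary least squares over all
points, and the **curvature coefficient** is $C = c \times 10^3$:
positive for lordosis, negative for kyphosis, larger in magnitude for
deeper curves. Because standardization removes position, rotation and
scale, $C$ is invariant to how the radiograph was digitized (the test
suite checks this to $10^{-6}$ under random rigid transforms).

Curvature is classified from $C$ with cutoffs at $\pm 0.8$: kyphotic
below $-0.8$, straight in the closed interval $[-0.8, 0.8]$, lordotic
above $0.8$. These cutoffs descend from global-angle criteria of the
Harrison posterior tangent method, in which lordosis is a global angle
below $-4^\circ$ and kyphosis above $+4^\circ$.

### The angle–coefficient correspondence

The package links the two scales through the endpoint tangents of the
standardized parabola: the tangents at $x = \pm h_0$ meet at

$$\theta \;=\; -2\,\arctan\!\big(2\,(C \times 10^{-3})\,h_0\big)
\quad\text{(degrees)},$$

a strictly decreasing bijection between coefficient and global angle
(`coefficient_to_angle()` / `angle_to_coefficient()`). The default
half-chord, $h_0 = \tan(2^\circ)/(2 \cdot 8\times 10^{-4}) \approx
21.8255$ (`half_chord_default()`), is the unique value that makes the
$\pm 0.8$ coefficient cutoffs and the $\pm 4^\circ$ angle cutoffs
coincide exactly, so classification by either scale is identical
everywhere, boundaries included. This endpoint-tangent construction is
our model of the C2–C7 posterior-tangent angle, adopted because the
cutoff pair is the only printed anchor tying the two scales together; it
is an approximation of the radiographic construction, not a claim about
it. `harrison_angle()` computes the posterior-tangent angle directly from
C2/C7 wall landmarks when those are available, with the same sign
convention (lordosis negative).

Two further conventions are deliberate choices where the source
conventions were under-specified:

* **Chord definition.** "Midpoint of the line" is read as the chord
  midpoint between the polyline's endpoints, not the arc-length midpoint;
  the chord is observable from any digitization and makes standardization
  a closed-form similarity transform.
* **Boundary handling.** The straight band is the closed interval: a
  coefficient of exactly $\pm 0.8$ is straight.

The fit uses equal weights and no robust loss; polylines are expected to
be segmentation or landmark output whose errors are small and roughly
homoscedastic after standardization. Degenerate inputs fail loudly with
typed errors: fewer than 5 points, coincident endpoints, or a
rank-deficient design (fewer than three distinct abscissae).

### From masks to polylines

`extract_anterior_polyline()` bridges raster segmentations to the
geometry pipeline: the largest 8-connected foreground component is
reduced to one point per raster row (row-wise centroid), cranial row
first. Raster rows thus approximate the cranio-caudal axis, which is the
usual orientation of a lateral cervical radiograph; two or more
substantial components make the mask ambiguous (threshold
`component_min_px`). `rasterize_polyline()` is its approximate inverse
and the pair round-trips the coefficient to within 0.05 for strokes up to
5 px thick — the residual error is centroid quantization, which shrinks
as the parabola's sag grows relative to the pixel grid.

## Agreement metrics

Segmentation quality is summarized by pixel-wise accuracy and mean
intersection-over-union across the two classes (line, background), with a
class absent from both masks contributing IoU 1.0 so degenerate fixtures
stay defined. Measurement agreement between two observers uses RMSE on
the coefficient scale and the intraclass correlation coefficient. The ICC
form is **ICC(2,1)** — two-way random effects, absolute agreement, single
measures — the standard choice for method-agreement studies, computed
from the two-way ANOVA mean squares. A fixed shift $\delta$ between two
raters enters the absolute-agreement denominator as a rater variance
component $\delta^2/2$, which is what the closed-form recovery test
asserts.

## The synthetic cohort generator

No subject-level data ship with the package; the generator reproduces the
*published summaries* of a 13 691-subject cross-sectional series
(2006–2018) and a 506-patient longitudinal subset, so that the analysis
stage can be exercised and validated end to end.

* **Spine polylines** (`generate_spine_polyline()`): standardized
  parabola with a chosen target coefficient, Gaussian landmark noise
  (default SD 0.05 standardized units, a visually small jitter relative
  to the ~0.95 sag of a $C = 2$ curve), and an arbitrary rigid transform
  + scale into image coordinates.
* **Cross-sectional strata** (`simulate_cohort()`): per year × sex or
  year × age-group cell, coefficients are Normal. Two calibration modes
  resolve the fact that published means/SDs and published class
  prevalences need not be mutually consistent under normality: *moment*
  mode matches a printed mean (SD), *quantile* mode matches printed
  kyphotic/straight prevalences exactly through the probit closed form in
  `calibrate_group_normal()`. The shipped defaults
  (`calibration_defaults()`) carry the printed yearly sample sizes,
  female fractions, the 2006/2018 overall means 1.76/1.24 (SD 1.37,
  linearly interpolated between, SD held constant), and the full grid of
  per-year straight/kyphotic prevalences by sex and age group. Prevalence
  cells printed as 0.0% are floored at 0.05% because quantile calibration
  needs strictly positive tail probabilities. Ages are uniform within
  their 10-year group (the open ≥70 group capped at 90); unset sex is
  assigned at the overall 58.8% female share.
* **Trend cohorts** (`simulate_trend_cohort()`): yearly mean
  $\mu_0 + \beta (y - 2006)$ with constant SD. The default drifts are the
  published per-sex slopes ($-0.05$/yr women, $-0.03$/yr men); the
  baseline $\mu_0 = 1.76$ (SD 1.37) is the overall 2006 value, since
  per-sex baselines were not printed — slope recovery is invariant to
  that choice.
* **Longitudinal data** (`simulate_longitudinal()`):
  $C_{ij} = \mu_0 + (\beta + b_i)\,t_{ij} + e_{ij}$ with per-subject
  random slope $b_i \sim N(0, \tau^2)$, residual $e_{ij} \sim N(0,
  \sigma^2)$, $t$ = years since 2006. First visits uniform over
  2006–2017, 2–3 visits per subject with gaps uniform on 1–4 years
  (matching a reported mean of ~2.1 images per patient); late entrants'
  follow-ups may run marginally past 2018. Defaults $\tau = 0.03$,
  $\sigma = 0.3$ put most variation in measurement/visit noise with a
  modest spread of individual trajectories, consistent with observer RMSE
  below 0.3 on this scale.

Every generator is bit-reproducible given its seed; the global seed
expands to per-stratum child seeds as `seed + stratum_index`, so
appending strata never perturbs existing ones.

**What the generator does not emulate:** within-stratum non-normality and
skew, correlation between age and year effects beyond the stratum grid,
informative follow-up (visit times are independent of curvature), secular
changes in radiographic technique, and segmentation failure modes other
than the validity checks the pipeline applies. Passing calibration tests
therefore demonstrates that the *pipeline* recovers the parameters of its
own data-generating process at the published design sizes — not that the
published cohort values are externally reproduced.

## The trend-analysis stage

* `estimate_prevalence()`: class proportions per stratum with Wald
  intervals $p \pm 1.96\sqrt{p(1-p)/n}$, clipped to $[0,1]$. The Wald
  form was chosen because recomputing a published prevalence cell from
  its implied count (104 of 420 straight) reproduces the printed interval
  (24.8%, 20.6–28.9) exactly at the 1-decimal reporting precision.
* `linear_trend()`: OLS of individual coefficients on calendar year
  centered at 2006, Wald CI and two-sided t-test p-value. Fits are on
  individual observations (not yearly means); with equal yearly n the
  slope estimate coincides, and individual fits keep the SE honest.
* `multinomial_trend()`: three-category outcome with lordotic (normal) as
  reference, so the two coefficient rows describe kyphotic-vs-lordotic
  and straight-vs-lordotic log-odds trends; linear predictors in year
  (centered), sex and age in years (continuous; the 10-year bins are for
  stratified reporting only). Fitting is maximum likelihood via
  `nnet::multinom` with a tight convergence tolerance; collapsing to two
  classes reproduces ordinary logistic regression to $10^{-6}$, which the
  suite uses as a dual-route check.
* `mixed_trend()`: REML linear mixed model with fixed year (+ optional
  sex, age) and a per-subject random intercept *and* random slope on
  year, unstructured 2×2 covariance, via lme4/lmerTest (Satterthwaite
  p-values). The random intercept is included by design even though only
  a random slope is strictly required: with 2–3 visits per subject a
  slope-only random effect anchored at a common intercept is rarely a
  defensible model, and the intercept costs little. Singular-fit warnings
  at variance boundaries are tolerated; variance components are
  constrained nonnegative by construction.

All p-values are two-sided with $\alpha = 0.05$. Reporting helpers round
percentages to 1 decimal and slopes to 2, the published precision.

## Pipeline and reproducibility

`run_pipeline()` chains the stages (simulate or measure → classify →
prevalence → trends) from a single config (list or YAML), writes every
intermediate table as CSV, logs one line per stage with record counts,
and enforces count conservation: inputs = measured + excluded, with each
exclusion recorded by its typed reason (insufficient points, degenerate
geometry, extreme residual). Reruns with the same config and seed are
byte-identical on all CSV outputs. A thin `Rscript` wrapper
(`inst/scripts/cervicurve.R`) exposes the same functions as shell
subcommands.

## Numerical choices and limitations

* Geometric comparisons are asserted at $10^{-9}$ for noiseless inputs
  and $10^{-6}$ after rigid transforms (floating-point rotation error
  compounds through the similarity transform).
* The probit calibration is exact to $10^{-12}$ round trip on the
  probability grid it is tested over.
* Calibration-recovery experiments in the tests use the published design
  sizes (e.g. n = 970 and 1202 for the 2006/2018 means, 800/year for
  cross-sectional trends, 500 subjects for the mixed model, $10^5$ draws
  for prevalence cells) with 3-standard-error tolerances from the CLT or
  the model's own covariance.
* The angle–coefficient conversion assumes the fitted parabola is a good
  model of the anterior vertebral line over the chord; for strongly
  S-shaped (sigmoid) necks a single quadratic under-describes the shape
  and the coefficient summarizes net convexity only.
* `extract_anterior_polyline()` assumes a roughly vertical spine in the
  raster (one crossing per row); severely rotated radiographs should be
  measured from digitized landmarks instead.
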