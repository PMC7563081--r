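# cervicurve

Quantify cervical sagittal alignment from a digitized anterior vertebral
line, and model how curvature classes shift across a population over
time.

Loss of cervical lordosis — the flattening or reversal of the neck's
normal anterior-convex curve — is usually graded from lateral radiographs
by hand-measured global angles. cervicurve implements a compact,
automation-friendly alternative for radiologists and musculoskeletal
epidemiologists: the polyline traced along the anterior margins of the
vertebral bodies is standardized to a chord-aligned frame (chord on the
x-axis, midpoint at the origin, half-chord rescaled to a fixed `h0`,
anterior side to +y) and fitted with a second-order polynomial

```
y = a + b x + c x^2,        C = c × 10³
```

The curvature coefficient `C` is invariant to position, rotation and
scale of the digitization. Classification uses cutoffs at ±0.8
(kyphotic < −0.8 ≤ straight ≤ 0.8 < lordotic), calibrated so that they
coincide exactly with the ±4° global-angle criteria of the Harrison
posterior tangent method through the endpoint-tangent relation
`θ = −2·atan(2 (C/1000) h0)` with `h0 = tan 2° / (2·8×10⁻⁴) ≈ 21.8255`.

The package also provides:

* segmentation/agreement metrics used to validate automated pipelines —
  pixel accuracy, mean IoU, RMSE and ICC(2,1);
* a synthetic cohort generator calibrated to published yearly means/SDs
  and class prevalences (2006–2018, by sex and 10-year age group),
  including longitudinal repeated measures with per-subject random
  slopes;
* the trend-analysis stage: Wald prevalence intervals, OLS trends of the
  mean coefficient on calendar year, multinomial logistic prevalence
  trends (lordotic as reference), and REML linear mixed models with a
  random slope on year;
* a `run_pipeline()` orchestrator plus a thin CLI wrapper
  (`inst/scripts/cervicurve.R`).

## Worked example

```r
library(cervicurve)

# a synthetic "radiograph": lordotic spine, landmark noise, arbitrary pose
pl <- generate_spine_polyline(spine_spec(
  target_coefficient = 1.8, noise_sd = 0.05,
  angle = 0.4, translation = c(310, 220), scale = 4, seed = 42
))
glance(measure_radiograph(pl))
#>   coefficient angle label    rms_residual n_points
#> 1        1.87 -9.31 lordotic       0.0619       25
```

The measured coefficient 1.87 sits near the generating value 1.8 (the
difference is landmark noise); the equivalent global angle −9.3° is well
below the −4° lordosis boundary, so the curve is classified lordotic.

```r
# a full simulated cross-sectional series from the shipped calibration
cohort <- simulate_cohort(default_quantile_strata("sex"), seed = 1)
nrow(cohort)
#> [1] 13691

prev <- estimate_prevalence(cohort, group_by = c("year", "sex"))
format_prevalence(prev) |>
  dplyr::filter(year %in% c(2006, 2018), label == "straight") |>
  dplyr::select(year, sex, n, prevalence)
#>    year sex        n prevalence
#> 1  2006 female   550 17.3 (14.1 to 20.4)
#> 2  2006 male     420 22.9 (18.8 to 26.9)
#> 3  2018 female   716 28.1 (24.8 to 31.4)
#> 4  2018 male     486 34.8 (30.5 to 39.0)

# recover a configured downward drift of the yearly mean coefficient
tc <- simulate_trend_cohort(beta = -0.05, n_per_year = 800, sex = "female", seed = 2)
tidy(linear_trend(tc))
#>   term  estimate std.error conf.low conf.high  p.value     n model
#> 1 year   -0.0482   0.00360  -0.0553   -0.0412 1.22e-40 10400 ols
```

Straight-curvature prevalence rises from 2006 to 2018 in both sexes
because the per-year stratum distributions are calibrated to do so, and
the fitted OLS slope −0.048 (95% CI −0.055 to −0.041) per year recovers
the configured drift of −0.05 within sampling error.

`autoplot()` methods are available for measurements, prevalence tables
and cohorts; `tidy()`/`glance()` follow broom conventions throughout.

## Package layout

| | |
|---|---|
| `R/geometry.R` | standardization, quadratic fit, classification, angle conversions |
| `R/mask.R` | mask ↔ polyline bridging, PNG I/O |
| `R/metrics.R` | pixel accuracy, mean IoU, RMSE, ICC(2,1) |
| `R/calibration.R`, `R/synthetic.R` | published-value defaults and generators |
| `R/trends.R` | prevalence, OLS / multinomial / mixed-model trends |
| `R/pipeline.R` | end-to-end orchestration |
| `vignettes/cervical-curvature-methods.Rmd` | full methods account |
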