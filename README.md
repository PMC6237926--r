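# yieldtrends

Trend, stagnation and variability analysis for long annual panels of
sub-national crop yields.

Agricultural statistics offices publish yields per administrative unit
(in France: 96 departments, ten major crops, in places back to 1900).
Questions that matter for food-supply foresight — are yields still
rising, where has growth stalled and since when, is inter-annual
variability shrinking — need more than a linear fit: trends change shape
over a century, series have gaps and digitization errors, and "growth
has stopped" must be a statistical statement, not a visual one.
`yieldtrends` packages that workflow for researchers working with such
panels:

* **Quality filters** — three outlier rules (absolute per-crop bound,
  ratio to the series' long-term mean, year-on-year jump), masking flags
  to missing rather than correcting them.
* **Trend estimation** — the local linear trend dynamic linear model
  `Y_t = a_t + ε_t`, `(a_t, b_t)' = G (a_{t-1}, b_{t-1})' + τ_t`, with
  `σ²_ε, σ²_a, σ²_b` estimated by maximum likelihood and a Kalman
  smoother (compiled core) giving level `a_t`, growth `b_t`, relative
  growth `g_t = b_t/a_t` and 90% intervals at every year, missing years
  included.
* **Stagnation detection** — equivalence-test scoring of each window
  year's growth CI against the band [0, 0.5%]/yr (ten CI positions,
  scores in [0,1]); overall score ≥ 0.5 marks a series "likely
  stagnating", with an onset year and area-weighted shares of stagnating
  cropping area.
* **Variability analytics** — decadal CVs (residual SD over raw mean)
  with categories, Taylor power-law fits (`SD ∝ mean^β`), residual
  skewness, cross-department quantile trends, cross-crop residual
  correlations.
* **Spatial structure and drivers** — era-wise UPGMA clustering of
  departmental mean yields with Calinski–Harabasz selection of the
  cluster count; Pearson correlation of yields with fertilizer series,
  raw and detrended.
* **A synthetic panel generator** with ground truth (logistic trends,
  heteroscedastic skew-normal noise, war dips, missingness, injected
  outliers, calibrated fertilizer series), so the whole pipeline is
  testable end-to-end without the partially-public historical data.

## Worked example

The built-in reference fixture is a deterministic 4-department ×
3-crop × 117-year panel with known outliers and known stagnation
structure:

```r
library(yieldtrends)

fx  <- reference_fixture()
out <- run_pipeline(panel = fx$panel,
                    stages = c("qc", "trend", "stagnation"))

out$qc_flags
#>   department_id       crop season_type year yield       rule
#> 1           D02      maize   aggregate 1970   0.3 mean_ratio
#> 2           D03      maize   aggregate 1960  14.0       jump
#> 3           D01 soft_wheat   aggregate 1985  12.0   absolute
```

Exactly the three crafted violations are flagged — a 12 t/ha soft wheat
yield above the 10 t/ha absolute bound, a maize value more than ten-fold
below its series mean, and a more-than-twenty-fold year-on-year jump —
and masked before trend fitting.

```r
subset(out$stagnation, crop == "soft_wheat")
#>   department_id       crop season_type overall_score likely onset_year n_years
#> 1           D01 soft_wheat   aggregate        0.6250   TRUE       1997      20
#> 2           D02 soft_wheat   aggregate        0.6375   TRUE       1997      20
#> 3           D03 soft_wheat   aggregate        0.1250  FALSE         NA      20
#> 4           D04 soft_wheat   aggregate        0.6625   TRUE       1997      20
```

D01, D02 and D04 are the fixture's constructed stagnating wheat series:
their 1997–2016 growth-rate CIs predominantly sit inside or below the
stagnation band (scores ≥ 0.5, onset 1997), while the growing D03 scores
0.125.  Shares weight these classifications by cropping area:

```r
out$stagnation_share
#>                  crop area_share n_assessed n_likely
#> soft_wheat soft_wheat  0.6517179          4        3
#> maize           maize  0.5947918          4        3
#> potatoes     potatoes  0.4951318          4        2
```

A single fitted trend can be inspected directly:

```r
out$fits[["D04|soft_wheat|aggregate"]]
#> Local linear trend fit: 117 years (117 observed), loglik -43.651
#>   sigma2_eps=0.0448 sigma2_a=0.01645 sigma2_b=0.0001409

tail(as.data.frame(out$fits[["D04|soft_wheat|aggregate"]]), 3)
#>     year        a      var_a           b       var_b            g        g_lo        g_hi
#> 115 2014 5.962256 0.01383032 -0.02419116 0.001480528 -0.004057384 -0.01467280 0.006558037
#> 116 2015 5.979079 0.01571386 -0.02351250 0.001610393 -0.003932461 -0.01497251 0.007107592
#> 117 2016 6.034826 0.02218874 -0.02351250 0.001751258 -0.003896135 -0.01530257 0.007510296
```

The smoothed level has flattened near 6 t/ha and the relative growth
rate is slightly negative (−0.4%/yr) with a CI straddling the band —
the signature the stagnation scorer keys on.

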