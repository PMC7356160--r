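# cdexposure

Dietary cadmium (Cd) exposure assessment by **individual food analysis**,
built for cohorts of female farmers in two Cd-polluted areas of northern
Japan but usable for any food-frequency-based contaminant assessment.

Cd accumulates in the kidney and chronic dietary exposure can cause renal
tubular dysfunction; the dominant route for non-smokers is food,
particularly rice grown on contaminated paddies. The assessment this
package implements multiplies each subject's questionnaire-derived food
intake (g/day) by the measured Cd concentration of that food (mg/kg ≡
µg/g), sums over foods into a daily intake *T* (µg/day), converts to
weekly intake per body weight

> *W* = 7 · *T* / weight  [µg/kg BW/week],

and compares *W* against the tolerable weekly intake (TWI) of
7 µg/kg BW/week. Cohort exposure is characterised by medians and
quartiles, TWI exceedance proportions (χ² contrast between areas),
age-stratified Steel–Dwass comparisons, iterative Smirnov–Grubbs outlier
screening, and a seeded lognormal Monte Carlo simulation
(10,000 repetitions) of the weekly intake distribution with its
closed-form exceedance probability 1 − Φ((ln 7 − µ)/σ).

The package ships:

* a replicate-level food Cd concentration table for ~100 items in two
  areas (reconstructed to reproduce the published per-item summaries
  exactly — see `cd_printed_summaries()`),
* a declarative YAML mapping reconciling questionnaire items with
  measured foods (weighted splits, item averages, individual rice Cd,
  explicit exclusions),
* a calibrated synthetic cohort generator (`generate_cohort()`) so every
  stage is testable without any subject-level data,
* report writers (`run_intake()`, `run_simulation()`, `run_compare()`)
  producing the cohort summary, exceedance, age-stratified, histogram,
  simulation and fold-ratio tables.

## Worked example

```r
library(cdexposure)

# a synthetic cohort with the structure of study area B (n = 432)
cohort <- generate_cohort(cohort_params("area_B"), seed = 1)
fit <- cd_exposure(cohort)
fit
#> Dietary Cd exposure assessment (individual food analysis)
#>   subjects: 432 (0 excluded)
#>   total Cd intake, median: 47.8 ug/day
#>   weekly intake per BW, median: 6.0 ug/kg BW/week
#>   at or above TWI (7): 162 (37.5%)

# Monte Carlo simulation of weekly intake (Grubbs screen, MLE fit, draws)
sim <- run_simulation(fit, seed = 1)
sim$fit
#> Lognormal intake model (mle, n = 432)
#>   mu = 1.8171, sigma = 0.4850  (median = 6.154)
round(sim$summary[1:5], 2)
#>   n_reps median   p5   p95  min
#> 1  10000   6.11 2.72 13.73 1.04
```

The median total intake (47.8 µg/day) and weekly intake per body weight
(6.0 µg/kg BW/week, 37.5% of subjects at or above the TWI) match the
published area-B cohort values the generator was calibrated to; the
simulated median (6.11) agrees with the cohort median, confirming the
lognormal supposition is adequate. `summary(fit)` prints the per-subgroup
daily intakes (rice dominates), the exceedance partition and the
age-stratified medians; `plot(fit)` draws the weekly-intake histogram
with the TWI marked.

Fitting from printed summaries instead of a cohort:

```r
fit_b <- fit_lognormal_quantiles(4.4, 6.0, 8.5)  # area-B quartiles
round(100 * tail_probability(fit_b, 7), 1)        # model-based exceedance %
#> [1] 37.6
```

## Documentation

The methods vignette (`vignettes/cadmium-exposure-methods.Rmd`) documents
the model, censoring rules, the mapping, the statistical procedures, the
Monte Carlo design, the synthetic generator's calibration and its
limitations.
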