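---
title: "Methods: dietary cadmium exposure assessment by individual food analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary cadmium exposure assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdexposure)
```

## The assessment model

Dietary cadmium (Cd) exposure is assessed here by *individual food
analysis*: for each subject and each food item of a diet history
questionnaire (DHQ), the daily Cd contribution is

$$\text{contribution}_{ij} \;=\; C_j \;\times\; I_{ij} \;\times\; f_j
\quad [\mu g/\text{day}],$$

where $C_j$ is the effective Cd concentration of item $j$ in mg/kg
(equivalently µg/g), $I_{ij}$ is subject $i$'s intake of that item in
g/day, and $f_j$ is a dimensionless mass-change factor converting the
reported (usually cooked) mass to the mass basis on which the
concentration was measured. Contributions are summed into seven reporting
subgroups (rice and rice products; cereals, tubers and roots; soybeans;
vegetables; mushrooms; seafood — merging seaweed, fish and shellfish; and
others — absorbing livestock foods and miscellaneous items; fruit,
in which Cd was not detected, is excluded). The total daily intake is
converted to weekly intake per body weight,

$$W_i = 7 \, T_i / w_i \quad [\mu g/\text{kg BW}/\text{week}],$$

and compared against the tolerable weekly intake (TWI) of
7 µg/kg BW/week; a subject at exactly the threshold counts as exceeding
it, matching the "≥ 7" binning convention of the source surveys.

Rice is treated individually: each subject's own rice Cd concentration is
used (farmers predominantly eat self-harvested rice, and rice dominates
exposure in these areas), multiplied by 0.9 when the subject eats brown
rice — polishing removes roughly 10% of the Cd — and substituted by the
cohort's area-specific geometric mean when the individual measurement is
missing. All other items use the pooled arithmetic mean concentration
across both sampling areas.

## Concentration data and censoring

The packaged concentration table covers about 100 food items in ten
subgroups. Because the source publication prints per-item summaries only
(n, mean, range), the packaged replicates are *synthetic*: the two range
endpoints are stored as printed and the interior replicates share a value
solved so the arithmetic mean (geometric mean for rice) reproduces the
printed figure. Three printed rows are internally inconsistent (the mean
cannot lie inside the printed range: kiritampo, ampan, chocolate); these
are flagged `consistent = FALSE` in `cd_printed_summaries()` and their
replicates honour the range while approaching the printed mean as closely
as possible.

Values below the detection limit (0.01 mg/kg cereals, 0.005 mg/kg other
foods, 0.001 mg/L water) are censored observations. Two substitution
rules are defaults in different roles:

* **summaries** use `half_lod` (LOD/2), the common convention for
  presenting partially censored data;
* **intake contributions** use `zero`, so fully non-detected foods (meat,
  eggs, milk, brewed tea, fruit) contribute nothing — matching how the
  source assessment excluded them. Both rules (and `lod`) are selectable
  everywhere; the choice matters only for items censored at one end of
  the range, e.g. whether salmon roe enters the fish-egg average as 0 or
  0.0025 mg/kg.

A censored value printed as a range endpoint of an otherwise detected
item is stored as an uncensored value at the detection limit, because the
printed range treats it that way.

## The questionnaire mapping

Questionnaire items and measured foods are not one-to-one. A declarative
YAML rule set resolves each DHQ item to a weighted combination of
concentration sources: barley rice is 70% rice / 30% wheat flour; the
combined noodle item splits half udon, half soba; bread-like and
confectionery items borrow the white-bread and sweet-bun concentrations;
collective items (tubers, tofu, leafy greens, shrimp, fish eggs, other
shellfish, liver) use averages of their member items; mushrooms split
evenly between shiitake and maitake. Items never evaluated by the DHQ
(garlic, okra, belvedere fruit, kelp, hijiki, agar-agar, mozuku, scallops
with innards) remain measured-but-unused, and `validate_coverage()`
reports exactly these sets. Component weights must sum to 1 (tolerance
1e-9); resolution is linear in the concentration table.

Mass-change factors default to 1.0 in the mapping because the external
food-composition mass-change table is not part of the data. The one
factor that demonstrably matters is rice: questionnaire rice intake is
reported as cooked rice, while Cd is measured in raw rice. Cooking
roughly doubles rice mass (≈2.1×), i.e. a factor of 0.476 raw-equivalent
per reported gram; this value reconciles the concentration-level and
intake-level summaries of both study areas (e.g. 0.158 mg/kg × 371.8
g/day × 0.476 ≈ 28 µg/day, the printed rice-subgroup median in area A,
where a factor of 1 would give an impossible 59 µg/day). The synthetic
cohort presets therefore carry `mass_change_factors = c(rice = 0.476)`,
attached to generated cohorts and picked up by `cd_exposure()`.

## Cohort filters and summaries

Subjects with implausible energy intake (≤ 1000 or ≥ 3500 kcal/day, both
boundaries excluded) or zero rice consumption are removed before
analysis; the filter is idempotent and logs a reason per subject.
Skewed intake quantities are summarised as medians with 25th/75th
percentiles using linear interpolation of order statistics (R's quantile
type 7) — the convention is a single switch away should another be
preferred. Reported tables round to one decimal at serialisation only;
companion full-precision columns are retained.

## Statistical procedures

The procedures are implemented from first principles (base R supplies
only the reference distributions):

* **Median test** (two samples): pooled grand median; counts above vs at
  or below (ties fall in the "at or below" cell); Pearson χ² with 1 df,
  no continuity correction by default (Yates correction by flag). The
  test is mildly conservative at moderate n — the null simulation in the
  test suite measures a size of ≈0.045 at a nominal 0.05.
* **χ² test of proportions** on 2×2 tables, used for the TWI exceedance
  contrast between areas.
* **Unpaired Student's t-test**, pooled variance, for the approximately
  normal background variables (age, height, weight, energy, rice intake).
* **Steel–Dwass all-pairs comparison** for age-stratified intakes:
  pairwise Wilcoxon rank sums, tie-corrected variance, referred to the
  studentized range with infinite df. At $k = 2$ it reduces exactly to
  the two-sided normal-approximation Wilcoxon test. Exact small-sample
  permutation versions are out of scope.
* **Iterative Smirnov–Grubbs screening**, two-sided at α = 0.05, removing
  the most extreme point while $G$ exceeds the critical value
  $\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$, $t$ the upper $\alpha/(2n)$
  t-quantile with $n-2$ df. In the simulation pipeline the screen is
  applied to **log** weekly intakes: the working model is lognormal, so
  Grubbs' normality assumption holds on the log scale, whereas on the raw
  scale the natural lognormal upper tail itself trips the criterion at
  n ≈ 700 and the screen would discard legitimate observations.
  Sample standard deviations use the n−1 denominator throughout.

## Lognormal Monte Carlo simulation

Weekly intake is modelled as lognormal. Two fits are supported:

* `fit_lognormal_mle()` — mean and sd of log intakes, for use with a
  cohort (after outlier screening); degenerate (zero-variance) input is
  an error rather than a silent point-mass fit;
* `fit_lognormal_quantiles()` — $\mu = \log(\text{median})$,
  $\sigma = \log(q_{75}/q_{25}) / (2 \times 0.67449)$, for use with
  printed summaries. The fit preserves the median and the quartile ratio
  exactly; the individual quartiles are reproduced exactly only when the
  input triple is log-symmetric.

`simulate()` draws 10,000 repetitions by default under a mandatory seed;
summaries report the median, the 5th–95th percentiles and the range
(ranges are extreme order statistics and are reported but never used as
calibration or acceptance quantities). The closed-form exceedance
probability at the TWI is $1 - \Phi((\log 7 - \mu)/\sigma)$. Fitted to
the printed area summaries, the model reproduces the empirical
exceedance percentages within one percentage point in both areas, which
is the package's own check that the lognormal supposition is adequate.

## The synthetic cohort generator

No subject-level data are deposited, so the generator emulates the two
study cohorts well enough to exercise every pipeline stage:

* anthropometrics, energy and rice intake are truncated normals with the
  printed means, SDs and ranges (712 and 432 subjects);
* ages are drawn by stratum with the printed decade-band proportions,
  means and SDs;
* individual rice Cd is lognormal around the printed area geometric
  means (0.158 / 0.109 mg/kg). The log-sd is derived from the printed
  share of rice above the 0.4 mg/kg safety standard (8.2% / 5.8%),
  giving 0.667 (A) and 0.827 (B);
* five percent of subjects eat brown rice (an assumption — the source
  reports no proportion), and area A has one subject with a missing rice
  measurement, exercising the geometric-mean substitution;
* all non-rice exposure is a single lognormal daily component, split in
  fixed shares across six representative questionnaire items (potato,
  miso, leafy greens, mushrooms, oysters, sweet bun) in proportion to the
  printed subgroup medians; grams are derived by dividing each item's Cd
  share by its effective concentration, so the intake engine reproduces
  the component exactly.

The non-rice `(mu, sigma)` presets were calibrated once with
`calibrate_nonrice_component()` (damped stochastic fixed point, cohorts
of 6,000, fixed seed) against the printed weekly-intake quantiles —
area A 5.2/7.2/9.7, area B 4.4/6.0/8.5 µg/kg BW/week — converging within
the 3% tolerance on all three quantiles in both areas. At the study
sizes the generated cohorts reproduce the printed medians within ±0.2
and the exceedance percentages within ~2 points.

What the generator does **not** emulate: correlation between food items
(each subject's non-rice component is one draw), seasonal variation, and
any dependence between rice Cd and rice consumption. Passing tests
therefore demonstrate that the pipeline computes the intended quantities
under the assumed structure, not that the structure captures every
feature of real dietary data — in particular, the real cohorts' subgroup
interquartile ranges are somewhat narrower relative to their totals than
independence allows.

## Problem sizes and numerical choices in the test suite

The suite runs cohorts at the study sizes (712/432) where the check is
about study conditions, and 40–400 where it is structural; null-size
simulations use 10,000 repetitions with 60 observations per group;
parameter-recovery checks use 10,000 draws. The full suite completes in
well under a minute. Tolerances follow the quantity being checked:
printed means to 3 decimals (absolute 5×10⁻⁴), machine precision
(1e-12) for additivity identities, 3 standard errors for stochastic
recovery, and the published one-decimal rounding for report-level
comparisons.

## Known limitations

* Per-item mass-change factors other than rice default to 1; users with
  the food-composition mass-change table can supply a named factor
  vector.
* The concentration replicates are summary-faithful reconstructions, not
  laboratory values; analyses sensitive to within-item distribution shape
  (anything beyond mean and range) should not rely on them.
* The monthly tolerable-intake accounting (25 µg/kg/month) is not
  implemented; the weekly threshold is configurable instead.
* The Steel–Dwass implementation is the large-sample approximation;
  p-values for very small strata (n < ~5) are indicative only.
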