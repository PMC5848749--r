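---
title: "Estimating diet cost and guideline accordance from linked diary and price data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diet cost and guideline accordance from linked diary and price data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietcost)
```

## The problem

Food cost is repeatedly cited as a barrier to healthy eating, but individual
dietary surveys do not record what diets cost. `dietcost` implements the
linkage-and-scoring pipeline used to answer that question for UK adults:
multi-day food diaries are joined to consumer scanner-panel prices to give
each person an estimated diet cost, diets are scored against eight SACN
(Scientific Advisory Committee on Nutrition) food and nutrient
recommendations and an eight-component DASH accordance score, and
survey-weighted regression compares the cost of diets that do and do not
meet each target.

Because neither the diary microdata nor the commercial price panel can be
redistributed, the package ships a first-class synthetic-data generator that
emulates both sources with configurable ground truth, so every estimator can
be exercised, and validated by parameter recovery, end to end.

## Price linkage

Scanner transactions record the price paid and unit weight of one purchase
of one generic product ("product sub mark"). The pipeline:

1. converts every transaction to pence per 100 g (`price_per_100g`);
2. takes, per sub mark, the **median** over all recorded per-100 g prices,
   duplicates retained (`submark_median_prices`) — promotional prices are
   part of the distribution;
3. maps each diary food to its matched sub marks (a one-to-many linkage
   key) and takes the **median of the sub-mark medians**
   (`link_food_prices`);
4. converts the purchased price to an as-consumed price by dividing by
   `cooking_fraction * edible_fraction`, where the cooking fraction is the
   cooked/raw weight ratio. Rice that trebles in weight on boiling becomes
   cheaper per 100 g eaten; fish with inedible bones becomes dearer.

Two conventions are deliberately explicit because the procedure is usually
described without them: an even number of prices is summarised by the
midpoint of the two central order statistics, and sub-mark medians are
combined unweighted (not weighted by transaction volume). The matching
itself — deciding which products are "relevant" to a diary food — is a
curated input (the linkage key), not an algorithm; the package takes the
key as data.

## From diaries to person-level metrics

`aggregate_diary` multiplies grams eaten by the as-consumed price per gram
and sums over the diary, dividing by diary days for a daily cost and
rescaling by total energy for the isoenergetic cost:

$$\text{cost}/2000\,\text{kcal} = \frac{\sum_{\text{entries}} g_i\,p_i}
{\sum_{\text{entries}} g_i\,e_i} \times 2000 .$$

Persons with fewer than `min_days` diary days (default 3) are excluded
first, then persons with missing covariates (`apply_exclusions`), with a
balanced accounting log.

**SACN accordance** (`evaluate_sacn`) scores eight targets; the published
guidance defers numeric bounds to the underlying report, so the package
ships standard UK values as editable configuration
(`inst/extdata/sacn_thresholds.yaml`): fruit and vegetables ≥ 5 portions of
80 g/day, oily fish ≥ 20 g/day (one 140 g portion per week averaged over
days, since a 4-day diary cannot observe a literal week), red and processed
meat ≤ 70 g/day, NMES ≤ 11 % of food energy, fat ≤ 35 %, saturated fat
≤ 11 %, fibre ≥ 18 g/day, salt ≤ 6 g/day. All bounds are inclusive: hitting
a target exactly counts as meeting it. Percent-energy denominators use food
energy, with conversion factors 9 kcal/g for fat and 3.75 kcal/g for
carbohydrate-type sugars. The accordance count (0–8) is also banded
0,1,…,5,6–8 for reporting.

**DASH accordance** (`dash_score`) follows the quintile method: each of
eight components — fruit, vegetables, nuts and legumes, whole grains,
low-fat dairy encouraged; red and processed meat, salt, NMES discouraged
(NMES replaces sugar-sweetened beverages as a broader added-sugar measure)
— is energy-adjusted by the **residual method**: intake is regressed on
energy and the residual is recentred at the predicted intake at mean
energy, leaving a quantity uncorrelated with energy with the original mean.
Adjusted intakes are cut into population quintiles scored 1–5, discouraged
components reverse-scored (6 − quintile), and the eight scores summed to a
range of 8–40. The population is then classed into quintiles of the score
itself; because realised score cuts are data-specific, `dash_score` also
accepts fixed cut points.

**Quintile ties.** Tie handling changes scores, so it is pinned down: every
member of a tie group receives the quintile implied by the proportion of
strictly smaller observations, `floor(5 * frac_below) + 1`. An all-equal
vector is therefore assigned quintile 1, and with distinct values group
sizes differ by at most one.

## Survey-weighted estimation

NDNS-style weights correct for sampling and non-response; all means and
regressions are weighted. The workhorse is
`weighted_lsq`: coefficients minimise $\sum_i w_i (y_i - x_i\beta)^2$, and
the variance is the weights-only robust sandwich
$(X'WX)^{-1}\left(\sum_i w_i^2 e_i^2 x_i x_i'\right)(X'WX)^{-1}$ with
normal 95 % intervals (±1.96 SE). The survey's strata and PSU identifiers
are not part of the published design, so this is deliberately a
weights-only approximation to a full design-based estimator; tests verify
its intervals attain nominal coverage under weighted sampling.

Group means (`group_means`) come from a regression on group indicators
without an intercept — the coefficients are weighted group means. Adjusted
means add covariates **centred at their weighted means** (categorical
covariates as indicator contrasts centred at weighted proportions), so the
group coefficients remain interpretable as covariate-adjusted means from a
single fit. Met-vs-not cost differentials (`group_difference`), percent
differences rounded to integer percent (`percent_difference`), a
quintile-trend test treating the DASH quintile index 1–5 as a single
numeric regressor (`linear_trend`), and the unweighted cost–energy
regression (`cost_energy_regression`) complete the estimator set.
`run_pipeline` orchestrates everything and emits the stratum, per
recommendation, accordance-band and DASH-quintile tables with crude and
adjusted models, an exclusion log and a reproducibility manifest; reruns
with the same configuration are byte-identical.

## The synthetic world

`sim_config` fixes the study conditions: ~2083 adults (2045 after
emulated covariate exclusions), 4-day diaries, a 72-food universe across
twelve groups, 2–6 sub marks per food with 20–80 transactions each, 20 % of
transactions at a 25 % promotional discount, log-normal survey weights
(CV 0.5, renormalised to mean 1), ages uniform 19–96, 43.5 % male, four
occupational classes with realistic shares. All randomness flows from one
seed through named substreams, so each generator is independently
reproducible.

Diaries are constructed so that *whether a person meets each target is a
configurable Bernoulli draw*: fruit/vegetable, oily-fish and meat grams are
drawn directly on the intended side of their thresholds, while nutrient
shares (NMES, fat, saturated fat, fibre, salt) are hit by solving a small
linear system for six "lever" groups (confectionery for NMES, butter and
oils for the fat mix, whole grains for fibre, condiments for salt, refined
staples for the energy balance), with paired equation/lever removal when a
lever would go negative. Realised intakes can land on the wrong side of a
threshold in rare corner cases (a few percent for fat shares), so the
ground truth records both intended and realised adherence; realised
adherence is what the premium mechanism and tests key on where it matters.

**Cost structure.** Baseline prices are proportional to energy density — a
single pence-per-kcal rate for all groups, with a within-group price ladder
(evenly spaced log-normal quantiles, energy-weighted mean one) — so an
untilted diet costs the same per 2000 kcal whatever its composition. This
gives the generator an exact null: with zero premiums and zero healthiness
slope, no recommendation carries any cost signal. On top of this,
`healthiness_price_slope` prices healthiness into foods (making
DASH-accordant diets genuinely dearer), and per-recommendation premiums are
injected by **exponential tilting**: within each food group a person
selects foods with probability proportional to `exp(theta * z)` where `z`
is the standardised price per kcal, and `theta` is calibrated per person —
by inverting the ratio of expected diary cost to expected diary energy on a
grid — so that meeting a set of recommendations raises expected cost per
2000 kcal by exactly the sum of the configured premiums. Calibration uses
the *linked* (measured) prices when available, so premiums live on the cost
scale the analysis observes; infeasible premium demands raise a generation
error rather than silently truncating. Because promotional prices pull a
sub mark's median below its regular price, the generator offsets regular
prices so the measured median reproduces the assigned price.

Default premiums (pence per 2000 kcal: fruit and veg +87, oily fish +80,
saturated fat +60, fat +35, NMES +25, salt +15, fibre 0, red/processed meat
−20) and prevalences are set once to resemble the observational pattern in
UK data; the recovery and null experiments use their own controlled
configurations (single premium of +80, or all zero, with slope 0).

**What the generator does not emulate:** day-of-week and seasonal intake
structure, under-reporting bias, household purchase dynamics, correlated
adherence across recommendations, regional or temporal price
stratification, and out-of-home price premiums. Passing recovery tests
therefore show the *estimators* are correct and calibrated under the
assumed measurement model, not that real diary or price data meet those
assumptions.

## Numerical and design choices

- Prices are carried in pence throughout; report tables can be read in
  pounds by dividing by 100. Costs are reported to the penny, percent
  differences to the integer.
- Even-count medians use the central midpoint; quintile ties use the
  strict-fraction rule above.
- The consumed-price adjustment divides by cooking × edible fraction; the
  direction follows from cost per purchased gram of what is actually eaten.
- Degenerate inputs fail loudly with classed conditions: constant energy in
  the residual adjustment, empty sub-mark matches, rank-deficient designs
  (naming the collinear columns), non-positive weights or prices.
- Problem sizes in the test suite were chosen to make Monte-Carlo checks
  sharp at desk scale: 50 replicates of n = 2000 for premium recovery
  against one fixed price panel (fresh survey samples against fixed price
  data mirrors the study design, where one year of price data serves a
  survey sample), 100 replicates of n = 600 for the null size check, and
  200 replicates of n = 300 for interval coverage.

## Known limitations

- The weights-only sandwich understates design effects a stratified,
  clustered survey would have; with real survey design variables a full
  design-based variance should replace it.
- Realised adherence prevalence can drift a point or two from the
  configured values for the solved nutrient shares; ground truth records
  both.
- The DASH quintile classes are computed from the realised score
  distribution unless fixed cuts are supplied, so class boundaries are
  sample-dependent, exactly as in published applications of the score.
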