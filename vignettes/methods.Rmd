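---
title: "Case-crossover analysis of heat illness risk: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-crossover analysis of heat illness risk: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatcco)
```

## The scientific problem

Exertional heat illness during school sports club activities is governed in
Japan by wet-bulb globe temperature (WBGT) thresholds: strenuous exercise
should cease above 28 °C and all exercise above 31 °C. These heat safety
thresholds (HSTs) are population-average guidelines; the risk they gate
varies with the sport, the region, the venue, the season, and how
heat-acclimatized the athletes are. `heatcco` implements a self-controlled
epidemiological pipeline that quantifies that variation from incident
records and hourly WBGT series, and derives threshold adjustments for
strata whose risk is demonstrably elevated.

## Exposure model

WBGT is estimated from standard weather variables with the published
polynomial used by the national monitoring network:

$$\mathrm{WBGT} = 0.735\,T_a + 0.0374\,RH + 0.00292\,T_a RH
  + 7.619\,SR - 4.557\,SR^2 - 0.0572\,WS - 4.064,$$

with $T_a$ air temperature (°C), $RH$ relative humidity (%), $SR$ solar
radiation (kW/m²), $WS$ wind speed (m/s). `estimate_wbgt()` evaluates the
polynomial exactly, with no clamping; unit mix-ups are the realistic
failure mode, so humidity below 1.5 (plausibly a fraction) and radiation
above 2 kW/m² (plausibly W/m²) raise warnings rather than silent rescales.

Three exposure features feed the regression:

* **WBGT-0** — the same-hour WBGT at the incident, either as degrees
  Celsius (one coefficient) or as the five guideline categories with
  boundaries 21/25/28/31 °C. All intervals are left-open right-closed
  (28 °C is category 3), one uniform convention chosen because the
  guideline's own notation writes the upper categories as
  $28 < \mathrm{WBGT} \le 31$.
* **WBGT-1 / WBGT-2** — the previous-day and two-days-prior daily-mean
  WBGT, binned in 1 °C steps with an open-ended reference bin below
  15 °C. The daily mean uses all 24 hourly values of the calendar day;
  the averaging window is not otherwise specified in the guideline
  literature and day-long means are the least arbitrary choice.
* **WBGT-Summer** — a site's May–October mean across study years,
  banded at 18/20/22/24 °C, serving as a climatology /
  heat-acclimatization proxy.

Sparse lag bins are merged into their lower neighbour before dummy coding
(`min_bin_count`, default 30 observations). Without this, extreme bins at
desk-scale case counts regularly contain referents only, the conditional
likelihood is monotone in their coefficient, and the fit has no finite
maximum. Merging sparse categories follows the same convention the
incident data themselves use for rare clubs and locations.

## Matched-set construction

The case-crossover design compares each case's exposure with the same
place and clock time on referent days, cancelling everything constant
within the stratum (school, club, venue, seasonal activity pattern).
Referents are **time-stratified**: every other day in the same calendar
month and year sharing the case's day of week, at the case's hour
(`select_referents()`). A complete month therefore yields exactly 3 or 4
referents, and the selection is symmetric — applying it to a referent
datetime recovers the case's datetime — which makes the conditional
likelihood valid. Incident minutes round to the nearest hour, ties upward.
Records are linked to their municipality's WBGT site and kept when the
haversine (WGS84) distance is at most 10 km, the diagnosis is a
heat-illness label, the circumstance is a club activity, and the aid year
falls in the study window. Sets missing any exposure on any observation
are dropped whole; complete-set analysis is the conservative reading of an
analysis dataset described as "without missing values".

## Conditional logistic regression

With one case per set $s$ and covariates $x_j$, the conditional likelihood
is

$$\log L(\beta) = \sum_s \Big[ x_{\mathrm{case},s}\beta -
  \log \sum_{j \in s} e^{x_j \beta} \Big].$$

`fit_clogit()` maximizes this by Newton–Raphson from $\beta = 0$ with
analytic gradient and Hessian, step-halving to guarantee ascent,
convergence at max-gradient $10^{-8}$ or relative log-likelihood change
$10^{-10}$, and a cap of 50 iterations. Standard errors come from the
inverse observed information; 95% intervals use
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$, so every odds ratio is the
geometric mean of its interval bounds. Degenerate inputs are handled
explicitly: covariates constant within every set are removed (they cancel
exactly — the cancellation is also asserted numerically in the tests), a
singular information matrix triggers one ridge-jittered retry before
erroring, and monotone likelihoods (a perfectly separating column, or a
perfect fit) raise an error naming the offending column rather than
returning a divergent estimate.

Diagnostics (`fit_diagnostics()`) report concordance over within-set
(case, referent) pairs with ties counted one half and a set-clustered
ratio-estimator standard error, the likelihood-ratio / Wald / score
statistics against the null, and variance inflation factors from the
stacked design columns.

## Group-lasso variable selection

`group_lasso_path()` minimizes
$-\tfrac1S \log L(\beta) + \lambda \sum_g \sqrt{p_g}\,\lVert\beta_g\rVert_2$
with one group per categorical block, by FISTA proximal gradient with
block soft-thresholding, backtracking line search, momentum restarts, and
warm starts along a descending grid of 100 log-spaced $\lambda$ values
from $\lambda_{\max} = \max_g \lVert\nabla_g f(0)\rVert / \sqrt{p_g}$ down
to $10^{-4}\lambda_{\max}$. Columns are standardized internally and
coefficients returned on the original scale. Cross-validation assigns
whole matched sets to folds (10 by default) and scores the held-out mean
negative conditional log-likelihood per set.

Two selection rules are exposed. The default picks the CV-error minimum,
which is prediction-optimal but deliberately liberal — it retains any
group whose inclusion does not hurt held-out likelihood, and on data where
all candidate blocks carry some signal it will keep all of them. The
`"1se"` rule (largest $\lambda$ within one standard error of the minimum)
is the standard sparser choice when support recovery matters. Neither rule
is model-selection-consistent; in our seeded selection study the 1-SE rule
recovers both signal blocks essentially always but excludes all pure-noise
blocks in only about three quarters of replicates. This is a property of
CV-tuned lasso selection, not of the optimizer: the $\lambda = 0$ solution
matches the Newton MLE to $10^{-4}$ and the null solution at
$\lambda \ge \lambda_{\max}$ is exactly zero by the KKT condition.

One structural note: attributes copied from the case to its referents
(club, region, month, year, hour, climatology band) are constant within
sets, contribute zero gradient, and therefore can never be selected by a
penalty on the conditional likelihood — only the time-varying exposures
(WBGT-0/1/2) are selectable in this design.

## Stratified comparison and threshold adjustment

`fit_strata()` refits the five-category model within each stratum of a
grouping attribute (reference: WBGT ≤ 21 °C, odds ratio 1). By default the
stratum models carry only the category term: the lag terms are dropped
(they can be retained via the design argument), since per-stratum lag-bin
support is thin and their retention status in the original analysis is not
stated. Categories without estimable contrasts in a stratum are flagged
with a reason and excluded from comparisons.

For every unordered pair of strata, at the two threshold categories
(4: cease strenuous exercise; 5: cease all exercise), `compare_strata()`
computes the Wald statistic on the log odds ratios,
$z = (\log OR_a - \log OR_b)/\sqrt{SE_a^2 + SE_b^2}$, two-sided with the
direction recorded (a one-sided option exists but is off by default, since
the published per-test levels are consistent with two-sided pair counts).
Multiplicity is controlled two ways: Bonferroni at
$\alpha / (\binom{k}{2} \times 2)$ with $k$ counting all strata in the
group (a stratum is removed from $k$ only when it has no estimable
category at all), and Benjamini–Hochberg step-up at a false-discovery rate
of 0.05 over the group family.

`adjust_hst()` implements the one-category rule: any stratum
significantly *higher* than another under Bonferroni at a threshold
category has its thresholds lowered by exactly one category (3 °C):
$28 < \mathrm{WBGT} \le 31$ becomes $25 < \mathrm{WBGT} \le 28$, and
$\mathrm{WBGT} > 31$ becomes $28 < \mathrm{WBGT} \le 31$. Each significant
pair is re-tested with the lowered stratum's odds ratio at its new
(one-lower) category against the other stratum's odds ratio at the
original category — the minimal reading of "lowering eliminates the
significant difference" — and the recommendation reports the worst
post-adjustment p-value per category. If any re-test remains significant
the stratum is flagged "one-category insufficient" rather than silently
assumed healed. Benjamini–Hochberg significance is reported
pre-adjustment only, because a rank-based rule cannot be re-applied
coherently after moving one stratum's category.

## The synthetic-data generator

The real incident data are confidential, so every stage is exercised on
synthetic data with known ground truth.

* `generate_wbgt()` builds hourly series per site as a site offset plus a
  seasonal cosine peaking in early August, a diurnal cosine peaking at
  15:00, and AR(1) noise. The offset is solved so the deterministic
  May–October mean equals the site's configured climatology target, making
  realized summer means unbiased. Defaults: 3 sites spanning the
  climatology bands (17.5/22.5/25 °C), seasonal amplitude 8 °C, diurnal
  3 °C, AR coefficient 0.7, innovation SD 1.2 °C, two years — values in
  the range of Japanese station climate.
* `generate_incidents()` enumerates eligible unit-hours (site × club ×
  April–October, 09:00–18:00, Monday–Saturday), computes event log-odds
  from a per-°C WBGT-0 effect (0.7 by default; a length-5 vector gives
  per-category effects instead), linear-above-15 °C lag effects (+0.06 /
  −0.03 per °C, matching the sign and approximate magnitude of the
  published lag pattern), and club/location offsets, then draws Bernoulli
  events for each of 50 independent exposure units per unit-hour. The
  baseline is calibrated so the expected case count hits its target
  (2,000 by default, within the published stratum-size range). The unit
  multiplier matters: without it the hottest hours saturate, the
  rare-event assumption of the design fails, and recovery of the per-°C
  effect is visibly biased.
* `simulate_matched_sets()` samples matched sets directly from the
  conditional model (case chosen by within-set softmax) — the exact
  distribution the conditional likelihood assumes — giving fast,
  bias-free material for coverage, type-I-error, and selection studies.
* `make_fixture()` registers deterministic fixtures, including
  `"highrisk"`: three strata with category log odds rising 0.7 per
  category, the first stratum shifted up by exactly one category step so
  that its true category-3 odds ratio equals the others' category-4 odds
  ratio — the geometry under which a one-category lowering exactly heals
  the significant difference.

What the generator does *not* emulate: spatial correlation between sites,
weather fronts, holidays and exam periods in the activity calendar,
reporting delays, or events during referent windows (the pipeline, like
the design, assumes referent periods are event-free). Passing tests
therefore validate the statistical machinery under the design's own
assumptions, not the meteorological realism of any particular region.

## Numerical choices and problem sizes

Tolerances: Newton gradient $10^{-8}$ / relative log-likelihood
$10^{-10}$, 50 iterations; proximal gradient relative objective $10^{-8}$
(tightened to $10^{-12}$ when checking the unpenalized limit), 5,000
iterations. The Wald critical value 1.96, the 0.05 family level, the
category boundaries, the 15 °C bin floor and the 10 km linkage radius are
all named configuration (`cc_config()`), not in-code literals.

The test suite runs at deliberately modest sizes: recovery at ~2,000
cases, interval coverage over 100 replicates of 300 sets, type-I error
over 200 replicates, selection over 50 replicates of 500 sets,
family-wise-error of the stratified screen over 200 replicates of four
150-set strata. Statements about frequencies (e.g. "≥ 90% of replicates")
inherit Monte-Carlo margins of a few percentage points at these sizes.
The lag-effect sign-propagation check uses an amplified-contrast scenario
(±0.15 per °C, cool climate): with the default-magnitude lag effects the per-bin
dummies are identified by only ~1,300 distinct site-days regardless of
case count, so the default conditions cannot resolve the sign reliably at
any desk-scale size — an informative limitation of lag-bin designs on
short site networks.

## Known limitations

* The five-category coding needs cases in the reference category; under a
  strong continuous effect (0.7/°C) and ~2,000 cases, category 1 receives
  none, the reference contrast is a monotone likelihood, and the pipeline
  records the separation diagnostic instead of category odds ratios.
  Category-effect scenarios estimate cleanly.
* CV-tuned group-lasso selection is not support-consistent (see above);
  selected-group lists should be read as predictive, not causal.
* Concordance and its clustered standard error are computed over within-
  set pairs only and are not comparable to cohort-study c-statistics.
* The pipeline assumes referent periods are event-free and does not
  correct for the small bias this induces when events are common.
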