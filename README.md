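# heatcco

Case-crossover analysis of exertional heat illness during school sports
club activities, built around wet-bulb globe temperature (WBGT) exposure
and the Japanese sports-guideline heat safety thresholds (HSTs): cease
strenuous exercise when 28 < WBGT ≤ 31 °C, cease all exercise when
WBGT > 31 °C.

The package is for epidemiologists and sports-medicine analysts who have
(or can simulate) incident records with a time and a place, plus hourly
weather or WBGT series from nearby monitoring sites, and who want to ask:
*how does heat-illness risk scale with WBGT, and for which strata — clubs,
regions, venues, months — should the thresholds be lowered?*

## The method

1. **Exposure.** WBGT is estimated from air temperature, relative
   humidity, solar radiation and wind speed with the published polynomial
   `WBGT = 0.735·Ta + 0.0374·RH + 0.00292·Ta·RH + 7.619·SR − 4.557·SR² −
   0.0572·WS − 4.064`, categorized at 21/25/28/31 °C, and summarized into
   previous-day (WBGT-1) and two-days-prior (WBGT-2) daily-mean bins and a
   May–October site climatology (WBGT-Summer).
2. **Design.** Each case is matched to the 3–4 other days in the same
   year-month sharing its day of week, at the same hour (time-stratified
   referent selection), after eligibility filters including a 10 km
   case-to-station linkage radius.
3. **Model.** Conditional logistic regression fitted from the exact
   conditional likelihood `log L = Σ_s [x_case·β − log Σ_j exp(x_j·β)]`
   (Newton–Raphson, analytic derivatives), with Wald odds-ratio intervals
   `exp(β̂ ± 1.96·SE)`; group-lasso selection over a cross-validated λ
   path is available for the candidate-variable screen.
4. **Stratified comparison.** Per-stratum category odds ratios are
   compared pairwise at the two threshold categories with the Wald test on
   log odds ratios under Bonferroni (α / (C(k,2)·2)) and
   Benjamini–Hochberg control, and strata with significantly elevated
   risk receive a one-category (3 °C) threshold-lowering recommendation
   that is re-tested after the shift.
5. **Synthetic data.** A generator with known ground truth (seasonal +
   diurnal + AR(1) WBGT series; rare-event Bernoulli incidents driven by
   WBGT-0/1/2 and stratum offsets) makes the whole pipeline testable
   without confidential records.

## Worked example

```r
library(heatcco)

estimate_wbgt(30, 60, 0.8, 1.0)
#> [1] 28.60752
wbgt_category(28.60752)
#> [1] 4

report <- run_case_crossover(cc_config(seed = 1))
report
#> Case-crossover analysis report
#>   incidents generated: 1990 | eligible: 1990 | matched sets: 1990 | observations: 8872
#>   per-deg-C WBGT-0 log-OR: 0.692 | concordance: 0.807
#>   strata ( club ): 4 | significant pairs (Bonferroni): 0 | HST recommendations: 0
```

The default scenario generates ~2,000 incidents whose true per-°C log
odds ratio is 0.7; the fitted 0.692 (OR ≈ 2.0 per °C) recovers it within
one standard error, and the concordance says the case has the highest
linear predictor in ~81% of within-set pairs. No threshold adjustment is
recommended because the default clubs share the same exposure-response.

An engineered high-risk stratum shows the adjustment rule firing:

```r
d   <- make_fixture("highrisk")       # one stratum shifted up one category
sf  <- fit_strata(d, "stratum")
rec <- adjust_hst(sf, compare_strata(sf))
rec[, c("stratum", "orig_cat4", "adj_cat4", "orig_cat5", "adj_cat5")]
#>   stratum   orig_cat4    adj_cat4 orig_cat5    adj_cat5
#> 1   kyudo 28<WBGT<=31 25<WBGT<=28   WBGT>31 28<WBGT<=31
```

The elevated stratum's thresholds are lowered by exactly one category
(3 °C), and the post-adjustment Wald tests no longer reject.

## Package layout

- `R/wbgt.R` — WBGT estimation, categories, lag bins, climatology
- `R/casecrossover.R` — filters, referent selection, matched sets
- `R/clogit.R` — conditional likelihood, Newton fit, Wald geometry,
  diagnostics
- `R/grouplasso.R` — proximal-gradient group lasso with set-level CV
- `R/strata.R` — stratum odds ratios, pairwise Wald tests, multiplicity,
  HST adjustment
- `R/simulate.R` — WBGT and incident generators, conditional sampler,
  fixtures
- `R/pipeline.R` — configuration, end-to-end run, provenance-stamped CSVs
- `vignettes/methods.Rmd` — models, assumptions, numerical choices,
  limitations
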