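# hppeval

Do heat prevention plans (HPPs) — national heat-health warning systems
and heat action plans — actually reduce heat-related mortality?
Answering this requires separating the effect of a plan's introduction
from underlying temporal trends in heat vulnerability and from
geographic differences in climate and risk. `hppeval` implements, as a
tested and reusable R pipeline, the three-stage multilevel longitudinal
design used in multi-country temperature-mortality epidemiology to make
that separation:

1. **Stage 1 — location-subperiod curves.** For each city and each
   aligned three-year subperiod, a quasi-Poisson time-series regression
   for warm-season (May–September) daily deaths with a distributed lag
   non-linear cross-basis for temperature: quadratic B-spline in the
   exposure dimension (knots at the 50th/90th percentile of the
   location's full-period warm-season temperatures, expressed on the
   percentile scale so curves pool across climates), natural cubic
   spline over lags 0–10 days (knots log-spaced), seasonal spline ×
   year interaction and day-of-week controls. The fitted cross-basis is
   reduced to the overall cumulative exposure-response curve
   \(\log RR(x)\), centred at its minimum-mortality temperature (MMT).
2. **Stage 2 — multilevel meta-regression.** The reduced coefficients
   \(\hat\theta_{ij}\) (4-vectors with known within-unit covariance)
   are pooled in a multivariate mixed-effect meta-regression with fixed
   effects for an HPP indicator and Region × Time trends, and
   city-level random intercepts and time slopes with diagonal
   covariance, fitted by maximum likelihood; the HPP effect is tested
   by likelihood ratio.
3. **Stage 3 — counterfactual attribution.** Best linear unbiased
   predictions (BLUPs) give each city-subperiod curve under a *factual*
   (HPP as observed) and *counterfactual* (HPP forced off) scenario.
   On days above the 95th temperature percentile the attributable
   fraction \((RR-1)/RR\) converts deaths into heat-attributable
   fractions (HAF) and annual rates per 100 000 (HAD); scenario
   contrasts quantify the deaths avoided by the plans, with 95%
   empirical confidence intervals from 1000 Monte-Carlo draws of the
   meta-regression coefficients.

Real multi-city mortality series of this kind are held under
data-sharing agreements, so the package ships a synthetic multi-city
generator (overdispersed counts, lagged non-linear heat effects,
region-specific trends, per-country implementation years, an HPP
catalogue with scores and tercile classes) with known ground truth,
enabling end-to-end parameter-recovery validation. Intended users are
environmental epidemiologists and biostatisticians studying
intervention effectiveness in temperature-mortality data.

## Worked example

A recovery experiment — 30 cities observed 1996–2019, true HPP effect
0.7 (a 30% cut in the above-MMT log-risk slope):

```r
library(hppeval)

res <- recovery_experiment(n_cities = 30, years = c(1996, 2019),
                           hpp_effect = 0.7, n_samples = 250, seed = 1)
res[c("haf_change", "haf_change_ci", "true_haf_change", "lrt_p")]
#> $haf_change
#> [1] -30.2572
#>
#> $haf_change_ci
#> [1] -39.68059 -16.66298
#>
#> $true_haf_change
#> [1] -26.51244
#>
#> $lrt_p
#> [1] 0.002984606
```

The pipeline estimates that HPP implementation cut the
heat-attributable fraction of deaths by 30.3% (95% CI 16.7–39.7%),
against a ground-truth reduction of 26.5%, and the likelihood-ratio
test detects the HPP effect (p ≈ 0.003). For the full object, run the
stages yourself: `run <- run_all(run_config(n_samples = 250, seed = 1),
cohort = build_cohort(truth_params(...)))` — then
`run$attribution$table` holds the per-country/region/class breakdown
with CIs, `run$attribution$trajectories` the per-subperiod HAF under
both scenarios, and `run$rr99` the pooled relative risk at the 99th
percentile per region under both scenarios.

Individual stages are exposed (`first_stage()`,
`assemble_meta_dataset()`, `fit_meta()`, `lrt()`, `blup()`,
`monte_carlo_attribution()`), as are the building blocks
(`cross_basis()`, `reduce_to_overall()`, `find_mmt()`,
`fit_quasipoisson()`, `hpp_indicator()`, `classify_hpp()`).

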