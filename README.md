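# emtdx

Evaluating a primary-tumor marker of epithelial–mesenchymal transition (EMT)
as a **third diagnostic test of cancer-cell detachment**, alongside the two
established tests used in tumor staging: lymph node evaluation (LN) and
radiologic imaging (RI).

The package is aimed at biostatisticians and cancer epidemiologists who have
subject-level data with TNM stage, a continuous marker score (an
immunohistochemistry intensity on the 0–3 scale, e.g. membrane E-cadherin),
and mortality follow-up, and who want to answer two questions:

1. **Diagnostic accuracy.** How sensitive and specific is the dichotomized
   marker for detachment, given that *no* gold standard exists — LN and RI
   are themselves imperfect?
2. **Prediction increment.** Does adding the marker to LN + RI improve
   5-year mortality prediction at the level of individual risk
   classification?

## The models

**Bayesian latent class model.** Detachment is a latent binary state
`D ~ Bernoulli(π)`. Conditional on `D = d` and a shared subject-level random
effect `Z ~ N(0,1)`, test `j` is positive with probability

    P(Y_j = 1 | D = d, Z = z) = Φ(a_dj + c_dj z)

The loading `c_dj` induces conditional dependence (correlated test errors)
within class `d`; marginally over `Z`, test accuracy has the closed form
`Se_j = Φ(a_1j / √(1 + c_1j²))`, `1 − Sp_j = Φ(a_0j / √(1 + c_0j²))`.
Eight dependence structures are fit: fully independent (all `c = 0`), fully
dependent (all free), and six partial models (PDM1–PDM6) constraining the
loadings of one test or one pair of tests to zero. Priors are uniform on
the accuracy scale — LN and RI get informative Se 60–70% / Sp 95–99% from
external literature, the marker and the prevalence are uniform(0, 1) — and a
seeded random-walk Metropolis-within-Gibbs sampler (burn-in 5000, 50,000
retained draws) with a Gauss–Hermite quadrature likelihood produces
posterior medians and 95% credible intervals.

**Risk reclassification.** Cox models (Breslow ties and baseline hazard)
of time to all-cause mortality, censored at 5 years, convert LN/RI (imputed
from TNM stage: local → LN−/RI−, regional → LN+/RI−, distant → RI+ with LN
from N-stage) and the marker into absolute 5-year risks. Models with and
without the marker are compared by censored-outcome c-index, event NRI,
non-event NRI, IDI, risk stratification tables on the 20/30/40% categories,
and a Hosmer–Lemeshow-type reclassification calibration statistic, with
percentile bootstrap CIs (B = 1000, models refit per replicate).

A synthetic-cohort generator (`generate_cohort()`, `cancors_like_preset()`)
emits cohorts from exactly this generative model with known latent truth, so
the full pipeline is testable without any external data.

## Worked example

```r
library(emtdx)

cohort <- generate_cohort(cancors_like_preset(), seed = 42)
#> cohort_table: 188 subjects, marker direction 'epithelial'

counts <- pattern_counts(cohort, cut_point = 0.85)
fit <- fit_latent_class(counts, dependence_spec("fully_independent"),
                        build_priors(),
                        mcmc = list(burn_in = 5000, iterations = 50000, seed = 42))
fit
#> latent class fit: fully_independent (seed 42)
#>    parameter median lower95 upper95   ess acceptance
#> 1 prevalence  0.549   0.462   0.633  9004      0.454
#> 2     se_emt  0.641   0.534   0.747  8572      0.463
#> 3      se_ln  0.692   0.660   0.700  7756      0.404
#> 4      se_ri  0.605   0.600   0.626  7319      0.438
#> 5     sp_emt  0.975   0.903   0.999  8726      0.346
#> 6      sp_ln  0.957   0.950   0.982 10503      0.469
#> 7      sp_ri  0.980   0.954   0.990 17795      0.649
```

The marker's posterior median sensitivity for detachment is 64% (95% CrI
53–75%) at cut point 0.85 in this synthetic cohort; LN and RI posteriors sit
inside their informative prior supports, which is what anchors the labeling
of the latent classes.

```r
pred <- run_prediction_pipeline(run_config(seed = 42, bootstrap_B = 1000))
pred$risk_table
#>        model min max p10 p25 p50 p75 p90 mean sd
#> 1       base  19  46  22  22  42  46  46   34 12
#> 2 continuous  12  60  16  21  32  46  53   34 14
#> 3   cut_0.52  19  52  22  22  39  44  52   34 12
#> 4    cut_0.6  19  53  22  22  37  42  53   34 12
#> 5   cut_0.85  18  52  21  21  33  45  52   34 13

pred$metrics[, c("form", "c_index", "event_nri", "nonevent_nri", "idi",
                 "calibration_p", "reclassified_pct")]
#>         form c_index event_nri nonevent_nri  idi calibration_p reclassified_pct
#> 1 continuous      65     -12.5         35.5 2.42          0.64             38.3
#> 2   cut_0.52      61     -10.9          7.3 0.34          0.83              9.6
#> 3    cut_0.6      62      -9.4          7.3 0.69          0.94              9.0
#> 4   cut_0.85      63     -18.8         13.7 0.84          0.18             23.9
```

Reading the metrics row for the continuous marker: adding it to LN + RI
raises the c-index from 61% (base) to 65%, widens the spread of individual
predicted risks (rows above: base risks concentrate on ≤ 4 values because
stage-imputed LN/RI admit only 4 covariate patterns), moves 36% of 5-year
survivors to a lower risk category net (non-event NRI +35.5) at the cost of
a net 12.5% of decedents also moving down (event NRI −12.5), and improves
the discrimination slope by 2.4 points (IDI). Calibration p-values above
0.05 indicate no evidence of miscalibration.

A full Table-2-style accuracy run across 3 cut points × 8 dependence models
is `run_accuracy_pipeline(run_config())`; `cutpoint_scan()` sweeps every
achievable dichotomization. A command-line wrapper lives in
`inst/cli/emtdx` (subcommands `simulate`, `accuracy`, `predict`, `scan`,
`all`; JSON config via `read_run_config()`).

## Vignette

`vignettes/emt-marker-evaluation.Rmd` documents the model assumptions, every
tunable parameter with its default and rationale, what the synthetic world
does and does not emulate, numerical choices (quadrature order, tie and
boundary conventions, cell merging), and known limitations.
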