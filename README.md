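# saceps

Bayesian estimation of the **survivor average causal effect (SACE)** of a
non-randomized, possibly time-valued treatment on an outcome that is
**censored by death**, combining principal stratification with standard
and generalized propensity scores.  The motivating setting is a clinical
registry of a rapidly fatal disease — e.g., the effect of a palliative
feeding tube (PEG) on BMI one year after the first clinic visit in an
ALS cohort — where patients who die before the landmark have no outcome,
and treatment is taken by sicker patients.

The package is for biostatisticians and epidemiologists analyzing
observational registries with truncation by death: it ingests a
longitudinal visit table, derives the landmark analysis variables,
fits the treatment models, runs the estimator, and ships a synthetic
registry generator so every stage is testable against known truth.

## The model in brief

Each subject has a latent principal stratum determined by potential
survival at the horizon `t°` under treatment and control:

* `LL` alive either way, `LD` alive only if treated,
  `DL` alive only if untreated, `DD` dead either way.

The SACE is `E[Y(1) − Y(0) | G = LL]` — the only stratum where the
outcome exists under both treatments.  Stratum membership follows a
multinomial logit on propensity terms (`π_g ∝ exp(x₂'α_g)`, reference
`DD`); survivors' outcomes are normal within stratum,
`Y | G = g ~ N(x₁,g' η_g, σ²_g)`, where the `LL` design carries the
treatment indicator and, in the time-of-treatment model, the lag from
treatment to the horizon in months, so the effect at lag Δ is
`η_Z + η_T·Δ`.  Confounding is absorbed by the propensity score —
logistic for the binary treatment model, the linear predictor of a Cox
proportional-hazards model for time to treatment (a generalized
propensity score) for the time model — entering both the outcome and
stratum models as polynomial terms (orders 0–3).

Inference is by data augmentation: an I-step imputes each subject's
stratum from its compatible set (each observed group `O(Z,S)` mixes
exactly two strata; one under the monotonicity assumption, which removes
`DL`), and a P-step updates `(η, σ²)` by conjugate Gibbs draws and `α`
by random-walk Metropolis–Hastings.  Defaults: 10,000 iterations, 5,000
burn-in, equal-tailed 95% credible intervals.

## Worked example

A synthetic ALS-like registry with known truth (true SACE at treatment
2.5 BMI units, waning by −0.3 per month of lag), run end to end:

```r
library(saceps)

truth <- als_like_truth()                      # true SACE 2.5, slope -0.3
coh   <- generate_cohort(truth, n = 600, seed = 7)
write.csv(coh$registry, "registry.csv", row.names = FALSE)

records <- load_registry("registry.csv", synthetic_schema())
ex      <- apply_exclusions(records)
rows    <- derive_analysis_rows(ex$records)
sc      <- attach_scores(rows)                 # logistic PS + Cox GPS

cfg   <- sampler_config(seed = 7, model_type = "time", monotonicity = TRUE)
draws <- run_da_mcmc(sc$rows, cfg)
compute_sace(draws)
#>   term      mean       lower      upper significant
#> 1    Z  1.367996  0.09318679 2.66698170        TRUE
#> 2 time -0.112396 -0.29428016 0.07051008       FALSE

effect_curve(draws, delta_grid = c(0, 3, 6, 12))
#>   delta_months       mean       lower    upper
#> 1            0 1.36799573  0.09318679 2.666982
#> 2            3 1.03080759  0.08826743 1.973244
#> 3            6 0.69361945 -0.14581782 1.540651
#> 4           12 0.01924317 -1.41941363 1.490800

naive_analysis(sc$rows, "time", ps_order = 0)[2, ]
#>   term  estimate      lower    upper        se
#> 2    Z 0.4839287 -0.8837715 1.851629 0.6949754
```

Reading the output: the principal-stratification fit finds a positive,
significant effect of treatment at the time of treatment (posterior mean
1.37, 95% CrI 0.09–2.67; the interval covers the generating value 2.5)
that attenuates with the lag from treatment to the landmark, while the
naive survivors-only regression — biased by confounding and by
conditioning on survival — finds no effect (0.48, 95% CI −0.88–1.85).
This is the qualitative pattern the method is designed to produce:
effects recoverable inside the always-survivor stratum that ordinary
survivor analyses miss.

`recovery_experiment()` repeats this across replicates and reports bias,
RMSE and coverage against the truth; `mcmc_diagnostics()` gives
effective sample sizes, split-chain R-hat and acceptance rates;
`balance_table()` checks covariate balance before and after propensity
adjustment; `results_report()` assembles the 2-model × 4-order ×
2-assumption variant grid.

## Package layout

* `R/cohort.R` — registry ingestion, exclusions, landmark derivation,
  normalization, descriptive summaries
* `R/propensity.R` — logistic PS, Cox GPS (Breslow ties), polynomial
  terms, balance diagnostics
* `R/strata.R` — principal strata, observed-group compatibility,
  membership probabilities, stratum-model likelihood
* `R/outcome.R` — per-stratum normal regressions, conjugate priors and
  Gibbs updates
* `R/sampler.R` — the DA-MCMC (I-step / P-step), adaptation,
  diagnostics
* `R/effects.R` — SACE summaries, effect-versus-lag curve, naive
  comparator, variant grid
* `R/synthetic.R` — the ALS-like generator, recovery experiments,
  latent-strata oracle checks
* `vignettes/sace-methods.Rmd` — models, priors, initialization,
  numerical choices, generator design, known limitations
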