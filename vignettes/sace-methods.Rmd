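---
title: "Estimating survivor average causal effects with propensity scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating survivor average causal effects with propensity scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In registries of rapidly fatal diseases such as ALS, a clinical outcome
measured at a landmark time (here: BMI one year after the first clinic
visit) is undefined — not merely missing — for patients who die before
that time.  Comparing treated and untreated *survivors* conditions on a
post-treatment variable and is biased whenever treatment affects
survival; and in an observational registry the treatment (here:
percutaneous endoscopic gastrostomy, a palliative feeding tube) is taken
by sicker patients, so the comparison is confounded as well.

`saceps` addresses both problems jointly:

* **Censoring by death** is handled by principal stratification.  Each
  subject belongs to a latent stratum defined by the pair of potential
  survival statuses at the horizon under treatment and under control:
  LL (alive either way), LD (alive only if treated), DL (alive only if
  untreated), DD (dead either way).  The estimand is the **survivor
  average causal effect (SACE)**: the mean treated-vs-untreated outcome
  difference inside LL, the only stratum in which the outcome exists
  under both treatments.
* **Confounding** is handled by propensity scores used as regression
  adjustments in both the outcome models and the stratum-membership
  model.  For the binary treatment definition this is the classical
  logistic propensity score; for the time-of-treatment definition it is
  a *generalized* propensity score: the linear predictor of a Cox
  proportional-hazards model for time to treatment, which is a balancing
  score for the non-binary exposure.

## Observed data and derived variables

The raw input is a longitudinal table of clinic visits.  For each
subject the package derives, relative to the first visit (baseline):

* `Z` — indicator of treatment on or before the horizon `t°`
  (configurable, default 365 days);
* `T_Z` — day of treatment, and the lag `(t° − T_Z)` converted to months
  at 30.4375 days/month (the conversion is a package convention; effects
  "per month" depend on it);
* `S` — indicator of survival past the horizon;
* `Y` — the outcome at the **latest** visit at or before the horizon
  with a non-missing measurement ("closest to but not past" the horizon;
  the phrase is resolved as latest-not-past, since a nearest-in-absolute
  distance reading would allow post-horizon visits);
* standardized continuous covariates.

Exclusions are applied in a fixed order with first-rule-wins accounting:
(1) no follow-up visit within the horizon; (2) observed survival beyond
five years (1826 days); (3) alive at the horizon but no eligible outcome
measurement.  Subjects under rule 3 are excluded rather than treated as
missing at random.

## The model

Observed groups `O(Z, S)` are mixtures of exactly two strata:

| group | compatible strata | outcome observed |
|-------|-------------------|------------------|
| O(1,1) | LL, LD | yes |
| O(1,0) | DL, DD | no |
| O(0,1) | LL, DL | yes |
| O(0,0) | LD, DD | no |

Under the **monotonicity** assumption (treatment never causes a death
that would not otherwise occur) DL is removed, and the O(1,0) and O(0,1)
groups become deterministic (DD and LL respectively).

Stratum membership follows a multinomial logit on a design `x2`
(intercept plus propensity terms by default; baseline covariates can be
added), with DD as the reference stratum:

$$\Pr(G_i = g \mid x_{2i}) = \frac{\exp(x_{2i}^\top \alpha_g)}
 {\sum_h \exp(x_{2i}^\top \alpha_h)}, \qquad \alpha_{DD} \equiv 0.$$

Outcomes of survivors are normal within stratum,
$Y_i \mid G_i = g \sim N(x_{1,g,i}^\top \eta_g,\ \sigma^2_g)$, with

* LL, binary model: `x1 = [1, Z, PS terms]`;
* LL, time model: `x1 = [1, Z, Z·(months from treatment to horizon), GPS terms]`,
  so the SACE at lag $\Delta$ months is $\eta_Z + \eta_T \Delta$ — an
  effect that is largest immediately after treatment and attenuates
  linearly with the lag;
* LD and DL: `x1 = [1, PS terms]` (their observed members are all
  treated, respectively all untreated, so no treatment column is
  identified);
* DD: no outcome model (its members never yield an outcome).

## Priors

* $\eta_g \sim \mathrm{MVN}(\mu_0, \Sigma_0)$ with $\Sigma_0 = 100 I$
  and $\mu_0 = (\bar y, 0, \dots, 0)$ by default, where $\bar y$ is the
  observed survivor mean outcome.  Centering the intercept at $\bar y$
  matters: a stratum can hold no survivors for stretches of the chain,
  and if its coefficients then revert to a prior centered at zero on the
  outcome scale, its outcome density near the data becomes negligible
  and the stratum can never be repopulated.
* $\sigma^2_g \sim \mathrm{InvGamma}(a_0 = 2,\ b_0 = 4)$: proper and on
  the outcome scale (prior mean 4, infinite variance).  An arbitrarily
  diffuse shape such as 0.01 produces astronomical no-data prior draws
  whose densities underflow, permanently locking the imputation out of
  the stratum.
* $\alpha_g$: independent $N(0, 5^2)$ per coefficient.  A flat prior —
  the natural-looking "non-informative" choice — makes the posterior
  *improper*: as any stratum's coefficients head to $-\infty$ the
  stratum empties and the observed-data likelihood tends to a positive
  constant, so the tail carries infinite mass, and chains eventually
  drift there.  `sampler_config(alpha_prior_sd = Inf)` restores the flat
  target for short exploratory runs.

All hyperparameters are overridable via `prior_spec()` and
`sampler_config()`.

## The data-augmentation sampler

Each iteration alternates:

* **I-step** — each subject's stratum is drawn from its conditional
  membership probabilities: within the compatible set, survivors weight
  the stratum probability $\pi_g$ by the outcome density
  $f_g(Y_i)$; non-survivors use $\pi_g$ alone.  All weights are
  computed in log space.
* **P-step** — conjugate Gibbs draws of each stratum's $(\eta_g,
  \sigma^2_g)$ from the normal/inverse-gamma full conditionals, then one
  Gaussian random-walk Metropolis–Hastings update per non-reference
  $\alpha$ block.

Proposal scales adapt toward 30% acceptance during burn-in
(Robbins–Monro on the log scale, clamped to $[10^{-3}, 5]$ because a
nearly flat block target accepts at any scale) and are frozen afterwards
so the retained chain is Markov.  The default run is 10,000 iterations
with 5,000 burn-in, a single chain; multi-seed replication and
effective-sample-size / split-$\hat R$ diagnostics are available via
`mcmc_diagnostics()`.

**Initialization.**  Non-survivors start uniformly over their compatible
strata.  Survivor groups of at least 10 are split by outcome: the
lowest-outcome fifth of each arm's survivors starts in the arm's frail
mixed stratum (LD for treated, DL for untreated), the rest in LL.  With
a uniform split, every stratum regression initializes at the common
mixture mean and the imputation essentially never discovers a minority
stratum — the standard informed-initialization argument for mixture
fitting.  Outcome coefficients then start at per-stratum OLS values.

## Propensity machinery

The logistic model is fitted by IRLS (`stats::glm.fit`), with explicit
separation and collinearity checks.  The Cox model is fitted by partial
likelihood with Breslow tie handling (`survival::coxph`; registry data
are day-resolution, so ties are routine), and the GPS is the linear
predictor — defined up to an additive constant, which is immaterial
because scores are standardized before use.  Untreated subjects enter
the risk sets censored at the earlier of death and the horizon;
subjects treated after the horizon are censored at the horizon (the
risk-set convention is configurable since either choice is defensible).
Propensity scores enter downstream models as raw polynomials (orders
1–3) of the standardized score; `balance_table()` checks covariate
balance by regressing each covariate on treatment with and without the
score terms.

## The synthetic registry

`als_like_truth()` emulates the gross composition of an ALS clinic
registry; all of its parameters were set once, from published
registry-scale descriptions, and none is derived from any fitted model:

* covariates: age at diagnosis 63 (SD 11.5) years, baseline BMI 25.4
  (5.7), baseline FVC 71 (26) percent predicted, 45% female, 67% spinal
  onset, 19% with a diagnosis-to-first-visit delay over 30 days;
* treatment times from a Weibull proportional-hazards model (shape 1.2,
  increasing hazard) on the covariates, baseline rate calibrated so
  roughly one third of subjects are treated within the first year;
  treated subjects are older, with lower FVC and less spinal onset —
  i.e., sicker, as in the registry;
* strata from a multinomial logit on the covariates **directly** (not on
  any propensity score), so that propensity adjustment in the fitted
  model is a genuine sufficiency claim under test, with intercepts set
  for roughly half the cohort surviving the first year, LL and DD
  dominating, and LD and DL each near 2.5% (under 5%, as described for
  the registry);
* outcomes: LL mean 25 BMI units (residual SD 2) plus covariate effects
  (2.5 per SD of baseline BMI — by one year, progression noise dominates
  the baseline correlation — 0.8 per SD of FVC, −0.4 per SD of age), a
  treatment effect `eta_Z` (default 2.5) and lag slope `eta_T` (default
  −0.3/month); the frail LD stratum centers at 22 and DL at 23.5, both
  with residual SD 2.5.

The generator also lays each cohort out as a visit-level registry file
(3–8 visits per subject, occasional missing measurements, deaths
truncating the visit stream) whose derivation reproduces the generated
`(Z, S, Y)` exactly, so ingestion, exclusions and derivation are
exercised end to end.  It returns the latent strata for oracle tests.

What the generator does **not** emulate: correlated covariates, visit
frequency that depends on disease severity, measurement error in
treatment or death dates, or informative censoring of the outcome among
survivors.  Passing recovery tests therefore demonstrate correctness of
the machinery under the stated data-generating process, not robustness
to those features of real registries.

## Recovery experiments and problem sizes

`recovery_experiment()` repeatedly generates cohorts, runs the full
pipeline (propensity fits, DA-MCMC, SACE summary) and aggregates bias,
RMSE and empirical 95%-credible-interval coverage against the known
truth, alongside the naive survivors-only OLS comparator (both
unadjusted and propensity-adjusted).  The default desk-scale experiment
uses n = 600 subjects, 50 replicates and 2,000/500 iterations — sizes
chosen so a full experiment completes in minutes on one core while the
per-replicate posterior is still well past burn-in (the full-length
10,000/5,000 run is the default everywhere else).  Replicate `r` uses
seed `base + r`.

Under the default truth the unadjusted survivors-only estimator is
biased downward by most of a BMI unit (confounding plus survivor
selection); the propensity-adjusted comparator and the DA estimator
remove the bulk of it, with the DA fit additionally providing the
stratum-level interpretation and credible intervals whose empirical
coverage the experiment verifies.

## Numerical choices

* Probabilities and membership weights in log space with max
  subtraction throughout; softmax reference category fixed at DD.
* Degenerate inputs: constant covariates are rejected at
  standardization; a constant-covariate Cox fit returns zero
  coefficients with a degenerate-fit flag; empty strata draw from their
  priors; non-finite Metropolis–Hastings proposals are rejected.
* Credible intervals are equal-tailed empirical percentiles (type-7
  quantiles); "significant" means the 95% interval excludes 0.
* Variance draws are clamped to $[10^{-12}, 10^{12}]$ to guard against
  gamma underflow at extreme shapes.
* Subject-level random draws are consumed in fixed subject order, so a
  run is bit-reproducible from `sampler_config(seed = )`.

## Known limitations

* **Weak identifiability of minority strata.**  With stratum mean gaps
  comparable to the residual SD, the posterior places substantial mass
  on configurations in which a small stratum (LD or DL) is empty and
  its members are absorbed into LL; the chain then reproduces the
  propensity-adjusted survivors-only estimate.  This is a property of
  the mixture model itself, not of the sampler.  Without monotonicity
  there is additionally a label-degenerate mode in which LL empties
  (treated survivors to LD, untreated survivors to DL) and the SACE is
  informed only by the prior; long four-strata chains can migrate
  there, which is visible as an exploding credible interval and an
  emptied LL count in `strata_counts`.  The monotonicity fit anchors
  untreated survivors to LL and is markedly more stable.
* The propensity scores are estimated once and plugged in; their
  sampling uncertainty is not propagated, and they are not updated
  inside the MCMC (joint updating is known to risk feedback bias).
* The two-point treatment encoding (indicator + linear lag) assumes the
  effect is affine in the lag; time-varying effect models are out of
  scope.
* No sensitivity analysis for unmeasured confounding is provided; the
  ignorability assumption is maintained throughout.
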