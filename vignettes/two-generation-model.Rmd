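---
title: "A joint Bayesian model for two-generation insecticide-stress experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A joint Bayesian model for two-generation insecticide-stress experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific setting

`sublethal` analyses a two-generation split-brood rearing experiment on the
Colorado potato beetle (*Leptinotarsa decemlineata*) in which second-instar
larvae receive a sublethal dose of a pyrethroid insecticide (a stressor, not
a kill agent: 24 h survival is ~95%). The questions are within-generational
(does an individual's own exposure change its survival, development time,
body mass, body composition?) and transgenerational (does the *mother's*
exposure change her offspring's traits, and their tolerance of the same
stressor?).

The split-brood design separates maternal treatment from paternal identity:
each control sire is mated to four dams, two control and two
insecticide-exposed, so maternal-treatment contrasts occur within sire.
Offspring are re-randomized to their own treatment, which makes the
within-by-maternal treatment interaction estimable.

## The joint model

A single joint posterior covers both generations. Eighteen submodels share
an individual-level covariate vocabulary (treatment: control = 0,
insecticide = 1; sex: female = 0, male = 1; maternal 10-day body mass in
mg, uncentred; gen-1 pre-treatment larval mass in mg):

* **Stage-conditional mortality logits.** Survival is modelled per life
  stage (first 24 h, remaining larval period, pupal stage, adult stage),
  each stage conditional on surviving all earlier stages — individuals dead
  earlier are excluded from later submodels, so the stage likelihoods
  factorize. Death is coded 1: a coefficient `b` multiplies the *death*
  odds by `exp(b)` and the *survival* odds by `exp(-b)`. The gen-1 24 h
  submodel additionally carries pre-treatment larval mass; gen-2 survival
  submodels carry maternal treatment, maternal mass and the
  within-by-maternal interaction (except adult survival, where too few
  deaths per treatment combination make the interaction inestimable).
* **Lognormal development time.** Egg-hatch-to-emergence time is analysed
  on the natural-log scale; the gen-2 submodel includes the
  sex-by-maternal-treatment interaction.
* **Normal body masses** at emergence and at fixed adult ages (day 10 in
  gen 1; days 7 and 14 in gen 2), in mg.
* **Beta composition fractions** (relative lipid, water and dry-mass
  content of 14-day gen-2 adults) with a logit link on the mean and a
  precision parameter per trait.

Priors are independent normals: Normal(0, 2.5²) on logit-scale effect
coefficients with Normal(0, 10²) on logit intercepts, Normal(0, 100²) on
normal-family coefficients, Half-Normal(0, 10) on residual SDs and
Gamma(0.01, 0.01) on beta precisions. The scale-2.5 effect prior is the
standard weakly-informative choice for logistic regression, and it
matters here: the gen-2 24 h stage has ~25 deaths in 842 larvae spread
over four treatment cells, and the adult stage a handful, so the
mortality likelihoods are near-separated in some directions. Under a
much wider effect prior the posterior mean runs away from zero in the
separation direction (recovery experiments show biases of 1–2 posterior
SDs on exactly those coefficients); scale 2.5 regularizes them while
staying vague relative to every plausible effect (the largest published
logit effect is ~2.1). Intercepts stay wide because the gen-2 survival
intercepts are genuinely large (≈ −6.7 with the uncentred maternal-mass
term). Normal-family coefficients get scale 100 because the outcomes are
of order 100 mg, so a scale-10 prior would be strongly informative about
an intercept near 120–165 mg. All of these are configurable
(`prior_spec()`), including per-coefficient overrides — which is also the
mechanism for using a first-generation posterior summary as the prior of a
second-generation coefficient (`priors_from_summary()`).

### Model reduction

The full model carries all interactions. After the full fit, every
non-treatment interaction (sex-by-maternal-treatment) whose 95% credible
interval contains zero is removed and the model refit; treatment
interactions (within-by-maternal) are always kept because they are a
primary quantity of interest (`reduce_model()`, `run_fit()`).

## Sampling

`sample_posterior()` runs a blockwise random-walk Metropolis sampler
written in C++: one block per submodel, containing its coefficients and
(for normal and beta families) the log of its scale parameter, updated
jointly. During burn-in each block adapts a full multivariate-normal
proposal from the empirical covariance of its own history (Haario-style),
with a Robbins–Monro global scale steering acceptance to ~0.30; proposals
freeze after burn-in. Joint coefficient+scale blocks and full-covariance
proposals matter here because the uncentred maternal-mass covariate makes
intercepts and mass slopes strongly correlated a posteriori.

Two schedules are built in: the `"study"` preset (2,000,000 burn-in
iterations, 5,000,000 more with every 500th draw kept, a single chain,
posterior sample 10,000) reproduces the original analysis schedule; the
`"desk"` preset (burn-in 20,000; 2,000 draws at thinning 10) is the
default for testing and simulation studies, where each fit takes a few
seconds and mixing diagnostics (`diagnostics()`: autocorrelations,
effective sample size with a flag below ESS 100 — our convention, the
original analysis states no threshold) show ESS in the hundreds to
thousands for every parameter at the study's sample sizes.

Starting values are data-based by default (least squares for normal
families, logit of the outcome mean otherwise): with a 120–165 mg
intercept, starting at the prior mean 0 spends burn-in walking to the
posterior instead of exploring it. `mcmc_config(init = "prior")` restores
prior-mean-with-jitter starts.

### Missing maternal mass and within-chain imputation

Some dams die during the adult stage before the 10-day weighing, so their
mass — a covariate of every gen-2 submodel — is missing for all their
offspring. Such rows are retained and flagged, never dropped. Each sweep,
every missing mass is redrawn by an independence Metropolis step proposing
from the dam's gen-1 predictive (her treatment and sex under the current
mass-model parameters); because the proposal equals the conditional prior,
the acceptance ratio reduces to the likelihood ratio of the offspring rows
the mass enters. The dam's latent mass also contributes a row to the gen-1
mass model, so information flows both between generations and back.
Observed masses are never altered. With the offspring likelihood
uninformative the imputed draws are exactly the gen-1 predictive (this is
a property test).

## The synthetic cohort generator

No raw data are deposited with the original study, so the package pairs
the model with a generator (`simulate_cohort()`) that emulates the
experiment: 245 gen-1 larvae randomized 50:50, 14 control sires × 4 dams
(56 families), 842 gen-2 larvae allocated near-uniformly to families and
re-randomized 50:50. Default generator coefficients are the published
posterior means (`reference_estimates()`, `default_params()`).

Choices the study leaves open, fixed once here:

* **Residual scales and beta precisions** are not reported. Defaults:
  SD 0.05 on log development time (~5% CV, ~1.5 days), 15 mg at emergence,
  20–25 mg at later adult ages (≈12–15% CV, typical for adult beetle mass
  data), and beta precisions 150/200/300 for lipid/water/dry fractions
  (fraction SDs of ~2–3 percentage points).
* **Pre-treatment larval mass**: Normal(4, 1) mg truncated at zero. The
  study reports no larval masses; 4 mg is a realistic second-instar mass,
  and the published mass slope (−0.73 per mg) then spans a meaningful
  survival range.
* **Maternal mass** enters uncentred in mg, consistent with the magnitude
  of the published slopes (~0.01 against masses of 150–180 mg).
* **Sex** is Bernoulli(1/2) independent of treatment; no sex ratio is
  reported.
* **Missingness** is purely stage-conditional: a trait is missing exactly
  when the individual died before its measurement age (sex and development
  time require emergence; day-7/10/14 masses and composition require
  surviving the adult stage). Dams are drawn from females that emerged;
  those that die as adults have missing 10-day mass, which propagates to
  their offspring's covariate and exercises the imputation machinery.
  About 10% of simulated offspring carry a missing maternal mass.
* **Composition weights.** The published water-content formula
  ("lean minus fresh over fresh") is negative as written, and the three
  logit intercepts are not mutually consistent with any exact weight
  identity, so the three fractions are simulated directly from their
  fitted submodels. Fresh/dry/lean weights are derived only from the lipid
  and dry-mass definitions (`dry = drymass_frac * fresh`,
  `lean = dry - lipid_frac * fresh`, with lipid draws conditioned below
  the dry fraction so lean stays positive); the water fraction is stored
  as drawn and no identity is enforced.
* **Boundary shrinkage** for beta outcomes, `(y(n-1)+0.5)/n`
  (`smooth_fractions()`), is applied when data touch 0 or 1. Simulated
  Beta draws are interior almost surely, and applying the map
  unconditionally would inject a small systematic shift (~0.1% toward
  0.5, which at n≈220 is roughly half a posterior SD on the lipid
  intercept), so it is conditional.

A feasibility note: at the study's sizes the mating design needs 28
emerged females per arm out of ~36 expected, so roughly one cohort in ten
cannot be mated and the generator raises an explicit shortfall error with
counts; the recovery driver re-simulates under the next derived seed and
reports how often.

What passing tests on synthetic cohorts do *not* show about real data:
the generator has no family (brood) random effects — matching the
fixed-effects model — no seasonal or cage effects, no measurement error
in masses, and independent composition fractions; real beetles would
violate several of these.

## Numerical choices

* Mortality likelihoods use numerically stable `log(1+exp(eta))`
  evaluation; beta likelihoods clamp the mean into `(1e-12, 1-1e-12)`.
* The lognormal likelihood includes the `-log y` Jacobian so that
  densities are comparable across transforms (a constant for the sampler,
  relevant for model comparison).
* Incremental likelihood-cache updates during imputation are re-anchored
  by a full recomputation every 2,000 iterations.
* `hpd_interval()` is the exact shortest-window scan over order
  statistics (the "shortest interval" definition); Table-style summaries
  default to equal-tail intervals, since that is what 2.5%/97.5% columns
  report, and both kinds are available. A constant sample yields the
  degenerate point interval, flagged.
* The dagger ("moderate effect") flag is our operationalization:
  sign probability in `[0.90, 0.975)` with an interval containing zero;
  the band is configurable.
* Posterior-predictive discrepancies summarize replicate statistics by
  the normal-approximation central 95% band (mean ± 1.96 SD): with the
  conventional 10 replicates an empirical 2.5% quantile is undefined.

## Verification strategy and problem sizes

The test suite checks every likelihood against independent density
oracles (`dbinom`/`dnorm`/`dlnorm`/`dbeta`) to 1e-10; the HPD routine
against an exhaustive window scan; the sampler against 1-D and 2-D grid
quadrature on toy posteriors (moments within 3 Monte-Carlo SEs); the
imputation step against its closed-form predictive distribution; and the
whole pipeline by parameter recovery — 50 cohorts at the study's sizes
(245/842) simulated at the published posterior means, fitted with the
desk schedule, with 95%-interval coverage and bias scored per parameter —
and by posterior-predictive self-consistency over 10 seeds. These sizes
were chosen as the smallest that give the checks real statistical teeth.

## Known limitations

* No random family effects (deliberate: mirrors the original
  fixed-effects model); clustered broods would need an extended model.
* Only maternal mass is imputed; responses are never imputed (excluded
  rows are excluded).
* The adult-stage death indicator is a single flag per stage, so a gen-2
  adult dying between day 7 and day 14 is treated as unmeasured at both
  ages.
* Single-chain defaults match the original schedule; run two chains
  (`n_chains = 2`) for split-chain comparisons when in doubt.
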