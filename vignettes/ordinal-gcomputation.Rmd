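---
title: "Causal g-computation for cross-cultural ordinal survey outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal g-computation for cross-cultural ordinal survey outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ordgcomp)
```

## The scientific question and the estimation problem

The material-insecurity hypothesis of religion predicts that threats to
material well-being — here, worry about household food supply and (on some
readings) lack of exposure to formal secular education — increase an
individual's religious commitment. Testing this with observational
cross-site survey data requires three things that `ordgcomp` packages
together: an explicit causal model whose identification claims can be
machine-checked; an outcome model appropriate for 5-point ordinal
religiosity items collected in culturally heterogeneous sites; and a way to
turn the fitted model into *marginal causal contrasts* rather than
conditional regression coefficients.

## The causal model

The working DAG (`build_study_dag()`) encodes: Sex and Age are exogenous
confounders of everything downstream (edges into Education, FoodInsecurity
and Religiosity); Education affects Children, FoodInsecurity and
Religiosity; Children affect FoodInsecurity and Religiosity; FoodInsecurity
affects Religiosity. For the focal query — the effect of food-insecurity
worry on religiosity — the observed set {Sex, Age, Education, Children}
closes every backdoor path, which `backdoor_valid()` verifies with Pearl's
criterion: no member of the set is a descendant of the exposure, and the
set d-separates exposure from outcome once the exposure's outgoing edges
are removed.

Two deliberately independent d-separation routines are exported —
`d_separated()` (explicit path enumeration with the chain/fork/collider
rules) and `d_separated_moral()` (ancestral moralization plus undirected
connectivity) — and the test suite requires them to agree on every node
pair and every conditioning subset of the working DAG and of randomly
generated DAGs. Path enumeration is exponential, which is irrelevant at
fewer than ten nodes and keeps the implementation auditable.

The unmeasured-confounding scenario that matters scientifically is the
*type* (not amount) of education — religious versus secular schooling.
While education type affects religiosity only, it lies on no backdoor path
for either query and its omission is harmless; if it also caused food
insecurity it would open `FoodInsecurity <- EducationType -> Religiosity`,
which no observed set can block. `build_study_dag(TRUE, FALSE)` and
`build_study_dag(TRUE, TRUE)` encode the two scenarios, and the acceptance
suite asserts the valid/invalid flip. The DAG is data, not code: edge lists
round-trip through a plain-text format (`read_dag()`/`write_dag()`) so
alternative readings — e.g. dropping the Children→Religiosity edge, whose
presence we inferred from the collider-bias discussion rather than an
explicit statement — are testable without touching the package.

## The outcome model

`fit_ordinal()` fits, separately per outcome (ideational and behavioural
commitment), a multilevel cumulative-logit model: the probability of
category *k* is the difference of logistic CDFs at ordered cutpoints
`kappa` minus a linear predictor `xi`. The linear predictor combines
indicator-coded sex and food insecurity with *monotonic* effects of
education, age and children: `mo(x, zeta) = D * sum(zeta[1:x])`, `zeta` a
simplex. The scalar coefficient multiplying `mo` is then the expected
average difference between adjacent predictor levels, and the simplex lets
the data allocate that change unevenly across levels — an extra year of
schooling need not matter equally at year 2 and year 14. An equal simplex
recovers an ordinary linear term, which is what the generator uses as its
default truth.

Priors are the study model's: `Normal(0, 10)` on cutpoints, `Normal(0,
0.5)` on all coefficients, `Dirichlet(2, ..., 2)` on each simplex,
`Exponential(1)` on every varying-effect standard deviation and `LKJ(4)` on
the site-effect correlation matrix. `prior_predictive()` exists to make the
"weakly regularising" claim checkable: prior simulations cover all five
response categories without concentrating on any.

### Design choices that were genuinely open

- **"Random cut-points."** A site-varying full cutpoint vector is not
  identified against a site-varying intercept. We resolve the ambiguity as
  population-level cutpoints plus a varying intercept and varying
  coefficient offsets for all five predictors ("fully varies effects
  across sites"), with one shared 6×6 LKJ-correlated covariance.
- **Simplexes are population-level.** Only the scalar monotonic
  coefficients vary by site — the multilevel default of the monotonic-
  effects framework; site-specific simplexes would be weakly identified at
  a few hundred respondents per site.
- **Age origin.** Ages enter as increments above the observed sample
  minimum (17, the adult cutoff), since the origin is otherwise
  unidentified against the intercept; the increment count is the observed
  range.
- **Sparse increments keep their mass.** Education levels with no
  observations still carry Dirichlet prior mass; no collapsing, so
  counterfactual education grids never step outside the parameter space.
- **Ordering transform.** Cutpoints are sampled on the unconstrained scale
  as (first, log-increments) with the Jacobian included — the standard
  induced-ordering parameterization; results are insensitive to this choice
  because the posterior for four cutpoints at these sample sizes is sharp.

### The sampler

No Stan-family backend exists in the deployment environment, so the
posterior is sampled by a No-U-Turn sampler written for exactly this model
(`src/ordlogit.cpp`): analytic gradients on the unconstrained scale
(ordered, multinomial-logit simplex, log, and tanh/Cholesky-correlation
transforms, each with its Jacobian), slice-based tree doubling with a
divergence threshold of 1000 on the Hamiltonian error, dual-averaging step
size targeting 0.8 acceptance, and windowed diagonal mass-matrix
adaptation. Site effects are non-centred (`u = diag(sigma) L z`,
`z ~ N(0, 1)`), which is what makes the hierarchical geometry tractable.
The gradient is verified against central finite differences in the test
suite — the single most load-bearing test in the package. Default sampler
settings are 4 chains of 1000 warmup + 1000 sampling iterations with a
mandatory seed; chains run sequentially off R's RNG, so a seed fixes every
draw bit-for-bit.

`fit_diagnostics()` reports rank-normalized split R-hat and bulk/tail
effective sample sizes (Geyer initial-monotone autocorrelation sums),
flagging R-hat above 1.01; the pipeline refuses to proceed past a fit whose
monitored parameters exceed the gate unless explicitly overridden.

## G-computation

The three-step procedure is implemented draw-wise, never on summaries:

1. `impute_potential_outcomes()` sets every individual's exposure to each
   grid level (food worry 0/1; education 0, 5, ..., 30 years), holds all
   other covariates as observed, and stores the full category-probability
   vector per posterior draw. We impute *probabilities*, not resampled
   outcomes: both are valid readings of the procedure, and retaining the
   probability vector removes an avoidable Monte Carlo layer.
2. `marginalize()` averages over individuals — within site by default,
   matching the study's per-site trajectory displays, or pooled — and only
   then summarizes across draws (posterior mean, central 95% interval; the
   mass is configurable, the study never states one).
3. `contrast_levels()` differences two levels per draw and summarizes the
   contrast distribution.

Because site-average and draw-summary both act linearly on means, the
per-individual posterior means retained for plotting are the same whichever
order is taken; interval endpoints are not, which is why both operations
work on the draw scale throughout. Counterfactual education values for
individuals in sites with sparse observed ranges use the shared simplex;
the only domain guard is the global 0–30 instrument range.

The estimand note: holding children and food insecurity as observed while
manipulating education makes the education contrast a *direct* (not total)
effect — which is the study's declared estimand, since it conditions on
those variables by design.

## Poststratification

`poststratify()` re-weights the same per-draw stratum-mean probability
vectors by external weights on banded covariates (default 10-year age
bands, 5-year education bands — the same granularity as the counterfactual
education grid). With weights equal to the empirical stratum frequencies it
reproduces `marginalize()` exactly, which is the identity the tests pin at
1e-10. The shipped Denmark-like stratum table
(`inst/extdata/strata_denmark_synthetic.csv`) is synthetic — shaped like a
wealthy ageing population for illustration, not sourced from any census.
Site effects are kept at each individual's own site (the sample's site
composition), since the external table defines no site structure.

## The synthetic-data generator as the stated world

`simulate_population()` draws from structural equations that follow the
working DAG exactly: sex Bernoulli(1/2); age 17 plus a scaled Beta(1.5,
2.5) on 0–60 (median around the late thirties); education Binomial(30)
with a sex- and age-dependent success probability; children Poisson with a
log-rate increasing in age and decreasing in education (capped at the
simplex range); food insecurity Bernoulli with a logit linear in sex, age,
education and children near 50% prevalence; and both ordinal outcomes drawn
independently from the cumulative-logit model at the true monotonic linear
predictor plus a Normal(0, 0.5) site intercept.

Defaults are fixed once, in `scm_params()`: indicator effects
`beta_sex = -0.3`, `beta_m = 0.8`; per-increment monotonic effects
`beta_edu = -0.02`, `beta_age = 0.012`, `beta_children = 0.05` (full-range
effects of about -0.6, +0.7 and +0.75 log-odds — visible but not
caricatural); equal simplexes; cutpoints (-1.5, -0.5, 0.5, 1.5). The
published study does not report its simulation's parameter values, so these
are the package's own stated world; they were chosen for scale
plausibility, not tuned to test outcomes.

What the generator deliberately does *not* emulate: site-specific
demographic profiles (sites differ only through their intercepts), any
cross-outcome correlation (both outcomes share one linear predictor with
independent residual draws — the pipeline fits them separately anyway),
informative missingness (`inject_missingness()` is MCAR only, because the
analysis it exercises is complete-case by design), and recruitment
artefacts. A green recovery test therefore establishes that the estimator
chain is correct *under the model family and MCAR*, not that the model is
robust to misspecification.

`true_marginal_probs()` evaluates the generator's own structural equations
under intervention — no outcome sampling — giving an exact g-formula oracle
against which the posterior contrasts are checked, including under the
latent education-type scenario.

## Numerical choices and degenerate inputs

- Cumulative-logit log-probabilities are computed with `log1p`/`log1pexp`
  stabilized differences; probabilities are floored at 1e-300 in gradient
  denominators.
- Non-finite log posteriors are treated as divergences, never errors, so a
  bad leapfrog step costs one rejected trajectory.
- A simplex of dimension 1 (a predictor with a single increment) has no
  free parameters and `mo` degenerates to the identity on {0, 1}.
- Empty tables yield a log-likelihood of 0; identical contrast levels yield
  an all-zero contrast with a note rather than an error.
- Draw thinning for g-computation (`max_gcomp_draws`) is deterministic
  (evenly spaced), preserving reproducibility.

## Known limitations

- The sampler is specialized to this model family; it is not a general
  PPL, and approximate backends (variational inference) are out of scope.
- Prediction for sites absent from the fit is refused rather than drawn
  from the population distribution of site effects; poststratification to
  a new population reuses sampled sites' effects.
- Mediation decomposition (direct/indirect through food security) and
  sensitivity analyses (E-values) are out of scope, as is any
  Gaussian-process alternative to the monotonic covariate coding.
- With 20 replicate null fits the straddling-rate acceptance check has
  nontrivial Monte Carlo noise; it bounds gross miscalibration, not the
  exact 95% level.
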