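# ordgcomp

Bayesian ordinal g-computation for cross-site survey data.

`ordgcomp` implements a complete causal-inference workflow for a question
from the cultural evolution of religion: does material insecurity — worry
about food, or (lack of) formal education — cause individuals to be more
religious? The data situation it is built for is a multi-site field survey:
~14 culturally diverse sites, a few hundred adults each, two 5-point ordinal
religiosity outcomes (how often a person thinks about a locally relevant
deity; how often they perform activities to appease it), a binary
food-insecurity worry item, years of formal education (0–30), age, sex and
number of children.

The workflow has four stages, each a package module:

1. **Identification** (`causal_dag`, `d_separated`, `backdoor_valid`,
   `enumerate_minimal_adjustment_sets`). The assumed causal structure is a
   small DAG (sex and age confound everything downstream; education affects
   children, food insecurity and religiosity; children affect food
   insecurity and religiosity; food insecurity affects religiosity). The
   package machine-checks the adjustment-set reasoning with two independent
   d-separation implementations (path enumeration and moralization), and
   reproduces the key robustness argument: an *unmeasured* education-type
   variable is harmless while it affects religiosity only, but invalidates
   the observed adjustment set the moment it also causes food insecurity.

2. **Model fitting** (`fit_ordinal`). A multilevel Bayesian cumulative-logit
   model. For individual *i* in site *j* with category probabilities given
   by differences of logistic CDFs at ordered cutpoints `kappa`:

   ```
   Pr(Y_i = k) = logistic(kappa_k - xi_i) - logistic(kappa_{k-1} - xi_i)
   xi_i = a_j + (bS + uS_j) S_i + (bM + uM_j) M_i
        + (bE + uE_j) mo(E_i, zE) + (bA + uA_j) mo(A_i - A_min, zA)
        + (bC + uC_j) mo(C_i, zC)
   ```

   Education, age and children enter *monotonically*: `mo(x, z) = D *
   sum(z[1:x])` with `z` a simplex, so each coefficient is the average
   adjacent-level difference and the data decide the shape of the dose
   response. Sex and food insecurity are indicators. Every coefficient and
   the intercept vary by site with a full covariance structure
   (non-centred). Priors: `kappa ~ Normal(0, 10)`, all `b ~ Normal(0, 0.5)`,
   simplexes `Dirichlet(2, ..., 2)`, varying-effect SDs `Exponential(1)`,
   correlation `LKJ(4)`. Because no probabilistic-programming backend is
   available in the target environment, the package ships its own
   No-U-Turn sampler (Rcpp, analytic gradients, Stan-style warmup
   adaptation), with rank-normalized split R-hat and bulk/tail ESS
   diagnostics (`fit_diagnostics`).

3. **G-computation** (`impute_potential_outcomes`, `marginalize`,
   `contrast_levels`). For each posterior draw and each hypothetical
   exposure level (food worry 0/1; education 0–30 by fives), every
   individual's category-probability vector is imputed with all other
   covariates held as observed, then averaged over the sample (per site or
   pooled) and summarized across draws — the g-formula / standardization
   estimate of the marginal causal effect, with full posterior uncertainty.

4. **Poststratification** (`poststratify`). Re-weights the same
   counterfactual predictions to an external target population given a
   banded stratum-weight table (a synthetic Denmark-like fixture ships in
   `inst/extdata/`).

A structural-equation **synthetic-data generator** (`simulate_population`)
with known ground truth (`true_marginal_probs` is an exact g-formula
oracle) backs the end-to-end recovery tests, and `run_pipeline` /
`ordgcomp_cli` orchestrate everything with complete-case accounting,
config hashing and byte-reproducible outputs.

## Worked example

```r
library(ordgcomp)

## identification: is {Sex, Age, Education, Children} a valid backdoor set?
g <- build_study_dag()
backdoor_valid(g, "FoodInsecurity", "Religiosity",
               c("Sex", "Age", "Education", "Children"))
#> [1] TRUE
backdoor_valid(build_study_dag(TRUE, TRUE), "FoodInsecurity", "Religiosity",
               c("Sex", "Age", "Education", "Children"))
#> [1] FALSE     # unmeasured education type -> food insecurity breaks it

## simulate a survey with a known food-insecurity effect (+0.8 log-odds)
p   <- scm_params(n_sites = 8, n_per_site = 250, seed = 11)
tab <- simulate_population(p)

## fit the multilevel ordered-logit model (reduced chains for the example)
fit <- fit_ordinal(tab, model_spec_from_data(tab, "think_freq"),
                   chains = 2, iter_warmup = 500, iter_sampling = 500,
                   seed = 1)
fit
#> ordgcomp_fit: think_freq on 2000 rows, 8 sites
#>    2 chains x 500 draws; 0 divergent transitions
#>   posterior means: b_S -0.356, b_M 0.808, b_E -0.024, b_A 0.013, b_C 0.088

## g-computation: food worry 0 -> 1, pooled over the sample
po  <- impute_potential_outcomes(fit, tab, exposure_grid("food_insecure"))
ctr <- contrast_levels(po, 0, 1, by_site = FALSE)
ctr[, c("category", "mean", "lower", "upper")]
#>   category        mean       lower       upper
#> 1        1 -0.09166449 -0.11152648 -0.07336829
#> 2        2 -0.06889435 -0.08389806 -0.05418154
#> 3        3 -0.02680385 -0.03716545 -0.01669350
#> 4        4  0.03991153  0.02924207  0.05039779
#> 5        5  0.14745116  0.12067341  0.17670040
```

The contrast rows are the posterior mean (and 95% interval) change in the
probability of each response category when every individual is moved from
"not worried about food" to "worried": the three lowest religiosity
categories lose probability (about 9, 7 and 3 points) and the two highest
gain (about 4 and 15 points) — the imposed positive effect, recovered
marginally. The generator's exact g-formula truth for the same sample, from
`true_marginal_probs`, is (-0.098, -0.061, -0.023, 0.039, 0.143), inside
every interval.

## Layout

- `R/` — modules: DAG (`dag.R`), generator (`simulate.R`), model and priors
  (`model.R`, `fit.R`, `diagnostics.R`), g-computation (`gcomp.R`),
  poststratification (`poststrat.R`), I/O and pipeline (`io.R`,
  `pipeline.R`, `cli.R`)
- `src/ordlogit.cpp` — log posterior, gradients, NUTS
- `vignettes/ordinal-gcomputation.Rmd` — model, assumptions, design choices
- `tests/testthat/` — unit, property and acceptance suites
- `scripts/acceptance.R` — the acceptance report
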