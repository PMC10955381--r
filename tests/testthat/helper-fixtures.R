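# Shared fixtures: tiny toy draws, hand-built fits, random DAGs and the
# memoized recovery fit reused by the acceptance suite (it is the
# expensive object; computing it once keeps the suite inside its budget).

toy_spec <- function(K = 5L, D_edu = 4L, D_age = 5L, D_children = 3L,
                     age_min = 17L, outcome = "think_freq") {
  model_spec(outcome = outcome, K = K, D_edu = D_edu, D_age = D_age,
             D_children = D_children, age_min = age_min)
}

# A deterministic single "posterior draw" for two sites.
toy_draw <- function(spec = toy_spec(),
                     beta = c(S = 0.4, M = 0.8, E = -0.1, A = 0.05, C = 0.2),
                     kappa = c(-1, 0, 1, 2)[seq_len(spec$K - 1L)],
                     sites = c("s1", "s2"), u = NULL) {
  if (is.null(u)) {
    u <- matrix(0, 6L, length(sites),
                dimnames = list(c("Intercept", "S", "M", "E", "A", "C"), sites))
  }
  list(kappa = kappa, beta = beta,
       zeta_E = rep(1 / spec$D_edu, spec$D_edu),
       zeta_A = rep(1 / spec$D_age, spec$D_age),
       zeta_C = rep(1 / spec$D_children, spec$D_children),
       sigma = rep(0.5, 6L), u = u)
}

toy_table <- function(spec = toy_spec(), sites = c("s1", "s2"), n_per = 3L) {
  n <- length(sites) * n_per
  data.frame(site = rep(sites, each = n_per),
             sex = rep_len(c(0L, 1L), n),
             age = spec$age_min + rep_len(c(0L, 2L, spec$D_age), n),
             education = rep_len(c(0L, 1L, spec$D_edu), n),
             children = rep_len(c(0L, 1L, spec$D_children), n),
             food_insecure = rep_len(c(0L, 1L), n),
             think_freq = rep_len(seq_len(spec$K), n),
             ritual_freq = rep_len(rev(seq_len(spec$K)), n),
             stringsAsFactors = FALSE)
}

# Wrap a list of draw-lists into an `ordgcomp_fit`-shaped object so the
# g-computation path can be exercised against hand-computable inputs.
make_fake_fit <- function(draws, spec, site_names) {
  pn <- ordgcomp:::constrained_names(spec, site_names)
  arr <- array(NA_real_, c(length(draws), 1L, length(pn) + 1L),
               dimnames = list(NULL, "chain1", c(pn, "lp__")))
  for (s in seq_along(draws)) {
    d <- draws[[s]]
    v <- c(d$kappa, d$beta, d$zeta_E, d$zeta_A, d$zeta_C, d$sigma,
           rep(0, 15L), as.vector(d$u), 0)
    arr[s, 1L, ] <- v
  }
  structure(list(draws = arr, spec = spec, site_names = site_names,
                 n_obs = NA_integer_, chains = 1L, seed = 0L,
                 iter_warmup = 0L, iter_sampling = length(draws),
                 divergent = matrix(0L, length(draws), 1L),
                 treedepth = matrix(1L, length(draws), 1L),
                 energy = matrix(0, length(draws), 1L),
                 accept = matrix(1, length(draws), 1L), step_size = 0.1),
            class = "ordgcomp_fit")
}

# Random DAG on `n` nodes: edges only from lower to higher topological
# index, each present with probability p.
random_dag <- function(n, p = 0.4) {
  nodes <- LETTERS[seq_len(n)]
  edges <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (stats::runif(1) < p) edges <- rbind(edges, c(nodes[i], nodes[j]))
  }
  if (is.null(edges)) {
    causal_dag(matrix(character(), ncol = 2L), nodes = nodes)
  } else {
    causal_dag(edges, nodes = nodes)
  }
}

all_subsets <- function(x) {
  out <- list(character(0))
  for (v in x) out <- c(out, lapply(out, c, v))
  out
}

# --- memoized fits (shared across test files) ---
.fit_cache <- new.env(parent = emptyenv())

# The recovery fit of the acceptance suite: data simulated from the model
# family at the generator defaults (8 sites x 250), fitted at the stated
# 4 chains x 1000 + 1000.
recovery_params <- function() scm_params(n_sites = 8L, n_per_site = 250L, seed = 11L)

recovery_fit <- function() {
  if (is.null(.fit_cache$recovery)) {
    p <- recovery_params()
    tab <- simulate_population(p)
    fit <- fit_ordinal(tab, model_spec_from_data(tab, "think_freq"),
                       chains = 4L, iter_warmup = 1000L, iter_sampling = 1000L,
                       seed = 20260901L)
    .fit_cache$recovery <- list(params = p, table = tab, fit = fit)
  }
  .fit_cache$recovery
}

# A small cheap real fit for unit tests that need genuine posterior draws.
small_fit <- function() {
  if (is.null(.fit_cache$small)) {
    p <- scm_params(n_sites = 3L, n_per_site = 60L, seed = 5L)
    tab <- simulate_population(p)
    fit <- fit_ordinal(tab, model_spec_from_data(tab, "think_freq"),
                       chains = 2L, iter_warmup = 200L, iter_sampling = 200L,
                       seed = 99L)
    .fit_cache$small <- list(params = p, table = tab, fit = fit)
  }
  .fit_cache$small
}
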