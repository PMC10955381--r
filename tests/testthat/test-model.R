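# true-parameter draw in linear_predictor() format, from generator params
draw_from_scm <- function(p, site_effects) {
  u <- matrix(0, 6L, length(site_effects),
              dimnames = list(c("Intercept", "S", "M", "E", "A", "C"),
                              names(site_effects)))
  u[1L, ] <- site_effects
  list(kappa = p$cutpoints,
       beta = c(S = p$beta_sex_on_y, M = p$beta_m_on_y, E = p$beta_edu_on_y,
                A = p$beta_age_on_y, C = p$beta_children_on_y),
       zeta_E = p$edu_simplex, zeta_A = p$age_simplex,
       zeta_C = p$children_simplex, sigma = rep(0, 6L), u = u)
}

scm_spec <- function(p, outcome = "think_freq") {
  model_spec(outcome = outcome, D_edu = length(p$edu_simplex),
             D_age = length(p$age_simplex),
             D_children = length(p$children_simplex), age_min = 17L)
}

test_that("mo matches its defining sum and is monotone", {
  expect_identical(mo(0, c(0.5, 0.5)), 0)
  expect_equal(mo(2, c(0.25, 0.25, 0.25, 0.25)), 2)
  expect_equal(mo(2, c(0.5, 0.3, 0.1, 0.1)), 3.2)
  expect_error(mo(5, c(0.5, 0.5)), "lie in")
  expect_error(mo(1, c(0.7, 0.7)), "simplex")
  set.seed(42)
  for (rep in 1:50) {
    D <- sample(2:12, 1L)
    z <- as.vector(ordgcomp:::rdirichlet(1L, 0.7, D))
    vals <- mo(0:D, z)
    expect_true(all(diff(vals) >= -1e-12))
    expect_equal(vals[D + 1L], D)                 # mo(D) = D exactly
    x <- sample(0:D, 1L)
    expect_equal(vals[x + 1L], D * sum(z[seq_len(x)]))
  }
})

test_that("category_probs matches logistic-CDF differencing", {
  expect_equal(drop(category_probs(0, 0)), c(k1 = 0.5, k2 = 0.5))
  p <- drop(category_probs(0, c(-1, 0, 1, 2)))
  expect_equal(unname(p), c(0.2689, 0.2311, 0.2311, 0.1498, 0.1192),
               tolerance = 1e-3)
  # limits
  expect_equal(unname(drop(category_probs(50, c(-1, 0, 1, 2)))),
               c(0, 0, 0, 0, 1), tolerance = 1e-12)
  expect_error(category_probs(0, c(1, 0)), "increasing")
  # shift invariance: adding c to xi and kappa leaves probabilities fixed
  set.seed(7)
  for (rep in 1:20) {
    k <- sort(stats::rnorm(4, 0, 2))
    xi <- stats::rnorm(3)
    cshift <- stats::rnorm(1)
    expect_equal(category_probs(xi + cshift, k + cshift),
                 category_probs(xi, k), tolerance = 1e-12)
    expect_equal(rowSums(category_probs(xi, k)), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("linear_predictor follows the model equation", {
  spec <- toy_spec()
  d <- toy_draw(spec)
  ref <- data.frame(site = "s1", sex = 0L, age = 17L, education = 0L,
                    children = 0L, food_insecure = 0L, think_freq = 1L,
                    ritual_freq = 1L)
  expect_identical(linear_predictor(ref, d, spec), 0)  # reference point
  # indicator contrast: M 0 -> 1 moves xi by exactly beta_M + site offset
  d2 <- d; d2$u["M", "s1"] <- 0.15
  ref1 <- ref; ref1$food_insecure <- 1L
  expect_equal(linear_predictor(ref1, d2, spec) - linear_predictor(ref, d2, spec),
               d2$beta[["M"]] + 0.15)
  # hand-computed oracle on a nontrivial row (independent arithmetic)
  row <- data.frame(site = "s2", sex = 1L, age = 20L, education = 3L,
                    children = 2L, food_insecure = 1L, think_freq = 2L,
                    ritual_freq = 2L)
  u <- matrix(0.1 * (1:12), 6L, 2L,
              dimnames = list(c("Intercept", "S", "M", "E", "A", "C"),
                              c("s1", "s2")))
  d3 <- toy_draw(spec, u = u)
  d3$zeta_E <- c(0.4, 0.3, 0.2, 0.1)
  d3$zeta_A <- c(0.5, 0.2, 0.1, 0.1, 0.1)
  d3$zeta_C <- c(0.6, 0.3, 0.1)
  by_hand <- 0.7 +                      # site intercept
    (0.4 + 0.8) * 1 +                   # sex
    (0.8 + 0.9) * 1 +                   # food insecurity
    (-0.1 + 1.0) * 4 * (0.4 + 0.3 + 0.2) +  # education mo
    (0.05 + 1.1) * 5 * (0.5 + 0.2 + 0.1) +  # age mo at A - 17 = 3
    (0.2 + 1.2) * 3 * (0.6 + 0.3)       # children mo
  expect_equal(linear_predictor(row, d3, spec), by_hand)
  # unknown site and incomplete rows are errors
  bad <- row; bad$site <- "elsewhere"
  expect_error(linear_predictor(bad, d3, spec), "unknown site")
  nas <- row; nas$children <- NA_integer_
  expect_error(linear_predictor(nas, d3, spec), "complete-case")
})

test_that("log_likelihood sums per-row log probabilities", {
  spec <- toy_spec(K = 2L)
  d <- toy_draw(spec, kappa = 0)
  ref <- data.frame(site = "s1", sex = 0L, age = 17L, education = 0L,
                    children = 0L, food_insecure = 0L, think_freq = 1L,
                    ritual_freq = 1L)
  expect_equal(log_likelihood(ref, d, spec), log(0.5))
  expect_identical(log_likelihood(ref[0, ], d, spec), 0)
  tab <- toy_table(spec)
  tab$think_freq <- rep_len(1:2, nrow(tab))
  per_row <- vapply(seq_len(nrow(tab)), function(i) {
    log_likelihood(tab[i, ], d, spec)
  }, numeric(1))
  expect_equal(log_likelihood(tab, d, spec), sum(per_row))
  bad <- tab; bad$think_freq[1] <- 7L
  expect_error(log_likelihood(bad, d, spec), "outside 1..K")
})

test_that("likelihood is maximized at the generating parameters vs decoys", {
  p <- scm_params(n_sites = 6L, n_per_site = 300L, seed = 31L)
  tab <- simulate_population(p)
  spec <- scm_spec(p)
  truth <- draw_from_scm(p, attr(tab, "site_effects"))
  ll_true <- log_likelihood(tab, truth, spec)
  set.seed(99)
  for (rep in 1:10) {
    decoy <- truth
    perm <- sample(5L)
    while (all(perm == 1:5)) perm <- sample(5L)
    decoy$beta <- stats::setNames(truth$beta[perm], names(truth$beta))
    expect_lt(log_likelihood(tab, decoy, spec), ll_true)
  }
  flipped <- truth
  flipped$beta <- -truth$beta
  expect_lt(log_likelihood(tab, flipped, spec), ll_true)
})

test_that("prior predictive draws match the stated priors", {
  p <- scm_params(n_sites = 2L, n_per_site = 50L, seed = 3L)
  tab <- simulate_population(p)
  spec <- model_spec(outcome = "think_freq", D_edu = 30L, D_age = 60L,
                     D_children = 15L)
  pp <- prior_predictive(spec, tab, n_draws = 400L, seed = 8L)
  # simplex prior mean is uniform
  zE <- t(vapply(pp$parameters, `[[`, numeric(spec$D_edu), "zeta_E"))
  expect_equal(colMeans(zE), rep(1 / spec$D_edu, spec$D_edu), tolerance = 0.15)
  # coefficient prior SD is 0.5
  bM <- vapply(pp$parameters, function(d) d$beta[["M"]], numeric(1))
  expect_equal(stats::sd(bM), 0.5, tolerance = 0.12)
  expect_equal(mean(bM), 0, tolerance = 0.1)
  # cutpoints ordered in every draw
  expect_true(all(vapply(pp$parameters, function(d) !is.unsorted(d$kappa),
                         logical(1))))
  # outcomes cover all categories without degenerate concentration
  freq <- tabulate(pp$outcomes, nbins = 5L) / length(pp$outcomes)
  expect_true(all(freq > 0.02))
  expect_true(max(freq) < 0.9)
})
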