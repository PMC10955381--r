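test_that("exposure_grid validates levels", {
  expect_equal(exposure_grid("education")$levels, seq(0, 30, 5))
  expect_equal(exposure_grid("food_insecure")$levels, c(0, 1))
  expect_error(exposure_grid("education", c(0, 35)), "domain")
  expect_error(exposure_grid("food_insecure", c(1, 0)), "increasing")
  expect_error(exposure_grid("food_insecure", 1), "increasing")
})

test_that("imputation is consistent with in-sample fitted probabilities", {
  spec <- toy_spec()
  tab <- toy_table(spec)
  d <- toy_draw(spec, u = matrix(c(0.3, rep(0.1, 5), -0.2, rep(0, 5)), 6L, 2L,
                                 dimnames = list(NULL, c("s1", "s2"))))
  fit <- make_fake_fit(list(d), spec, c("s1", "s2"))
  po <- impute_potential_outcomes(fit, tab, exposure_grid("food_insecure"))
  expect_identical(dim(po), c(1L, nrow(tab), 2L, 5L))
  # at each row's observed exposure the imputed vector equals the fitted one
  fitted <- category_probs(linear_predictor(tab, d, spec), d$kappa)
  for (i in seq_len(nrow(tab))) {
    li <- match(tab$food_insecure[i], c(0, 1))
    expect_equal(po[1L, i, li, ], unname(fitted[i, ]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # hand oracle at the counterfactual level for one individual
  t1 <- tab[3L, ]; t1$food_insecure <- 1L
  expect_equal(po[1L, 3L, 2L, ],
               drop(category_probs(linear_predictor(t1, d, spec), d$kappa)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("null coefficients give level-invariant imputations", {
  spec <- toy_spec()
  tab <- toy_table(spec)
  d <- toy_draw(spec, beta = c(S = 0, M = 0, E = 0, A = 0, C = 0))
  fit <- make_fake_fit(list(d), spec, c("s1", "s2"))
  po <- impute_potential_outcomes(fit, tab, exposure_grid("education", c(0, 2, 4)))
  for (li in 2:3) {
    expect_equal(po[, , li, ], po[, , 1L, ], tolerance = 1e-12)
  }
})

test_that("marginalize averages individuals then summarizes draws", {
  spec <- toy_spec()
  set.seed(21)
  draws <- lapply(1:30, function(s) {
    d <- toy_draw(spec)
    d$beta["M"] <- stats::rnorm(1, 0.8, 0.2)
    d$u[1, ] <- stats::rnorm(2, 0, 0.3)
    d
  })
  fit <- make_fake_fit(draws, spec, c("s1", "s2"))
  tab <- toy_table(spec, n_per = 4L)
  po <- impute_potential_outcomes(fit, tab, exposure_grid("food_insecure"))
  # single individual: marginal equals that individual's own summary
  po1 <- impute_potential_outcomes(fit, tab[1L, ], exposure_grid("food_insecure"))
  m1 <- marginalize(po1, by_site = TRUE)
  expect_equal(m1$mean[m1$level == 0],
               colMeans(po1[, 1L, 1L, , drop = TRUE]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # two identical individuals: marginal equals either one's summary
  tab2 <- tab[c(1L, 1L), ]
  po2 <- impute_potential_outcomes(fit, tab2, exposure_grid("food_insecure"))
  m2 <- marginalize(po2, by_site = TRUE)
  expect_equal(m2$mean, m1$mean, tolerance = 1e-12)
  expect_equal(m2$lower, m1$lower, tolerance = 1e-12)
  # posterior-mean category probabilities sum to 1 per (unit, level)
  msum <- stats::aggregate(mean ~ site + level, data = marginalize(po), FUN = sum)
  expect_equal(msum$mean, rep(1, nrow(msum)), tolerance = 1e-6)
  # interval brackets the mean
  mm <- marginalize(po)
  expect_true(all(mm$lower <= mm$mean + 1e-12 & mm$mean <= mm$upper + 1e-12))
  # per-individual means retained with the right shape
  ind <- attr(mm, "individual_means")
  expect_identical(dim(ind), c(nrow(tab), 2L, 5L))
})

test_that("marginalize matches closed-form standardization on a discrete toy", {
  # one site, one binary covariate (sex), saturated truth:
  # P(Y = k | a, x) known exactly, P(x) empirical
  spec <- toy_spec()
  d <- toy_draw(spec, beta = c(S = 0.7, M = 1.1, E = 0, A = 0, C = 0),
                sites = "s1",
                u = matrix(0, 6L, 1L, dimnames = list(NULL, "s1")))
  fit <- make_fake_fit(list(d), spec, "s1")
  n_x1 <- 3L; n_x0 <- 7L
  tab <- data.frame(site = "s1", sex = rep(c(1L, 0L), c(n_x1, n_x0)),
                    age = 17L, education = 0L, children = 0L,
                    food_insecure = rep_len(c(0L, 1L), 10L),
                    think_freq = 1L, ritual_freq = 1L)
  po <- impute_potential_outcomes(fit, tab, exposure_grid("food_insecure"))
  marg <- marginalize(po, by_site = FALSE)
  for (a in c(0, 1)) {
    p_x1 <- drop(category_probs(d$beta[["S"]] + d$beta[["M"]] * a, d$kappa))
    p_x0 <- drop(category_probs(d$beta[["M"]] * a, d$kappa))
    std <- (n_x1 * p_x1 + n_x0 * p_x0) / 10  # sum_x P(Y|a,x) P(x)
    got <- marg$mean[marg$level == a]
    expect_equal(got, unname(std), tolerance = 1e-8)
  }
})

test_that("contrasts are draw-wise, antisymmetric and probability-conserving", {
  spec <- toy_spec()
  set.seed(33)
  draws <- lapply(1:40, function(s) {
    d <- toy_draw(spec)
    d$beta["M"] <- stats::rnorm(1, 0.9, 0.3)
    d
  })
  fit <- make_fake_fit(draws, spec, c("s1", "s2"))
  tab <- toy_table(spec, n_per = 5L)
  po <- impute_potential_outcomes(fit, tab, exposure_grid("food_insecure"))
  ctr <- contrast_levels(po, 0, 1)
  # positive food-insecurity effect: highest category up, lowest down
  expect_true(all(ctr$mean[ctr$category == 5] > 0))
  expect_true(all(ctr$mean[ctr$category == 1] < 0))
  # contrasts over the 5 categories sum to 0 per site
  s <- stats::aggregate(mean ~ site, data = ctr, FUN = sum)
  expect_equal(s$mean, rep(0, nrow(s)), tolerance = 1e-6)
  # antisymmetry
  rev <- contrast_levels(po, 1, 0)
  expect_equal(rev$mean, -ctr$mean, tolerance = 1e-12)
  expect_equal(rev$lower, -ctr$upper, tolerance = 1e-12)
  # identical levels: zero vector with note
  z <- contrast_levels(po, 1, 1)
  expect_true(all(z$mean == 0))
  expect_match(attr(z, "note"), "identical")
  expect_error(contrast_levels(po, 0, 0.5), "grid")
})
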