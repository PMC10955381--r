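make_po_fixture <- function(n_draws = 25L, n_per = 6L) {
  spec <- toy_spec()
  set.seed(55)
  draws <- lapply(seq_len(n_draws), function(s) {
    d <- toy_draw(spec)
    d$beta["M"] <- stats::rnorm(1, 0.8, 0.2)
    d$beta["S"] <- stats::rnorm(1, -0.3, 0.2)
    d
  })
  fit <- make_fake_fit(draws, spec, c("s1", "s2"))
  tab <- toy_table(spec, n_per = n_per)
  tab$age <- spec$age_min + rep_len(c(0L, 3L, 5L), nrow(tab))
  po <- impute_potential_outcomes(fit, tab, exposure_grid("food_insecure"))
  list(po = po, tab = tab, spec = spec)
}

test_that("strata_table validates and normalizes weights", {
  df <- data.frame(sex = c(0, 1), weight = c(2, 6))
  st <- strata_table(df)
  expect_equal(st$weight, c(0.25, 0.75))
  expect_error(strata_table(data.frame(sex = 1)), "weight")
  expect_error(strata_table(data.frame(color = 1, weight = 1)), "unknown stratum")
  expect_error(strata_table(data.frame(sex = c(1, 1), weight = c(1, 1))),
               "duplicated")
  expect_error(strata_table(data.frame(sex = 0:1, weight = c(-1, 2))),
               "nonnegative")
})

test_that("empirical-frequency weights reproduce the pooled marginal", {
  fx <- make_po_fixture()
  freq <- table(fx$tab$sex) / nrow(fx$tab)
  st <- strata_table(data.frame(sex = as.integer(names(freq)),
                                weight = as.vector(freq)))
  ps <- poststratify(fx$po, st, fx$tab)
  marg <- marginalize(fx$po, by_site = FALSE)
  expect_equal(ps$mean, marg$mean, tolerance = 1e-10)
  expect_equal(ps$lower, marg$lower, tolerance = 1e-10)
  expect_equal(ps$upper, marg$upper, tolerance = 1e-10)
})

test_that("degenerate and hand-set weights match manual arithmetic", {
  fx <- make_po_fixture()
  sex <- fx$tab$sex
  # all weight on one stratum -> that stratum's mean vector
  st1 <- strata_table(data.frame(sex = c(0L, 1L), weight = c(1, 0)))
  ps1 <- poststratify(fx$po, st1, fx$tab)
  own <- apply(fx$po[, sex == 0L, , , drop = FALSE], c(1L, 3L, 4L), mean)
  expect_equal(ps1$mean[ps1$level == 0 & ps1$category == 3],
               mean(own[, 1L, 3L]), tolerance = 1e-12)
  # two strata, weights (0.3, 0.7): weighted mean by hand, per draw
  st2 <- strata_table(data.frame(sex = c(0L, 1L), weight = c(0.3, 0.7)))
  ps2 <- poststratify(fx$po, st2, fx$tab)
  m0 <- apply(fx$po[, sex == 0L, , , drop = FALSE], c(1L, 3L, 4L), mean)
  m1 <- apply(fx$po[, sex == 1L, , , drop = FALSE], c(1L, 3L, 4L), mean)
  byhand <- 0.3 * m0 + 0.7 * m1
  for (li in 1:2) for (k in 1:5) {
    v <- byhand[, li, k]
    got <- ps2[ps2$level == c(0, 1)[li] & ps2$category == k, ]
    expect_equal(got$mean, mean(v), tolerance = 1e-12)
    expect_equal(got$lower, stats::quantile(v, 0.025, names = FALSE),
                 tolerance = 1e-12)
  }
  # linearity in weights: poststratify(w) is the convex combination
  wa <- strata_table(data.frame(sex = c(0L, 1L), weight = c(0.5, 0.5)))
  psa <- poststratify(fx$po, wa, fx$tab)
  expect_equal(psa$mean, (0.5 * ps1$mean +
                            0.5 * poststratify(fx$po,
                                               strata_table(data.frame(sex = c(0L, 1L),
                                                                       weight = c(0, 1))),
                                               fx$tab)$mean),
               tolerance = 1e-10)
  # probabilities sum to 1 per level
  s <- stats::aggregate(mean ~ level, data = ps2, FUN = sum)
  expect_equal(s$mean, rep(1, 2), tolerance = 1e-8)
})

test_that("stratum assignment errors are informative", {
  fx <- make_po_fixture()
  # a stratum table that misses some individuals
  st <- strata_table(data.frame(age_band = "[17,27)", weight = 1))
  tab_hi <- fx$tab
  tab_hi$age[1L] <- 40L
  po <- fx$po
  expect_error(poststratify(po, st, tab_hi), "matching no stratum")
  # empty stratum with positive weight
  st2 <- strata_table(data.frame(sex = c(0L, 1L, 1L),
                                 age_band = c("[17,27)", "[17,27)", "[67,Inf)"),
                                 weight = c(0.4, 0.4, 0.2)))
  expect_error(poststratify(fx$po, st2, fx$tab), "empty stratum")
})

test_that("the packaged Denmark-like fixture poststratifies a synthetic sample", {
  path <- system.file("extdata", "strata_denmark_synthetic.csv",
                      package = "ordgcomp")
  st <- read_strata_csv(path)
  expect_equal(sum(st$weight), 1, tolerance = 1e-9)
  p <- scm_params(n_sites = 2L, n_per_site = 80L, seed = 91L)
  tab <- simulate_population(p)
  spec <- toy_spec(D_edu = 30L, D_age = 60L, D_children = 15L)
  d <- toy_draw(spec, sites = sort(unique(tab$site)),
                u = matrix(0, 6L, 2L, dimnames = list(NULL, sort(unique(tab$site)))))
  fit <- make_fake_fit(list(d), spec, sort(unique(tab$site)))
  po <- impute_potential_outcomes(fit, tab, exposure_grid("food_insecure"))
  ps <- poststratify(po, st, tab,
                     bands = strata_bands(age_breaks = c(17, 27, 37, 47, 57, Inf)))
  s <- stats::aggregate(mean ~ level, data = ps, FUN = sum)
  expect_equal(s$mean, rep(1, 2), tolerance = 1e-8)
  # reweighting moved the estimate away from the sample marginal
  marg <- marginalize(po, by_site = FALSE)
  expect_false(isTRUE(all.equal(ps$mean, marg$mean, tolerance = 1e-6)))
})
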