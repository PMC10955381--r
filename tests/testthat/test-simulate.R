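test_that("scm_params validates its invariants", {
  expect_s3_class(scm_params(), "scm_params")
  expect_error(scm_params(n_sites = 0), ">= 1")
  expect_error(scm_params(edu_simplex = c(0.5, 0.4)), "sum to 1")
  expect_error(scm_params(cutpoints = c(0, 0, 1, 2)), "increasing")
})

test_that("simulate_population has the right frame and is deterministic", {
  p <- scm_params(n_sites = 14L, n_per_site = 150L, seed = 2L)
  tab <- simulate_population(p)
  expect_identical(nrow(tab), 2100L)
  expect_length(unique(tab$site), 14L)
  expect_true(all(tab$think_freq %in% 1:5) && all(tab$ritual_freq %in% 1:5))
  expect_true(all(tab$food_insecure %in% 0:1))
  expect_true(all(tab$age >= 17))
  expect_true(all(tab$education >= 0 & tab$education <= 30))
  expect_true(all(tab$children >= 0))
  expect_identical(simulate_population(p), tab)  # seed determinism
  expect_false(identical(simulate_population(scm_params(seed = 3L))$think_freq,
                         simulate_population(scm_params(seed = 4L))$think_freq))
})

test_that("generated outcome frequencies match the analytic probabilities", {
  # chi-square goodness of fit at the true parameters, large n, fixed seed
  p <- scm_params(n_sites = 1L, n_per_site = 50000L, site_effect_sd = 0,
                  seed = 123L)
  tab <- simulate_population(p)
  xi <- ordgcomp:::scm_linear_predictor(p, tab$sex, tab$age, tab$education,
                                        tab$children, tab$food_insecure)
  expected <- colMeans(category_probs(xi, p$cutpoints))
  observed <- tabulate(tab$think_freq, 5L)
  gof <- stats::chisq.test(observed, p = expected, rescale.p = TRUE)
  expect_gt(gof$p.value, 0.01)
})

test_that("true_marginal_probs is a proper, interpretable oracle", {
  p <- scm_params(n_sites = 2L, n_per_site = 100L, seed = 6L)
  tab <- simulate_population(p)
  for (lv in c(0, 1)) {
    v <- true_marginal_probs(p, tab, "food_insecure", lv)
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
  # null food-insecurity effect: identical across levels
  p0 <- scm_params(n_sites = 2L, n_per_site = 100L, beta_m_on_y = 0, seed = 6L)
  tab0 <- simulate_population(p0)
  expect_equal(true_marginal_probs(p0, tab0, "food_insecure", 0),
               true_marginal_probs(p0, tab0, "food_insecure", 1),
               tolerance = 1e-12)
  # degenerate average: single individual equals category_probs at true xi
  one <- tab[1L, ]
  attr(one, "site_effects") <- attr(tab, "site_effects")
  one$food_insecure <- 1L
  xi1 <- ordgcomp:::scm_linear_predictor(p, one$sex, one$age, one$education,
                                         one$children, 1L) +
    attr(tab, "site_effects")[one$site]
  expect_equal(unname(true_marginal_probs(p, one, "food_insecure", 1)),
               unname(drop(category_probs(xi1, p$cutpoints))), tolerance = 1e-12)
  # two-individual table: hand-computed mean of the two category vectors
  two <- tab[1:2, ]
  attr(two, "site_effects") <- attr(tab, "site_effects")
  per <- vapply(1:2, function(i) {
    r <- two[i, ]
    xi <- ordgcomp:::scm_linear_predictor(p, r$sex, r$age, 10L, r$children,
                                          r$food_insecure) +
      attr(tab, "site_effects")[r$site]
    drop(category_probs(xi, p$cutpoints))
  }, numeric(5))
  expect_equal(unname(true_marginal_probs(p, two, "education", 10L)),
               unname(rowMeans(per)), tolerance = 1e-12)
  expect_error(true_marginal_probs(p, tab, "age", 20), "unknown exposure")
})

test_that("a latent education type (religiosity-only) leaves the truth stable", {
  # the oracle with the latent variable present still reflects beta_edu only
  pU <- scm_params(n_sites = 2L, n_per_site = 2000L, seed = 13L,
                   education_type_effect = 0.8)
  tabU <- simulate_population(pU)
  expect_false(is.null(attr(tabU, "education_type")))
  c5 <- true_marginal_probs(pU, tabU, "education", 30)[5] -
    true_marginal_probs(pU, tabU, "education", 0)[5]
  # same contrast with the latent effect switched off, same covariates
  pN <- pU; pN$education_type_effect <- 0
  tabN <- tabU
  attr(tabN, "education_type") <- NULL
  c5N <- true_marginal_probs(pN, tabN, "education", 30)[5] -
    true_marginal_probs(pN, tabN, "education", 0)[5]
  # the latent term shifts response levels; through the logistic
  # nonlinearity it can rescale — but not redirect — the education contrast
  expect_identical(sign(c5), sign(c5N))
  expect_gt(abs(c5) / abs(c5N), 0.5)
  expect_lt(abs(c5) / abs(c5N), 2)
})

test_that("inject_missingness is MCAR with the stated rate", {
  p <- scm_params(n_sites = 5L, n_per_site = 200L, seed = 9L)
  tab <- simulate_population(p)
  expect_identical(inject_missingness(tab, 0), tab)
  expect_error(inject_missingness(tab, 1.2), "rate")
  m <- inject_missingness(tab, 0.1, seed = 77L)
  n_na <- sum(is.na(m))
  expected <- nrow(tab) * ncol(tab) * 0.1
  expect_lt(abs(n_na - expected), 4 * sqrt(expected * 0.9))  # binomial band
  # complete-case recount oracle
  m2 <- inject_missingness(tab, 0.5, seed = 78L)
  cc <- complete_cases(m2, quiet = TRUE)
  expect_identical(nrow(cc), sum(rowSums(is.na(m2)) == 0L))
})

test_that("scm params and survey tables round-trip through files", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("n_sites: 3", "n_per_site: 20", "beta_m_on_y: 0.5",
               "cutpoints: -1,-0.2,0.4,1.1", "seed: 17"), path)
  p <- scm_params_from_file(path)
  expect_identical(p$n_sites, 3L)
  expect_equal(p$cutpoints, c(-1, -0.2, 0.4, 1.1))
  expect_equal(p$beta_m_on_y, 0.5)
  expect_error({
    writeLines("nonsense_key: 1", path)
    scm_params_from_file(path)
  }, "unknown scm parameter")

  tab <- simulate_population(scm_params(n_sites = 2L, n_per_site = 15L, seed = 1L))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(inject_missingness(tab, 0.2, seed = 3L), csv)
  back <- read_survey_csv(csv)
  expect_identical(nrow(back), nrow(tab))
  expect_identical(nrow(attr(back, "invalid")), 0L)
  expect_gt(sum(attr(back, "missingness")), 0L)
})
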