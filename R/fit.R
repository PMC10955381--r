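EFFECT_NAMES <- c("Intercept", "S", "M", "E", "A", "C")

# Assemble the C++ data list from a complete-case table and spec.
model_data <- function(table, spec) {
  check_model_table(table, spec)
  site_names <- sort(unique(as.character(table$site)))
  list(y = as.integer(table[[spec$outcome]]),
       site = match(as.character(table$site), site_names),
       E = as.integer(table$education),
       A = as.integer(table$age - spec$age_min),
       C = as.integer(table$children),
       S = as.numeric(table$sex), M = as.numeric(table$food_insecure),
       J = length(site_names), K = spec$K,
       DE = spec$D_edu, DA = spec$D_age, DC = spec$D_children,
       th_scale = spec$prior_threshold_scale, b_scale = spec$prior_coef_scale,
       dir_alpha = spec$prior_dirichlet, sd_rate = spec$prior_sd_rate,
       lkj_eta = spec$prior_lkj, site_names = site_names)
}

unconstrained_dim <- function(spec, J) {
  (spec$K - 1L) + 5L + (spec$D_edu - 1L) + (spec$D_age - 1L) +
    (spec$D_children - 1L) + 6L + 15L + 6L * J
}

constrained_names <- function(spec, site_names) {
  P <- 6L
  cor_names <- character(0)
  for (i in 2:P) for (j in 1:(i - 1L)) {
    cor_names <- c(cor_names,
                   sprintf("Omega[%s,%s]", EFFECT_NAMES[i], EFFECT_NAMES[j]))
  }
  c(paste0("kappa[", seq_len(spec$K - 1L), "]"),
    paste0("b_", c("S", "M", "E", "A", "C")),
    paste0("zeta_E[", seq_len(spec$D_edu), "]"),
    paste0("zeta_A[", seq_len(spec$D_age), "]"),
    paste0("zeta_C[", seq_len(spec$D_children), "]"),
    paste0("sigma_", EFFECT_NAMES),
    cor_names,
    as.vector(outer(EFFECT_NAMES, site_names,
                    function(e, s) sprintf("u_%s[%s]", e, s))))
}

#' Fit the multilevel ordered-logit model by MCMC
#'
#' Samples the posterior of the cumulative-logit model of
#' [linear_predictor()] under the spec's priors with the package's
#' No-U-Turn sampler (non-centred site effects, Stan-style transforms and
#' warmup adaptation). Chains run sequentially; the whole run is
#' deterministic given `seed`.
#'
#' @param table complete-case survey data (see [complete_cases()]).
#' @param spec a [model_spec()]; defaults to [model_spec_from_data()] on
#'   `table`.
#' @param chains,iter_warmup,iter_sampling sampler size (defaults
#'   4 x 1000 + 1000).
#' @param seed integer seed (required).
#' @param adapt_delta target acceptance statistic.
#' @param max_treedepth NUTS doubling cap.
#' @return An object of class `ordgcomp_fit`: posterior draws as an
#'   `iter x chain x parameter` array (constrained scale) plus sampler
#'   metadata (per-draw divergence flags, tree depths, energies).
#' @export
fit_ordinal <- function(table, spec = NULL, chains = 4L, iter_warmup = 1000L,
                        iter_sampling = 1000L, seed, adapt_delta = 0.8,
                        max_treedepth = 10L) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(spec)) spec <- model_spec_from_data(table)
  dat <- model_data(table, spec)
  if (dat$J < 2L) stop("need >= 2 sites for varying effects", call. = FALSE)
  dim_u <- unconstrained_dim(spec, dat$J)
  pn <- constrained_names(spec, dat$site_names)

  set.seed(seed)
  draws <- array(NA_real_, c(iter_sampling, chains, length(pn) + 1L),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 c(pn, "lp__")))
  divergent <- treedepth <- matrix(NA_integer_, iter_sampling, chains)
  energy <- accept <- matrix(NA_real_, iter_sampling, chains)
  step_size <- numeric(chains)
  for (ch in seq_len(chains)) {
    theta0 <- stats::runif(dim_u, -0.5, 0.5)
    res <- ordlogit_nuts(dat, theta0, as.integer(iter_warmup),
                         as.integer(iter_sampling), adapt_delta,
                         as.integer(max_treedepth))
    draws[, ch, seq_along(pn)] <- ordlogit_constrain(res$draws, dat)
    draws[, ch, length(pn) + 1L] <- res$lp
    divergent[, ch] <- res$divergent
    treedepth[, ch] <- res$treedepth
    energy[, ch] <- res$energy
    accept[, ch] <- res$accept
    step_size[ch] <- res$step_size
  }
  if (all(divergent == 1L)) {
    stop("sampler failure: every post-warmup draw was divergent", call. = FALSE)
  }
  structure(list(draws = draws, spec = spec, site_names = dat$site_names,
                 n_obs = nrow(table), chains = chains, seed = seed,
                 iter_warmup = iter_warmup, iter_sampling = iter_sampling,
                 divergent = divergent, treedepth = treedepth,
                 energy = energy, accept = accept, step_size = step_size),
            class = "ordgcomp_fit")
}

#' @export
print.ordgcomp_fit <- function(x, ...) {
  cat("ordgcomp_fit:", x$spec$outcome, "on", x$n_obs, "rows,",
      length(x$site_names), "sites\n")
  cat("  ", x$chains, "chains x", x$iter_sampling, "draws;",
      sum(x$divergent), "divergent transitions\n")
  b <- extract_draws(x, paste0("b_", c("S", "M", "E", "A", "C")))
  cat("  posterior means:",
      paste(colnames(b), sprintf("%.3f", colMeans(b)), collapse = ", "), "\n")
  invisible(x)
}

#' Extract posterior draws as a matrix
#'
#' @param fit an `ordgcomp_fit`.
#' @param pars parameter names (default: all).
#' @return A `(iter * chain) x length(pars)` matrix, chains stacked.
#' @export
extract_draws <- function(fit, pars = NULL) {
  pn <- dimnames(fit$draws)[[3]]
  if (is.null(pars)) pars <- pn
  bad <- setdiff(pars, pn)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  m <- apply(fit$draws[, , pars, drop = FALSE], 3L, identity)
  matrix(m, ncol = length(pars), dimnames = list(NULL, pars))
}

n_draws <- function(fit) fit$iter_sampling * fit$chains

# One posterior draw in the list format linear_predictor() expects.
#' Extract a single posterior draw
#'
#' Returns draw `s` (1-based over stacked chains) as the list structure
#' [linear_predictor()] consumes.
#'
#' @param fit an `ordgcomp_fit`.
#' @param s draw index in `1..(iter * chains)`.
#' @return A list with `kappa`, `beta`, `zeta_E`, `zeta_A`, `zeta_C`,
#'   `sigma`, `u`.
#' @export
as_draw <- function(fit, s) {
  stopifnot(s >= 1L, s <= n_draws(fit))
  it <- (s - 1L) %% fit$iter_sampling + 1L
  ch <- (s - 1L) %/% fit$iter_sampling + 1L
  v <- fit$draws[it, ch, ]
  spec <- fit$spec
  J <- length(fit$site_names)
  u <- matrix(v[grep("^u_", names(v))], nrow = 6L,
              dimnames = list(EFFECT_NAMES, fit$site_names))
  list(kappa = unname(v[paste0("kappa[", seq_len(spec$K - 1L), "]")]),
       beta = stats::setNames(unname(v[paste0("b_", c("S", "M", "E", "A", "C"))]),
                              c("S", "M", "E", "A", "C")),
       zeta_E = unname(v[paste0("zeta_E[", seq_len(spec$D_edu), "]")]),
       zeta_A = unname(v[paste0("zeta_A[", seq_len(spec$D_age), "]")]),
       zeta_C = unname(v[paste0("zeta_C[", seq_len(spec$D_children), "]")]),
       sigma = unname(v[paste0("sigma_", EFFECT_NAMES)]),
       u = u)
}

#' Serialize posterior draws to CSV
#'
#' One column per scalar parameter, one row per draw (chains stacked),
#' with `# key: value` metadata header lines (chains, iterations, seed,
#' spec hash).
#'
#' @param fit an `ordgcomp_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  spec_hash <- md5_of_text(paste(utils::capture.output(utils::str(fit$spec)),
                                 collapse = "\n"))
  hdr <- c(sprintf("# chains: %d", fit$chains),
           sprintf("# iter_warmup: %d", fit$iter_warmup),
           sprintf("# iter_sampling: %d", fit$iter_sampling),
           sprintf("# seed: %d", fit$seed),
           sprintf("# spec_hash: %s", spec_hash))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  m <- extract_draws(fit)
  m <- cbind(m, chain = rep(seq_len(fit$chains), each = fit$iter_sampling),
             divergent = as.vector(fit$divergent))
  utils::write.csv(as.data.frame(m), con, row.names = FALSE)
  invisible(path)
}

# md5 of a text string via base tools (no extra dependency).
md5_of_text <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
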