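#' Monotonic transform of an ordinal predictor
#'
#' Decomposes the effect of an ordinal predictor with `D` increments into a
#' scalar coefficient times a normalized shape: `mo(x, zeta) = D *
#' sum(zeta[1:x])`, with `mo(0) = 0`. `zeta` is a simplex (nonnegative,
#' summing to 1), so the attached regression coefficient is the expected
#' average difference between two adjacent levels of the predictor and the
#' full-range effect is `coefficient * D`. An equal simplex recovers an
#' ordinary linear term.
#'
#' @param x integer level(s) in `0..D` (vectorized).
#' @param zeta simplex vector of length `D`.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' mo(2, c(0.25, 0.25, 0.25, 0.25))  # 2: equal simplex is linear
#' @export
mo <- function(x, zeta) {
  D <- length(zeta)
  if (D < 1L) stop("zeta must have at least one element", call. = FALSE)
  if (any(zeta < -1e-9) || abs(sum(zeta) - 1) > 1e-9) {
    stop("zeta must be a simplex (nonnegative, summing to 1)", call. = FALSE)
  }
  if (any(is.na(x)) || any(x < 0L | x > D)) {
    stop("x must lie in [0, ", D, "]", call. = FALSE)
  }
  cs <- c(0, cumsum(zeta))
  D * cs[x + 1L]
}

#' Cumulative-logit category probabilities
#'
#' For ordered categories `1..K` with strictly increasing cutpoints
#' `kappa` (length `K - 1`) and linear predictor `xi`,
#' `P(Y = k) = logistic(kappa_k - xi) - logistic(kappa_{k-1} - xi)` with
#' `kappa_0 = -Inf`, `kappa_K = +Inf`.
#'
#' @param xi numeric vector of linear predictors.
#' @param kappa strictly increasing cutpoint vector.
#' @return A `length(xi) x K` matrix of probabilities; rows sum to 1.
#' @export
category_probs <- function(xi, kappa) {
  if (is.unsorted(kappa, strictly = TRUE)) {
    stop("kappa must be strictly increasing", call. = FALSE)
  }
  K <- length(kappa) + 1L
  cum <- stats::plogis(outer(-xi, kappa, `+`))  # n x (K-1): P(Y <= k)
  p <- cbind(cum, 1) - cbind(0, cum)
  dimnames(p) <- list(NULL, paste0("k", seq_len(K)))
  p
}

#' Model specification for the multilevel cumulative-logit fit
#'
#' Captures the outcome, the ordinal scale, the monotonic predictors'
#' increment counts, and the prior settings of the study model: thresholds
#' Normal(0, 10), all coefficients Normal(0, 0.5), monotonic simplexes
#' Dirichlet(2, ..., 2), varying-effect standard deviations
#' Exponential(1), and the site-effect correlation matrix LKJ(4).
#'
#' @param outcome `"think_freq"` or `"ritual_freq"`.
#' @param K number of ordinal categories (default 5).
#' @param D_edu,D_age,D_children number of increments of the monotonic
#'   predictors (education defaults to the instrument's 0–30 range; age and
#'   children default to the observed range when built via
#'   [model_spec_from_data()]).
#' @param age_min origin of the age increments (ages enter as `age - age_min`).
#' @param prior_threshold_scale,prior_coef_scale,prior_dirichlet,prior_sd_rate,prior_lkj
#'   prior hyperparameters; defaults are the study model's.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("think_freq", "ritual_freq"),
                       K = 5L, D_edu = 30L, D_age = 60L, D_children = 15L,
                       age_min = 17L,
                       prior_threshold_scale = 10, prior_coef_scale = 0.5,
                       prior_dirichlet = 2, prior_sd_rate = 1, prior_lkj = 4) {
  outcome <- match.arg(outcome)
  stopifnot(K >= 2L, D_edu >= 1L, D_age >= 1L, D_children >= 1L,
            prior_threshold_scale > 0, prior_coef_scale > 0,
            prior_dirichlet > 0, prior_sd_rate > 0, prior_lkj > 0)
  structure(list(outcome = outcome, K = as.integer(K),
                 D_edu = as.integer(D_edu), D_age = as.integer(D_age),
                 D_children = as.integer(D_children),
                 age_min = as.integer(age_min),
                 prior_threshold_scale = prior_threshold_scale,
                 prior_coef_scale = prior_coef_scale,
                 prior_dirichlet = prior_dirichlet,
                 prior_sd_rate = prior_sd_rate,
                 prior_lkj = prior_lkj),
            class = "model_spec")
}

#' Build a model spec with increment counts taken from the data
#'
#' Education keeps its full instrument range (0–30); age increments span
#' the observed range above the observed minimum; children increments span
#' `0..max(children)`.
#'
#' @param table a survey data.frame (see [simulate_population()]).
#' @param outcome outcome column name.
#' @param ... passed to [model_spec()].
#' @return A `model_spec`.
#' @export
model_spec_from_data <- function(table, outcome = "think_freq", ...) {
  age <- table$age[!is.na(table$age)]
  ch <- table$children[!is.na(table$children)]
  model_spec(outcome = outcome,
             D_age = max(1L, as.integer(diff(range(age)))),
             D_children = max(1L, as.integer(max(ch))),
             age_min = as.integer(min(age)), ...)
}

model_variables <- function(spec) {
  c("site", "sex", "age", "education", "children", "food_insecure", spec$outcome)
}

# Validate a table against a spec (complete cases, domains).
check_model_table <- function(table, spec) {
  vars <- model_variables(spec)
  miss <- setdiff(vars, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyNA(table[vars])) {
    stop("table must be complete-case on the model variables; see complete_cases()",
         call. = FALSE)
  }
  y <- table[[spec$outcome]]
  if (any(y < 1L | y > spec$K)) stop("outcome outside 1..K", call. = FALSE)
  if (any(table$education < 0L | table$education > spec$D_edu)) {
    stop("education outside [0, ", spec$D_edu, "]", call. = FALSE)
  }
  if (any(table$age < spec$age_min | table$age > spec$age_min + spec$D_age)) {
    stop("age outside the spec's range", call. = FALSE)
  }
  if (any(table$children < 0L | table$children > spec$D_children)) {
    stop("children outside [0, ", spec$D_children, "]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Linear predictor of the multilevel ordered-logit model
#'
#' `xi = a_site + (bS + uS_site) S + (bM + uM_site) M +
#'  (bE + uE_site) mo(E, zE) + (bA + uA_site) mo(A - age_min, zA) +
#'  (bC + uC_site) mo(C, zC)`, with sex `S` and food insecurity `M`
#' indicator-coded. Site offsets are the rows intercept, S, M, E, A, C of
#' `draw$u`.
#'
#' @param table complete-case survey rows.
#' @param draw a single posterior (or true-parameter) draw: a list with
#'   `beta` (named S, M, E, A, C), `zeta_E`, `zeta_A`, `zeta_C`, `u`
#'   (6 x J matrix of site offsets, rows intercept/S/M/E/A/C, columns named
#'   by site), and `kappa`.
#' @param spec a [model_spec()].
#' @return Numeric vector of linear predictors, one per row.
#' @export
linear_predictor <- function(table, draw, spec) {
  check_model_table(table, spec)
  sites <- colnames(draw$u)
  j <- match(as.character(table$site), sites)
  if (anyNA(j)) {
    stop("unknown site(s): ",
         paste(unique(table$site[is.na(j)]), collapse = ", "), call. = FALSE)
  }
  moE <- mo(table$education, draw$zeta_E)
  moA <- mo(table$age - spec$age_min, draw$zeta_A)
  moC <- mo(table$children, draw$zeta_C)
  b <- draw$beta
  draw$u[1L, j] +
    (b[["S"]] + draw$u[2L, j]) * table$sex +
    (b[["M"]] + draw$u[3L, j]) * table$food_insecure +
    (b[["E"]] + draw$u[4L, j]) * moE +
    (b[["A"]] + draw$u[5L, j]) * moA +
    (b[["C"]] + draw$u[6L, j]) * moC
}

#' Log-likelihood of a draw on a table
#'
#' Sum over rows of the log cumulative-logit probability of the observed
#' outcome category at the draw's parameters.
#'
#' @inheritParams linear_predictor
#' @return A scalar.
#' @export
log_likelihood <- function(table, draw, spec) {
  if (nrow(table) == 0L) return(0)
  xi <- linear_predictor(table, draw, spec)
  p <- category_probs(xi, draw$kappa)
  sum(log(p[cbind(seq_len(nrow(table)), table[[spec$outcome]])]))
}

# Symmetric-Dirichlet draws, n x D.
rdirichlet <- function(n, alpha, D) {
  g <- matrix(stats::rgamma(n * D, shape = alpha), nrow = n)
  g / rowSums(g)
}

# LKJ(eta) correlation draw via the C-vine / partial-correlation method.
rlkj <- function(P, eta) {
  R <- diag(P)
  if (P == 1L) return(R)
  pc <- matrix(0, P, P)
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      a <- eta + (P - 1L - i) / 2
      pc[i, j] <- 2 * stats::rbeta(1L, a, a) - 1
    }
  }
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      r <- pc[i, j]
      if (i > 1L) {
        for (k in (i - 1L):1L) {
          r <- r * sqrt((1 - pc[k, i]^2) * (1 - pc[k, j]^2)) + pc[k, i] * pc[k, j]
        }
      }
      R[i, j] <- R[j, i] <- r
    }
  }
  R
}

# One draw of all model parameters from the priors.
draw_from_prior <- function(spec, site_names) {
  J <- length(site_names)
  P <- 6L
  kappa <- sort(stats::rnorm(spec$K - 1L, 0, spec$prior_threshold_scale))
  beta <- stats::setNames(stats::rnorm(5L, 0, spec$prior_coef_scale),
                          c("S", "M", "E", "A", "C"))
  sigma <- stats::rexp(P, spec$prior_sd_rate)
  Omega <- rlkj(P, spec$prior_lkj)
  L <- t(chol(Omega))
  u <- diag(sigma, P) %*% L %*% matrix(stats::rnorm(P * J), P, J)
  colnames(u) <- site_names
  list(kappa = kappa, beta = beta,
       zeta_E = drop(rdirichlet(1L, spec$prior_dirichlet, spec$D_edu)),
       zeta_A = drop(rdirichlet(1L, spec$prior_dirichlet, spec$D_age)),
       zeta_C = drop(rdirichlet(1L, spec$prior_dirichlet, spec$D_children)),
       sigma = sigma, Omega = Omega, u = u)
}

#' Prior predictive simulation
#'
#' Samples all parameters from the model's priors and simulates ordinal
#' outcomes for the given covariate table — the check that the priors are
#' weakly regularising rather than informative.
#'
#' @param spec a [model_spec()].
#' @param table covariate table (complete-case on the covariates; the
#'   outcome column is ignored and may be absent).
#' @param n_draws number of prior draws.
#' @param seed RNG seed.
#' @return A list with `parameters` (list of prior draws) and `outcomes`
#'   (`n_draws x nrow(table)` integer matrix of simulated categories).
#' @export
prior_predictive <- function(spec, table, n_draws = 100L, seed = 1L) {
  stopifnot(n_draws >= 1L)
  set.seed(seed)
  tab <- table
  tab[[spec$outcome]] <- 1L  # placeholder so completeness checks pass
  site_names <- sort(unique(as.character(tab$site)))
  params <- vector("list", n_draws)
  outcomes <- matrix(NA_integer_, n_draws, nrow(tab))
  for (s in seq_len(n_draws)) {
    d <- draw_from_prior(spec, site_names)
    params[[s]] <- d
    p <- category_probs(linear_predictor(tab, d, spec), d$kappa)
    outcomes[s, ] <- apply(p, 1L, function(pr) sample.int(spec$K, 1L, prob = pr))
  }
  list(parameters = params, outcomes = outcomes)
}
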