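# MCMC convergence diagnostics: rank-normalized split R-hat and bulk/tail
# effective sample size, computed from first principles (no external MCMC
# package in the toolchain). Formulas follow the now-standard improved
# R-hat workflow: chains are split in half, rank-normalized via the
# (r - 3/8)/(S + 1/4) blom transform, and ESS uses Geyer's initial
# monotone positive sequence on per-chain autocorrelations.

split_chains <- function(m) {
  # m: iter x chain matrix -> iter/2 x (2*chain)
  n <- nrow(m)
  h <- n %/% 2L
  cbind(m[seq_len(h), , drop = FALSE],
        m[(n - h + 1L):n, , drop = FALSE])
}

rank_normalize <- function(m) {
  S <- length(m)
  z <- stats::qnorm((rank(as.vector(m)) - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow = nrow(m))
}

rhat_basic <- function(m) {
  # m: iter x chain (>= 2 chains)
  n <- nrow(m)
  mu <- colMeans(m)
  s2 <- apply(m, 2L, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W <= 0) return(NA_real_)
  sqrt((W * (n - 1) / n + B / n) / W)
}

ess_geyer <- function(m) {
  # standard formulation: rho_0 = 1; pairs (rho_{2t}, rho_{2t+1})
  n <- nrow(m); nc <- ncol(m)
  if (n < 4L || stats::sd(as.vector(m)) == 0) return(NA_real_)
  mu <- colMeans(m)
  s2 <- apply(m, 2L, stats::var)
  W <- mean(s2)
  varp <- W * (n - 1) / n + (if (nc > 1L) stats::var(mu) else 0)
  if (varp <= 0 || W <= 0) return(NA_real_)
  acov <- vapply(seq_len(nc), function(c) {
    stats::acf(m[, c], lag.max = n - 1L, plot = FALSE,
               type = "covariance")$acf[, 1L, 1L]
  }, numeric(n))
  mean_acov <- rowMeans(acov) * (n - 1) / n
  rho <- 1 - (W - mean_acov) / varp   # rho[1] is lag 0
  # initial positive monotone sequence on consecutive pairs
  tau <- rho[1L]
  prev <- Inf
  t <- 2L
  while (t + 1L <= length(rho)) {
    ps <- rho[t] + rho[t + 1L]
    if (!is.finite(ps) || ps < 0) break
    ps <- min(ps, prev)
    prev <- ps
    tau <- tau + 2 * ps
    t <- t + 2L
  }
  n * nc / max(tau, 1e-12)
}

#' Sampler diagnostics report
#'
#' Computes, per parameter: rank-normalized split R-hat, bulk effective
#' sample size (ESS of the rank-normalized draws) and tail ESS (minimum
#' ESS of the 5% / 95% tail indicators), plus the total divergence count.
#' Parameters with R-hat above 1.01 are flagged.
#'
#' @param fit an `ordgcomp_fit`.
#' @param pars parameters to include (default: cutpoints, coefficients,
#'   standard deviations and lp__ — the quantities that drive inference).
#' @return A list with `summary` (data.frame parameter, rhat, ess_bulk,
#'   ess_tail), `divergences`, `flagged` (parameter names with
#'   R-hat > 1.01), `max_rhat`.
#' @export
fit_diagnostics <- function(fit, pars = NULL) {
  if (is.null(pars)) {
    pn <- dimnames(fit$draws)[[3]]
    pars <- pn[grepl("^kappa\\[|^b_|^sigma_|^lp__$", pn)]
  }
  single <- fit$chains < 2L
  if (single) warning("single chain: R-hat omitted", call. = FALSE)
  rows <- lapply(pars, function(p) {
    m <- fit$draws[, , p, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = fit$chains)
    sm <- split_chains(m)
    if (stats::sd(as.vector(sm)) == 0) {
      return(data.frame(parameter = p, rhat = NA_real_,
                        ess_bulk = NA_real_, ess_tail = NA_real_))
    }
    z <- rank_normalize(sm)
    rh <- if (single) NA_real_ else rhat_basic(z)
    q05 <- stats::quantile(m, 0.05); q95 <- stats::quantile(m, 0.95)
    tl <- ess_geyer(rank_normalize(split_chains(0 + (m <= q05))))
    tu <- ess_geyer(rank_normalize(split_chains(0 + (m >= q95))))
    data.frame(parameter = p, rhat = rh, ess_bulk = ess_geyer(z),
               ess_tail = min(tl, tu, na.rm = TRUE))
  })
  summary <- do.call(rbind, rows)
  flagged <- summary$parameter[!is.na(summary$rhat) & summary$rhat > 1.01]
  list(summary = summary,
       divergences = sum(fit$divergent),
       flagged = flagged,
       max_rhat = if (all(is.na(summary$rhat))) NA_real_
                  else max(summary$rhat, na.rm = TRUE))
}
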