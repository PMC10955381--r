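// Multilevel Bayesian cumulative-logit model with monotonic ordinal
// predictors: log posterior with analytic gradients on the unconstrained
// scale, plus a No-U-Turn sampler with dual-averaging step-size and
// diagonal mass-matrix adaptation.
//
// Unconstrained parameter layout (P = 6 site-effect dimensions:
// intercept, S, M, E, A, C):
//   [0, K-1)                     t_kappa   (ordered transform)
//   [.., +5)                     beta      (S, M, E, A, C)
//   [.., +DE-1)                  t_zeta_E  (multinomial-logit simplex)
//   [.., +DA-1)                  t_zeta_A
//   [.., +DC-1)                  t_zeta_C
//   [.., +P)                     log sigma
//   [.., +P(P-1)/2)              w_corr    (tanh partial correlations,
//                                           rows i=1..P-1, j<i, row-major)
//   [.., +P*J)                   z         (standard-normal site effects,
//                                           column-major P x J)
//
// Priors: kappa ~ Normal(0, th_scale) on the ordered scale; beta ~
// Normal(0, b_scale); zeta ~ Dirichlet(alpha); sigma ~ Exponential(rate);
// correlation ~ LKJ(eta); z ~ Normal(0, 1). All transform Jacobians
// included, so the sampler targets exactly this posterior.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const int P = 6;
static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct ModelData {
  IntegerVector y, site, E, A, C;
  NumericVector S, M;
  int n, J, K, DE, DA, DC;
  double th_scale, b_scale, dir_alpha, sd_rate, lkj_eta;
};

static ModelData unpack(const List& data) {
  ModelData d;
  d.y = data["y"]; d.site = data["site"];
  d.E = data["E"]; d.A = data["A"]; d.C = data["C"];
  d.S = data["S"]; d.M = data["M"];
  d.n = d.y.size();
  d.J = as<int>(data["J"]); d.K = as<int>(data["K"]);
  d.DE = as<int>(data["DE"]); d.DA = as<int>(data["DA"]);
  d.DC = as<int>(data["DC"]);
  d.th_scale = as<double>(data["th_scale"]);
  d.b_scale = as<double>(data["b_scale"]);
  d.dir_alpha = as<double>(data["dir_alpha"]);
  d.sd_rate = as<double>(data["sd_rate"]);
  d.lkj_eta = as<double>(data["lkj_eta"]);
  return d;
}

static int model_dim(const ModelData& d) {
  return (d.K - 1) + 5 + (d.DE - 1) + (d.DA - 1) + (d.DC - 1) +
         P + P * (P - 1) / 2 + P * d.J;
}

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double inv_logit(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

// softmax of (t_1..t_{D-1}, 0) -> simplex of length D
static void simplex_constrain(const double* t, int D, std::vector<double>& x) {
  x.assign(D, 1.0);
  if (D == 1) return;
  double mx = 0.0;
  for (int j = 0; j < D - 1; ++j) if (t[j] > mx) mx = t[j];
  double Z = std::exp(-mx);
  for (int j = 0; j < D - 1; ++j) Z += std::exp(t[j] - mx);
  for (int j = 0; j < D - 1; ++j) x[j] = std::exp(t[j] - mx) / Z;
  x[D - 1] = std::exp(-mx) / Z;
}

// Log posterior and gradient; returns -Inf (grad zeroed) on numerical failure.
static double lp_grad(const ModelData& d, const std::vector<double>& th,
                      std::vector<double>& g) {
  const int dim = model_dim(d);
  g.assign(dim, 0.0);
  const int Km1 = d.K - 1;
  const int o_tk = 0;
  const int o_b = o_tk + Km1;
  const int o_tE = o_b + 5;
  const int o_tA = o_tE + d.DE - 1;
  const int o_tC = o_tA + d.DA - 1;
  const int o_ls = o_tC + d.DC - 1;
  const int o_w = o_ls + P;
  const int o_z = o_w + P * (P - 1) / 2;

  double lp = 0.0;

  // --- constrain ---
  std::vector<double> kappa(Km1);
  kappa[0] = th[o_tk];
  for (int k = 1; k < Km1; ++k) kappa[k] = kappa[k - 1] + std::exp(th[o_tk + k]);
  const double* beta = &th[o_b];  // S, M, E, A, C
  std::vector<double> zE, zA, zC;
  simplex_constrain(&th[o_tE], d.DE, zE);
  simplex_constrain(&th[o_tA], d.DA, zA);
  simplex_constrain(&th[o_tC], d.DC, zC);
  std::vector<double> sig(P);
  for (int p = 0; p < P; ++p) sig[p] = std::exp(th[o_ls + p]);

  // partial correlations -> Cholesky factor L
  std::vector<double> r(P * (P - 1) / 2), L(P * P, 0.0);
  for (int m = 0; m < P * (P - 1) / 2; ++m) r[m] = std::tanh(th[o_w + m]);
  L[0] = 1.0;
  {
    int m = 0;
    for (int i = 1; i < P; ++i) {
      double prod = 1.0;
      for (int j = 0; j < i; ++j, ++m) {
        L[i * P + j] = r[m] * prod;
        prod *= std::sqrt(1.0 - r[m] * r[m]);
      }
      L[i * P + i] = prod;
    }
  }

  // site effects u = diag(sig) * L * z   (P x J)
  std::vector<double> v(P * d.J, 0.0), u(P * d.J, 0.0);
  for (int j = 0; j < d.J; ++j) {
    for (int p = 0; p < P; ++p) {
      double acc = 0.0;
      for (int q = 0; q <= p; ++q) acc += L[p * P + q] * th[o_z + j * P + q];
      v[j * P + p] = acc;
      u[j * P + p] = sig[p] * acc;
    }
  }

  // monotonic lookups: mo(x) = D * cumsum(zeta)[x]
  std::vector<double> moE(d.DE + 1, 0.0), moA(d.DA + 1, 0.0), moC(d.DC + 1, 0.0);
  for (int x = 1; x <= d.DE; ++x) moE[x] = moE[x - 1] + d.DE * zE[x - 1];
  for (int x = 1; x <= d.DA; ++x) moA[x] = moA[x - 1] + d.DA * zA[x - 1];
  for (int x = 1; x <= d.DC; ++x) moC[x] = moC[x - 1] + d.DC * zC[x - 1];

  // --- likelihood ---
  std::vector<double> gkappa(Km1, 0.0), gu(P * d.J, 0.0);
  std::vector<double> aE(d.DE + 1, 0.0), aA(d.DA + 1, 0.0), aC(d.DC + 1, 0.0);
  double gbS = 0, gbM = 0, gbE = 0, gbA = 0, gbC = 0;

  for (int i = 0; i < d.n; ++i) {
    const int j = d.site[i] - 1;
    const double* uj = &u[j * P];
    const double mE = moE[d.E[i]], mA = moA[d.A[i]], mC = moC[d.C[i]];
    const double xi = uj[0] +
      (beta[0] + uj[1]) * d.S[i] + (beta[1] + uj[2]) * d.M[i] +
      (beta[2] + uj[3]) * mE + (beta[3] + uj[4]) * mA + (beta[4] + uj[5]) * mC;
    const int k = d.y[i];  // 1..K
    const bool has_hi = (k < d.K), has_lo = (k > 1);
    const double h = has_hi ? kappa[k - 1] - xi : 0.0;
    const double l = has_lo ? kappa[k - 2] - xi : 0.0;
    double logp, fph = 0.0, fpl = 0.0, pr;
    if (has_hi && has_lo) {
      logp = h + std::log1p(-std::exp(l - h)) - log1pexp_(h) - log1pexp_(l);
      double sh = inv_logit(h), sl = inv_logit(l);
      fph = sh * (1.0 - sh); fpl = sl * (1.0 - sl);
      pr = std::exp(logp);
    } else if (has_hi) {            // k = 1
      logp = -log1pexp_(-h);
      double sh = inv_logit(h);
      fph = sh * (1.0 - sh);
      pr = sh;
    } else {                        // k = K
      logp = -log1pexp_(l);
      double sl = inv_logit(l);
      fpl = sl * (1.0 - sl);
      pr = 1.0 - sl;
    }
    if (!std::isfinite(logp)) { g.assign(dim, 0.0); return NEG_INF; }
    lp += logp;
    if (pr < 1e-300) pr = 1e-300;
    const double gxi = (fpl - fph) / pr;
    if (has_hi) gkappa[k - 1] += fph / pr;
    if (has_lo) gkappa[k - 2] -= fpl / pr;
    // design gradients
    double* guj = &gu[j * P];
    guj[0] += gxi;
    guj[1] += gxi * d.S[i];
    guj[2] += gxi * d.M[i];
    guj[3] += gxi * mE;
    guj[4] += gxi * mA;
    guj[5] += gxi * mC;
    gbS += gxi * d.S[i]; gbM += gxi * d.M[i];
    gbE += gxi * mE; gbA += gxi * mA; gbC += gxi * mC;
    aE[d.E[i]] += gxi * (beta[2] + uj[3]);
    aA[d.A[i]] += gxi * (beta[3] + uj[4]);
    aC[d.C[i]] += gxi * (beta[4] + uj[5]);
  }

  // --- priors & transforms ---
  // cutpoints: Normal(0, th_scale), ordered transform Jacobian
  const double th_var = d.th_scale * d.th_scale;
  for (int k = 0; k < Km1; ++k) {
    lp += -0.5 * kappa[k] * kappa[k] / th_var;
    gkappa[k] += -kappa[k] / th_var;
  }
  {
    double suff = 0.0;
    for (int k = Km1 - 1; k >= 1; --k) {
      suff += gkappa[k];
      g[o_tk + k] = std::exp(th[o_tk + k]) * suff + 1.0;  // +1: Jacobian
      lp += th[o_tk + k];
    }
    g[o_tk] = suff + gkappa[0];
  }

  // beta: Normal(0, b_scale)
  const double b_var = d.b_scale * d.b_scale;
  double gb[5] = { gbS, gbM, gbE, gbA, gbC };
  for (int q = 0; q < 5; ++q) {
    lp += -0.5 * beta[q] * beta[q] / b_var;
    g[o_b + q] = gb[q] - beta[q] / b_var;
  }

  // simplexes: likelihood suffix sums -> gzeta, then Dirichlet + Jacobian
  auto simplex_block = [&](const std::vector<double>& zeta,
                           const std::vector<double>& acc, int D, int off) {
    // gzeta[m-1] = D * sum_{x >= m} acc[x]
    std::vector<double> gz(D, 0.0);
    double suff = 0.0;
    for (int x = D; x >= 1; --x) { suff += acc[x]; gz[x - 1] = D * suff; }
    double dot = 0.0;
    for (int m = 0; m < D; ++m) dot += gz[m] * zeta[m];
    for (int m = 0; m < D; ++m) {
      lp += d.dir_alpha * std::log(zeta[m]);  // Dirichlet(alpha) + Jacobian
      if (m < D - 1)
        g[off + m] = zeta[m] * (gz[m] - dot) + d.dir_alpha * (1.0 - D * zeta[m]);
    }
  };
  simplex_block(zE, aE, d.DE, o_tE);
  simplex_block(zA, aA, d.DA, o_tA);
  simplex_block(zC, aC, d.DC, o_tC);

  // sigma: Exponential(rate), log transform
  std::vector<double> gv(P * d.J);
  for (int p = 0; p < P; ++p) {
    double gs = 0.0;
    for (int j = 0; j < d.J; ++j) {
      gv[j * P + p] = sig[p] * gu[j * P + p];
      gs += gu[j * P + p] * v[j * P + p];
    }
    lp += -d.sd_rate * sig[p] + th[o_ls + p];
    g[o_ls + p] = sig[p] * (gs - d.sd_rate) + 1.0;
  }

  // z: standard normal; gz = L^T gv - z
  for (int j = 0; j < d.J; ++j) {
    for (int q = 0; q < P; ++q) {
      double acc = 0.0;
      for (int p = q; p < P; ++p) acc += L[p * P + q] * gv[j * P + p];
      const double zz = th[o_z + j * P + q];
      lp += -0.5 * zz * zz;
      g[o_z + j * P + q] = acc - zz;
    }
  }

  // correlation Cholesky: likelihood gL = gv z^T, LKJ prior, Jacobians
  std::vector<double> gL(P * P, 0.0);
  for (int p = 0; p < P; ++p)
    for (int q = 0; q <= p; ++q) {
      double acc = 0.0;
      for (int j = 0; j < d.J; ++j) acc += gv[j * P + p] * th[o_z + j * P + q];
      gL[p * P + q] = acc;
    }
  for (int i = 1; i < P; ++i) {  // LKJ(eta) on the Cholesky factor
    const double coef = P - (i + 1) + 2.0 * d.lkj_eta - 2.0;
    lp += coef * std::log(L[i * P + i]);
    gL[i * P + i] += coef / L[i * P + i];
  }
  {
    int mrow = 0;
    for (int i = 1; i < P; ++i) {
      // prod[j] = prod_{k<=j} sqrt(1-r_k^2); L(i,j) = r_j * prod[j-1]
      double suffT = gL[i * P + i] * L[i * P + i];
      for (int j = i - 1; j >= 0; --j) {
        const int m = mrow + j;
        const double rm = r[m];
        double pm1 = 1.0;  // prod_{k<j} sqrt(1 - r_k^2)
        for (int k = 0; k < j; ++k) pm1 *= std::sqrt(1.0 - r[mrow + k] * r[mrow + k]);
        double gr = gL[i * P + j] * pm1 - rm / (1.0 - rm * rm) * suffT;
        // Jacobians: tanh (-2 r) and construction (-(i-1-j) r)
        g[o_w + m] = gr * (1.0 - rm * rm) - 2.0 * rm - (i - 1 - j) * rm;
        lp += std::log(1.0 - rm * rm) + 0.5 * (i - 1 - j) * std::log(1.0 - rm * rm);
        suffT += gL[i * P + j] * L[i * P + j];
      }
      mrow += i;
    }
  }

  if (!std::isfinite(lp)) { g.assign(dim, 0.0); return NEG_INF; }
  return lp;
}

// [[Rcpp::export]]
List ordlogit_lpgrad(NumericVector theta, List data) {
  ModelData d = unpack(data);
  if (theta.size() != model_dim(d)) stop("theta has wrong length");
  std::vector<double> th(theta.begin(), theta.end()), g;
  double lp = lp_grad(d, th, g);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(g.begin(), g.end()));
}

// ---------------- NUTS ----------------

struct NutsCtx {
  const ModelData* d;
  std::vector<double> Minv;  // inverse mass (positions' variances)
  double eps;
};

static double kinetic(const NutsCtx& c, const std::vector<double>& p) {
  double k = 0.0;
  for (size_t i = 0; i < p.size(); ++i) k += c.Minv[i] * p[i] * p[i];
  return 0.5 * k;
}

static double leapfrog(const NutsCtx& c, std::vector<double>& q,
                       std::vector<double>& p, std::vector<double>& grad,
                       double direction) {
  const double e = direction * c.eps;
  for (size_t i = 0; i < q.size(); ++i) p[i] += 0.5 * e * grad[i];
  for (size_t i = 0; i < q.size(); ++i) q[i] += e * c.Minv[i] * p[i];
  double lp = lp_grad(*c.d, q, grad);
  for (size_t i = 0; i < q.size(); ++i) p[i] += 0.5 * e * grad[i];
  return lp;
}

static bool no_uturn(const NutsCtx& c,
                     const std::vector<double>& qm, const std::vector<double>& pm,
                     const std::vector<double>& qp, const std::vector<double>& pp) {
  double dm = 0.0, dp = 0.0;
  for (size_t i = 0; i < qm.size(); ++i) {
    const double dq = qp[i] - qm[i];
    dm += dq * c.Minv[i] * pm[i];
    dp += dq * c.Minv[i] * pp[i];
  }
  return dm >= 0.0 && dp >= 0.0;
}

struct Tree {
  std::vector<double> qm, pm, gm, qp, pp, gp, qprop, gprop;
  double lpm, lpp, lpprop;
  long n;
  bool ok;        // no divergence / U-turn inside
  double alpha;   // accumulated accept statistic
  long nalpha;
  bool div;
};

static void build_tree(const NutsCtx& c, const std::vector<double>& q,
                       const std::vector<double>& p, const std::vector<double>& grad,
                       double lp, double logu, int dir, int depth, double H0,
                       Tree& out) {
  if (depth == 0) {
    out.qm = q; out.pm = p; out.gm = grad; out.lpm = lp;
    double lp1 = leapfrog(c, out.qm, out.pm, out.gm, dir);
    out.lpm = lp1;
    out.qp = out.qm; out.pp = out.pm; out.gp = out.gm; out.lpp = lp1;
    out.qprop = out.qm; out.gprop = out.gm; out.lpprop = lp1;
    const double f = lp1 - kinetic(c, out.pm);  // -H
    out.n = (logu <= f) ? 1 : 0;
    out.div = !(f - logu > -1000.0) || !std::isfinite(f);
    out.ok = !out.div;
    double a = std::exp(f + H0);  // exp(-(H - H0))
    out.alpha = std::isfinite(a) ? std::min(1.0, a) : 0.0;
    out.nalpha = 1;
    return;
  }
  Tree first;
  build_tree(c, q, p, grad, lp, logu, dir, depth - 1, H0, first);
  out = first;
  if (!first.ok) return;
  Tree second;
  if (dir == -1) {
    build_tree(c, first.qm, first.pm, first.gm, first.lpm, logu, dir, depth - 1,
               H0, second);
    out.qm = second.qm; out.pm = second.pm; out.gm = second.gm; out.lpm = second.lpm;
  } else {
    build_tree(c, first.qp, first.pp, first.gp, first.lpp, logu, dir, depth - 1,
               H0, second);
    out.qp = second.qp; out.pp = second.pp; out.gp = second.gp; out.lpp = second.lpp;
  }
  const long ntot = first.n + second.n;
  if (second.n > 0 && ntot > 0 &&
      R::unif_rand() < (double)second.n / (double)ntot) {
    out.qprop = second.qprop; out.gprop = second.gprop; out.lpprop = second.lpprop;
  }
  out.n = ntot;
  out.alpha = first.alpha + second.alpha;
  out.nalpha = first.nalpha + second.nalpha;
  out.div = first.div || second.div;
  out.ok = second.ok && no_uturn(c, out.qm, out.pm, out.qp, out.pp);
}

// [[Rcpp::export]]
List ordlogit_nuts(List data, NumericVector theta0, int iter_warmup,
                   int iter_sampling, double adapt_delta = 0.8,
                   int max_treedepth = 10) {
  RNGScope scope;
  ModelData d = unpack(data);
  const int dim = model_dim(d);
  if (theta0.size() != dim) stop("theta0 has wrong length");

  NutsCtx c; c.d = &d; c.Minv.assign(dim, 1.0); c.eps = 0.1;
  std::vector<double> q(theta0.begin(), theta0.end()), grad;
  double lp = lp_grad(d, q, grad);
  if (!std::isfinite(lp)) stop("initial point has non-finite log posterior");

  // --- step-size heuristic (one-step accept prob ~ 0.5) ---
  {
    std::vector<double> p(dim), q1, g1;
    for (int i = 0; i < dim; ++i) p[i] = norm_rand() / std::sqrt(c.Minv[i]);
    double H0 = -lp + kinetic(c, p);
    double dir = 0.0;
    for (int it = 0; it < 50; ++it) {
      q1 = q; g1 = grad;
      std::vector<double> p1 = p;
      double lp1 = leapfrog(c, q1, p1, g1, 1.0);
      double dH = H0 - (-lp1 + kinetic(c, p1));  // log accept prob
      if (!std::isfinite(dH)) dH = -1e10;
      double want = (dH > std::log(0.5)) ? 1.0 : -1.0;
      if (dir == 0.0) dir = want;
      if (want != dir) break;
      c.eps *= (dir > 0) ? 2.0 : 0.5;
      if (c.eps > 1e3 || c.eps < 1e-8) break;
    }
  }

  // --- dual averaging state ---
  const double da_gamma = 0.05, da_t0 = 10.0, da_kappa = 0.75;
  double mu = std::log(10.0 * c.eps), logeps = std::log(c.eps),
         logeps_bar = 0.0, Hbar = 0.0;
  int da_count = 0;

  // --- warmup windows (Stan-style) ---
  int b_init = 75, b_term = 50, w_first = 25;
  if (iter_warmup < 150) {
    b_init = (int)(0.15 * iter_warmup);
    b_term = (int)(0.10 * iter_warmup);
    w_first = std::max(1, iter_warmup - b_init - b_term);
  }
  std::vector<int> window_ends;
  {
    int start = b_init, w = w_first;
    while (start < iter_warmup - b_term) {
      int end = start + w;
      if (end + 2 * w > iter_warmup - b_term) end = iter_warmup - b_term;
      window_ends.push_back(end);
      start = end; w *= 2;
    }
  }
  std::vector<double> wf_mean(dim, 0.0), wf_m2(dim, 0.0);
  long wf_n = 0;
  size_t win_idx = 0;

  NumericMatrix draws(iter_sampling, dim);
  IntegerVector divergent(iter_sampling), treedepth(iter_sampling);
  NumericVector energy(iter_sampling), lp_out(iter_sampling),
                accept(iter_sampling);
  int warmup_div = 0;

  const int total = iter_warmup + iter_sampling;
  for (int it = 0; it < total; ++it) {
    const bool warm = it < iter_warmup;
    std::vector<double> p(dim);
    for (int i = 0; i < dim; ++i) p[i] = norm_rand() / std::sqrt(c.Minv[i]);
    const double f0 = lp - kinetic(c, p);
    const double H0 = -f0;
    const double logu = f0 - exp_rand();

    std::vector<double> qm = q, pm = p, gm = grad, qp = q, pp = p, gp = grad;
    double lpm = lp, lpp = lp;
    std::vector<double> qprop = q, gprop = grad;
    double lpprop = lp;
    long nvalid = 1;
    bool ok = true, any_div = false;
    int depth = 0;
    double alpha_sum = 0.0; long nalpha = 0;

    while (ok && depth < max_treedepth) {
      const int dir = (unif_rand() < 0.5) ? -1 : 1;
      Tree t;
      if (dir == -1) {
        build_tree(c, qm, pm, gm, lpm, logu, dir, depth, H0, t);
        qm = t.qm; pm = t.pm; gm = t.gm; lpm = t.lpm;
      } else {
        build_tree(c, qp, pp, gp, lpp, logu, dir, depth, H0, t);
        qp = t.qp; pp = t.pp; gp = t.gp; lpp = t.lpp;
      }
      alpha_sum += t.alpha; nalpha += t.nalpha;
      any_div = any_div || t.div;
      if (t.ok && t.n > 0 &&
          unif_rand() < std::min(1.0, (double)t.n / (double)nvalid)) {
        qprop = t.qprop; gprop = t.gprop; lpprop = t.lpprop;
      }
      nvalid += t.n;
      ok = t.ok && no_uturn(c, qm, pm, qp, pp);
      ++depth;
    }
    q = qprop; grad = gprop; lp = lpprop;
    const double astat = (nalpha > 0) ? alpha_sum / nalpha : 0.0;

    if (warm) {
      if (any_div) ++warmup_div;
      // dual averaging
      ++da_count;
      const double eta = 1.0 / (da_count + da_t0);
      Hbar = (1.0 - eta) * Hbar + eta * (adapt_delta - astat);
      logeps = mu - std::sqrt((double)da_count) / da_gamma * Hbar;
      const double xeta = std::pow((double)da_count, -da_kappa);
      logeps_bar = xeta * logeps + (1.0 - xeta) * logeps_bar;
      c.eps = std::exp(logeps);
      // mass-matrix windows
      if (win_idx < window_ends.size() && it >= b_init) {
        ++wf_n;
        for (int i = 0; i < dim; ++i) {
          const double delta = q[i] - wf_mean[i];
          wf_mean[i] += delta / wf_n;
          wf_m2[i] += delta * (q[i] - wf_mean[i]);
        }
        if (it + 1 == window_ends[win_idx]) {
          if (wf_n > 2) {
            for (int i = 0; i < dim; ++i) {
              double var = wf_m2[i] / (wf_n - 1);
              c.Minv[i] = (double)wf_n / (wf_n + 5.0) * var +
                          1e-3 * (5.0 / (wf_n + 5.0));
              if (!(c.Minv[i] > 1e-10)) c.Minv[i] = 1e-10;
            }
          }
          wf_mean.assign(dim, 0.0); wf_m2.assign(dim, 0.0); wf_n = 0;
          ++win_idx;
          // restart step-size adaptation around the current value
          mu = std::log(10.0 * c.eps);
          Hbar = 0.0; logeps_bar = std::log(c.eps); da_count = 0;
        }
      }
      if (it + 1 == iter_warmup) c.eps = std::exp(logeps_bar);
    } else {
      const int s = it - iter_warmup;
      for (int i = 0; i < dim; ++i) draws(s, i) = q[i];
      divergent[s] = any_div ? 1 : 0;
      treedepth[s] = depth;
      energy[s] = H0;
      lp_out[s] = lp;
      accept[s] = astat;
    }
    if (it % 100 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws, _["divergent"] = divergent,
                      _["treedepth"] = treedepth, _["energy"] = energy,
                      _["lp"] = lp_out, _["accept"] = accept,
                      _["step_size"] = c.eps,
                      _["inv_mass"] = NumericVector(c.Minv.begin(), c.Minv.end()),
                      _["warmup_divergences"] = warmup_div);
}

// Map unconstrained draws to the constrained parameter block:
// kappa (K-1), beta (5), zeta_E (DE), zeta_A (DA), zeta_C (DC), sigma (P),
// Omega lower-triangle correlations (P(P-1)/2), u site offsets (P x J).
// [[Rcpp::export]]
NumericMatrix ordlogit_constrain(NumericMatrix theta, List data) {
  ModelData d = unpack(data);
  const int dim = model_dim(d);
  if (theta.ncol() != dim) stop("theta has wrong number of columns");
  const int Km1 = d.K - 1;
  const int o_tk = 0, o_b = o_tk + Km1, o_tE = o_b + 5,
            o_tA = o_tE + d.DE - 1, o_tC = o_tA + d.DA - 1,
            o_ls = o_tC + d.DC - 1, o_w = o_ls + P,
            o_z = o_w + P * (P - 1) / 2;
  const int ncor = P * (P - 1) / 2;
  const int nout = Km1 + 5 + d.DE + d.DA + d.DC + P + ncor + P * d.J;
  NumericMatrix out(theta.nrow(), nout);
  std::vector<double> zE, zA, zC;
  for (int s = 0; s < theta.nrow(); ++s) {
    int o = 0;
    double kap = theta(s, o_tk);
    out(s, o++) = kap;
    for (int k = 1; k < Km1; ++k) { kap += std::exp(theta(s, o_tk + k)); out(s, o++) = kap; }
    for (int qd = 0; qd < 5; ++qd) out(s, o++) = theta(s, o_b + qd);
    std::vector<double> trow(dim);
    for (int i = 0; i < dim; ++i) trow[i] = theta(s, i);
    simplex_constrain(&trow[o_tE], d.DE, zE);
    simplex_constrain(&trow[o_tA], d.DA, zA);
    simplex_constrain(&trow[o_tC], d.DC, zC);
    for (int m = 0; m < d.DE; ++m) out(s, o++) = zE[m];
    for (int m = 0; m < d.DA; ++m) out(s, o++) = zA[m];
    for (int m = 0; m < d.DC; ++m) out(s, o++) = zC[m];
    std::vector<double> sig(P);
    for (int p = 0; p < P; ++p) { sig[p] = std::exp(trow[o_ls + p]); out(s, o++) = sig[p]; }
    // L and Omega = L L^T
    std::vector<double> r(ncor), L(P * P, 0.0);
    for (int m = 0; m < ncor; ++m) r[m] = std::tanh(trow[o_w + m]);
    L[0] = 1.0;
    {
      int m = 0;
      for (int i = 1; i < P; ++i) {
        double prod = 1.0;
        for (int j = 0; j < i; ++j, ++m) {
          L[i * P + j] = r[m] * prod;
          prod *= std::sqrt(1.0 - r[m] * r[m]);
        }
        L[i * P + i] = prod;
      }
    }
    for (int i = 1; i < P; ++i)
      for (int j = 0; j < i; ++j) {
        double acc = 0.0;
        for (int k = 0; k <= j; ++k) acc += L[i * P + k] * L[j * P + k];
        out(s, o++) = acc;
      }
    for (int j = 0; j < d.J; ++j)
      for (int p = 0; p < P; ++p) {
        double acc = 0.0;
        for (int qd = 0; qd <= p; ++qd) acc += L[p * P + qd] * trow[o_z + j * P + qd];
        out(s, o++) = sig[p] * acc;
      }
  }
  return out;
}
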