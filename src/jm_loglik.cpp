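// Joint-model likelihood kernel: shared-parameter model linking a linear
// mixed longitudinal sub-model (shared fixed/random basis) to a
// proportional-hazards sub-model with piecewise-constant baseline hazard
// through the current true biomarker level m_i(t).  The random effects are
// integrated out by adaptive Gauss-Hermite quadrature; the cumulative
// hazard inside the survival density is integrated by fixed Gauss-Legendre
// nodes per baseline-hazard piece (precomputed in R and passed in).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);
static const double EXP_CAP = 500.0;  // exponent clamp against overflow

struct Pat {
  vec y;        // observed log-biomarker values (may be empty)
  mat X;        // basis at observation times, n_i x q
  vec w;        // baseline covariates, p
  int delta;    // event indicator
  vec xT;       // basis at the observed time, q
  int pieceT;   // 0-based baseline-hazard piece containing T_i
  mat Bgl;      // basis at Gauss-Legendre nodes on (0, T_i], G x q
  vec wgl;      // GL weights including segment lengths, G
  uvec pgl;     // 0-based piece index per GL node, G
};

struct Pars {
  vec beta; double alpha; vec gamma; vec logh; double logsig; mat L;
  int q, p, Q;
  double sig2, sumlogL;
  mat Dinv;
};

static std::vector<Pat> parse_list(const Rcpp::List& dat) {
  int n = dat.size();
  std::vector<Pat> out(n);
  for (int i = 0; i < n; ++i) {
    Rcpp::List d = dat[i];
    out[i].y = Rcpp::as<vec>(d["y"]);
    out[i].X = Rcpp::as<mat>(d["X"]);
    out[i].w = Rcpp::as<vec>(d["w"]);
    out[i].delta = Rcpp::as<int>(d["delta"]);
    out[i].xT = Rcpp::as<vec>(d["xT"]);
    out[i].pieceT = Rcpp::as<int>(d["pieceT"]) - 1;
    out[i].Bgl = Rcpp::as<mat>(d["Bgl"]);
    out[i].wgl = Rcpp::as<vec>(d["wgl"]);
    out[i].pgl = Rcpp::as<uvec>(d["pgl"]) - 1;
  }
  return out;
}

// cache the parsed per-patient blocks behind an external pointer so
// repeated likelihood calls skip the R-to-Armadillo conversion
// [[Rcpp::export]]
SEXP jm_cache_cpp(const Rcpp::List& dat) {
  Rcpp::XPtr<std::vector<Pat> > p(new std::vector<Pat>(parse_list(dat)),
                                  true);
  return p;
}

static const std::vector<Pat>& parse_data(SEXP dat,
                                          std::vector<Pat>& scratch) {
  if (TYPEOF(dat) == EXTPTRSXP) {
    Rcpp::XPtr<std::vector<Pat> > p(dat);
    return *p;
  }
  scratch = parse_list(Rcpp::List(dat));
  return scratch;
}

static Pars parse_theta(const vec& th, int q, int p, int Q) {
  Pars pr;
  pr.q = q; pr.p = p; pr.Q = Q;
  pr.beta = th.subvec(0, q - 1);
  pr.alpha = th(q);
  pr.gamma = th.subvec(q + 1, q + p);
  pr.logh = th.subvec(q + p + 1, q + p + Q);
  pr.logsig = th(q + p + Q + 1);
  pr.sig2 = std::exp(2.0 * pr.logsig);
  pr.L = zeros<mat>(q, q);
  int off = q + p + Q + 2;
  // floor keeps the triangular solves finite when the optimizer probes a
  // near-degenerate random-effects covariance
  for (int j = 0; j < q; ++j)
    pr.L(j, j) = std::min(std::max(std::exp(th(off + j)), 1e-10), 1e10);
  off += q;
  for (int k = 0; k < q; ++k)
    for (int j = k + 1; j < q; ++j) pr.L(j, k) = th(off++);
  pr.sumlogL = sum(log(pr.L.diag()));
  mat Linv = solve(trimatl(pr.L), eye<mat>(q, q));
  pr.Dinv = Linv.t() * Linv;
  return pr;
}

static mat cexp(const mat& A) { return exp(clamp(A, -EXP_CAP, EXP_CAP)); }

// log integrand g(b) and its b-derivatives for one patient (mode finding)
static double g_of_b(const Pat& P, const Pars& pr, const vec& b,
                     vec* grad, mat* hess) {
  int q = pr.q;
  vec bb = pr.beta + b;
  double g = 0.0;
  double lpw = dot(pr.gamma, P.w);
  int ni = P.y.n_elem;
  vec r;
  if (ni > 0) {
    r = P.y - P.X * bb;
    g += -ni * pr.logsig - 0.5 * ni * LOG2PI - 0.5 * dot(r, r) / pr.sig2;
  }
  double mT = dot(P.xT, bb);
  if (P.delta) g += pr.logh(P.pieceT) + lpw + pr.alpha * mT;
  vec eta = P.Bgl * bb;
  vec cg = exp(pr.logh(P.pgl)) % P.wgl %
           vectorise(cexp(mat(pr.alpha * eta)));
  double ch = std::exp(std::min(lpw, EXP_CAP)) * accu(cg);
  g += -ch;
  vec u = solve(trimatl(pr.L), b);
  g += -0.5 * q * LOG2PI - pr.sumlogL - 0.5 * dot(u, u);
  if (grad) {
    vec gr = -pr.Dinv * b;
    if (ni > 0) gr += P.X.t() * r / pr.sig2;
    if (P.delta) gr += pr.alpha * P.xT;
    gr -= std::exp(std::min(lpw, EXP_CAP)) * pr.alpha * (P.Bgl.t() * cg);
    *grad = gr;
  }
  if (hess) {
    mat H = -pr.Dinv;
    if (ni > 0) H -= P.X.t() * P.X / pr.sig2;
    H -= std::exp(std::min(lpw, EXP_CAP)) * pr.alpha * pr.alpha *
         (P.Bgl.t() * (P.Bgl.each_col() % cg));
    *hess = H;
  }
  return g;
}

// posterior mode and Cholesky factor of the inverse curvature
static bool find_mode(const Pat& P, const Pars& pr, vec& mu, mat& C,
                      double& logdetC) {
  int q = pr.q;
  vec b = mu;  // warm start
  vec grad; mat hess;
  double g = g_of_b(P, pr, b, &grad, &hess);
  if (!std::isfinite(g)) { b.zeros(); g = g_of_b(P, pr, b, &grad, &hess); }
  for (int it = 0; it < 60; ++it) {
    if (!grad.is_finite() || !hess.is_finite()) return false;
    vec step;
    bool ok = solve(step, -hess, grad, solve_opts::likely_sympd +
                                        solve_opts::no_approx);
    if (!ok) return false;
    double sc = 1.0;
    vec bn; double gn = -datum::inf;
    for (int h = 0; h < 30; ++h) {
      bn = b + sc * step;
      gn = g_of_b(P, pr, bn, nullptr, nullptr);
      if (std::isfinite(gn) && gn >= g - 1e-12) break;
      sc *= 0.5;
    }
    if (!std::isfinite(gn)) return false;
    b = bn;
    double gprev = g;
    g = g_of_b(P, pr, b, &grad, &hess);
    if (norm(grad) < 1e-8 * (1.0 + std::abs(g)) ||
        std::abs(g - gprev) < 1e-12 * (1.0 + std::abs(g))) break;
  }
  g = g_of_b(P, pr, b, &grad, &hess);
  mat A = -hess;
  mat R;
  if (!A.is_finite() || !chol(R, A)) return false;
  if (R.diag().min() <= 0 || !R.is_finite()) return false;
  mu = b;
  if (!solve(C, trimatu(R), eye<mat>(q, q),
             solve_opts::no_approx)) return false;   // C C' = A^{-1}
  logdetC = -sum(log(R.diag()));
  return true;
}

// [[Rcpp::export]]
Rcpp::List jm_modes_cpp(const arma::vec& theta, SEXP dat,
                        int q, int p, int Q, const arma::mat& warm) {
  std::vector<Pat> scratch;
  const std::vector<Pat>& pats = parse_data(dat, scratch);
  Pars pr = parse_theta(theta, q, p, Q);
  int n = pats.size();
  mat modes(n, q, fill::zeros);
  cube Cs(q, q, n, fill::zeros);
  vec ldC(n, fill::zeros);
  ivec ok(n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    vec mu(q, fill::zeros);
    if (warm.n_rows == (unsigned)n) mu = warm.row(i).t();
    mat C; double l;
    if (find_mode(pats[i], pr, mu, C, l)) {
      modes.row(i) = mu.t();
      Cs.slice(i) = C;
      ldC(i) = l;
      ok(i) = 1;
    }
  }
  return Rcpp::List::create(Rcpp::Named("modes") = modes,
                            Rcpp::Named("chols") = Cs,
                            Rcpp::Named("logdetC") = ldC,
                            Rcpp::Named("ok") = ok);
}

// log-likelihood (and analytic gradient) under a frozen quadrature rule
// [[Rcpp::export]]
Rcpp::List jm_loglik_cpp(const arma::vec& theta, SEXP dat,
                         int q, int p, int Q,
                         const arma::mat& Z, const arma::vec& lw,
                         const arma::mat& modes, const arma::cube& chols,
                         const arma::vec& logdetC, bool want_grad) {
  std::vector<Pat> scratch;
  const std::vector<Pat>& pats = parse_data(dat, scratch);
  Pars pr = parse_theta(theta, q, p, Q);
  int n = pats.size(), K = Z.n_rows;
  int npar = theta.n_elem;
  double ll = 0.0;
  vec grad(npar, fill::zeros);
  const double s2 = std::sqrt(2.0);
  int Loff = q + p + Q + 2;
  for (int i = 0; i < n; ++i) {
    const Pat& P = pats[i];
    int ni = P.y.n_elem, G = P.Bgl.n_rows;
    mat C = chols.slice(i);
    mat B = repmat(modes.row(i).t(), 1, K) + s2 * (C * Z.t());  // q x K
    double lpw = dot(pr.gamma, P.w);
    double elpw = std::exp(std::min(lpw, EXP_CAP));
    rowvec gy(K, fill::zeros), rss(K, fill::zeros);
    mat R;
    if (ni > 0) {
      vec r0 = P.y - P.X * pr.beta;
      R = repmat(r0, 1, K) - P.X * B;                           // ni x K
      rss = sum(R % R, 0);
      gy = -ni * pr.logsig - 0.5 * ni * LOG2PI - 0.5 * rss / pr.sig2;
    }
    rowvec mT = P.xT.t() * B + dot(P.xT, pr.beta);
    rowvec gev(K, fill::zeros);
    if (P.delta) gev = pr.logh(P.pieceT) + lpw + pr.alpha * mT;
    vec base_c = exp(pr.logh(P.pgl)) % P.wgl;                   // G
    vec eta0 = P.Bgl * pr.beta;                                 // G
    mat EtaM = P.Bgl * B;                                       // G x K
    EtaM.each_col() += eta0;
    mat Cm = cexp(pr.alpha * EtaM).each_col() % base_c;         // G x K
    rowvec S = sum(Cm, 0);
    rowvec gch = -elpw * S;
    mat U = solve(trimatl(pr.L), B);                            // q x K
    rowvec gb = -0.5 * q * LOG2PI - pr.sumlogL - 0.5 * sum(U % U, 0);
    vec t = lw + (gy + gev + gch + gb).t();
    double mx = t.max();
    if (!std::isfinite(mx)) {
      return Rcpp::List::create(Rcpp::Named("loglik") = -datum::inf,
                                Rcpp::Named("grad") = grad);
    }
    vec e = exp(t - mx);
    double Ei = accu(e);
    ll += 0.5 * q * std::log(2.0) + logdetC(i) + mx + std::log(Ei);
    if (want_grad) {
      vec pk = e / Ei;
      // beta
      vec gbeta(q, fill::zeros);
      if (ni > 0) gbeta += P.X.t() * (R * pk) / pr.sig2;
      if (P.delta) gbeta += pr.alpha * P.xT;
      gbeta -= elpw * pr.alpha * (P.Bgl.t() * (Cm * pk));
      grad.subvec(0, q - 1) += gbeta;
      // alpha
      double ga = 0.0;
      if (P.delta) ga += dot(mT.t(), pk);
      ga -= elpw * dot(sum(Cm % EtaM, 0).t(), pk);
      grad(q) += ga;
      // gamma
      double gscal = (P.delta ? 1.0 : 0.0) - elpw * dot(S.t(), pk);
      grad.subvec(q + 1, q + p) += gscal * P.w;
      // log-heights
      vec hsum(Q, fill::zeros);
      vec Cmp = Cm * pk;                                        // G
      for (int g = 0; g < G; ++g) hsum(P.pgl(g)) += Cmp(g);
      for (int qq = 0; qq < Q; ++qq) {
        double gh = -elpw * hsum(qq);
        if (P.delta && P.pieceT == qq) gh += 1.0;
        grad(q + p + 1 + qq) += gh;
      }
      // log-sigma
      if (ni > 0)
        grad(q + p + Q + 1) += dot((-ni + rss / pr.sig2).t(), pk);
      // Cholesky parameters of D
      mat V = solve(trimatu(pr.L.t()), U);                      // q x K
      mat GL = V * diagmat(pk) * U.t();                         // q x q
      for (int j = 0; j < q; ++j)
        grad(Loff + j) += pr.L(j, j) * GL(j, j) - 1.0;
      int off = Loff + q;
      for (int k = 0; k < q; ++k)
        for (int j = k + 1; j < q; ++j) grad(off++) += GL(j, k);
    }
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                            Rcpp::Named("grad") = grad);
}
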