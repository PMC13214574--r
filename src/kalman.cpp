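// Exact discrete-time machinery for the 2-state volume/change-rate model:
//  - Van Loan augmented-exponential discretization of (F, B(t), Q(t))
//  - covariance Kalman filter (Joseph-form update) and RTS smoother
//  - negative log posterior and structured finite-difference gradient used
//    by the MAP optimizer and the NUTS sampler.
// The state is 2-dimensional throughout, so all inner-loop algebra is
// hand-rolled on doubles; arma is used only for the 4x4/3x3 matrix
// exponentials of the discretization.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double softplus(double x) {
  // numerically stable log(1 + exp(x))
  if (x > 30.0) return x;
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// ---------------------------------------------------------------------------
// Discretization: for time-invariant drift F over a step of length delta,
//   F_star = expm(F delta)
//   m1     = (int_0^delta expm(F s) ds) e2   (unit acceleration-bias gain)
//   M2     = int_0^delta expm(F s) e2 e2' expm(F' s) ds  (unit process noise)
// so that B*_k = b_k m1 and Q*_k = sigma_q^2(t_k) M2 under the zero-order
// hold. Computed with the Van Loan block-exponential construction.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_vanloan_parts")]]
List cpp_vanloan_parts(const arma::mat& F, double delta) {
  if (!F.is_finite() || !std::isfinite(delta))
    stop("non-finite input to discretization");
  // M2 via Van Loan: C = [[-F, N],[0, F']] * delta, N = e2 e2'
  arma::mat C(4, 4, arma::fill::zeros);
  C.submat(0, 0, 1, 1) = -F;
  C(1, 3) = 1.0;              // N = e2 e2'
  C.submat(2, 2, 3, 3) = F.t();
  C *= delta;
  arma::mat E = arma::expmat(C);
  arma::mat F3 = E.submat(2, 2, 3, 3);   // expm(F' delta)
  arma::mat G = E.submat(0, 2, 1, 3);
  arma::mat Fstar = F3.t();
  arma::mat M2 = Fstar * G;
  M2 = 0.5 * (M2 + M2.t());
  // m1 via [[F, e2],[0, 0]]: top-right of the exponential is
  // (int_0^delta expm(F s) ds) e2
  arma::mat A(3, 3, arma::fill::zeros);
  A.submat(0, 0, 1, 1) = F;
  A(1, 2) = 1.0;
  A *= delta;
  arma::mat EA = arma::expmat(A);
  arma::vec m1 = EA.submat(0, 2, 1, 2);
  return List::create(_["F_star"] = Fstar, _["m1"] = m1, _["M2"] = M2);
}

// ---------------------------------------------------------------------------
// Filter / smoother for one subject.
//
// Grid: beliefs live at steps 0..K (ages t0 + k*delta); transitions k -> k+1
// use B_star[k], Q_star[k], k = 0..K-1. Observations: 0-based step index,
// strictly increasing; each carries a site bias and noise variance.
// ---------------------------------------------------------------------------

struct Belief { double m0, m1, s00, s01, s11; };

static inline void sym_propagate(Belief& b, const double* Fs,
                                 const double* Bs, const double* Qs) {
  // mean: mu <- F* mu + B*
  double m0 = Fs[0] * b.m0 + Fs[1] * b.m1 + Bs[0];
  double m1 = Fs[2] * b.m0 + Fs[3] * b.m1 + Bs[1];
  // cov: Sigma <- F* Sigma F*' + Q*
  double a00 = Fs[0] * b.s00 + Fs[1] * b.s01;
  double a01 = Fs[0] * b.s01 + Fs[1] * b.s11;
  double a10 = Fs[2] * b.s00 + Fs[3] * b.s01;
  double a11 = Fs[2] * b.s01 + Fs[3] * b.s11;
  double s00 = a00 * Fs[0] + a01 * Fs[1] + Qs[0];
  double s01 = a00 * Fs[2] + a01 * Fs[3] + Qs[1];
  double s11 = a10 * Fs[2] + a11 * Fs[3] + Qs[2];
  b.m0 = m0; b.m1 = m1; b.s00 = s00; b.s01 = s01; b.s11 = s11;
}

static inline double joseph_update(Belief& b, double y, double bias,
                                   double rvar) {
  // measurement y = s + bias + noise; H = [1 0]
  double S = b.s00 + rvar;
  if (S <= 0.0) S = 1e-300;
  double e = y - (b.m0 + bias);
  double k0 = b.s00 / S, k1 = b.s01 / S;
  b.m0 += k0 * e;
  b.m1 += k1 * e;
  // Joseph form: (I-KH) Sigma (I-KH)' + K R K'
  double a = 1.0 - k0;
  double s00 = a * a * b.s00 + k0 * k0 * rvar;
  double s01 = a * (b.s01 - k1 * b.s00) + k0 * k1 * rvar;
  double s11 = b.s11 - 2.0 * k1 * b.s01 + k1 * k1 * b.s00 + k1 * k1 * rvar;
  b.s00 = s00; b.s01 = s01; b.s11 = s11;
  return -0.5 * (std::log(2.0 * M_PI * S) + e * e / S);
}

// Forward filter; if store != nullptr, record predicted and filtered beliefs
// at every step 0..K. Returns the log marginal likelihood.
static double filter_subject(Belief prior,
                             const double* Fs,
                             const double* Bstar,  // K x 2 column-major
                             const double* Qstar,  // K x 3 column-major
                             int K,
                             const int* steps, const double* y,
                             const double* bias, const double* rvar, int m,
                             int last_step,
                             double* pred, double* filt) {
  // pred/filt are (K+1) x 5 column-major: m0, m1, s00, s01, s11
  double ll = 0.0;
  Belief b = prior;
  int oi = 0;
  int KK = K + 1;
  for (int k = 0; k <= last_step; ++k) {
    if (k > 0) {
      double Bk[2] = { Bstar[k - 1], Bstar[(k - 1) + K] };
      double Qk[3] = { Qstar[k - 1], Qstar[(k - 1) + K], Qstar[(k - 1) + 2 * K] };
      sym_propagate(b, Fs, Bk, Qk);
    }
    if (pred) {
      pred[k] = b.m0; pred[k + KK] = b.m1; pred[k + 2 * KK] = b.s00;
      pred[k + 3 * KK] = b.s01; pred[k + 4 * KK] = b.s11;
    }
    while (oi < m && steps[oi] == k) {
      ll += joseph_update(b, y[oi], bias[oi], rvar[oi]);
      ++oi;
    }
    if (filt) {
      filt[k] = b.m0; filt[k + KK] = b.m1; filt[k + 2 * KK] = b.s00;
      filt[k + 3 * KK] = b.s01; filt[k + 4 * KK] = b.s11;
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".cpp_filter_subject")]]
List cpp_filter_subject(NumericVector mu0, NumericVector Sigma0,
                        NumericVector F_star, NumericMatrix B_star,
                        NumericMatrix Q_star,
                        IntegerVector steps, NumericVector y,
                        NumericVector bias, NumericVector rvar,
                        bool store) {
  int K = B_star.nrow();
  int m = steps.size();
  Belief prior{ mu0[0], mu0[1], Sigma0[0], Sigma0[1], Sigma0[2] };
  double Fs[4] = { F_star[0], F_star[1], F_star[2], F_star[3] };
  NumericMatrix pred, filt;
  double *pp = nullptr, *pf = nullptr;
  if (store) {
    pred = NumericMatrix(K + 1, 5);
    filt = NumericMatrix(K + 1, 5);
    pp = REAL(pred); pf = REAL(filt);
  }
  int last = store ? K : (m > 0 ? steps[m - 1] : 0);
  double ll = filter_subject(prior, Fs, REAL(B_star), REAL(Q_star), K,
                             INTEGER(steps), REAL(y), REAL(bias), REAL(rvar),
                             m, last, pp, pf);
  if (store)
    return List::create(_["loglik"] = ll, _["pred"] = pred, _["filt"] = filt);
  return List::create(_["loglik"] = ll);
}

// RTS backward pass. pred/filt as produced above ((K+1) x 5). Returns
// smoothed beliefs (K+1) x 5.
// [[Rcpp::export(name = ".cpp_rts_smooth")]]
NumericMatrix cpp_rts_smooth(NumericMatrix pred, NumericMatrix filt,
                             NumericVector F_star) {
  int KK = pred.nrow();
  NumericMatrix sm(KK, 5);
  double Fs[4] = { F_star[0], F_star[1], F_star[2], F_star[3] };
  for (int j = 0; j < 5; ++j) sm(KK - 1, j) = filt(KK - 1, j);
  for (int k = KK - 2; k >= 0; --k) {
    double f00 = filt(k, 2), f01 = filt(k, 3), f11 = filt(k, 4);
    double p00 = pred(k + 1, 2), p01 = pred(k + 1, 3), p11 = pred(k + 1, 4);
    // C = Sigma_f F*' P^{-1}
    double A00 = f00 * Fs[0] + f01 * Fs[1];
    double A01 = f00 * Fs[2] + f01 * Fs[3];
    double A10 = f01 * Fs[0] + f11 * Fs[1];
    double A11 = f01 * Fs[2] + f11 * Fs[3];
    double det = p00 * p11 - p01 * p01;
    double C00, C01, C10, C11;
    double scale = std::max(std::max(std::abs(p00), std::abs(p11)), 1.0);
    if (std::abs(det) < 1e-300 * scale * scale) {
      // degenerate predicted covariance: no information flows backward
      C00 = C01 = C10 = C11 = 0.0;
    } else {
      double i00 = p11 / det, i01 = -p01 / det, i11 = p00 / det;
      C00 = A00 * i00 + A01 * i01;
      C01 = A00 * i01 + A01 * i11;
      C10 = A10 * i00 + A11 * i01;
      C11 = A10 * i01 + A11 * i11;
    }
    double dm0 = sm(k + 1, 0) - pred(k + 1, 0);
    double dm1 = sm(k + 1, 1) - pred(k + 1, 1);
    sm(k, 0) = filt(k, 0) + C00 * dm0 + C01 * dm1;
    sm(k, 1) = filt(k, 1) + C10 * dm0 + C11 * dm1;
    double d00 = sm(k + 1, 2) - p00, d01 = sm(k + 1, 3) - p01,
           d11 = sm(k + 1, 4) - p11;
    // Sigma_s = Sigma_f + C D C'
    double t00 = C00 * d00 + C01 * d01, t01 = C00 * d01 + C01 * d11;
    double u00 = C10 * d00 + C11 * d01, u01 = C10 * d01 + C11 * d11;
    sm(k, 2) = f00 + t00 * C00 + t01 * C01;
    sm(k, 3) = f01 + t00 * C10 + t01 * C11;
    sm(k, 4) = f11 + u00 * C10 + u01 * C11;
  }
  return sm;
}

// ---------------------------------------------------------------------------
// Fit objective. Unconstrained parameter vector theta (J sites):
//   [0] u_fs, [1] u_fv                (softplus -> fs, fv)
//   [2..6]  b spline control values   (mm^3/yr^2, unconstrained)
//   [7..11] q spline control values   (softplus -> sigma_q(t))
//   [12..17] beta_s0, beta_s0_sex, beta_s0_icv, beta_v0, beta_v0_sex, beta_v0_icv
//   [18..20] log-Cholesky of Sigma_z0: l11, l21, l22 (diag on log scale)
//   [21..21+J-2]    J-1 free site biases (last = -sum)
//   [21+J-1..20+2J] u_sr per site     (softplus -> sigma_r)
// pack (R list, built once per dataset):
//   W        (K+1) x 5 spline basis over grid ages
//   K        number of transition steps
//   delta    step length (years)
//   subj_ptr S+1 0-based offsets into observation arrays
//   obs_step, obs_y, obs_site (0-based)
//   sex, icv per subject
//   n_sites
//   prior_mean, prior_sd  per-theta Gaussian prior on the unconstrained scale
// ---------------------------------------------------------------------------

struct Pack {
  const double* W; int Wrows;
  int K; double delta;
  const int* subj_ptr; int S;
  const int* obs_step; const double* obs_y; const int* obs_site; int n_obs;
  const double* sex; const double* icv;
  int J;
  const double* p_mean; const double* p_sd; int npar;
};

static Pack unpack(const List& pack) {
  Pack p;
  NumericMatrix W = pack["W"];
  p.W = REAL(W); p.Wrows = W.nrow();
  p.K = as<int>(pack["K"]);
  p.delta = as<double>(pack["delta"]);
  IntegerVector sp = pack["subj_ptr"];
  p.subj_ptr = INTEGER(sp); p.S = sp.size() - 1;
  IntegerVector os = pack["obs_step"];
  p.obs_step = INTEGER(os); p.n_obs = os.size();
  NumericVector oy = pack["obs_y"]; p.obs_y = REAL(oy);
  IntegerVector osi = pack["obs_site"]; p.obs_site = INTEGER(osi);
  NumericVector sx = pack["sex"]; p.sex = REAL(sx);
  NumericVector ic = pack["icv"]; p.icv = REAL(ic);
  p.J = as<int>(pack["n_sites"]);
  NumericVector pm = pack["prior_mean"]; p.p_mean = REAL(pm);
  NumericVector ps = pack["prior_sd"]; p.p_sd = REAL(ps); p.npar = pm.size();
  return p;
}

// log posterior given precomputed discretization parts for (fs, fv)
static double log_post_given_parts(const double* th, const Pack& p,
                                   const double* Fs, const double* m1,
                                   const double* M2) {
  int K = p.K, J = p.J;
  // per-step inputs from the splines (left-endpoint zero-order hold)
  std::vector<double> Bst(2 * K), Qst(3 * K);
  for (int k = 0; k < K; ++k) {
    double b = 0.0, u = 0.0;
    for (int j = 0; j < 5; ++j) {
      b += p.W[k + j * p.Wrows] * th[2 + j];
      u += p.W[k + j * p.Wrows] * th[7 + j];
    }
    double sq = softplus(u);
    double qv = sq * sq;
    Bst[k] = b * m1[0]; Bst[k + K] = b * m1[1];
    Qst[k] = qv * M2[0]; Qst[k + K] = qv * M2[1]; Qst[k + 2 * K] = qv * M2[2];
  }
  // site parameters
  std::vector<double> sbias(J), srvar(J);
  double last = 0.0;
  for (int j = 0; j < J - 1; ++j) { sbias[j] = th[21 + j]; last -= th[21 + j]; }
  sbias[J - 1] = (J >= 1) ? last : 0.0;
  if (J == 1) sbias[0] = 0.0;
  for (int j = 0; j < J; ++j) {
    double sr = softplus(th[21 + (J - 1) + j]);
    srvar[j] = sr * sr;
  }
  double l11 = std::exp(th[18]), l21 = th[19], l22 = std::exp(th[20]);
  double s00 = l11 * l11, s01 = l11 * l21, s11 = l21 * l21 + l22 * l22;
  double ll = 0.0;
  std::vector<double> ob(16), obias(16), orvar(16); // small scratch grown below
  for (int s = 0; s < p.S; ++s) {
    int lo = p.subj_ptr[s], hi = p.subj_ptr[s + 1];
    int m = hi - lo;
    if (m == 0) continue;
    Belief prior;
    prior.m0 = th[12] + th[13] * p.sex[s] + th[14] * p.icv[s];
    prior.m1 = th[15] + th[16] * p.sex[s] + th[17] * p.icv[s];
    prior.s00 = s00; prior.s01 = s01; prior.s11 = s11;
    if ((int)obias.size() < m) { obias.resize(m); orvar.resize(m); }
    for (int i = 0; i < m; ++i) {
      int site = p.obs_site[lo + i];
      obias[i] = sbias[site];
      orvar[i] = srvar[site];
    }
    ll += filter_subject(prior, Fs, Bst.data(), Qst.data(), K,
                         p.obs_step + lo, p.obs_y + lo, obias.data(),
                         orvar.data(), m, p.obs_step[hi - 1], nullptr, nullptr);
  }
  // Gaussian prior on the unconstrained scale
  for (int i = 0; i < p.npar; ++i) {
    double z = (th[i] - p.p_mean[i]) / p.p_sd[i];
    ll += -0.5 * z * z - std::log(p.p_sd[i]) - 0.5 * std::log(2.0 * M_PI);
  }
  return ll;
}

static void feedback_parts(const double* th, double delta,
                           double* Fs, double* m1, double* M2) {
  double fs = softplus(th[0]), fv = softplus(th[1]);
  if (fs > 1e6 || fv > 1e6) { // expm would overflow; flag as non-finite
    for (int i = 0; i < 4; ++i) Fs[i] = NA_REAL;
    m1[0] = m1[1] = NA_REAL; M2[0] = M2[1] = M2[2] = NA_REAL;
    return;
  }
  arma::mat F = { {0.0, 1.0}, {-fs, -fv} };
  List parts = cpp_vanloan_parts(F, delta);
  arma::mat Fstar = parts["F_star"];
  arma::vec mm1 = parts["m1"];
  arma::mat MM2 = parts["M2"];
  Fs[0] = Fstar(0, 0); Fs[1] = Fstar(0, 1); Fs[2] = Fstar(1, 0); Fs[3] = Fstar(1, 1);
  m1[0] = mm1(0); m1[1] = mm1(1);
  M2[0] = MM2(0, 0); M2[1] = MM2(0, 1); M2[2] = MM2(1, 1);
}

static bool finite4(const double* x, int n) {
  for (int i = 0; i < n; ++i) if (!std::isfinite(x[i])) return false;
  return true;
}

// [[Rcpp::export(name = ".cpp_log_post")]]
double cpp_log_post(NumericVector theta, List pack) {
  Pack p = unpack(pack);
  if (!finite4(REAL(theta), theta.size()))
    return -std::numeric_limits<double>::infinity();
  double Fs[4], m1[2], M2[3];
  feedback_parts(REAL(theta), p.delta, Fs, m1, M2);
  if (!finite4(Fs, 4) || !finite4(m1, 2) || !finite4(M2, 3))
    return -std::numeric_limits<double>::infinity();
  double ll = log_post_given_parts(REAL(theta), p, Fs, m1, M2);
  if (std::isnan(ll)) ll = -std::numeric_limits<double>::infinity();
  return ll;
}

// Central finite-difference gradient; the Van Loan discretization depends
// only on theta[0:1], so it is recomputed only for those two coordinates.
// [[Rcpp::export(name = ".cpp_log_post_grad")]]
NumericVector cpp_log_post_grad(NumericVector theta, List pack, double eps) {
  Pack p = unpack(pack);
  int n = theta.size();
  NumericVector g(n);
  if (!finite4(REAL(theta), n)) return g;  // zero gradient off-support
  std::vector<double> th(REAL(theta), REAL(theta) + n);
  double Fs[4], m1[2], M2[3];
  feedback_parts(th.data(), p.delta, Fs, m1, M2);
  if (!finite4(Fs, 4)) return g;
  for (int i = 0; i < n; ++i) {
    double h = eps * std::max(1.0, std::abs(th[i]));
    double orig = th[i];
    double fp, fm;
    if (i < 2) {
      double Fs2[4], m12[2], M22[3];
      th[i] = orig + h;
      feedback_parts(th.data(), p.delta, Fs2, m12, M22);
      fp = log_post_given_parts(th.data(), p, Fs2, m12, M22);
      th[i] = orig - h;
      feedback_parts(th.data(), p.delta, Fs2, m12, M22);
      fm = log_post_given_parts(th.data(), p, Fs2, m12, M22);
    } else {
      th[i] = orig + h;
      fp = log_post_given_parts(th.data(), p, Fs, m1, M2);
      th[i] = orig - h;
      fm = log_post_given_parts(th.data(), p, Fs, m1, M2);
    }
    th[i] = orig;
    double gi = (fp - fm) / (2.0 * h);
    g[i] = std::isfinite(gi) ? gi : 0.0;
  }
  return g;
}
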