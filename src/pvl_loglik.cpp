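#include <Rcpp.h>
using namespace Rcpp;

// Prospect utility of a net outcome x under outcome sensitivity A and loss
// aversion w.  x == 0 is defined to have utility 0 for every A in [0,1]
// (continuity from below), which also sidesteps pow(0, 0) == 1.
static inline double prospect_utility(double x, double A, double w) {
  if (x == 0.0) return 0.0;
  if (x > 0.0) return std::pow(x, A);
  return -w * std::pow(-x, A);
}

// Log-likelihood of each participant's choice sequence under the PVL-Delta
// model.  Trial 1 is uniform over the four decks (contributes log 1/4); the
// choice on trial t >= 2 follows a softmax over expected utilities built from
// the observed outcomes of trials 1..t-1 with the delta learning rule.
// Indexed fast path used by the sampler: the IGT payoff schedule produces
// only a handful of distinct net outcomes, so per-participant utilities are
// computed once per distinct value (netidx maps each trial to 1..K in vals).
// [[Rcpp::export]]
NumericVector pvl_loglik_idx_cpp(NumericMatrix par, IntegerMatrix choice,
                                 IntegerMatrix netidx, NumericVector vals) {
  const int N = par.nrow();
  const int T = choice.nrow();
  const int K = vals.size();
  if (choice.ncol() != N || netidx.ncol() != N || netidx.nrow() != T)
    stop("dimension mismatch");
  std::vector<double> uval(K);
  NumericVector ll(N);
  for (int i = 0; i < N; ++i) {
    const double A = par(i, 0), w = par(i, 1), a = par(i, 2), c = par(i, 3);
    const double theta = std::pow(3.0, c) - 1.0;
    for (int v = 0; v < K; ++v) uval[v] = prospect_utility(vals[v], A, w);
    double Ev[4] = {0.0, 0.0, 0.0, 0.0};
    // incremental softmax state: E[j] = theta*Ev[j], e[j] = exp(E[j] - base);
    // only the chosen deck's term changes per trial, so one exp suffices,
    // with an occasional rebase to keep the terms in range
    double E[4] = {0.0, 0.0, 0.0, 0.0};
    double e[4] = {1.0, 1.0, 1.0, 1.0};
    double base = 0.0;
    double s = -std::log(4.0);
    for (int t = 0; t < T; ++t) {
      const int k = choice(t, i) - 1;
      if (t > 0) {
        double S = e[0] + e[1] + e[2] + e[3];
        if (S < 1e-280) { // all terms far below the stale base: rebase
          base = std::max(std::max(E[0], E[1]), std::max(E[2], E[3]));
          for (int j = 0; j < 4; ++j) e[j] = std::exp(E[j] - base);
          S = e[0] + e[1] + e[2] + e[3];
        }
        s += E[k] - base - std::log(S);
      }
      const double u = uval[netidx(t, i) - 1];
      Ev[k] += a * (u - Ev[k]);
      E[k] = theta * Ev[k];
      const double d = E[k] - base;
      if (d > 40.0) {
        base = std::max(std::max(E[0], E[1]), std::max(E[2], E[3]));
        for (int j = 0; j < 4; ++j) e[j] = std::exp(E[j] - base);
      } else {
        e[k] = std::exp(d);
      }
    }
    ll[i] = s;
  }
  return ll;
}

// Single-participant log-likelihood with utility memoization over the K
// distinct net outcomes; p4 = (A, w, a, c).
static double pvl_ll_one(const double *p4, const int *choice_i,
                         const int *netidx_i, const double *vals, int K,
                         int T, double *uval) {
  const double A = p4[0], w = p4[1], a = p4[2], c = p4[3];
  const double theta = std::pow(3.0, c) - 1.0;
  for (int v = 0; v < K; ++v) uval[v] = prospect_utility(vals[v], A, w);
  double Ev[4] = {0.0, 0.0, 0.0, 0.0};
  double E[4] = {0.0, 0.0, 0.0, 0.0};
  double e[4] = {1.0, 1.0, 1.0, 1.0};
  double base = 0.0;
  double s = -std::log(4.0);
  for (int t = 0; t < T; ++t) {
    const int k = choice_i[t] - 1;
    if (t > 0) {
      double S = e[0] + e[1] + e[2] + e[3];
      if (S < 1e-280) {
        base = std::max(std::max(E[0], E[1]), std::max(E[2], E[3]));
        for (int j = 0; j < 4; ++j) e[j] = std::exp(E[j] - base);
        S = e[0] + e[1] + e[2] + e[3];
      }
      s += E[k] - base - std::log(S);
    }
    const double u = uval[netidx_i[t] - 1];
    Ev[k] += a * (u - Ev[k]);
    E[k] = theta * Ev[k];
    const double d = E[k] - base;
    if (d > 40.0) {
      base = std::max(std::max(E[0], E[1]), std::max(E[2], E[3]));
      for (int j = 0; j < 4; ++j) e[j] = std::exp(E[j] - base);
    } else {
      e[k] = std::exp(d);
    }
  }
  return s;
}

// Joint adaptive Metropolis update of each participant's 4-vector of
// probit-scale parameters: one proposal per participant from a learned
// per-participant covariance (packed lower-triangular Cholesky factors in
// Lpack, one row of 16 column-major entries per participant) times a scalar
// step. One likelihood recursion per participant per call. zp, nat, ll and
// acc are updated in place; proposals consume R's RNG.
// [[Rcpp::export]]
void pvl_zp_joint_cpp(NumericMatrix zp, NumericMatrix nat, NumericVector ll,
                      NumericMatrix Lpack, NumericVector step,
                      IntegerMatrix choice, IntegerMatrix netidx,
                      NumericVector vals, NumericMatrix mean_mat,
                      NumericVector sigma2, NumericVector bounds,
                      NumericVector acc) {
  const int N = zp.nrow(), J = zp.ncol(), T = choice.nrow(), K = vals.size();
  std::vector<double> uval(K);
  double sd[4], prop[4], natp[4];
  for (int j = 0; j < J; ++j) sd[j] = std::sqrt(sigma2[j]);
  for (int i = 0; i < N; ++i) {
    double z4[4];
    for (int q = 0; q < J; ++q) z4[q] = norm_rand();
    double logr = 0.0;
    for (int q = 0; q < J; ++q) {
      double e = 0.0;
      for (int r = 0; r <= q; ++r) e += Lpack(i, q + 4 * r) * z4[r];
      prop[q] = zp(i, q) + step[i] * e;
      natp[q] = bounds[q] * R::pnorm(prop[q], 0.0, 1.0, 1, 0);
      logr += R::dnorm(prop[q], mean_mat(i, q), sd[q], 1) -
        R::dnorm(zp(i, q), mean_mat(i, q), sd[q], 1);
    }
    const double llp = pvl_ll_one(natp, &choice(0, i), &netidx(0, i),
                                  vals.begin(), K, T, uval.data());
    if (std::log(unif_rand()) < llp - ll[i] + logr) {
      for (int q = 0; q < J; ++q) { zp(i, q) = prop[q]; nat(i, q) = natp[q]; }
      ll[i] = llp;
      acc[i] += 1.0;
    }
  }
}

// Log-likelihood of all participants with one probit-scale column replaced:
// used by the translation and scale moves without copying matrices in R.
// [[Rcpp::export]]
NumericVector pvl_loglik_col_cpp(NumericMatrix nat, int col,
                                 NumericVector nat_col, IntegerMatrix choice,
                                 IntegerMatrix netidx, NumericVector vals) {
  const int N = nat.nrow(), T = choice.nrow(), K = vals.size();
  std::vector<double> uval(K);
  std::vector<double> p4(4);
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    for (int q = 0; q < 4; ++q) p4[q] = nat(i, q);
    p4[col - 1] = nat_col[i];
    out[i] = pvl_ll_one(p4.data(), &choice(0, i), &netidx(0, i),
                        vals.begin(), K, T, uval.data());
  }
  return out;
}

// Reference implementation on raw net-outcome matrices (full max-shifted
// softmax every trial); the fast paths above are tested against it.
// par:    N x 4 matrix of natural-scale parameters (A, w, a, c) per row.
// choice: T x N matrix of deck indices in 1..4, one column per participant.
// net:    T x N matrix of net outcomes (win + loss) actually observed.
// [[Rcpp::export]]
NumericVector pvl_loglik_cpp(NumericMatrix par, IntegerMatrix choice,
                             NumericMatrix net) {
  const int N = par.nrow();
  const int T = choice.nrow();
  if (choice.ncol() != N || net.ncol() != N || net.nrow() != T)
    stop("dimension mismatch between parameters, choices and outcomes");
  NumericVector ll(N);
  for (int i = 0; i < N; ++i) {
    const double A = par(i, 0), w = par(i, 1), a = par(i, 2), c = par(i, 3);
    const double theta = std::pow(3.0, c) - 1.0;
    double Ev[4] = {0.0, 0.0, 0.0, 0.0};
    double s = -std::log(4.0); // trial 1: uniform first choice
    for (int t = 0; t < T; ++t) {
      const int k = choice(t, i) - 1;
      if (k < 0 || k > 3) stop("deck index out of range");
      if (t > 0) {
        // softmax log-probability of the observed choice, max-shifted
        double m = theta * Ev[0];
        for (int j = 1; j < 4; ++j) m = std::max(m, theta * Ev[j]);
        double z = 0.0;
        for (int j = 0; j < 4; ++j) z += std::exp(theta * Ev[j] - m);
        s += theta * Ev[k] - m - std::log(z);
      }
      const double u = prospect_utility(net(t, i), A, w);
      Ev[k] += a * (u - Ev[k]);
    }
    ll[i] = s;
  }
  return ll;
}
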