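#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Exact (Doob-Gillespie) simulation of the summed ensemble count vector
// n(t) of Nch independent channels. State = count vector, reaction
// propensities n_j * K(i,j); equivalent to Nch independent channels but
// O(events) instead of O(Nch * events).
//
// Klist : list of M x M rate matrices (s^-1), one per protocol segment,
//         convention K(i,j) = rate j -> i, off-diagonals >= 0.
// seg_end : cumulative segment end times (s), length = #segments.
// grid  : strictly increasing sample times in [0, seg_end.back()].
// n0    : initial count vector (sums to Nch).
// Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
arma::imat gillespie_core(List Klist, const arma::vec& seg_end,
                          const arma::vec& grid, const arma::ivec& n0) {
  const int M = n0.n_elem;
  const int G = grid.n_elem;
  arma::ivec n = n0;
  arma::imat out(M, G);
  double t = 0.0;
  int g = 0;
  RNGScope scope;

  for (unsigned int s = 0; s < seg_end.n_elem; ++s) {
    arma::mat K = as<arma::mat>(Klist[s]);
    const double tend = seg_end[s];
    for (;;) {
      // total propensity of all off-diagonal reactions
      double a0 = 0.0;
      for (int j = 0; j < M; ++j) {
        if (n[j] == 0) continue;
        for (int i = 0; i < M; ++i)
          if (i != j) a0 += n[j] * K(i, j);
      }
      if (a0 > 1e12)
        stop("propensity overflow: expected waiting time < 1e-12 s");
      double tnext = (a0 <= 0.0) ? tend : t - std::log(unif_rand()) / a0;
      if (tnext >= tend) {
        while (g < G && grid[g] < tend) { out.col(g) = n; ++g; }
        t = tend;  // concentration jump: instantaneous, state carries over
        break;
      }
      while (g < G && grid[g] < tnext) { out.col(g) = n; ++g; }
      t = tnext;
      // pick reaction j -> i
      double u = unif_rand() * a0, acc = 0.0;
      int ri = -1, rj = -1;
      for (int j = 0; j < M && ri < 0; ++j) {
        if (n[j] == 0) continue;
        for (int i = 0; i < M; ++i) {
          if (i == j) continue;
          acc += n[j] * K(i, j);
          if (u <= acc) { ri = i; rj = j; break; }
        }
      }
      if (ri < 0) { ri = M - 1; rj = M - 1; continue; }  // numerical guard
      n[rj] -= 1;
      n[ri] += 1;
    }
  }
  while (g < G) { out.col(g) = n; ++g; }  // grid points at/after final time
  return out;
}

// One Cholesky-based multivariate-normal log density with jitter
// escalation (1e-10 -> 1e-6 relative to trace), mirroring the R-level
// innovation contract.
static double dmvn_chol(const arma::vec& r, arma::mat S, int* njit) {
  arma::mat L;
  double tr = arma::trace(S);
  if (tr <= 0) tr = 1.0;
  double jit = 0.0;
  for (int k = 0; k < 3; ++k) {
    if (arma::chol(L, S + jit * arma::eye(S.n_rows, S.n_cols), "lower"))
      break;
    jit = (jit == 0.0) ? 1e-10 * tr : jit * 1e2;
    if (njit) ++(*njit);
    L.reset();
  }
  if (L.n_rows == 0)
    stop("innovation covariance not positive definite");
  arma::vec z = arma::solve(arma::trimatl(L), r);
  double logdet = 2.0 * arma::accu(arma::log(L.diag()));
  const double l2pi = 1.837877066409345;  // log(2*pi)
  return -0.5 * (r.n_elem * l2pi + logdet + arma::dot(z, z));
}

// Project a symmetric matrix onto the PSD cone (eigenvalue clipping)
// when its smallest eigenvalue falls below -1e-8 * trace.  The process
// noise Q(T, n) is PSD only for n >= 0; posterior means may go
// slightly negative at low occupancy (they are moments, not
// probabilities), so P needs an occasional projection.
static bool psd_project(arma::mat& P) {
  double tr = std::max(arma::trace(P), 1e-300);
  arma::vec ev;
  arma::mat V;
  if (!arma::eig_sym(ev, V, P)) return false;
  if (ev.min() >= -1e-8 * tr) return false;
  ev.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  P = V * arma::diagmat(ev) * V.t();
  P = 0.5 * (P + P.t());
  return true;
}

// Generalized Kalman filter for one trace.
//
// y       : N x nobs observations (row t = sample t).
// seg     : integer vector length N; seg[t] = index (1-based) into Tlist
//           of the transition matrix propagating sample t-1 -> t
//           (seg[0] unused).
// Tlist   : list of M x M column-stochastic transition matrices.
// H       : nobs x M observation matrix.
// n0, P0  : equilibrium initial moments.
// wopen   : length-M conducting weights (n_open = wopen . n).
// flu_row, cur_row : 1-based row indices of the fluorescence / current
//           observable in y and H, or 0 if absent.
// noise   : (sigma_m2, sigma_op2, sigma_back2).
// The first sample only conditions the state (Bayesian update without a
// likelihood contribution); samples 2..N contribute log N(y | H nbar,
// H P H' + Sigma(nbar)).
// [[Rcpp::export]]
List kf_core(const arma::mat& y, const arma::ivec& seg, List Tlist,
             const arma::mat& H, const arma::vec& n0, const arma::mat& P0,
             const arma::vec& wopen, int flu_row, int cur_row,
             const arma::vec& noise, bool return_pred = false) {
  const int N = y.n_rows;
  const int nobs = y.n_cols;
  std::vector<arma::mat> Ts(Tlist.size());
  for (int s = 0; s < Tlist.size(); ++s) Ts[s] = as<arma::mat>(Tlist[s]);

  arma::vec n = n0;
  arma::mat P = P0;
  double ll = 0.0;
  int njit = 0, nproj = 0;
  arma::mat pred_mean, pred_sd;
  if (return_pred) { pred_mean.set_size(N, nobs); pred_sd.set_size(N, nobs); }

  for (int t = 0; t < N; ++t) {
    if (t > 0) {
      const arma::mat& T = Ts[seg[t] - 1];
      arma::vec Tn = T * n;
      P = arma::diagmat(Tn) - T * arma::diagmat(n) * T.t() + T * P * T.t();
      P = 0.5 * (P + P.t());
      if (psd_project(P)) ++nproj;
      n = Tn;
    }
    // state-dependent observation covariance at the prior mean
    arma::vec sig(nobs, arma::fill::zeros);
    if (cur_row > 0) {
      double nop = arma::dot(wopen, n);
      sig[cur_row - 1] = noise[0] + noise[1] * std::max(nop, 0.0);
    }
    if (flu_row > 0) {
      double mflu = arma::dot(H.row(flu_row - 1).t(), n);
      sig[flu_row - 1] = noise[2] + std::max(mflu, 0.0);
    }
    arma::mat S = H * P * H.t() + arma::diagmat(sig);
    S = 0.5 * (S + S.t());
    arma::vec r = y.row(t).t() - H * n;
    if (return_pred) {
      pred_mean.row(t) = (H * n).t();
      pred_sd.row(t) = arma::sqrt(S.diag()).t();
    }
    if (t > 0) ll += dmvn_chol(r, S, &njit);
    // correction (Bayesian update): K = P H' S^-1
    arma::mat Kk = arma::solve(S, H * P).t();
    n += Kk * r;
    P -= Kk * S * Kk.t();
    P = 0.5 * (P + P.t());
    if (psd_project(P)) ++nproj;
  }
  List out = List::create(_["loglik"] = ll, _["n_jitter"] = njit,
                          _["n_psd_proj"] = nproj,
                          _["n"] = n, _["P"] = P);
  if (return_pred) { out["pred_mean"] = pred_mean; out["pred_sd"] = pred_sd; }
  return out;
}
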