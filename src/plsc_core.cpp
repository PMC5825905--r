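// Hot path of the estimator: Mode A weight iteration and the consistent
// (disattenuated) correlation matrix, called thousands of times per
// Monte Carlo cell. Mirrors the contracts of the R-level wrappers in
// R/pls_engine.R and R/plsc.R.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static std::vector<uvec> as_index_list(const Rcpp::List& x) {
  std::vector<uvec> out;
  out.reserve(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    Rcpp::IntegerVector v(x[i]);
    uvec u(v.size());
    for (R_xlen_t j = 0; j < v.size(); ++j) u[j] = (uword)v[j];
    out.push_back(u);
  }
  return out;
}

// Normalize each weight column to unit composite variance with the positive
// weight-sum sign convention (tie broken by the first weight's sign).
// Returns false on a degenerate (nonpositive / nonfinite) composite variance.
static bool normalize_cols(mat& W, const mat& S,
                           const std::vector<uvec>& blk) {
  const uword L = W.n_cols;
  for (uword j = 0; j < L; ++j) {
    const uvec& idx = blk[j];
    vec w = W(idx, uvec{j});
    double v = as_scalar(w.t() * S(idx, idx) * w);
    if (!std::isfinite(v) || v <= 0.0) return false;
    double s = accu(w);
    double sgn = (s < 0.0 || (s == 0.0 && w[0] < 0.0)) ? -1.0 : 1.0;
    W(idx, uvec{j}) = w * (sgn / std::sqrt(v));
  }
  return true;
}

// Mode A fixed point under the path (0), centroid (1) or factorial (2)
// inner weighting scheme. status: 0 ok, 1 not converged, 2 degenerate.
static int weights_core(const mat& S, const std::vector<uvec>& blk,
                        const std::vector<uvec>& par,
                        const std::vector<uvec>& chd, int scheme, double tol,
                        int max_iter, const vec& w_start, mat& W, int& iters) {
  const uword p = S.n_rows, L = blk.size();
  W.zeros(p, L);
  uword pos = 0;
  for (uword j = 0; j < L; ++j) {
    for (uword k = 0; k < blk[j].n_elem; ++k) W(blk[j][k], j) = w_start[pos++];
  }
  if (!normalize_cols(W, S, blk)) return 2;
  iters = 0;
  mat T1, C, E(L, L), T2, Wnew(p, L);
  while (iters < max_iter) {
    ++iters;
    T1 = S * W;
    C = W.t() * T1;
    E.zeros();
    for (uword j = 0; j < L; ++j) {
      const uvec& pa = par[j];
      const uvec& ch = chd[j];
      if (scheme == 0) {
        if (pa.n_elem > 0) {
          vec ej;
          if (!solve(ej, C(pa, pa), C(pa, uvec{j}))) return 2;
          E(pa, uvec{j}) = ej;
        }
        for (uword k = 0; k < ch.n_elem; ++k) E(ch[k], j) = C(ch[k], j);
      } else {
        uvec nb = join_cols(pa, ch);
        for (uword k = 0; k < nb.n_elem; ++k) {
          double c = C(nb[k], j);
          E(nb[k], j) = (scheme == 1) ? ((c > 0) - (c < 0)) : c;
        }
      }
    }
    T2 = T1 * E;
    Wnew.zeros();
    for (uword j = 0; j < L; ++j)
      Wnew(blk[j], uvec{j}) = T2(blk[j], uvec{j});
    if (!normalize_cols(Wnew, S, blk)) return 2;
    double delta = abs(Wnew - W).max();
    W = Wnew;
    if (delta < tol) return 0;
  }
  return 1;
}

static vec start_vector(const std::vector<uvec>& blk,
                        Rcpp::Nullable<Rcpp::NumericVector> w_init) {
  uword total = 0;
  for (const uvec& b : blk) total += b.n_elem;
  if (w_init.isNotNull()) {
    Rcpp::NumericVector wi(w_init);
    vec out(wi.begin(), wi.size());
    return out;
  }
  return vec(total, fill::ones);
}

// [[Rcpp::export]]
Rcpp::List cpp_pls_weights(const arma::mat& S, const Rcpp::List& blocks,
                           const Rcpp::List& parents, const Rcpp::List& children,
                           int scheme, double tol, int max_iter,
                           Rcpp::Nullable<Rcpp::NumericVector> w_init) {
  std::vector<uvec> blk = as_index_list(blocks);
  std::vector<uvec> par = as_index_list(parents);
  std::vector<uvec> chd = as_index_list(children);
  mat W;
  int iters = 0;
  int status = weights_core(S, blk, par, chd, scheme, tol, max_iter,
                            start_vector(blk, w_init), W, iters);
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("status") = status);
}

// Steps 1-2: weights, rho_A per block, composite (proxy) correlations, and
// the disattenuated latent correlation matrix with its smallest eigenvalue.
// When rho_fixed is supplied (e.g. full-sample reliabilities reused across
// bootstrap resamples), it replaces the rho_A estimation step.
// [[Rcpp::export]]
Rcpp::List cpp_consistent_core(const arma::mat& S, const Rcpp::List& blocks,
                               const Rcpp::List& parents,
                               const Rcpp::List& children, int scheme,
                               double tol, int max_iter,
                               Rcpp::Nullable<Rcpp::NumericVector> w_init,
                               Rcpp::Nullable<Rcpp::NumericVector> rho_fixed,
                               bool clamp_r) {
  std::vector<uvec> blk = as_index_list(blocks);
  std::vector<uvec> par = as_index_list(parents);
  std::vector<uvec> chd = as_index_list(children);
  mat W;
  int iters = 0;
  int status = weights_core(S, blk, par, chd, scheme, tol, max_iter,
                            start_vector(blk, w_init), W, iters);
  if (status != 0)
    return Rcpp::List::create(Rcpp::Named("status") = status,
                              Rcpp::Named("iterations") = iters,
                              Rcpp::Named("W") = W);
  const uword L = blk.size();
  vec rho(L);
  if (rho_fixed.isNotNull()) {
    Rcpp::NumericVector rf(rho_fixed);
    rho = vec(rf.begin(), rf.size());
  } else {
    // composite variance is 1 by normalization, so the numerator quadratic
    // form of rho_A reduces to 1 - sum_i w_i^2 S_ii
    for (uword j = 0; j < L; ++j) {
      vec w = W(blk[j], uvec{j});
      double ww = dot(w, w);
      double wd = 0.0;
      for (uword k = 0; k < blk[j].n_elem; ++k)
        wd += w[k] * w[k] * S(blk[j][k], blk[j][k]);
      double den = ww * ww - accu(pow(w, 4));
      rho[j] = ww * ww * (1.0 - wd) / den;
    }
  }
  if (!rho.is_finite() || rho.min() <= 0.0)
    return Rcpp::List::create(Rcpp::Named("status") = 2,
                              Rcpp::Named("iterations") = iters,
                              Rcpp::Named("W") = W);
  mat Cp = W.t() * (S * W);
  Cp = 0.5 * (Cp + Cp.t());
  Cp.diag().ones();
  mat Rc = Cp / sqrt(rho * rho.t());
  if (clamp_r) Rc = clamp(Rc, -1.0, 1.0);
  Rc.diag().ones();
  vec ev;
  if (!eig_sym(ev, Rc))
    return Rcpp::List::create(Rcpp::Named("status") = 2,
                              Rcpp::Named("iterations") = iters,
                              Rcpp::Named("W") = W);
  return Rcpp::List::create(
      Rcpp::Named("status") = 0, Rcpp::Named("W") = W,
      Rcpp::Named("iterations") = iters, Rcpp::Named("rho") = rho,
      Rcpp::Named("proxy") = Cp, Rcpp::Named("R") = Rc,
      Rcpp::Named("min_eig") = ev.min());
}

// Standardize columns (divisor n - 1) and hand off to the consistent core.
// Used by the bootstrap loop to avoid per-resample R overhead; status 3
// flags a zero-variance column in the resample.
// [[Rcpp::export]]
Rcpp::List cpp_consistent_from_data(const arma::mat& X, const Rcpp::List& blocks,
                                    const Rcpp::List& parents,
                                    const Rcpp::List& children, int scheme,
                                    double tol, int max_iter,
                                    Rcpp::Nullable<Rcpp::NumericVector> w_init,
                                    Rcpp::Nullable<Rcpp::NumericVector> rho_fixed,
                                    bool clamp_r) {
  const uword n = X.n_rows;
  mat Xs = X.each_row() - mean(X, 0);
  rowvec sd = sqrt(sum(square(Xs), 0) / double(n - 1));
  if (!sd.is_finite() || sd.min() <= 0.0)
    return Rcpp::List::create(Rcpp::Named("status") = 3);
  Xs.each_row() /= sd;
  mat S = (Xs.t() * Xs) / double(n - 1);
  return cpp_consistent_core(S, blocks, parents, children, scheme, tol,
                             max_iter, w_init, rho_fixed, clamp_r);
}
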