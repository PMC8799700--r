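// Echo-state network core: leaky-tanh reservoir iteration and the
// leave-one-block-out ridge-readout cross-validated prediction error that
// underlies the echo-state Granger causality statistic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One leaky-tanh update: s <- (1 - leak) s + leak tanh(W s + a), where `a`
// holds the input drive on entry. Hand-rolled column sweep: the recurrence
// is the hot loop of the whole package.
static inline void esn_update(const arma::mat& W, arma::vec& s, arma::vec& a,
                              double leak) {
  const arma::uword n = s.n_elem;
  const double* Wm = W.memptr();
  double* ap = a.memptr();
  double* sp = s.memptr();
  for (arma::uword j = 0; j < n; ++j) {
    const double sj = sp[j];
    if (sj == 0.0) continue;
    const double* col = Wm + j * n;
    for (arma::uword i = 0; i < n; ++i) ap[i] += col[i] * sj;
  }
  for (arma::uword i = 0; i < n; ++i) {
    sp[i] = (1.0 - leak) * sp[i] + leak * std::tanh(ap[i]);
  }
}

// s_t = (1 - leak) s_{t-1} + leak * tanh(W s_{t-1} + Win u_t), s_0 = 0.
// The state is reset at every block start, so a block's states depend only
// on that block's inputs.
static arma::mat esn_run(const arma::mat& U, const arma::mat& W,
                         const arma::mat& Win, const arma::vec& bias,
                         double leak) {
  const arma::uword T = U.n_rows, n = W.n_rows, d = U.n_cols;
  arma::mat S(T, n);
  arma::vec s(n, arma::fill::zeros), a(n);
  for (arma::uword t = 0; t < T; ++t) {
    a = bias;
    for (arma::uword c = 0; c < d; ++c) {
      const double u = U(t, c);
      for (arma::uword i = 0; i < n; ++i) a[i] += Win(i, c) * u;
    }
    esn_update(W, s, a, leak);
    S.row(t) = s.t();
  }
  return S;
}

// [[Rcpp::export(name = ".esn_states_cpp")]]
arma::mat esn_states_cpp(const arma::mat& u, const arma::mat& W,
                         const arma::mat& Win, const arma::vec& bias,
                         double leak) {
  if (!u.is_finite()) stop("input series contains non-finite values");
  return esn_run(u, W, Win, bias, leak);
}

// Pooled held-out MSE of a ridge readout predicting target[t+1] from the
// reservoir state at t, under leave-one-block-out cross-validation.
// `inputs` is a list of T_b x d matrices (already standardised), `targets`
// the matching list of length-T_b target series. The first `washout` states
// of every block are discarded; the intercept column is not penalised.
// [[Rcpp::export(name = ".esgc_cv_mse_cpp")]]
NumericVector esgc_cv_mse_cpp(List inputs, List targets, const arma::mat& W,
                              const arma::mat& Win, const arma::vec& bias,
                              double leak, double ridge, int washout) {
  const int B = inputs.size();
  if (B < 2) stop("leave-one-block-out needs at least 2 blocks");
  const arma::uword n = W.n_rows, k = n + 1;
  std::vector<arma::mat> X(B);
  std::vector<arma::vec> y(B);
  std::vector<arma::mat> G(B);
  std::vector<arma::vec> c(B);
  for (int b = 0; b < B; ++b) {
    arma::mat U = as<arma::mat>(inputs[b]);
    arma::vec tv = as<arma::vec>(targets[b]);
    const int T = U.n_rows;
    if ((int)tv.n_elem != T) stop("input/target length mismatch in block");
    if (!U.is_finite() || !tv.is_finite()) stop("non-finite values in block");
    if (T < washout + 2) stop("block shorter than washout + 2 frames");
    arma::mat S = esn_run(U, W, Win, bias, leak);
    arma::mat Xb(T - 1 - washout, k);
    Xb.cols(0, n - 1) = S.rows(washout, T - 2);
    Xb.col(n).ones();
    X[b] = Xb;
    y[b] = tv.subvec(washout + 1, T - 1);
    G[b] = Xb.t() * Xb;
    c[b] = Xb.t() * y[b];
  }
  arma::mat P = ridge * arma::eye<arma::mat>(k, k);
  P(n, n) = 0.0;
  arma::mat Gall(k, k, arma::fill::zeros);
  arma::vec call(k, arma::fill::zeros);
  for (int b = 0; b < B; ++b) { Gall += G[b]; call += c[b]; }
  double sse = 0.0, m = 0.0;
  for (int h = 0; h < B; ++h) {
    arma::vec beta = arma::solve(Gall - G[h] + P, call - c[h],
                                 arma::solve_opts::likely_sympd);
    arma::vec r = X[h] * beta - y[h];
    sse += arma::dot(r, r);
    m += (double)r.n_elem;
  }
  return NumericVector::create(sse / m, m);
}

// Whole-grid ESGC for one reservoir realisation: pooled LOBO MSE of the
// restricted model per target channel and of the full model per
// (source, target) channel pair. Blocks are T_b x nau matrices of
// standardised channel series; channels flagged FALSE in src_ok / tgt_ok
// (zero variance) are skipped and reported as NA.
// [[Rcpp::export(name = ".esgc_grid_cpp")]]
List esgc_grid_cpp(List src_blocks, List tgt_blocks, const arma::mat& W,
                   const arma::mat& win1, const arma::mat& win2,
                   const arma::vec& bias, double leak, double ridge,
                   int washout, const LogicalVector& src_ok,
                   const LogicalVector& tgt_ok) {
  const int B = src_blocks.size();
  if (B < 2) stop("leave-one-block-out needs at least 2 blocks");
  const arma::uword n = W.n_rows, k = n + 1;
  std::vector<arma::mat> S(B), Tg(B);
  for (int b = 0; b < B; ++b) {
    S[b] = as<arma::mat>(src_blocks[b]);
    Tg[b] = as<arma::mat>(tgt_blocks[b]);
    if (S[b].n_rows != Tg[b].n_rows) stop("member block length mismatch");
    if ((int)S[b].n_rows < washout + 2) stop("block shorter than washout + 2 frames");
  }
  const int nau = S[0].n_cols;
  arma::mat P = ridge * arma::eye<arma::mat>(k, k);
  P(n, n) = 0.0;
  const arma::vec w1 = win1.col(0);
  const arma::vec w2t = win2.col(0), w2s = win2.col(1);

  // reservoir design for one block, driven by target alone or by
  // (target, source); stored transposed (k x m, one column per retained
  // state, states washout .. T-2, last row the intercept) so each step
  // writes contiguously
  arma::vec s(n), a(n);
  auto design = [&](const arma::vec& ut, const arma::vec* us) {
    const int T = ut.n_elem;
    s.zeros();
    arma::mat Xt(k, T - 1 - washout);
    for (int t = 0; t < T; ++t) {
      if (us == nullptr) {
        for (arma::uword i = 0; i < n; ++i) a[i] = bias[i] + w1[i] * ut[t];
      } else {
        const double uv = ut[t], sv = (*us)[t];
        for (arma::uword i = 0; i < n; ++i) {
          a[i] = bias[i] + w2t[i] * uv + w2s[i] * sv;
        }
      }
      esn_update(W, s, a, leak);
      if (t >= washout && t <= T - 2) {
        double* col = Xt.colptr(t - washout);
        std::copy(s.memptr(), s.memptr() + n, col);
        col[n] = 1.0;
      }
    }
    return Xt;
  };

  auto cv_pool = [&](const std::vector<arma::mat>& Xt,
                     const std::vector<arma::vec>& y) {
    arma::mat Gall(k, k, arma::fill::zeros);
    arma::vec call(k, arma::fill::zeros);
    std::vector<arma::mat> G(B);
    std::vector<arma::vec> c(B);
    for (int b = 0; b < B; ++b) {
      G[b] = Xt[b] * Xt[b].t();
      c[b] = Xt[b] * y[b];
      Gall += G[b];
      call += c[b];
    }
    double sse = 0.0, m = 0.0;
    for (int h = 0; h < B; ++h) {
      arma::vec beta = arma::solve(Gall - G[h] + P, call - c[h],
                                   arma::solve_opts::likely_sympd);
      arma::vec r = Xt[h].t() * beta - y[h];
      sse += arma::dot(r, r);
      m += (double)r.n_elem;
    }
    return sse / m;
  };

  NumericVector mr(nau, NA_REAL);
  NumericMatrix mf(nau, nau);
  std::fill(mf.begin(), mf.end(), NA_REAL);
  std::vector<std::vector<arma::vec>> ytab(nau, std::vector<arma::vec>(B));
  for (int j = 0; j < nau; ++j) {
    if (!tgt_ok[j]) continue;
    for (int b = 0; b < B; ++b) {
      const int T = Tg[b].n_rows;
      ytab[j][b] = Tg[b].col(j).subvec(washout + 1, T - 1);
    }
  }
  std::vector<arma::mat> X(B);
  std::vector<arma::vec> y(B);
  for (int j = 0; j < nau; ++j) {
    if (!tgt_ok[j]) continue;
    for (int b = 0; b < B; ++b) {
      arma::vec ut = Tg[b].col(j);
      X[b] = design(ut, nullptr);
      y[b] = ytab[j][b];
    }
    mr[j] = cv_pool(X, y);
    for (int i = 0; i < nau; ++i) {
      if (!src_ok[i]) continue;
      for (int b = 0; b < B; ++b) {
        arma::vec ut = Tg[b].col(j);
        arma::vec us = S[b].col(i);
        X[b] = design(ut, &us);
        y[b] = ytab[j][b];
      }
      mf(i, j) = cv_pool(X, y);
    }
  }
  return List::create(Named("mse_restricted") = mr,
                      Named("mse_full") = mf);
}
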