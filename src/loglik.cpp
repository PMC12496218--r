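#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

// Panel logit log-likelihood in WTP space, simulated over normal draws, with
// analytic gradient and (optionally) per-respondent score vectors.
//
// Utility of alternative i:  V = alpha_n * (beta_n' a_i - cost_i)
//   beta_n  = mu + Lambda x_n + zeta_n      (WTP coefficients, EUR)
//   alpha_n = exp(pi + gamma' x_n + eta_n)  (marginal utility of money x scale)
// (zeta_n, eta_n) = Chol u_n with u_n standard normal; the random subset of
// the K+1 coefficient slots is given by rand_idx (slot K = the money term).
//
// Parameter vector layout (full, before any fixing done in R):
//   mu[K] | vec(Lambda)[K*C] (column-major) | pi | gamma[C] |
//   chol lower triangle, row-wise: (0,0), (1,0), (1,1), (2,0), ...
//
// Data layout: rows sorted by (respondent, task, alternative);
// task_start[t]..task_start[t+1]-1 are the rows of task t (0-based, global
// task index); resp_task_start[n]..resp_task_start[n+1]-1 are the tasks of
// respondent n.  draws holds R rows per respondent, stacked.

// [[Rcpp::export]]
List cpp_panel_loglik(const arma::vec& par,
                      const arma::mat& A,
                      const arma::vec& cost,
                      const arma::ivec& chosen,
                      const arma::ivec& task_start,
                      const arma::ivec& resp_task_start,
                      const arma::mat& X,
                      const arma::mat& draws,
                      const arma::ivec& rand_idx,
                      int n_draws,
                      bool want_grad,
                      bool want_scores) {
  const uword K = A.n_cols;
  const uword C = X.n_cols;
  const uword N = resp_task_start.n_elem - 1;
  const uword D = rand_idx.n_elem;
  const uword R = (D > 0) ? (uword) n_draws : 1u;
  const uword P = K + K * C + 1 + C + D * (D + 1) / 2;
  if (par.n_elem != P)
    stop("parameter vector has length %d, expected %d", (int) par.n_elem, (int) P);
  if (D > 0 && draws.n_rows != N * R)
    stop("draw matrix has %d rows, expected %d", (int) draws.n_rows, (int) (N * R));
  if (D > 0 && draws.n_cols != D)
    stop("draw matrix has %d columns, expected %d", (int) draws.n_cols, (int) D);

  vec mu = par.subvec(0, K - 1);
  mat Lambda(K, C);
  if (C > 0) Lambda = reshape(par.subvec(K, K + K * C - 1), K, C);
  const double pi_ = par(K + K * C);
  vec gamma(C);
  if (C > 0) gamma = par.subvec(K + K * C + 1, K + K * C + C);
  mat Chol(D, D, arma::fill::zeros);
  {
    uword p = K + K * C + 1 + C;
    for (uword i = 0; i < D; ++i)
      for (uword j = 0; j <= i; ++j)
        Chol(i, j) = par(p++);
  }
  // which random dimension (if any) feeds each beta slot / the money slot
  int money_dim = -1;
  std::vector<int> beta_dim(K, -1);
  for (uword d = 0; d < D; ++d) {
    int slot = rand_idx(d);
    if (slot < 0 || slot > (int) K)
      stop("rand_idx entries must lie in 0..K");
    if (slot == (int) K) money_dim = (int) d; else beta_dim[slot] = (int) d;
  }

  double loglik = 0.0;
  vec grad(P, arma::fill::zeros);
  mat scores;
  if (want_scores) scores.zeros(N, P);

  mat U, Z, Bmat, S, Pm;
  vec logw(R), omega(R), alpha(R);

  for (uword n = 0; n < N; ++n) {
    const uword t0 = (uword) resp_task_start(n);
    const uword t1 = (uword) resp_task_start(n + 1);
    const uword row0 = (uword) task_start(t0);
    const uword row1 = (uword) task_start(t1); // one past last row
    const uword M = row1 - row0;
    const mat An = A.rows(row0, row1 - 1);
    const vec cost_n = cost.subvec(row0, row1 - 1);

    vec xn(C);
    if (C > 0) xn = X.row(n).t();
    vec b0 = mu;
    if (C > 0) b0 += Lambda * xn;
    double la0 = pi_;
    if (C > 0) la0 += arma::dot(gamma, xn);

    if (D > 0) {
      U = draws.rows(n * R, n * R + R - 1); // R x D
      Z = U * Chol.t();                     // R x D, row r = (zeta, eta)
    }
    Bmat.set_size(K, R);
    Bmat.each_col() = b0;
    for (uword k = 0; k < K; ++k)
      if (beta_dim[k] >= 0)
        Bmat.row(k) += Z.col((uword) beta_dim[k]).t();
    alpha.set_size(R);
    if (money_dim >= 0)
      alpha = arma::exp(la0 + Z.col((uword) money_dim));
    else
      alpha.fill(std::exp(la0));

    S = An * Bmat;            // M x R, beta' a
    S.each_col() -= cost_n;   // money-metric net value
    Pm = S;                   // becomes utilities, then probabilities
    Pm.each_row() %= alpha.t();
    if (!Pm.is_finite())
      stop("non-finite utility for respondent index %d (overflowing alpha?)", (int) n + 1);

    // per-draw log product of task choice probabilities; overwrite Pm with
    // choice probabilities for the gradient pass
    logw.zeros();
    for (uword r = 0; r < R; ++r) {
      double* col = Pm.colptr(r);
      double lw = 0.0;
      for (uword t = t0; t < t1; ++t) {
        const uword a0 = (uword) task_start(t) - row0;
        const uword a1 = (uword) task_start(t + 1) - row0;
        double mx = col[a0];
        for (uword i = a0 + 1; i < a1; ++i) if (col[i] > mx) mx = col[i];
        double se = 0.0, vc = 0.0;
        for (uword i = a0; i < a1; ++i) {
          if (chosen(row0 + i)) vc = col[i] - mx;
          col[i] = std::exp(col[i] - mx);
          se += col[i];
        }
        for (uword i = a0; i < a1; ++i) col[i] /= se;
        // log probability of the chosen alternative, exact in log space even
        // when its probability underflows to zero
        lw += vc - std::log(se);
      }
      logw(r) = lw;
    }
    const double mxw = logw.max();
    if (!std::isfinite(mxw))
      stop("simulated probability underflow for respondent index %d", (int) n + 1);
    vec w = arma::exp(logw - mxw);
    const double sw = arma::accu(w);
    loglik += mxw + std::log(sw) - std::log((double) R);

    if (!want_grad && !want_scores) continue;

    omega = w / sw; // normalized draw weights

    // E = (chosen indicator - P); reuse Pm storage
    for (uword r = 0; r < R; ++r) {
      double* col = Pm.colptr(r);
      for (uword i = 0; i < M; ++i)
        col[i] = (chosen(row0 + i) ? 1.0 : 0.0) - col[i];
    }

    vec sc(P, arma::fill::zeros);
    // d logPn / d mu = An' * E * (omega % alpha)
    vec v = Pm * (omega % alpha);      // M
    vec gmu = An.t() * v;              // K
    sc.subvec(0, K - 1) = gmu;
    if (C > 0)
      sc.subvec(K, K + K * C - 1) = arma::vectorise(gmu * xn.t());
    // money direction: q_r = alpha_r * sum_i E_ir * S_ir
    vec q = (arma::sum(Pm % S, 0).t()) % alpha; // R
    const double gpi = arma::dot(omega, q);
    sc(K + K * C) = gpi;
    if (C > 0)
      sc.subvec(K + K * C + 1, K + K * C + C) = gpi * xn;
    if (D > 0) {
      // G(k, r) = alpha_r * (An' E)(k, r); chol grad for beta rows
      mat G = An.t() * Pm;             // K x R
      G.each_row() %= alpha.t();
      uword p = K + K * C + 1 + C;
      for (uword i = 0; i < D; ++i) {
        const int slot = rand_idx(i);
        arma::rowvec gr;
        if (slot == (int) K)
          gr = (q % omega).t();
        else
          gr = G.row((uword) slot) % omega.t();
        for (uword j = 0; j <= i; ++j)
          sc(p++) = arma::dot(gr.t(), U.col(j));
      }
    }
    grad += sc;
    if (want_scores) scores.row(n) = sc.t();
  }

  List out = List::create(_["loglik"] = loglik);
  if (want_grad) out["grad"] = grad;
  if (want_scores) out["scores"] = scores;
  return out;
}

// Simulated choice probabilities averaged over draws, per row of the data;
// used for model-predicted status-quo shares.
// [[Rcpp::export]]
arma::vec cpp_mean_probs(const arma::vec& par,
                         const arma::mat& A,
                         const arma::vec& cost,
                         const arma::ivec& task_start,
                         const arma::ivec& resp_task_start,
                         const arma::mat& X,
                         const arma::mat& draws,
                         const arma::ivec& rand_idx,
                         int n_draws) {
  const uword K = A.n_cols;
  const uword C = X.n_cols;
  const uword N = resp_task_start.n_elem - 1;
  const uword D = rand_idx.n_elem;
  const uword R = (D > 0) ? (uword) n_draws : 1u;
  if (par.n_elem != K + K * C + 1 + C + D * (D + 1) / 2)
    stop("parameter vector has length %d, expected %d", (int) par.n_elem,
         (int) (K + K * C + 1 + C + D * (D + 1) / 2));

  vec mu = par.subvec(0, K - 1);
  mat Lambda(K, C);
  if (C > 0) Lambda = reshape(par.subvec(K, K + K * C - 1), K, C);
  const double pi_ = par(K + K * C);
  vec gamma(C);
  if (C > 0) gamma = par.subvec(K + K * C + 1, K + K * C + C);
  mat Chol(D, D, arma::fill::zeros);
  {
    uword p = K + K * C + 1 + C;
    for (uword i = 0; i < D; ++i)
      for (uword j = 0; j <= i; ++j)
        Chol(i, j) = par(p++);
  }
  int money_dim = -1;
  std::vector<int> beta_dim(K, -1);
  for (uword d = 0; d < D; ++d) {
    int slot = rand_idx(d);
    if (slot == (int) K) money_dim = (int) d; else beta_dim[slot] = (int) d;
  }

  vec out(A.n_rows, arma::fill::zeros);
  mat U, Z, Bmat, S;
  vec alpha(R);
  for (uword n = 0; n < N; ++n) {
    const uword t0 = (uword) resp_task_start(n);
    const uword t1 = (uword) resp_task_start(n + 1);
    const uword row0 = (uword) task_start(t0);
    const uword row1 = (uword) task_start(t1);
    const mat An = A.rows(row0, row1 - 1);
    const vec cost_n = cost.subvec(row0, row1 - 1);

    vec xn(C);
    if (C > 0) xn = X.row(n).t();
    vec b0 = mu;
    if (C > 0) b0 += Lambda * xn;
    double la0 = pi_;
    if (C > 0) la0 += arma::dot(gamma, xn);

    if (D > 0) {
      U = draws.rows(n * R, n * R + R - 1);
      Z = U * Chol.t();
    }
    Bmat.set_size(K, R);
    Bmat.each_col() = b0;
    for (uword k = 0; k < K; ++k)
      if (beta_dim[k] >= 0)
        Bmat.row(k) += Z.col((uword) beta_dim[k]).t();
    if (money_dim >= 0)
      alpha = arma::exp(la0 + Z.col((uword) money_dim));
    else
      alpha.fill(std::exp(la0));

    S = An * Bmat;
    S.each_col() -= cost_n;
    S.each_row() %= alpha.t();

    for (uword r = 0; r < R; ++r) {
      double* col = S.colptr(r);
      for (uword t = t0; t < t1; ++t) {
        const uword a0 = (uword) task_start(t) - row0;
        const uword a1 = (uword) task_start(t + 1) - row0;
        double mx = col[a0];
        for (uword i = a0 + 1; i < a1; ++i) if (col[i] > mx) mx = col[i];
        double se = 0.0;
        for (uword i = a0; i < a1; ++i) { col[i] = std::exp(col[i] - mx); se += col[i]; }
        for (uword i = a0; i < a1; ++i) out(row0 + i) += col[i] / se;
      }
    }
  }
  return out / (double) R;
}
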