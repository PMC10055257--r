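// Inner loops of the empirical-Bayes multivariate shrinkage model:
// per-association log-likelihoods under each mixture component and the
// mixture posterior summaries (mean, sd, local false sign rate).
// Components are N(0, omega_l * U_k) priors with per-row diagonal
// measurement error S_i; missing conditions (non-finite se) are dropped
// from the likelihood row-wise.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double log_mvnorm_zero(const vec &b, const mat &Sigma) {
  mat L;
  if (!chol(L, Sigma, "lower")) return -datum::inf;
  vec z = solve(trimatl(L), b);
  double logdet = 2.0 * sum(log(L.diag()));
  return -0.5 * (b.n_elem * std::log(2.0 * datum::pi) + logdet + dot(z, z));
}

// B, S: n x R (S may contain non-finite entries = missing condition).
// Ulist: list of R x R prior covariances, grid: vector of scales omega.
// Returns n x (1 + K*L) matrix of log-likelihoods; column 0 is the null
// (point mass at zero) component.
// [[Rcpp::export(name = ".mash_loglik_cpp")]]
arma::mat mash_loglik_cpp(const arma::mat &B, const arma::mat &S,
                          const Rcpp::List &Ulist, const arma::vec &grid) {
  const uword n = B.n_rows, R = B.n_cols;
  const uword K = Ulist.size(), L = grid.n_elem;
  std::vector<mat> U(K);
  for (uword k = 0; k < K; ++k) U[k] = Rcpp::as<mat>(Ulist[k]);
  mat out(n, 1 + K * L);
  for (uword i = 0; i < n; ++i) {
    rowvec si = S.row(i);
    uvec obs = find_finite(si);
    vec b = B.row(i).t();
    b = b.elem(obs);
    vec s2 = square(si.t());
    s2 = s2.elem(obs);
    // null component: b ~ N(0, diag(s2))
    double ll0 = 0.0;
    for (uword r = 0; r < obs.n_elem; ++r)
      ll0 += -0.5 * (std::log(2.0 * datum::pi * s2[r]) + b[r] * b[r] / s2[r]);
    out(i, 0) = ll0;
    for (uword k = 0; k < K; ++k) {
      mat Uk = U[k].submat(obs, obs);
      for (uword l = 0; l < L; ++l) {
        mat Sigma = grid[l] * Uk;
        Sigma.diag() += s2;
        out(i, 1 + k * L + l) = log_mvnorm_zero(b, Sigma);
      }
    }
  }
  return out;
}

// Posterior summaries under fitted mixture weights pi (length 1 + K*L,
// null first). Returns post_mean, post_sd, lfsr, and the per-condition
// negative/positive/zero posterior sign masses.
// [[Rcpp::export(name = ".mash_posterior_cpp")]]
Rcpp::List mash_posterior_cpp(const arma::mat &B, const arma::mat &S,
                              const Rcpp::List &Ulist, const arma::vec &grid,
                              const arma::vec &pi) {
  const uword n = B.n_rows, R = B.n_cols;
  const uword K = Ulist.size(), L = grid.n_elem;
  std::vector<mat> U(K);
  for (uword k = 0; k < K; ++k) U[k] = Rcpp::as<mat>(Ulist[k]);
  mat post_mean(n, R, fill::value(datum::nan));
  mat post_sd(n, R, fill::value(datum::nan));
  mat lfsr(n, R, fill::value(datum::nan));
  mat prob_neg(n, R, fill::value(datum::nan));
  mat prob_pos(n, R, fill::value(datum::nan));
  mat prob_zero(n, R, fill::value(datum::nan));
  const double sqrt2 = std::sqrt(2.0);

  for (uword i = 0; i < n; ++i) {
    rowvec si = S.row(i);
    uvec obs = find_finite(si);
    const uword m = obs.n_elem;
    if (m == 0) continue;
    vec b = B.row(i).t();
    b = b.elem(obs);
    vec s2 = square(si.t());
    s2 = s2.elem(obs);

    // log-likelihood per component, then responsibilities
    vec ll(1 + K * L, fill::zeros);
    double ll0 = 0.0;
    for (uword r = 0; r < m; ++r)
      ll0 += -0.5 * (std::log(2.0 * datum::pi * s2[r]) + b[r] * b[r] / s2[r]);
    ll[0] = ll0;
    // cache posterior means / vars per component
    mat mu(m, 1 + K * L, fill::zeros);
    mat v(m, 1 + K * L, fill::zeros);
    for (uword k = 0; k < K; ++k) {
      mat Uk = U[k].submat(obs, obs);
      for (uword l = 0; l < L; ++l) {
        const uword c = 1 + k * L + l;
        if (pi[c] <= 0) { ll[c] = -datum::inf; continue; }
        mat Up = grid[l] * Uk;
        mat Sigma = Up;
        Sigma.diag() += s2;
        mat Lch;
        if (!chol(Lch, Sigma, "lower")) { ll[c] = -datum::inf; continue; }
        vec z = solve(trimatl(Lch), b);
        double logdet = 2.0 * sum(log(Lch.diag()));
        ll[c] = -0.5 * (m * std::log(2.0 * datum::pi) + logdet + dot(z, z));
        // posterior: mu1 = Up Sigma^-1 b ; V1 = Up - Up Sigma^-1 Up
        mat SinvUp = solve(trimatl(Lch), Up);       // L^-1 Up
        vec mu1 = SinvUp.t() * z;                    // Up Sigma^-1 b
        mat V1 = Up - SinvUp.t() * SinvUp;
        mu.col(c) = mu1;
        v.col(c) = clamp(V1.diag(), 0.0, datum::inf);
      }
    }
    double M = ll.elem(find(pi > 0)).max();
    vec resp = pi % exp(ll - M);
    resp /= accu(resp);

    for (uword r = 0; r < m; ++r) {
      double pm = 0.0, pm2 = 0.0, pneg = 0.0, ppos = 0.0, pzero = 0.0;
      for (uword c = 0; c < resp.n_elem; ++c) {
        if (resp[c] <= 0) continue;
        if (c == 0) { pzero += resp[c]; continue; }
        double m1 = mu(r, c), v1 = v(r, c);
        pm += resp[c] * m1;
        pm2 += resp[c] * (m1 * m1 + v1);
        if (v1 <= 1e-300) {
          if (m1 == 0.0) pzero += resp[c];
          else if (m1 < 0) pneg += resp[c];
          else ppos += resp[c];
        } else {
          double pn = 0.5 * std::erfc(m1 / std::sqrt(v1) / sqrt2); // P(beta < 0)
          pneg += resp[c] * pn;
          ppos += resp[c] * (1.0 - pn);
        }
      }
      uword rr = obs[r];
      post_mean(i, rr) = pm;
      post_sd(i, rr) = std::sqrt(std::max(pm2 - pm * pm, 0.0));
      prob_neg(i, rr) = pneg;
      prob_pos(i, rr) = ppos;
      prob_zero(i, rr) = pzero;
      lfsr(i, rr) = std::min(pneg + pzero, ppos + pzero);
    }
  }
  return Rcpp::List::create(Rcpp::Named("post_mean") = post_mean,
                            Rcpp::Named("post_sd") = post_sd,
                            Rcpp::Named("lfsr") = lfsr,
                            Rcpp::Named("prob_neg") = prob_neg,
                            Rcpp::Named("prob_pos") = prob_pos,
                            Rcpp::Named("prob_zero") = prob_zero);
}
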