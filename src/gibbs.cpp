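// Gibbs sampler for the multivariate nested half-sib mixed model
//   y_n = mu + s_{sire(n)} + d_{dam(n)} + b_{block(n)} + e_n
// with conditionally conjugate inverse-Wishart priors on all four
// covariance components. Uses R's RNG so results follow set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Wishart(df, V) draw via the Bartlett decomposition.
static arma::mat rwishart(double df, const arma::mat& V) {
  const arma::uword p = V.n_cols;
  arma::mat L = arma::chol(V, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Inverse-Wishart(df, S) draw: X ~ IW(df, S)  <=>  X^{-1} ~ W(df, S^{-1}).
static arma::mat riwishart(double df, const arma::mat& S) {
  return arma::inv_sympd(arma::symmatu(rwishart(df, arma::inv_sympd(arma::symmatu(S)))));
}

static arma::vec rmvnorm(const arma::vec& mu, const arma::mat& Sigma) {
  const arma::uword p = mu.n_elem;
  arma::vec z(p);
  for (arma::uword i = 0; i < p; ++i) z(i) = R::norm_rand();
  return mu + arma::chol(arma::symmatu(Sigma), "lower") * z;
}

// Accumulate row sums of P by level index into T (nlev x p).
static void level_sums(const arma::mat& P, const arma::uvec& idx, arma::mat& T) {
  T.zeros();
  for (arma::uword n = 0; n < P.n_rows; ++n) T.row(idx(n)) += P.row(n);
}

// Sample a set of random effects given partial residuals P (N x p):
// eff_i | . ~ N( (n_i Einv + Uinv)^{-1} Einv rsum_i, (n_i Einv + Uinv)^{-1} )
static void update_effects(arma::mat& eff, const arma::mat& P,
                           const arma::uvec& idx, const arma::vec& nlev,
                           const arma::mat& Einv, const arma::mat& Uinv,
                           bool flat) {
  const arma::uword p = P.n_cols;
  arma::mat T(eff.n_rows, p);
  level_sums(P, idx, T);
  for (arma::uword i = 0; i < eff.n_rows; ++i) {
    arma::mat prec = nlev(i) * Einv;
    if (!flat) prec += Uinv;
    arma::mat cov = arma::inv_sympd(arma::symmatu(prec));
    arma::vec m = cov * (Einv * T.row(i).t());
    eff.row(i) = rmvnorm(m, cov).t();
  }
}

// [[Rcpp::export(name = ".gibbs_halfsib")]]
List gibbs_halfsib(const arma::mat& Y,
                   const arma::uvec& sire, const arma::uvec& dam,
                   const arma::uvec& block,
                   double df_s, const arma::mat& S_s,
                   double df_d, const arma::mat& S_d,
                   double df_b, const arma::mat& S_b,
                   double df_e, const arma::mat& S_e,
                   int nburn, int thin, int nsave,
                   bool block_random) {
  const arma::uword N = Y.n_rows, p = Y.n_cols;
  const arma::uword nS = sire.max() + 1, nD = dam.max() + 1, nB = block.max() + 1;

  arma::vec cntS(nS, arma::fill::zeros), cntD(nD, arma::fill::zeros),
            cntB(nB, arma::fill::zeros);
  for (arma::uword n = 0; n < N; ++n) {
    cntS(sire(n))++; cntD(dam(n))++; cntB(block(n))++;
  }

  // state
  arma::rowvec mu = arma::mean(Y, 0);
  arma::mat effS(nS, p, arma::fill::zeros), effD(nD, p, arma::fill::zeros),
            effB(nB, p, arma::fill::zeros);
  arma::mat Sig_s = S_s / df_s, Sig_d = S_d / df_d, Sig_b = S_b / df_b,
            Sig_e = arma::cov(Y);
  if (!Sig_e.is_sympd()) Sig_e = S_e / df_e;

  arma::cube out_s(p, p, nsave), out_d(p, p, nsave), out_b(p, p, nsave),
             out_e(p, p, nsave);
  arma::mat out_mu(nsave, p);
  arma::mat mean_s(nS, p, arma::fill::zeros), mean_d(nD, p, arma::fill::zeros),
            mean_b(nB, p, arma::fill::zeros);
  arma::rowvec mean_mu(p, arma::fill::zeros);

  arma::mat P(N, p);
  const int total = nburn + thin * nsave;
  int saved = 0;

  for (int it = 1; it <= total; ++it) {
    arma::mat Einv = arma::inv_sympd(arma::symmatu(Sig_e));

    // mu | .
    P = Y;
    for (arma::uword n = 0; n < N; ++n)
      P.row(n) -= effS.row(sire(n)) + effD.row(dam(n)) + effB.row(block(n));
    mu = rmvnorm(arma::mean(P, 0).t(), Sig_e / (double)N).t();

    // sire effects
    arma::mat Sinv = arma::inv_sympd(arma::symmatu(Sig_s));
    P = Y;
    for (arma::uword n = 0; n < N; ++n)
      P.row(n) -= mu + effD.row(dam(n)) + effB.row(block(n));
    update_effects(effS, P, sire, cntS, Einv, Sinv, false);

    // dam effects
    arma::mat Dinv = arma::inv_sympd(arma::symmatu(Sig_d));
    P = Y;
    for (arma::uword n = 0; n < N; ++n)
      P.row(n) -= mu + effS.row(sire(n)) + effB.row(block(n));
    update_effects(effD, P, dam, cntD, Einv, Dinv, false);

    // block effects (random with its own covariance, or flat-prior "fixed")
    arma::mat Binv = block_random ? arma::inv_sympd(arma::symmatu(Sig_b))
                                  : arma::mat(p, p, arma::fill::zeros);
    P = Y;
    for (arma::uword n = 0; n < N; ++n)
      P.row(n) -= mu + effS.row(sire(n)) + effD.row(dam(n));
    update_effects(effB, P, block, cntB, Einv, Binv, !block_random);
    if (!block_random) {
      // sum-to-zero to keep mu identifiable under the flat block prior
      arma::rowvec bbar = arma::mean(effB, 0);
      effB.each_row() -= bbar;
      mu += bbar;
    }

    // covariance components
    Sig_s = riwishart(df_s + (double)nS, S_s + effS.t() * effS);
    Sig_d = riwishart(df_d + (double)nD, S_d + effD.t() * effD);
    if (block_random)
      Sig_b = riwishart(df_b + (double)nB, S_b + effB.t() * effB);

    P = Y;
    for (arma::uword n = 0; n < N; ++n)
      P.row(n) -= mu + effS.row(sire(n)) + effD.row(dam(n)) + effB.row(block(n));
    Sig_e = riwishart(df_e + (double)N, S_e + P.t() * P);

    if (it > nburn && ((it - nburn) % thin == 0)) {
      out_s.slice(saved) = Sig_s;
      out_d.slice(saved) = Sig_d;
      out_b.slice(saved) = Sig_b;
      out_e.slice(saved) = Sig_e;
      out_mu.row(saved) = mu;
      mean_s += effS; mean_d += effD; mean_b += effB; mean_mu += mu;
      ++saved;
    }
  }

  mean_s /= (double)nsave; mean_d /= (double)nsave;
  mean_b /= (double)nsave; mean_mu /= (double)nsave;

  return List::create(
    _["sigma_sire"] = out_s, _["sigma_dam"] = out_d,
    _["sigma_block"] = out_b, _["sigma_resid"] = out_e,
    _["mu"] = out_mu,
    _["eff_sire"] = mean_s, _["eff_dam"] = mean_d, _["eff_block"] = mean_b,
    _["eff_mu"] = mean_mu);
}
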