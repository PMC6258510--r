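// Collapsed Gibbs sweep kernel for the TAGM sampler.
//
// Mirrors the reference R implementation (collapsed_gibbs_sweep) operation
// for operation, including the order in which random numbers are consumed
// from R's global RNG stream, so that chains are reproducible and the two
// implementations can be compared directly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double mvt_logpdf_c(const arma::vec& x, double df, const arma::vec& mu,
                           const arma::mat& sigma) {
  const int D = x.n_elem;
  arma::mat R;
  if (!arma::chol(R, sigma))
    stop("degenerate scale matrix in posterior predictive");
  arma::vec z = arma::solve(arma::trimatl(R.t()), x - mu);
  const double q = arma::dot(z, z);
  const double logdet = 2.0 * arma::accu(arma::log(R.diag()));
  return std::lgamma(0.5 * (df + D)) - std::lgamma(0.5 * df)
       - 0.5 * D * std::log(df * M_PI) - 0.5 * logdet
       - 0.5 * (df + D) * std::log1p(q / df);
}

// NIW posterior predictive log density of x for a class with members
// summarised by (n, xsum, xx)
static double niw_predictive_c(const arma::vec& x, double n,
                               const arma::vec& xsum, const arma::mat& xx,
                               const arma::vec& mu0, double lambda0,
                               double nu0, const arma::mat& S0) {
  const int D = x.n_elem;
  const double lam = lambda0 + n;
  const double nu = nu0 + n;
  arma::vec m;
  arma::mat S;
  if (n > 0) {
    arma::vec xbar = xsum / n;
    arma::vec d = xbar - mu0;
    S = S0 + (xx - n * (xbar * xbar.t())) + (lambda0 * n / lam) * (d * d.t());
    m = (lambda0 * mu0 + xsum) / lam;
  } else {
    S = S0;
    m = mu0;
  }
  const double df = nu - D + 1.0;
  arma::mat scale = S * ((lam + 1.0) / (lam * df));
  return mvt_logpdf_c(x, df, m, scale);
}

// [[Rcpp::export]]
List gibbs_kernel(const arma::mat& Xu, arma::ivec z, arma::ivec phi,
                  const arma::mat& marker_xsum, const arma::cube& marker_xx,
                  const arma::vec& marker_n, const arma::vec& beta,
                  const arma::vec& mu0, double lambda0, double nu0,
                  const arma::mat& S0, double u0, double v0,
                  const arma::vec& logg, double eps0, bool fix_eps,
                  int n_iter, int burn_in, int thin) {
  const int Nu = Xu.n_rows, D = Xu.n_cols, K = beta.n_elem;
  const int Tp = (n_iter - burn_in) / thin;

  // running class statistics: markers + phi=1 unlabelled members
  arma::vec cnt = marker_n;
  arma::mat xsum = marker_xsum;          // D x K
  arma::cube xx = marker_xx;             // D x D x K
  arma::vec nz(K, arma::fill::zeros);    // z counts over all proteins
  for (int k = 0; k < K; ++k) nz(k) = marker_n(k);
  for (int i = 0; i < Nu; ++i) {
    nz(z(i)) += 1.0;
    if (phi(i) == 1) {
      cnt(z(i)) += 1.0;
      xsum.col(z(i)) += Xu.row(i).t();
      xx.slice(z(i)) += Xu.row(i).t() * Xu.row(i);
    }
  }

  double eps = eps0;
  IntegerMatrix z_out(Tp, Nu), phi_out(Tp, Nu);
  arma::cube prob_out_cube(Nu, K, Tp);
  NumericMatrix pout_out(Tp, Nu);
  NumericVector eps_out(Tp), phi_trace(n_iter);
  arma::mat prob_cur(Nu, K);
  arma::vec pout_cur(Nu);
  arma::vec logw(2 * K), w(2 * K);

  for (int t = 1; t <= n_iter; ++t) {
    const double leps = std::log(eps);
    const double l1meps = std::log1p(-eps);
    for (int i = 0; i < Nu; ++i) {
      arma::vec x = Xu.row(i).t();
      int kc = z(i);
      nz(kc) -= 1.0;
      if (phi(i) == 1) {
        cnt(kc) -= 1.0;
        xsum.col(kc) -= x;
        xx.slice(kc) -= x * x.t();
      }
      for (int k = 0; k < K; ++k) {
        double lp = niw_predictive_c(x, cnt(k), xsum.col(k), xx.slice(k),
                                     mu0, lambda0, nu0, S0);
        double lnk = std::log(nz(k) + beta(k));
        logw(k) = lnk + l1meps + lp;
        logw(K + k) = lnk + leps + logg(i);
      }
      double m = logw.max();
      double tot = 0.0;
      for (int j = 0; j < 2 * K; ++j) { w(j) = std::exp(logw(j) - m); tot += w(j); }
      double uu = unif_rand();
      double cum = 0.0;
      int pick = 2 * K - 1;
      for (int j = 0; j < 2 * K; ++j) {
        cum += w(j) / tot;
        if (cum >= uu) { pick = j; break; }
      }
      int knew = pick % K;
      int phinew = pick < K ? 1 : 0;
      z(i) = knew;
      phi(i) = phinew;
      nz(knew) += 1.0;
      if (phinew == 1) {
        cnt(knew) += 1.0;
        xsum.col(knew) += x;
        xx.slice(knew) += x * x.t();
      }
      double ps = 0.0;
      for (int k = 0; k < K; ++k) { prob_cur(i, k) = w(k) / tot; ps += w(K + k) / tot; }
      pout_cur(i) = ps;
    }
    int n_in = 0;
    for (int i = 0; i < Nu; ++i) n_in += phi(i);
    if (!fix_eps) eps = R::rbeta(u0 + (Nu - n_in), v0 + n_in);
    phi_trace(t - 1) = n_in;

    // numerical drift guard: periodically rebuild statistics from scratch
    if (t % 1000 == 0) {
      cnt = marker_n;
      xsum = marker_xsum;
      xx = marker_xx;
      for (int k = 0; k < K; ++k) nz(k) = marker_n(k);
      for (int i = 0; i < Nu; ++i) {
        nz(z(i)) += 1.0;
        if (phi(i) == 1) {
          cnt(z(i)) += 1.0;
          xsum.col(z(i)) += Xu.row(i).t();
          xx.slice(z(i)) += Xu.row(i).t() * Xu.row(i);
        }
      }
    }

    if (t > burn_in && (t - burn_in) % thin == 0) {
      int s = (t - burn_in) / thin - 1;
      if (s < Tp) {
        for (int i = 0; i < Nu; ++i) {
          z_out(s, i) = z(i);
          phi_out(s, i) = phi(i);
          pout_out(s, i) = pout_cur(i);
        }
        prob_out_cube.slice(s) = arma::mat(prob_cur);
        eps_out(s) = eps;
      }
    }
    if (t % 200 == 0) Rcpp::checkUserInterrupt();
  }

  // N_U x K x T array for R
  NumericVector prob(Dimension(Nu, K, Tp));
  for (int s = 0; s < Tp; ++s)
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < Nu; ++i)
        prob[i + Nu * (k + K * s)] = prob_out_cube(i, k, s);

  return List::create(_["z"] = z_out, _["phi"] = phi_out,
                      _["prob"] = prob, _["prob_out"] = pout_out,
                      _["eps"] = eps_out, _["phi_trace"] = phi_trace);
}
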