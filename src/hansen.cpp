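// Fast inner loop for multi-regime Hansen (OU) model fitting on a fixed
// tree: profile likelihood over alpha per trait, with theta by GLS and
// sigma^2 analytic at each alpha. The R-level reference implementation
// (hansen_weights / hansen_vcv / hansen_loglik) defines the contract; this
// file only accelerates it for the stepwise regime search.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct HansenData {
  const mat& Y;          // n x m traits, tip order
  const mat& D;          // n x n patristic distances
  const mat& Tm;         // n x n shared (MRCA) depths
  const vec& depth;      // n tip depths
  const ivec& seg_tip;   // 0-based tip index per path segment
  const ivec& seg_reg;   // 0-based regime per path segment
  const vec& seg_t0;     // segment start time (from root)
  const vec& seg_t1;     // segment end time
  int k;                 // number of regimes
  int root_reg;          // 0-based root regime
};

// scaled covariance V / sigma^2 at given alpha
mat build_v0(const HansenData& d, double a) {
  mat V0 = (1.0 / (2.0 * a)) * exp(-a * d.D) % (1.0 - exp(-2.0 * a * d.Tm));
  return V0;
}

mat build_w(const HansenData& d, double a) {
  int n = d.Y.n_rows;
  mat W(n, d.k, fill::zeros);
  for (int i = 0; i < n; ++i) W(i, d.root_reg) += std::exp(-a * d.depth(i));
  for (uword s = 0; s < d.seg_tip.n_elem; ++s) {
    int i = d.seg_tip(s);
    double T = d.depth(i);
    W(i, d.seg_reg(s)) +=
        std::exp(-a * (T - d.seg_t1(s))) - std::exp(-a * (T - d.seg_t0(s)));
  }
  return W;
}

// profile log-likelihood for one trait at one alpha; fills theta and sigma2
double trait_loglik(const HansenData& d, double a, const vec& y, vec& theta,
                    double& sigma2) {
  int n = y.n_elem;
  mat V0 = build_v0(d, a);
  mat R;
  if (!chol(R, V0)) return -datum::inf;
  mat W = build_w(d, a);
  mat X = solve(trimatl(R.t()), W);
  vec z = solve(trimatl(R.t()), y);
  mat A = X.t() * X;
  A.diag() += 1e-12 * (trace(A) / d.k + 1.0);  // guard rank deficiency
  theta = solve(A, X.t() * z, solve_opts::likely_sympd);
  vec r = z - X * theta;
  sigma2 = dot(r, r) / n;
  if (!(sigma2 > 0)) sigma2 = 1e-12;
  double logdet = 2.0 * sum(log(R.diag()));
  return -0.5 * (n * std::log(2.0 * datum::pi * sigma2) + logdet + n);
}

} // namespace

// Grid-profile fit against precomputed whitening factors: Lcube slice g is
// the lower Cholesky factor of V/sigma^2 at grid alpha g, Zcube slice g the
// whitened traits. Only W changes with the painting, so candidate fits in
// the stepwise search cost one triangular solve each.
// [[Rcpp::export(name = ".hansen_grid_fit_cpp")]]
Rcpp::List hansen_grid_fit_cpp(const arma::cube& Lcube, const arma::cube& Zcube,
                               const arma::vec& logdets, const arma::vec& alphas,
                               const arma::mat& Y, const arma::vec& depth,
                               const arma::ivec& seg_tip, const arma::ivec& seg_reg,
                               const arma::vec& seg_t0, const arma::vec& seg_t1,
                               int k, int root_reg) {
  int n = Y.n_rows, m = Y.n_cols, g = alphas.n_elem;
  HansenData d{Y, Lcube.slice(0), Lcube.slice(0), depth, seg_tip, seg_reg,
               seg_t0, seg_t1, k, root_reg};
  mat best_theta(k, m);
  vec best_ll(m); best_ll.fill(-datum::inf);
  vec best_a(m), best_s2(m);
  ivec best_g(m, fill::zeros);
  for (int gi = 0; gi < g; ++gi) {
    mat W = build_w(d, alphas(gi));
    mat X = solve(trimatl(Lcube.slice(gi)), W);
    mat A = X.t() * X;
    A.diag() += 1e-12 * (trace(A) / k + 1.0);
    for (int j = 0; j < m; ++j) {
      vec z = Zcube.slice(gi).col(j);
      vec th = solve(A, X.t() * z, solve_opts::likely_sympd);
      vec r = z - X * th;
      double s2 = dot(r, r) / n;
      if (!(s2 > 0)) s2 = 1e-12;
      double ll = -0.5 * (n * std::log(2.0 * datum::pi * s2) + logdets(gi) + n);
      if (ll > best_ll(j)) {
        best_ll(j) = ll; best_theta.col(j) = th; best_a(j) = alphas(gi);
        best_s2(j) = s2; best_g(j) = gi;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("alpha") = best_a,
                            Rcpp::Named("sigma_sq") = best_s2,
                            Rcpp::Named("theta") = best_theta,
                            Rcpp::Named("loglik") = sum(best_ll),
                            Rcpp::Named("loglik_by_trait") = best_ll,
                            Rcpp::Named("grid_index") = best_g + 1);
}

// [[Rcpp::export(name = ".hansen_fit_cpp")]]
Rcpp::List hansen_fit_cpp(const arma::mat& Y, const arma::mat& D,
                          const arma::mat& Tm, const arma::vec& depth,
                          const arma::ivec& seg_tip, const arma::ivec& seg_reg,
                          const arma::vec& seg_t0, const arma::vec& seg_t1,
                          int k, int root_reg, double amin, double amax,
                          int ngrid = 15, int ngolden = 40) {
  HansenData d{Y, D, Tm, depth, seg_tip, seg_reg, seg_t0, seg_t1, k, root_reg};
  int m = Y.n_cols;
  vec alpha(m), sigma2(m), ll(m);
  mat theta(k, m);
  double la = std::log(amin), lb = std::log(amax);
  for (int j = 0; j < m; ++j) {
    vec y = Y.col(j);
    vec th(k); double s2;
    // coarse grid on log-alpha, then golden-section refinement
    double best_la = la, best_ll = -datum::inf;
    for (int g = 0; g < ngrid; ++g) {
      double lx = la + (lb - la) * g / (ngrid - 1.0);
      double v = trait_loglik(d, std::exp(lx), y, th, s2);
      if (v > best_ll) { best_ll = v; best_la = lx; }
    }
    double step = (lb - la) / (ngrid - 1.0);
    double lo = std::max(la, best_la - step), hi = std::min(lb, best_la + step);
    const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
    double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
    double f1 = trait_loglik(d, std::exp(x1), y, th, s2);
    double f2 = trait_loglik(d, std::exp(x2), y, th, s2);
    for (int it = 0; it < ngolden && (hi - lo) > 1e-6; ++it) {
      if (f1 < f2) {
        lo = x1; x1 = x2; f1 = f2;
        x2 = lo + gr * (hi - lo);
        f2 = trait_loglik(d, std::exp(x2), y, th, s2);
      } else {
        hi = x2; x2 = x1; f2 = f1;
        x1 = hi - gr * (hi - lo);
        f1 = trait_loglik(d, std::exp(x1), y, th, s2);
      }
    }
    double lx = (f1 > f2) ? x1 : x2;
    double fl = std::max(f1, f2);
    if (best_ll > fl) { lx = best_la; }
    double a_hat = std::exp(lx);
    ll(j) = trait_loglik(d, a_hat, y, th, s2);
    alpha(j) = a_hat; sigma2(j) = s2; theta.col(j) = th;
  }
  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("sigma_sq") = sigma2,
                            Rcpp::Named("theta") = theta,
                            Rcpp::Named("loglik") = sum(ll),
                            Rcpp::Named("loglik_by_trait") = ll);
}
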