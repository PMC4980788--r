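// Core numerical kernels for LARF: a coordinate-descent lasso solver in the
// Gram ("covariance updating") form, and the per-target lambda sweep with
// random featuring / random sampling.
//
// Objective convention (shared with the R layer):
//   (1 / (2 m)) * ||y - X b||_2^2 + lambda * ||b||_1
// with predictor columns standardized to mean 0 and unit population
// variance.  Under this convention the penalty at which a lone
// standardized predictor leaves the model is |x' y| / m.  The sweep
// additionally standardizes the response, putting that threshold on the
// correlation scale, so lambda grids are comparable across genes and
// datasets and a sweep needs at most max|cor|/stepsize fits.
//
// All randomness is drawn from R's RNG (Rcpp::sample), so results are
// reproducible from R seeds alone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Coordinate descent on the Gram form: G = X'X/m (p x p), c = X'y/m.
// Returns standardized-scale coefficients.
static arma::vec cd_lasso_gram(const arma::mat& G, const arma::vec& c,
                               double lambda, double tol, int maxit) {
  const int p = c.n_elem;
  arma::vec b(p, arma::fill::zeros);
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      double gjj = G(j, j);
      if (gjj < 1e-12) { b[j] = 0.0; continue; }
      double z = c[j] - arma::dot(G.col(j), b) + gjj * b[j];
      double bn = 0.0;
      if (z > lambda) bn = (z - lambda) / gjj;
      else if (z < -lambda) bn = (z + lambda) / gjj;
      double d = std::fabs(bn - b[j]);
      if (d > delta) delta = d;
      b[j] = bn;
    }
    if (delta < tol) break;
  }
  return b;
}

// [[Rcpp::export]]
arma::vec cd_lasso_cpp(const arma::mat& G, const arma::vec& c, double lambda,
                       double tol = 1e-8, int maxit = 100000) {
  return cd_lasso_gram(G, c, lambda, tol, maxit);
}

// One lambda sweep for one target gene.  X is the raw sample-by-gene
// matrix; target is 1-based.  Returns the per-gene selection counts, with
// attributes: steps performed, whether the lambda_max cap was hit, and the
// stopping lambda.
//
// stop_rule: 0 = "exhaustion" (run lambda from 0 up to the largest
// full-data marginal |covariance| over candidates, the level beyond which
// no candidate could be selected), 1 = "empty_step" (stop at the first
// step whose fit selects nothing).
// cd_tol / cd_maxit are looser than fit_lasso's defaults: the sweep only
// consumes the selected support, which stabilizes long before the exact
// coefficients of nearly-collinear gene pairs do, and a hard iteration
// cap keeps pathological duplicate-gene panels from stalling a sweep.
// [[Rcpp::export]]
IntegerVector larf_sweep_cpp(const arma::mat& X, int target, double alpha,
                             double r, double stepsize, double lambda_max,
                             int stop_rule, double coef_tol = 1e-8,
                             double cd_tol = 1e-6, int cd_maxit = 2000) {
  const int N = X.n_rows, n = X.n_cols;
  const int tgt = target - 1;
  const int n_cand = n - 1;
  const int nf = std::max(1, (int)std::ceil(alpha * n_cand));
  const int ns = std::max(1, (int)std::ceil(r * N));
  const bool full_samples = (ns >= N);
  const bool full_features = (nf >= n_cand);

  IntegerVector cand(n_cand);
  {
    int k = 0;
    for (int j = 0; j < n; ++j) if (j != tgt) cand[k++] = j;
  }

  // full-data standardized quantities (population sd), centered response
  arma::rowvec mu = arma::mean(X, 0);
  arma::rowvec sdv = arma::sqrt(arma::mean(arma::square(X), 0) -
                                arma::square(mu));
  arma::mat Xs = X;
  Xs.each_row() -= mu;
  for (int j = 0; j < n; ++j)
    if (sdv[j] > 1e-12) Xs.col(j) /= sdv[j]; else Xs.col(j).zeros();
  // response standardized like the predictors: the selection thresholds
  // all scale linearly with sd(y), and the per-row min-max normalization
  // removes any common scale, so scaling y leaves the frequency matrix
  // invariant while bounding the sweep at max|cor|/stepsize steps.
  arma::vec yc = X.col(tgt) - mu[tgt];
  if (sdv[tgt] > 1e-12) yc /= sdv[tgt];

  double lam_stop = 0.0;
  for (int k = 0; k < n_cand; ++k) {
    double cj = std::fabs(arma::dot(Xs.col(cand[k]), yc)) / N;
    if (cj > lam_stop) lam_stop = cj;
  }

  bool capped = false;
  if (stop_rule == 0 && lam_stop > lambda_max) { lam_stop = lambda_max; capped = true; }

  arma::mat Gfull;
  arma::vec cfull;
  if (full_samples) {            // Gram precomputation fast path
    Gfull = (Xs.t() * Xs) / N;
    cfull = (Xs.t() * yc) / N;
  }

  IntegerVector counts(n);
  double lam = 0.0;
  int steps = 0;
  while (true) {
    if (stop_rule == 0 && lam > lam_stop) break;
    if (lam > lambda_max) { capped = true; break; }

    IntegerVector f = full_features ? cand
                      : as<IntegerVector>(Rcpp::sample(cand, nf, false));
    arma::uvec fi(f.size());
    for (int k = 0; k < f.size(); ++k) fi[k] = (unsigned)f[k];

    arma::mat G;
    arma::vec c;
    if (full_samples) {
      G = Gfull.submat(fi, fi);
      c = cfull.elem(fi);
    } else {
      IntegerVector s = Rcpp::sample(N, ns, false);   // 1-based
      arma::uvec si(s.size());
      for (int k = 0; k < s.size(); ++k) si[k] = (unsigned)(s[k] - 1);
      arma::mat Xsub = X.submat(si, fi);
      arma::vec ysub = X.col(tgt);
      ysub = ysub.elem(si);
      arma::rowvec m2 = arma::mean(Xsub, 0);
      arma::rowvec s2 = arma::sqrt(arma::mean(arma::square(Xsub), 0) -
                                   arma::square(m2));
      Xsub.each_row() -= m2;
      for (unsigned j = 0; j < Xsub.n_cols; ++j)
        if (s2[j] > 1e-12) Xsub.col(j) /= s2[j]; else Xsub.col(j).zeros();
      double ymu = arma::mean(ysub);
      double ysd = std::sqrt(arma::mean(arma::square(ysub)) - ymu * ymu);
      ysub -= ymu;
      if (ysd > 1e-12) ysub /= ysd;
      G = (Xsub.t() * Xsub) / ns;
      c = (Xsub.t() * ysub) / ns;
    }

    arma::vec b;
    if (lam == 0.0) {
      b = arma::pinv(G) * c;     // minimum-norm least squares
    } else {
      b = cd_lasso_gram(G, c, lam, cd_tol, cd_maxit);
    }

    int n_sel = 0;
    for (int k = 0; k < f.size(); ++k) {
      if (std::fabs(b[k]) > coef_tol) { counts[f[k]] += 1; ++n_sel; }
    }
    ++steps;
    if (stop_rule == 1 && n_sel == 0) break;
    lam += stepsize;
  }

  counts.attr("steps") = steps;
  counts.attr("capped") = capped;
  counts.attr("lambda_stop") = lam_stop;
  return counts;
}
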