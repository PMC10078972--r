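#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Preorder traversal of the piecewise-OU moment recursions. Edges must be
// ordered parents-before-children; nodes are 1-based ape indices. Returns
// the root-to-node decay D, per-regime optimum weights W and accumulated
// variance v for every node.
// [[Rcpp::export]]
List ou_traverse_cpp(const arma::imat& edge, const arma::vec& len,
                     const arma::ivec& regIdx, const arma::vec& alphaReg,
                     const arma::vec& sigmaReg, const int nNode,
                     const int root, const int k) {
  arma::vec D(nNode, arma::fill::zeros);
  arma::vec v(nNode, arma::fill::zeros);
  arma::mat W(nNode, k, arma::fill::zeros);
  D(root - 1) = 1.0;
  const int nE = edge.n_rows;
  for (int e = 0; e < nE; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    const double t = len(e);
    const int r = regIdx(e) - 1;
    const double a = alphaReg(r), s2 = sigmaReg(r);
    double d, vinc;
    if (a * t < 1e-8) {           // Brownian-motion limit
      d = 1.0;
      vinc = s2 * t;
    } else {
      d = std::exp(-a * t);
      vinc = s2 * (1.0 - std::exp(-2.0 * a * t)) / (2.0 * a);
    }
    D(c) = D(p) * d;
    W.row(c) = W.row(p) * d;
    W(c, r) += 1.0 - d;
    v(c) = v(p) * d * d + vinc;
  }
  return List::create(_["D"] = D, _["W"] = W, _["v"] = v);
}

// Assemble the tip covariance matrix of a piecewise OU process from
// per-node accumulated variances v and root-to-node decay factors d:
// Cov(i, j) = v[mrca] * (d_i / d_mrca) * (d_j / d_mrca), Var(i) = v[i].
// Tips are nodes 1..n in ape's numbering, so row i of the mrca index
// matrix refers to tip node i.
static arma::mat build_cov(const arma::vec& vAll, const arma::vec& dAll,
                           const arma::imat& mrcaIdx) {
  const int n = mrcaIdx.n_rows;
  arma::mat V(n, n);
  for (int i = 0; i < n; ++i) {
    V(i, i) = vAll(i);
    for (int j = 0; j < i; ++j) {
      const int m = mrcaIdx(i, j) - 1;
      const double dm = dAll(m);
      double c = 0.0;
      if (dm > 0.0 && vAll(m) > 0.0) {
        c = vAll(m) * (dAll(i) / dm) * (dAll(j) / dm);
        if (!std::isfinite(c)) c = 0.0;
      }
      V(i, j) = V(j, i) = c;
    }
  }
  return V;
}

// Gaussian negative log-likelihood with the mean profiled out by GLS:
// beta = argmin (y - X b)' V^{-1} (y - X b), via one Cholesky factor.
// [[Rcpp::export]]
List ou_profile_nll_cpp(const arma::vec& y, const arma::mat& X,
                        const arma::vec& vAll, const arma::vec& dAll,
                        const arma::imat& mrcaIdx,
                        const double jitter_scale = 1e-10) {
  const int n = y.n_elem;
  arma::mat V = build_cov(vAll, dAll, mrcaIdx);
  V.diag() += jitter_scale * arma::mean(V.diag());
  arma::mat L;
  if (!arma::chol(L, V, "lower")) {
    return List::create(_["ok"] = false);
  }
  arma::mat Z = arma::solve(arma::trimatl(L), X);
  arma::vec w = arma::solve(arma::trimatl(L), y);
  arma::mat ZtZ = Z.t() * Z;
  arma::vec Ztw = Z.t() * w;
  arma::vec beta;
  if (!arma::solve(beta, ZtZ, Ztw, arma::solve_opts::no_approx)) {
    beta = arma::pinv(ZtZ) * Ztw;  // rank-deficient design (e.g. huge alpha)
  }
  arma::vec r = w - Z * beta;
  const double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  const double nll = 0.5 * (n * std::log(2.0 * M_PI) + logdet +
                            arma::dot(r, r));
  return List::create(_["ok"] = true, _["nll"] = nll, _["beta"] = beta);
}

// Same covariance assembly, likelihood at a fixed mean vector (used for
// finite-difference Hessians over the full parameter set).
// [[Rcpp::export]]
List ou_fixed_nll_cpp(const arma::vec& y, const arma::vec& mu,
                      const arma::vec& vAll, const arma::vec& dAll,
                      const arma::imat& mrcaIdx,
                      const double jitter_scale = 1e-10) {
  const int n = y.n_elem;
  arma::mat V = build_cov(vAll, dAll, mrcaIdx);
  V.diag() += jitter_scale * arma::mean(V.diag());
  arma::mat L;
  if (!arma::chol(L, V, "lower")) {
    return List::create(_["ok"] = false);
  }
  arma::vec r = arma::solve(arma::trimatl(L), y - mu);
  const double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  const double nll = 0.5 * (n * std::log(2.0 * M_PI) + logdet +
                            arma::dot(r, r));
  return List::create(_["ok"] = true, _["nll"] = nll);
}
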