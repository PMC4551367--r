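// Compiled kernels: the all-pairs bivariate GC scan, the ARACNE
// data-processing-inequality sweep and MRNET forward selection. These are
// O(n^2) - O(n^3) loops over thousands of genes, far too slow in plain R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// F statistics for all ordered pairs of a pairwise Granger scan.
// G = X'X ((np x np) lag cross-products, lag-major blocks), V = X'Y,
// yty = per-target squared norms, n genes, order p. m (= rows of X) sets the
// denominator degrees of freedom m - 2p. Returns an n x n matrix with
// F(i -> j) in entry (i, j); the diagonal is zero.
// [[Rcpp::export]]
arma::mat pgc_f_matrix_cpp(const arma::mat& G, const arma::mat& V,
                           const arma::vec& yty, int n, int p, int m) {
  arma::mat F(n, n, arma::fill::zeros);
  const double df2 = (double)(m - 2 * p);
  arma::uvec idx(p), idxc(2 * p);

  // reduced (univariate) RSS per target
  arma::vec rss_red(n);
  for (int j = 0; j < n; ++j) {
    for (int l = 0; l < p; ++l) idx(l) = (arma::uword)(l * n + j);
    arma::mat A = G.submat(idx, idx);
    arma::vec b = V.submat(idx, arma::uvec{(arma::uword)j});
    arma::vec sol = arma::solve(A, b, arma::solve_opts::likely_sympd);
    rss_red(j) = yty(j) - arma::dot(b, sol);
    if (rss_red(j) < 0) rss_red(j) = 0;
  }

  for (int j = 0; j < n; ++j) {
    for (int l = 0; l < p; ++l) idxc(l) = (arma::uword)(l * n + j);
    for (int i = 0; i < n; ++i) {
      if (i == j) continue;
      for (int l = 0; l < p; ++l) idxc(p + l) = (arma::uword)(l * n + i);
      arma::mat A = G.submat(idxc, idxc);
      arma::vec b = V.submat(idxc, arma::uvec{(arma::uword)j});
      arma::vec sol;
      bool ok = arma::solve(sol, A, b, arma::solve_opts::likely_sympd);
      if (!ok) { F(i, j) = 0; continue; }
      double rss_full = yty(j) - arma::dot(b, sol);
      if (rss_full < 1e-300) rss_full = 1e-300;
      double f = ((rss_red(j) - rss_full) / p) / (rss_full / df2);
      F(i, j) = (f > 0) ? f : 0.0;
    }
    if (j % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return F;
}

// ARACNE data-processing-inequality mask: entry (i, j) is true when the
// (symmetric) MI of pair (i, j) is below both MI(i, k) and MI(j, k) minus
// eps for some third gene k, i.e. the edge is explainable as indirect.
// [[Rcpp::export]]
LogicalMatrix dpi_mask_cpp(const arma::mat& M, double eps) {
  int n = M.n_rows;
  LogicalMatrix rem(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double mij = M(i, j);
      bool removed = false;
      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        double lo = std::min(M(i, k), M(j, k));
        if (mij < lo - eps) { removed = true; break; }
      }
      rem(i, j) = rem(j, i) = removed;
    }
    if (i % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return rem;
}

// MRNET maximum-relevance / minimum-redundancy forward selection.
// M is the (symmetric) MI matrix. For each target t predictors are selected
// greedily by score(j) = MI(j, t) - mean_{k in selected} MI(j, k) while the
// best score stays positive; the returned matrix S holds, in S(j, t), the
// score of predictor j at the moment it was selected (0 if never selected).
// [[Rcpp::export]]
arma::mat mrnet_scores_cpp(const arma::mat& M) {
  int n = M.n_rows;
  arma::mat S(n, n, arma::fill::zeros);
  std::vector<double> sumred(n);
  std::vector<char> sel(n);
  for (int t = 0; t < n; ++t) {
    std::fill(sumred.begin(), sumred.end(), 0.0);
    std::fill(sel.begin(), sel.end(), 0);
    sel[t] = 1;
    int nsel = 0;
    while (true) {
      int best = -1;
      double bestscore = 0.0;
      for (int j = 0; j < n; ++j) {
        if (sel[j]) continue;
        double sc = M(j, t) - (nsel ? sumred[j] / nsel : 0.0);
        if (sc > bestscore) { bestscore = sc; best = j; }
      }
      if (best < 0) break;
      S(best, t) = bestscore;
      sel[best] = 1;
      ++nsel;
      for (int j = 0; j < n; ++j)
        if (!sel[j]) sumred[j] += M(j, best);
    }
    if (t % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return S;
}
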