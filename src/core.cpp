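#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Neighbour lists arrive 1-based from R; all loops below subtract on use.

// Sequential ICM label sweeps. logdens is n x K (Gaussian log density of
// v - u under each cluster); beta the slide smoothness. Sweeps stop early
// once a full pass changes nothing. Ties go to the smaller cluster index.
// [[Rcpp::export]]
IntegerVector icm_labels_cpp(const arma::mat& logdens, double beta,
                             const List& nbrs, IntegerVector labels,
                             int max_sweeps) {
  const int n = logdens.n_rows, K = logdens.n_cols;
  IntegerVector lab = clone(labels);
  std::vector<double> score(K);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      IntegerVector nb = nbrs[i];
      for (int k = 0; k < K; ++k) score[k] = logdens(i, k);
      for (int j = 0; j < nb.size(); ++j)
        score[lab[nb[j] - 1] - 1] += beta;
      int best = 0;
      for (int k = 1; k < K; ++k)
        if (score[k] > score[best]) best = k;   // strict: ties keep smaller k
      if (best + 1 != lab[i]) { lab[i] = best + 1; changed = true; }
    }
    if (!changed) break;
  }
  return lab;
}

// One in-place ICM sweep over the batch embeddings u of a slide.
// siginv: K stacked q x q inverses of the cluster covariances;
// laminv: diagonal of Lambda_t^{-1}. For a spot with degree d and
// neighbour mean ubar the posterior mode solves
//   (Sigma_k^{-1} + d Lambda^{-1}) u = Sigma_k^{-1}(v - mu_k) + d Lambda^{-1} ubar;
// isolated spots use the marginal prior N(0, Lambda).
// [[Rcpp::export]]
arma::mat icm_u_cpp(const arma::mat& v, const arma::mat& mu,
                    const arma::cube& siginv, const arma::vec& laminv,
                    IntegerVector labels, const List& nbrs, arma::mat u) {
  const int n = v.n_rows, q = v.n_cols;
  arma::mat Lam = arma::diagmat(laminv);
  for (int i = 0; i < n; ++i) {
    const int k = labels[i] - 1;
    IntegerVector nb = nbrs[i];
    const int d = nb.size();
    arma::vec resid = (v.row(i) - mu.row(k)).t();
    arma::vec rhs = siginv.slice(k) * resid;
    arma::mat A = siginv.slice(k);
    if (d > 0) {
      arma::vec ubar(q, arma::fill::zeros);
      for (int j = 0; j < d; ++j) ubar += u.row(nb[j] - 1).t();
      ubar /= d;
      A += d * Lam;
      rhs += d * (Lam * ubar);
    } else {
      A += Lam;
    }
    u.row(i) = arma::solve(A, rhs, arma::solve_opts::likely_sympd).t();
  }
  return u;
}

// Gibbs sampler for the Potts field: sequential conditional updates
// P(y_i = k | neighbours) proportional to exp(beta * m_ik). Uses R's RNG
// so draws are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector potts_gibbs_cpp(const List& nbrs, int K, double beta,
                              IntegerVector init, int n_sweeps) {
  const int n = init.size();
  IntegerVector lab = clone(init);
  std::vector<double> w(K);
  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      IntegerVector nb = nbrs[i];
      std::vector<int> m(K, 0);
      for (int j = 0; j < nb.size(); ++j) m[lab[nb[j] - 1] - 1]++;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) { w[k] = std::exp(beta * m[k]); tot += w[k]; }
      double uny = unif_rand() * tot, acc = 0.0;
      int pick = K - 1;
      for (int k = 0; k < K; ++k) { acc += w[k]; if (uny <= acc) { pick = k; break; } }
      lab[i] = pick + 1;
    }
  }
  return lab;
}
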