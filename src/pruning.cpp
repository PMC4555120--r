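#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Felsenstein pruning for a reversible amino-acid model, one pass per rate
// category, with per-site scaling to avoid underflow on large trees.
//
// tips   : ntip x nsites integer matrix of state codes 1..20 (0 = missing)
// edge   : (parent, child) pairs, 1-based ape node ids, postorder
// elen   : branch lengths (expected substitutions/site), one per edge row
// V, Vinv, lambda : eigensystem of the scaled rate matrix Q
// pi     : equilibrium frequencies
// rates  : rate-category multipliers
//
// Returns an nsites x ncat matrix of per-category site log-likelihoods.
// [[Rcpp::export(name = ".prune_loglik_cpp")]]
arma::mat prune_loglik_cpp(const arma::imat& tips,
                           const arma::imat& edge,
                           const arma::vec& elen,
                           const int n_node,
                           const arma::mat& V,
                           const arma::mat& Vinv,
                           const arma::vec& lambda,
                           const arma::vec& pi,
                           const arma::vec& rates) {
  const int ntip = tips.n_rows;
  const int nsites = tips.n_cols;
  const int nedge = edge.n_rows;
  const int ntot = ntip + n_node;
  const int ncat = rates.n_elem;
  const int root = edge(nedge - 1, 0) - 1;

  arma::mat out(nsites, ncat);

  for (int k = 0; k < ncat; ++k) {
    std::vector<arma::mat> partial(ntot);
    std::vector<bool> started(ntot, false);
    arma::rowvec logscale(nsites, arma::fill::zeros);

    for (int e = 0; e < nedge; ++e) {
      const int parent = edge(e, 0) - 1;
      const int child = edge(e, 1) - 1;
      const double t = elen[e] * rates[k];
      arma::mat P;
      if (t == 0.0) {
        P = arma::eye(20, 20);    // exact identity at zero length
      } else {
        P = V * arma::diagmat(arma::exp(lambda * t)) * Vinv;
        P.clamp(0.0, arma::datum::inf);
      }

      arma::mat contrib(20, nsites);
      if (child < ntip) {
        const arma::vec ones20(20, arma::fill::ones);
        for (int i = 0; i < nsites; ++i) {
          const int code = tips(child, i);
          if (code > 0) contrib.col(i) = P.col(code - 1);
          else contrib.col(i) = ones20;
        }
      } else {
        // internal child: its partial is complete (postorder); rescale it
        // into the shared per-site log-scaler before use
        arma::mat& L = partial[child];
        for (int i = 0; i < nsites; ++i) {
          const double m = L.col(i).max();
          if (m > 0 && m < 1e-40) { /* keep; scaled below anyway */ }
          if (m > 0) {
            L.col(i) /= m;
            logscale[i] += std::log(m);
          }
        }
        contrib = P * L;
      }

      if (!started[parent]) {
        partial[parent] = contrib;
        started[parent] = true;
      } else {
        partial[parent] %= contrib;
      }
    }

    arma::rowvec site_l = pi.t() * partial[root];
    for (int i = 0; i < nsites; ++i) {
      out(i, k) = (site_l[i] > 0)
        ? std::log(site_l[i]) + logscale[i]
        : -arma::datum::inf;
    }
  }
  return out;
}
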