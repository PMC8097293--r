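// Felsenstein pruning for the 61-state codon model.
// The rate matrix is reversible (pi_i q_ij = pi_j q_ji), so transition
// matrices are obtained from the symmetric eigendecomposition of
// D^{1/2} Q D^{-1/2}, shared across branches of the same omega class.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat buildQ(const arma::vec& pi, double kappa, double omega,
                        const IntegerVector& nbr_i, const IntegerVector& nbr_j,
                        const IntegerVector& nbr_ti,
                        const IntegerVector& nbr_ns) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (int k = 0; k < nbr_i.size(); ++k) {
    double r = pi[nbr_j[k]];
    if (nbr_ti[k]) r *= kappa;
    if (nbr_ns[k]) r *= omega;
    Q(nbr_i[k], nbr_j[k]) = r;
  }
  arma::vec rs = arma::sum(Q, 1);
  Q.diag() = -rs;
  double scale = arma::dot(pi, rs);
  if (scale > 0) Q /= scale;
  return Q;
}

// [[Rcpp::export]]
double cpp_codon_lnL(IntegerMatrix edge, int nPatRows, IntegerMatrix patterns,
                     NumericVector weights, NumericVector pi_, double kappa,
                     NumericVector omega, IntegerVector edgeClass,
                     NumericVector tEdge, IntegerVector nbr_i,
                     IntegerVector nbr_j, IntegerVector nbr_ti,
                     IntegerVector nbr_ns) {
  const int n = pi_.size();            // 61
  const int nPat = patterns.ncol();
  const int nTip = patterns.nrow();
  const int nEdge = edge.nrow();
  arma::vec pi(pi_.begin(), n);
  arma::vec sq = arma::sqrt(pi);

  // eigendecomposition per omega class
  const int nClass = omega.size();
  std::vector<arma::vec> evals(nClass);
  std::vector<arma::mat> evecs(nClass);
  for (int c = 0; c < nClass; ++c) {
    arma::mat Q = buildQ(pi, kappa, omega[c], nbr_i, nbr_j, nbr_ti, nbr_ns);
    arma::mat S = Q;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        S(i, j) *= sq[i] / sq[j];
    S = 0.5 * (S + S.t());
    arma::vec ev; arma::mat V;
    if (!arma::eig_sym(ev, V, S)) return R_NegInf;
    evals[c] = ev; evecs[c] = V;
  }

  int nNode = 0;
  for (int e = 0; e < nEdge; ++e)
    nNode = std::max(nNode, std::max(edge(e, 0), edge(e, 1)));

  // partial likelihoods for internal nodes only
  std::vector<arma::mat> partial(nNode + 1);
  std::vector<bool> started(nNode + 1, false);
  arma::vec logScale(nPat, arma::fill::zeros);

  for (int e = 0; e < nEdge; ++e) {
    const int par = edge(e, 0);
    const int chd = edge(e, 1);
    const int cls = edgeClass[e];
    const arma::mat& V = evecs[cls];
    arma::vec expv = arma::exp(evals[cls] * tEdge[e]);
    arma::mat P = V * arma::diagmat(expv) * V.t();
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double v = P(i, j) * (sq[j] / sq[i]);
        P(i, j) = v > 0 ? v : 0.0;
      }

    arma::mat contrib(n, nPat);
    if (chd <= nTip) {                     // tip child
      arma::vec ones(n, arma::fill::ones);
      for (int p = 0; p < nPat; ++p) {
        int s = patterns(chd - 1, p);
        if (s < 0) contrib.col(p) = ones;  // gap: missing data
        else contrib.col(p) = P.col(s);
      }
    } else {
      arma::mat& L = partial[chd];
      // rescale child partials to avoid underflow
      for (int p = 0; p < nPat; ++p) {
        double m = L.col(p).max();
        if (m > 0 && m < 1e-200) {
          L.col(p) /= m;
          logScale[p] += std::log(m);
        } else if (m <= 0) {
          return R_NegInf;
        }
      }
      contrib = P * L;
    }
    if (!started[par]) {
      partial[par] = contrib;
      started[par] = true;
    } else {
      partial[par] %= contrib;
    }
  }

  const int root = nTip + 1;
  double lnL = 0.0;
  for (int p = 0; p < nPat; ++p) {
    double site = arma::dot(pi, partial[root].col(p));
    if (site <= 0 || !std::isfinite(site)) return R_NegInf;
    lnL += weights[p] * (std::log(site) + logScale[p]);
  }
  return lnL;
}
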