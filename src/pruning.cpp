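// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// P(t) = U diag(exp(lam t)) W for a reversible generator decomposed in R.
static arma::mat pmat(const arma::mat& U, const arma::vec& lam,
                      const arma::mat& W, double t) {
  arma::vec e = arma::exp(lam * t);
  arma::mat P = U * arma::diagmat(e) * W;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// [[Rcpp::export]]
NumericMatrix gy94_pmat_cpp(NumericMatrix U_, NumericVector lam_,
                            NumericMatrix W_, double t) {
  arma::mat U(U_.begin(), U_.nrow(), U_.ncol(), false);
  arma::vec lam(lam_.begin(), lam_.size(), false);
  arma::mat W(W_.begin(), W_.nrow(), W_.ncol(), false);
  return wrap(pmat(U, lam, W, t));
}

// Felsenstein pruning over codon site patterns.
//
// eig: list of per-rate-class lists(U, lam, W) so that P_c(t) = U e^{lam t} W.
// edge_parent/edge_child: 1-based node ids in postorder (children before
// parents); tips are 1..ntip. tip_states: ntip x npat matrix of codon state
// indices in 1..nstate, 0 = missing (gap/ambiguous codon; partial likelihood
// one over all states). weights: pattern multiplicities. pi: root frequencies.
// [[Rcpp::export]]
double pruning_lnl_cpp(List eig, IntegerVector edge_parent,
                       IntegerVector edge_child, NumericVector edge_len,
                       IntegerVector edge_class, IntegerMatrix tip_states,
                       NumericVector weights, NumericVector pi,
                       int n_nodes) {
  int nstate = pi.size();
  int npat = tip_states.ncol();
  int ntip = tip_states.nrow();
  int nedge = edge_parent.size();

  int nclass = eig.size();
  std::vector<arma::mat> Us(nclass), Ws(nclass);
  std::vector<arma::vec> lams(nclass);
  for (int c = 0; c < nclass; ++c) {
    List e = eig[c];
    NumericMatrix U_ = e["U"], W_ = e["W"];
    NumericVector l_ = e["lam"];
    Us[c] = arma::mat(U_.begin(), U_.nrow(), U_.ncol());
    Ws[c] = arma::mat(W_.begin(), W_.nrow(), W_.ncol());
    lams[c] = arma::vec(l_.begin(), l_.size());
  }

  std::vector<arma::mat> part(n_nodes + 1);
  double logscale = 0.0;
  arma::rowvec wts(npat);
  for (int s = 0; s < npat; ++s) wts(s) = weights[s];

  for (int e = 0; e < nedge; ++e) {
    int par = edge_parent[e], ch = edge_child[e];
    int cls = edge_class[e] - 1;
    arma::mat P = pmat(Us[cls], lams[cls], Ws[cls], edge_len[e]);
    arma::mat L(nstate, npat);
    if (ch <= ntip) {
      for (int s = 0; s < npat; ++s) {
        int st = tip_states(ch - 1, s);
        if (st == 0) L.col(s).ones();
        else L.col(s) = P.col(st - 1);
      }
    } else {
      L = P * part[ch];
      part[ch].reset();
      // rescale to avoid underflow
      arma::rowvec cm = arma::max(L, 0);
      if (cm.min() <= 0.0) return -std::numeric_limits<double>::infinity();
      L.each_row() /= cm;
      logscale += arma::dot(wts, arma::log(cm));
    }
    if (part[par].n_elem == 0) part[par] = L;
    else part[par] %= L;
  }

  int root = edge_parent[nedge - 1];
  arma::vec piv(pi.begin(), nstate);
  arma::rowvec rootl = piv.t() * part[root];
  if (rootl.min() <= 0.0) return -std::numeric_limits<double>::infinity();
  return logscale + arma::dot(wts, arma::log(rootl));
}
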