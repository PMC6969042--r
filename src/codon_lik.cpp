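// Felsenstein pruning likelihood for the MG94 x HKY codon model with equal
// codon frequencies. With uniform frequencies the rate matrix is symmetric,
// so transition probabilities come from one symmetric eigendecomposition per
// (alpha, beta) rate pair and P(t) v is applied as U (exp(lambda t) .* (U' v))
// without ever forming P.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NC = 61;

// pairs: npair x 4 integer matrix (i, j, transition, synonymous), 1-based i/j
static arma::mat build_q(const IntegerMatrix &pairs, double kappa,
                         double alpha, double beta, double scale) {
  arma::mat Q(NC, NC, arma::fill::zeros);
  for (int p = 0; p < pairs.nrow(); ++p) {
    int i = pairs(p, 0) - 1, j = pairs(p, 1) - 1;
    double r = (pairs(p, 2) == 1 ? kappa : 1.0) *
               (pairs(p, 3) == 1 ? alpha : beta);
    Q(i, j) = r / scale;
  }
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

// X: S x N codon-state matrix (1-based states, NA = missing)
// edge: E x 2 postorder edges (1-based node ids, tips 1..N)
// alpha/beta: length S (per-site rates); sites sharing a rate pair share
// one eigendecomposition.
// [[Rcpp::export]]
NumericVector cpp_mg94_site_loglik(IntegerMatrix X, IntegerMatrix edge,
                                   NumericVector blen, double kappa,
                                   NumericVector alpha, NumericVector beta,
                                   IntegerMatrix pairs, double scale) {
  int S = X.nrow(), N = X.ncol(), E = edge.nrow();
  int root = edge(E - 1, 0);
  int nnode = 0;
  for (int e = 0; e < E; ++e) {
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  }
  // group sites by (alpha, beta)
  std::vector<int> cls(S, -1);
  std::vector<std::pair<double, double>> uniq;
  for (int s = 0; s < S; ++s) {
    for (size_t u = 0; u < uniq.size(); ++u) {
      if (uniq[u].first == alpha[s] && uniq[u].second == beta[s]) {
        cls[s] = u;
        break;
      }
    }
    if (cls[s] < 0) {
      uniq.push_back({alpha[s], beta[s]});
      cls[s] = uniq.size() - 1;
    }
  }
  int C = uniq.size();
  std::vector<arma::mat> U(C);
  std::vector<arma::vec> lam(C);
  for (int c = 0; c < C; ++c) {
    arma::mat Q = build_q(pairs, kappa, uniq[c].first, uniq[c].second, scale);
    arma::vec ev;
    arma::mat evec;
    arma::eig_sym(ev, evec, Q);
    U[c] = evec;
    lam[c] = ev;
  }
  // per-edge, per-class exp(lambda * t)
  std::vector<std::vector<arma::vec>> ex(E, std::vector<arma::vec>(C));
  for (int e = 0; e < E; ++e)
    for (int c = 0; c < C; ++c) ex[e][c] = arma::exp(lam[c] * blen[e]);
  NumericVector out(S);
  arma::mat partial(NC, nnode);
  arma::vec ones(NC, arma::fill::ones);
  for (int s = 0; s < S; ++s) {
    int c = cls[s];
    double logscale = 0.0;
    std::vector<bool> init(nnode, false);
    for (int t = 0; t < N; ++t) {
      partial.col(t).zeros();
      if (IntegerMatrix::is_na(X(s, t))) {
        partial.col(t).ones();
      } else {
        partial(X(s, t) - 1, t) = 1.0;
      }
      init[t] = true;
    }
    for (int nd = N; nd < nnode; ++nd) init[nd] = false;
    for (int e = 0; e < E; ++e) {
      int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      arma::vec w = U[c].t() * partial.col(ch);
      w %= ex[e][c];
      arma::vec m = U[c] * w;
      m.transform([](double v) { return v < 1e-300 ? (v < 0 ? 0.0 : v) : v; });
      if (!init[par]) {
        partial.col(par) = m;
        init[par] = true;
      } else {
        partial.col(par) %= m;
      }
      double mx = partial.col(par).max();
      if (mx > 0 && mx < 1e-150) {
        partial.col(par) /= mx;
        logscale += std::log(mx);
      }
    }
    double lik = arma::mean(partial.col(root - 1));
    out[s] = lik > 0 ? std::log(lik) + logscale : R_NegInf;
  }
  return out;
}

// eigendecomposition of Q(alpha = 1, beta = omega); Q(alpha, alpha * omega)
// then shares the eigenvectors with eigenvalues scaled by alpha
// [[Rcpp::export]]
List cpp_mg94_eig(double kappa, double omega, IntegerMatrix pairs,
                  double scale) {
  arma::mat Q = build_q(pairs, kappa, 1.0, omega, scale);
  arma::vec ev;
  arma::mat evec;
  arma::eig_sym(ev, evec, Q);
  return List::create(_["U"] = evec, _["lam"] = ev);
}

// pruning likelihood from a fixed eigensystem with a per-site rate
// multiplier (alpha); avoids re-decomposing when only the overall site rate
// changes.
// [[Rcpp::export]]
NumericVector cpp_site_loglik_eig(IntegerMatrix X, IntegerMatrix edge,
                                  NumericVector blen, arma::mat U,
                                  arma::vec lam, NumericVector mult) {
  int S = X.nrow(), N = X.ncol(), E = edge.nrow();
  int root = edge(E - 1, 0);
  int nnode = 0;
  for (int e = 0; e < E; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));
  NumericVector out(S);
  arma::mat partial(NC, nnode);
  for (int s = 0; s < S; ++s) {
    double m_s = mult[s];
    double logscale = 0.0;
    std::vector<bool> init(nnode, false);
    for (int t = 0; t < N; ++t) {
      partial.col(t).zeros();
      if (IntegerMatrix::is_na(X(s, t))) partial.col(t).ones();
      else partial(X(s, t) - 1, t) = 1.0;
      init[t] = true;
    }
    for (int nd = N; nd < nnode; ++nd) init[nd] = false;
    for (int e = 0; e < E; ++e) {
      int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      arma::vec w = U.t() * partial.col(ch);
      w %= arma::exp(lam * (m_s * blen[e]));
      arma::vec m = U * w;
      m.transform([](double v) { return v < 0 ? 0.0 : v; });
      if (!init[par]) { partial.col(par) = m; init[par] = true; }
      else partial.col(par) %= m;
      double mx = partial.col(par).max();
      if (mx > 0 && mx < 1e-150) {
        partial.col(par) /= mx;
        logscale += std::log(mx);
      }
    }
    double lik = arma::mean(partial.col(root - 1));
    out[s] = lik > 0 ? std::log(lik) + logscale : R_NegInf;
  }
  return out;
}
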