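// Saitou-Nei neighbor joining with deterministic lexicographic tie-breaking
// and non-negative branch lengths (negative estimates are clamped to zero
// with the deficit moved to the sibling branch), plus the least-squares
// tree-misfit machinery used by the recombination breakpoint scan.
#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
using namespace Rcpp;

struct NJResult {
  std::string newick;
  std::vector<double> coph; // n x n tip-to-tip tree distances, row-major
};

// D: n x n distances (row-major vector), rank: tie-break rank per tip
// (lower rank wins; pass the lexicographic rank of the taxon label).
static NJResult nj_core(const std::vector<double> &D0, int n,
                        const std::vector<int> &rank,
                        const std::vector<std::string> &labels) {
  std::vector<double> D = D0;
  std::vector<bool> active(n, true);
  std::vector<std::string> frag(labels);
  std::vector<int> rep(rank); // representative rank per cluster
  // members of each cluster and their depth (distance to cluster root)
  std::vector<std::vector<int>> mem(n);
  std::vector<std::vector<double>> dep(n);
  for (int i = 0; i < n; ++i) { mem[i] = {i}; dep[i] = {0.0}; }
  NJResult res;
  res.coph.assign((size_t)n * n, 0.0);
  auto d = [&](int i, int j) -> double & { return D[(size_t)i * n + j]; };
  int r = n;
  while (r > 3) {
    // row sums over active clusters
    std::vector<double> R(n, 0.0);
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      for (int j = 0; j < n; ++j)
        if (active[j] && j != i) R[i] += d(i, j);
    }
    double bestQ = R_PosInf;
    int bi = -1, bj = -1;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      for (int j = i + 1; j < n; ++j) {
        if (!active[j]) continue;
        double Q = (r - 2) * d(i, j) - R[i] - R[j];
        int lo = std::min(rep[i], rep[j]), hi = std::max(rep[i], rep[j]);
        bool better = false;
        if (Q < bestQ - 1e-12) better = true;
        else if (std::fabs(Q - bestQ) <= 1e-12 && bi >= 0) {
          int blo = std::min(rep[bi], rep[bj]), bhi = std::max(rep[bi], rep[bj]);
          if (lo < blo || (lo == blo && hi < bhi)) better = true;
        }
        if (better) { bestQ = Q; bi = i; bj = j; }
      }
    }
    double bij = d(bi, bj);
    double li = 0.5 * bij + (R[bi] - R[bj]) / (2.0 * (r - 2));
    double lj = bij - li;
    if (li < 0) { lj += li; li = 0; }
    if (lj < 0) { li += lj; lj = 0; if (li < 0) li = 0; }
    // tree distances across the two clusters
    for (size_t a = 0; a < mem[bi].size(); ++a)
      for (size_t b = 0; b < mem[bj].size(); ++b) {
        int x = mem[bi][a], y = mem[bj][b];
        double v = dep[bi][a] + li + dep[bj][b] + lj;
        res.coph[(size_t)x * n + y] = v;
        res.coph[(size_t)y * n + x] = v;
      }
    // merge j into i
    char bufi[32], bufj[32];
    snprintf(bufi, 32, "%.10g", li);
    snprintf(bufj, 32, "%.10g", lj);
    frag[bi] = "(" + frag[bi] + ":" + bufi + "," + frag[bj] + ":" + bufj + ")";
    for (size_t a = 0; a < mem[bi].size(); ++a) dep[bi][a] += li;
    for (size_t b = 0; b < mem[bj].size(); ++b) {
      mem[bi].push_back(mem[bj][b]);
      dep[bi].push_back(dep[bj][b] + lj);
    }
    rep[bi] = std::min(rep[bi], rep[bj]);
    active[bj] = false;
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi) continue;
      double nd = 0.5 * (d(bi, k) + d(bj, k) - bij);
      if (nd < 0) nd = 0;
      d(bi, k) = nd;
      d(k, bi) = nd;
    }
    --r;
  }
  // final join of the remaining clusters (3, or 2 for tiny inputs)
  std::vector<int> rem;
  for (int i = 0; i < n; ++i)
    if (active[i]) rem.push_back(i);
  if (rem.size() == 3) {
    int a = rem[0], b = rem[1], c = rem[2];
    double la = 0.5 * (d(a, b) + d(a, c) - d(b, c));
    double lb = 0.5 * (d(a, b) + d(b, c) - d(a, c));
    double lc = 0.5 * (d(a, c) + d(b, c) - d(a, b));
    if (la < 0) la = 0;
    if (lb < 0) lb = 0;
    if (lc < 0) lc = 0;
    int cl[3] = {a, b, c};
    double ln[3] = {la, lb, lc};
    for (int u = 0; u < 3; ++u)
      for (int v = u + 1; v < 3; ++v)
        for (size_t p = 0; p < mem[cl[u]].size(); ++p)
          for (size_t q = 0; q < mem[cl[v]].size(); ++q) {
            int x = mem[cl[u]][p], y = mem[cl[v]][q];
            double val = dep[cl[u]][p] + ln[u] + dep[cl[v]][q] + ln[v];
            res.coph[(size_t)x * n + y] = val;
            res.coph[(size_t)y * n + x] = val;
          }
    char b1[32], b2[32], b3[32];
    snprintf(b1, 32, "%.10g", la);
    snprintf(b2, 32, "%.10g", lb);
    snprintf(b3, 32, "%.10g", lc);
    res.newick = "(" + frag[a] + ":" + b1 + "," + frag[b] + ":" + b2 + "," +
                 frag[c] + ":" + b3 + ");";
  } else if (rem.size() == 2) {
    int a = rem[0], b = rem[1];
    double half = d(a, b) / 2;
    for (size_t p = 0; p < mem[a].size(); ++p)
      for (size_t q = 0; q < mem[b].size(); ++q) {
        int x = mem[a][p], y = mem[b][q];
        double val = dep[a][p] + dep[b][q] + d(a, b);
        res.coph[(size_t)x * n + y] = val;
        res.coph[(size_t)y * n + x] = val;
      }
    char b1[32];
    snprintf(b1, 32, "%.10g", 2 * half);
    res.newick = "(" + frag[a] + ":0," + frag[b] + ":" + b1 + ");";
  } else {
    res.newick = frag[rem[0]] + ";";
  }
  return res;
}

// [[Rcpp::export]]
List cpp_nj(NumericMatrix D, IntegerVector rank, CharacterVector labels,
            bool want_coph = false) {
  int n = D.nrow();
  std::vector<double> dv(D.begin(), D.end()); // column-major == row-major (symmetric)
  std::vector<int> rk(rank.begin(), rank.end());
  std::vector<std::string> lb(n);
  for (int i = 0; i < n; ++i) lb[i] = as<std::string>(labels[i]);
  NJResult res = nj_core(dv, n, rk, lb);
  List out = List::create(_["newick"] = res.newick);
  if (want_coph) {
    NumericMatrix C(n, n);
    std::copy(res.coph.begin(), res.coph.end(), C.begin());
    out["coph"] = C;
  }
  return out;
}

// sum of squared differences between a tree's tip distances and a distance
// matrix, fitting the tree by NJ on `Dfit` and evaluating against `Deval`
static double nj_misfit(const std::vector<double> &coph,
                        const std::vector<double> &Deval, int n) {
  double s = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double diff = coph[(size_t)i * n + j] - Deval[(size_t)i * n + j];
      s += diff * diff;
    }
  return s;
}

// Breakpoint scan. diffs/valid: S x P matrices (P = n(n-1)/2 pairs in
// row-major (i<j) order) of per-site pair difference / comparability
// indicators. orders: (n_perm + 1) x S site orders, first row must be the
// identity. For each order and candidate split b, partition p-distance
// matrices are built from prefix sums, NJ trees are fitted per partition,
// and the improvement of the two-tree fit over the single full-data tree is
// recorded. Returns observed per-candidate improvements and the per-order
// maximum for the permuted orders.
// [[Rcpp::export]]
List cpp_scan_breakpoints(IntegerMatrix diffs, IntegerMatrix valid, int n,
                          IntegerVector candidates, IntegerMatrix orders) {
  int S = diffs.nrow(), P = diffs.ncol(), nc = candidates.size();
  int n_ord = orders.nrow();
  std::vector<int> pi, pj;
  pi.reserve(P);
  pj.reserve(P);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) { pi.push_back(i); pj.push_back(j); }
  std::vector<int> rk(n), totd(P, 0), totv(P, 0);
  std::vector<std::string> lb(n);
  for (int i = 0; i < n; ++i) { rk[i] = i; lb[i] = "t"; }
  for (int s = 0; s < S; ++s)
    for (int p = 0; p < P; ++p) {
      totd[p] += diffs(s, p);
      totv[p] += valid(s, p);
    }
  auto to_mat = [&](const std::vector<int> &dd, const std::vector<int> &vv) {
    std::vector<double> M((size_t)n * n, 0.0);
    for (int p = 0; p < P; ++p) {
      double v = vv[p] > 0 ? (double)dd[p] / vv[p] : 0.0;
      M[(size_t)pi[p] * n + pj[p]] = v;
      M[(size_t)pj[p] * n + pi[p]] = v;
    }
    return M;
  };
  std::vector<double> Dall = to_mat(totd, totv);
  NJResult Tall = nj_core(Dall, n, rk, lb); // order-invariant: totals fixed
  NumericVector obs(nc);
  NumericVector permmax(n_ord - 1);
  for (int o = 0; o < n_ord; ++o) {
    // prefix sums in this site order
    std::vector<std::vector<int>> cd(S + 1, std::vector<int>(P, 0));
    std::vector<std::vector<int>> cv(S + 1, std::vector<int>(P, 0));
    for (int s = 0; s < S; ++s) {
      int site = orders(o, s) - 1;
      for (int p = 0; p < P; ++p) {
        cd[s + 1][p] = cd[s][p] + diffs(site, p);
        cv[s + 1][p] = cv[s][p] + valid(site, p);
      }
    }
    double omax = R_NegInf;
    for (int c = 0; c < nc; ++c) {
      int b = candidates[c];
      std::vector<int> dl(P), vl(P), dr(P), vr(P);
      for (int p = 0; p < P; ++p) {
        dl[p] = cd[b][p];
        vl[p] = cv[b][p];
        dr[p] = totd[p] - dl[p];
        vr[p] = totv[p] - vl[p];
      }
      std::vector<double> DL = to_mat(dl, vl), DR = to_mat(dr, vr);
      NJResult TL = nj_core(DL, n, rk, lb);
      NJResult TR = nj_core(DR, n, rk, lb);
      // weight each partition by its site count: p-distance noise variance
      // scales as 1/sites, so unweighted misfits would let the smaller
      // partition's tree overfit noise and push the optimum to the margins
      double imp =
          (double)b * (nj_misfit(Tall.coph, DL, n) - nj_misfit(TL.coph, DL, n)) +
          (double)(S - b) *
              (nj_misfit(Tall.coph, DR, n) - nj_misfit(TR.coph, DR, n));
      if (o == 0) obs[c] = imp;
      if (imp > omax) omax = imp;
    }
    if (o > 0) permmax[o - 1] = omax;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["obs"] = obs, _["perm_max"] = permmax);
}
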