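// Glocal (global-in-model, free-flanking-sequence) Viterbi for the
// package's profile HMMs, in log2-odds space against an i.i.d. background.
// Flanking residues outside the matched core score zero, so the returned
// score is the best log-odds of threading the full match-state path
// (with internal inserts/deletes) through any window of the sequence.
#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static const double NEG_INF = -DBL_MAX / 4;

// transition column order in `tr` ((L+1) x 9, log2 probabilities):
enum { MM = 0, MI, MD, IM, II, ID, DM, DI, DD };

// core DP. If ptrs are non-null they must be (n+1)*(L+1) byte arrays.
static double viterbi_fill(const int *x, int n, int L,
                           const double *emis, /* L x 21, column-major */
                           const double *tr,   /* (L+1) x 9, column-major */
                           std::vector<double> &VM, std::vector<double> &VI,
                           std::vector<double> &VD,
                           std::vector<signed char> *pM,
                           std::vector<signed char> *pI,
                           std::vector<signed char> *pD,
                           int *best_i, int *best_state) {
  const int W = L + 1;
  auto E = [&](int k, int a) { return emis[(k - 1) + (size_t)a * L]; };
  auto T = [&](int l, int c) { return tr[l + (size_t)c * W]; };
  // row i = residues consumed, col k = match position
  auto at = [&](int i, int k) { return (size_t)i * W + k; };
  for (int i = 0; i <= n; ++i) {
    for (int k = 0; k <= L; ++k) {
      VM[at(i, k)] = NEG_INF;
      VI[at(i, k)] = NEG_INF;
      VD[at(i, k)] = NEG_INF;
    }
  }
  // leading deletions reachable after any number of flank residues
  for (int i = 0; i <= n; ++i) {
    VD[at(i, 1)] = T(0, MD);
    if (pD) (*pD)[at(i, 1)] = 0; // from begin
    for (int k = 2; k <= L; ++k) {
      double v = VD[at(i, k - 1)] + T(k - 1, DD);
      VD[at(i, k)] = v;
      if (pD) (*pD)[at(i, k)] = 3; // from D
    }
    if (i == 0) continue;
    int xi = x[i - 1];
    for (int k = 1; k <= L; ++k) {
      // match state k emitting residue i
      double vm;
      signed char pm;
      if (k == 1) {
        vm = T(0, MM); // free N-flank then begin -> M1
        pm = 0;
      } else {
        vm = VM[at(i - 1, k - 1)] + T(k - 1, MM);
        pm = 1;
        double vi = VI[at(i - 1, k - 1)] + T(k - 1, IM);
        if (vi > vm) { vm = vi; pm = 2; }
        double vd = VD[at(i - 1, k - 1)] + T(k - 1, DM);
        if (vd > vm) { vm = vd; pm = 3; }
      }
      VM[at(i, k)] = vm + E(k, xi);
      if (pM) (*pM)[at(i, k)] = pm;
      // insert state k (background emission, log-odds 0), k < L
      if (k < L) {
        double vi = VM[at(i - 1, k)] + T(k, MI);
        signed char pi = 1;
        double v2 = VI[at(i - 1, k)] + T(k, II);
        if (v2 > vi) { vi = v2; pi = 2; }
        double v3 = VD[at(i - 1, k)] + T(k, ID);
        if (v3 > vi) { vi = v3; pi = 3; }
        VI[at(i, k)] = vi;
        if (pI) (*pI)[at(i, k)] = pi;
      }
      // delete state k fed by this row's M/I at k-1 (no residue consumed)
      if (k >= 2) {
        double vd = VM[at(i, k - 1)] + T(k - 1, MD);
        signed char pd = 1;
        double v2 = VI[at(i, k - 1)] + T(k - 1, ID);
        if (v2 > vd) { vd = v2; pd = 2; }
        double v3 = VD[at(i, k - 1)] + T(k - 1, DD);
        if (v3 > vd) { vd = v3; pd = 3; }
        if (vd > VD[at(i, k)]) {
          VD[at(i, k)] = vd;
          if (pD) (*pD)[at(i, k)] = pd;
        }
      }
    }
  }
  double best = NEG_INF;
  int bi = 0, bs = 1; // 1 = M, 3 = D
  for (int i = 0; i <= n; ++i) {
    if (VM[at(i, L)] > best) { best = VM[at(i, L)]; bi = i; bs = 1; }
    if (VD[at(i, L)] > best) { best = VD[at(i, L)]; bi = i; bs = 3; }
  }
  if (best_i) *best_i = bi;
  if (best_state) *best_state = bs;
  return best;
}

// [[Rcpp::export]]
NumericVector cpp_viterbi_score(List seqs, NumericMatrix emis, NumericMatrix tr) {
  int L = emis.nrow();
  int nseq = seqs.size();
  NumericVector out(nseq);
  int nmax = 0;
  for (int s = 0; s < nseq; ++s) {
    IntegerVector x = seqs[s];
    if (x.size() > nmax) nmax = x.size();
  }
  std::vector<double> VM(((size_t)nmax + 1) * (L + 1)),
      VI(((size_t)nmax + 1) * (L + 1)), VD(((size_t)nmax + 1) * (L + 1));
  for (int s = 0; s < nseq; ++s) {
    IntegerVector x = seqs[s];
    out[s] = viterbi_fill(x.begin(), x.size(), L, emis.begin(), tr.begin(),
                          VM, VI, VD, nullptr, nullptr, nullptr, nullptr,
                          nullptr);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_viterbi_align(IntegerVector x, NumericMatrix emis, NumericMatrix tr) {
  int L = emis.nrow();
  int n = x.size();
  const int W = L + 1;
  std::vector<double> VM(((size_t)n + 1) * W), VI(((size_t)n + 1) * W),
      VD(((size_t)n + 1) * W);
  std::vector<signed char> pM(((size_t)n + 1) * W), pI(((size_t)n + 1) * W),
      pD(((size_t)n + 1) * W);
  int bi, bs;
  double score = viterbi_fill(x.begin(), n, L, emis.begin(), tr.begin(), VM,
                              VI, VD, &pM, &pI, &pD, &bi, &bs);
  auto at = [&](int i, int k) { return (size_t)i * W + k; };
  // trace back: match_pos[k] = 1-based residue index emitted at match k, 0 = delete
  IntegerVector match_pos(L);
  int i = bi, k = L, state = bs;
  while (k >= 1) {
    if (state == 1) { // M
      match_pos[k - 1] = i;
      signed char p = pM[at(i, k)];
      --i; --k;
      state = p == 0 ? 0 : p;
      if (p == 0) break;
    } else if (state == 2) { // I: consumed a residue at this k
      signed char p = pI[at(i, k)];
      --i;
      state = p;
    } else { // D
      match_pos[k - 1] = 0;
      signed char p = pD[at(i, k)];
      --k;
      state = p == 0 ? 0 : p;
      if (p == 0) break;
    }
  }
  int env_from = 0, env_to = 0, hmm_from = 0, hmm_to = 0;
  for (int kk = 0; kk < L; ++kk) {
    if (match_pos[kk] > 0) {
      if (env_from == 0) { env_from = match_pos[kk]; hmm_from = kk + 1; }
      env_to = match_pos[kk];
      hmm_to = kk + 1;
    }
  }
  return List::create(_["score"] = score, _["match_pos"] = match_pos,
                      _["env_from"] = env_from, _["env_to"] = env_to,
                      _["hmm_from"] = hmm_from, _["hmm_to"] = hmm_to);
}
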