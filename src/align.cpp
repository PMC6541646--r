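#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Affine-gap global alignment (Gotoh). A gap of length L costs open + L*ext.
// Tie-breaking is fixed: at equal score prefer the match/mismatch state, then
// the gap-in-b state (consume a; "up"), then gap-in-a ("left"), both when
// choosing a cell's predecessor and when choosing the final state.

static const double NEG = -1e30;

struct AlnBuffers {
  std::vector<double> M, X, Y;
  std::vector<uint8_t> tM, tX, tY;
  int ncol = 0;
  void resize(int n, int m) {
    ncol = m + 1;
    size_t sz = (size_t)(n + 1) * (m + 1);
    if (M.size() < sz) {
      M.resize(sz); X.resize(sz); Y.resize(sz);
      tM.resize(sz); tX.resize(sz); tY.resize(sz);
    }
  }
  inline size_t at(int i, int j) const { return (size_t)i * ncol + j; }
};

// pick max of (m, x, y) with preference M > X > Y at ties
static inline int argmax3(double m, double x, double y, double &best) {
  best = m; int s = 0;
  if (x > best) { best = x; s = 1; }
  if (y > best) { best = y; s = 2; }
  return s;
}

struct PairStats {
  double score;
  int n_both;   // columns with residues in both rows
  int n_ident;  // of those, identical
  int n_cols;   // total alignment columns
};

// core Gotoh fill + traceback over a precomputed cell score callback;
// Eq(i, j) reports residue identity for the identity count
template <typename ScoreFun, typename EqFun>
static PairStats gotoh(int n, int m, ScoreFun S, EqFun Eq,
                       double open, double ext,
                       AlnBuffers &B, std::vector<int> *pa = nullptr,
                       std::vector<int> *pb = nullptr) {
  B.resize(n, m);
  double go = open + ext;  // cost of the first gap column
  B.M[B.at(0, 0)] = 0.0; B.X[B.at(0, 0)] = NEG; B.Y[B.at(0, 0)] = NEG;
  for (int i = 1; i <= n; ++i) {
    size_t k = B.at(i, 0);
    B.M[k] = NEG; B.Y[k] = NEG;
    B.X[k] = -(open + i * ext);
    B.tX[k] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    size_t k = B.at(0, j);
    B.M[k] = NEG; B.X[k] = NEG;
    B.Y[k] = -(open + j * ext);
    B.tY[k] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t k = B.at(i, j), kd = B.at(i - 1, j - 1),
             ku = B.at(i - 1, j), kl = B.at(i, j - 1);
      double best;
      int s = argmax3(B.M[kd], B.X[kd], B.Y[kd], best);
      B.M[k] = best + S(i - 1, j - 1);
      B.tM[k] = (uint8_t)s;
      s = argmax3(B.M[ku] - go, B.X[ku] - ext, B.Y[ku] - go, best);
      B.X[k] = best; B.tX[k] = (uint8_t)s;
      s = argmax3(B.M[kl] - go, B.X[kl] - go, B.Y[kl] - ext, best);
      B.Y[k] = best; B.tY[k] = (uint8_t)s;
    }
  }
  size_t ke = B.at(n, m);
  double best;
  int st = argmax3(B.M[ke], B.X[ke], B.Y[ke], best);
  PairStats ps{best, 0, 0, 0};
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t k = B.at(i, j);
    ps.n_cols++;
    if (st == 0) {
      ps.n_both++;
      if (Eq(i - 1, j - 1)) ps.n_ident++;
      st = B.tM[k];
      if (pa) { pa->push_back(i); pb->push_back(j); }
      --i; --j;
    } else if (st == 1) {
      st = B.tX[k];
      if (pa) { pa->push_back(i); pb->push_back(0); }
      --i;
    } else {
      st = B.tY[k];
      if (pa) { pa->push_back(0); pb->push_back(j); }
      --j;
    }
  }
  if (pa) { std::reverse(pa->begin(), pa->end()); std::reverse(pb->begin(), pb->end()); }
  return ps;
}

// [[Rcpp::export]]
List cpp_dp_align(NumericMatrix S, double gap_open, double gap_ext) {
  int n = S.nrow(), m = S.ncol();
  AlnBuffers B;
  std::vector<int> pa, pb;
  PairStats ps = gotoh(n, m, [&](int i, int j) { return S(i, j); },
                       [](int, int) { return false; },
                       gap_open, gap_ext, B, &pa, &pb);
  return List::create(_["score"] = ps.score,
                      _["path_a"] = wrap(pa), _["path_b"] = wrap(pb));
}

static void build_lookup(const NumericMatrix &submat, double lut[128][128]) {
  CharacterVector rn = rownames(submat), cn = colnames(submat);
  for (int i = 0; i < 128; ++i)
    for (int j = 0; j < 128; ++j) lut[i][j] = 0.0;
  for (int i = 0; i < submat.nrow(); ++i) {
    char a = CHAR(STRING_ELT(rn, i))[0];
    for (int j = 0; j < submat.ncol(); ++j) {
      char b = CHAR(STRING_ELT(cn, j))[0];
      lut[(int)a][(int)b] = submat(i, j);
    }
  }
}

// distinct 4-mer codes, sorted
static std::vector<int> kmer_codes(const std::string &s) {
  std::vector<int> v;
  if (s.size() < 4) return v;
  v.reserve(s.size() - 3);
  for (size_t i = 0; i + 4 <= s.size(); ++i) {
    int c = 0;
    for (size_t k = 0; k < 4; ++k) c = c * 26 + (s[i + k] - 'A');
    v.push_back(c);
  }
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  return v;
}

static int n_shared(const std::vector<int> &a, const std::vector<int> &b) {
  int n = 0; size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// All-vs-all protein comparison across genomes. Hits are emitted once per
// unordered pair (alignment is symmetric); genome-internal pairs are skipped.
// kmer_min = 0 disables the shared 4-mer prefilter.
// [[Rcpp::export]]
DataFrame cpp_all_vs_all(CharacterVector seqs, IntegerVector genome,
                         NumericMatrix submat, double gap_open, double gap_ext,
                         double min_identity, double min_coverage,
                         int kmer_min, bool coverage_both) {
  int N = seqs.size();
  std::vector<std::string> sq(N);
  for (int i = 0; i < N; ++i) sq[i] = as<std::string>(seqs[i]);
  static double lut[128][128];
  build_lookup(submat, lut);
  std::vector<std::vector<int>> km(N);
  if (kmer_min > 0)
    for (int i = 0; i < N; ++i) km[i] = kmer_codes(sq[i]);
  AlnBuffers B;
  std::vector<int> qi, si;
  std::vector<double> ident, cq, cs, sc;
  for (int i = 0; i < N; ++i) {
    const std::string &a = sq[i];
    for (int j = i + 1; j < N; ++j) {
      if (genome[i] == genome[j]) continue;
      const std::string &b = sq[j];
      int la = (int)a.size(), lb = (int)b.size();
      if (coverage_both && min_coverage > 0) {
        double rmax = (double)std::min(la, lb) / (double)std::max(la, lb);
        if (rmax < min_coverage) continue;
      }
      if (kmer_min > 0 && la >= 4 && lb >= 4) {
        // a pair at the identity floor conserves ~ id^4 of its 4-mers;
        // require a quarter of that expectation (at least kmer_min)
        double idf = min_identity * min_identity * min_identity * min_identity;
        int need = std::max(kmer_min,
                            (int)(0.25 * idf * (std::min(la, lb) - 3)));
        if (n_shared(km[i], km[j]) < need) continue;
      }
      PairStats ps = gotoh(la, lb,
                           [&](int x, int y) { return lut[(int)a[x]][(int)b[y]]; },
                           [&](int x, int y) { return a[x] == b[y]; },
                           gap_open, gap_ext, B);
      if (ps.n_both == 0) continue;
      double id = (double)ps.n_ident / ps.n_both;
      double cova = (double)ps.n_both / la, covb = (double)ps.n_both / lb;
      bool covok = coverage_both ? (cova >= min_coverage && covb >= min_coverage)
                                 : (cova >= min_coverage || covb >= min_coverage);
      if (id >= min_identity && covok) {
        qi.push_back(i + 1); si.push_back(j + 1);
        ident.push_back(id); cq.push_back(cova); cs.push_back(covb);
        sc.push_back(ps.score);
      }
    }
  }
  return DataFrame::create(_["query"] = wrap(qi), _["subject"] = wrap(si),
                           _["identity"] = wrap(ident), _["cov_q"] = wrap(cq),
                           _["cov_s"] = wrap(cs), _["score"] = wrap(sc));
}
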