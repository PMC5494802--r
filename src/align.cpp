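// Local similarity search: affine-gap Smith-Waterman with traceback, exact
// word seeding with ungapped X-drop extension (BLAST-style two-stage
// filter), and a word-sharing candidate-pair screen for all-vs-all runs.
// Sequences arrive as integer codes; scoring is a substitution matrix, so
// the same kernels serve nucleotide (+1/-2 style) and protein (BLOSUM62)
// searches. Gap of length L costs gap_open + L * gap_extend.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <set>
#include <utility>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  const int m = q.size(), n = s.size();
  const double NEG = -1e30;
  // H, E, F as rolling rows; full byte traceback
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<double> Fcur(n + 1, NEG);
  // tb: 0 stop, 1 diag, 2 up (gap in s), 3 left (gap in q)
  // tbE/tbF bit: 1 = extend
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  const int nrowmat = submat.nrow();
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG;
    const double *srow = &submat(q[i - 1], 0);
    uint8_t *tbrow = &tb[(size_t)i * (n + 1)];
    uint8_t *tbErow = &tbE[(size_t)i * (n + 1)];
    uint8_t *tbFrow = &tbF[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (move left)
      double e_open = Hcur[j - 1] - gap_open - gap_extend;
      double e_ext = Ecur[j - 1] - gap_extend;
      Ecur[j] = e_open >= e_ext ? e_open : e_ext;
      tbErow[j] = e_ext > e_open ? 1 : 0;
      // F: gap in subject (move up); Fcur[j] holds F(i-1, j) until written
      double f_open = Hprev[j] - gap_open - gap_extend;
      double f_ext = Fcur[j] - gap_extend;
      double Fv = f_open >= f_ext ? f_open : f_ext;
      tbFrow[j] = f_ext > f_open ? 1 : 0;
      Fcur[j] = Fv;
      double diag = Hprev[j - 1] + srow[(size_t)s[j - 1] * nrowmat];
      double h = diag;
      uint8_t dir = 1;
      if (Ecur[j] > h) { h = Ecur[j]; dir = 3; }
      if (Fv > h) { h = Fv; dir = 2; }
      if (h <= 0.0) { h = 0.0; dir = 0; }
      Hcur[j] = h;
      tbrow[j] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  // traceback from (bi, bj)
  int i = bi, j = bj;
  int matches = 0, mismatches = 0, gaps = 0, cols = 0;
  int state = 0; // 0 = H
  while (i > 0 && j > 0) {
    uint8_t dir = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      if (dir == 0) break;
      if (dir == 1) {
        ++cols;
        if (q[i - 1] == s[j - 1]) ++matches; else ++mismatches;
        --i; --j;
      } else if (dir == 3) state = 3;
      else state = 2;
    } else if (state == 3) { // in E: gap in query, consume s[j]
      ++gaps; ++cols;
      uint8_t ext = tbE[(size_t)i * (n + 1) + j];
      --j;
      if (!ext) state = 0;
    } else { // state 2, in F: gap in subject, consume q[i]
      ++gaps; ++cols;
      uint8_t ext = tbF[(size_t)i * (n + 1) + j];
      --i;
      if (!ext) state = 0;
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,   // 0-based half-open
                      _["s_start"] = j, _["s_end"] = bj,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gaps"] = gaps, _["columns"] = cols);
}

// Best ungapped X-drop extension score over shared exact words.
// [[Rcpp::export(name = ".best_ungapped_cpp")]]
double best_ungapped_cpp(IntegerVector q, IntegerVector s, int w,
                         NumericMatrix submat, double xdrop, int alpha) {
  const int m = q.size(), n = s.size();
  if (m < w || n < w) return 0.0;
  // hash query words (codes must be < alpha; any code >= alpha breaks word)
  std::unordered_map<uint64_t, std::vector<int>> words;
  uint64_t h = 0, mask = 1;
  for (int k = 0; k < w; ++k) mask *= (uint64_t)alpha;
  int run = 0;
  for (int i = 0; i < m; ++i) {
    if (q[i] >= alpha || q[i] < 0) { run = 0; h = 0; continue; }
    h = (h * alpha + q[i]) % mask;
    if (++run >= w) words[h].push_back(i - w + 1);
  }
  double best = 0.0;
  const int ncol = submat.nrow();
  std::unordered_map<int, int> diag_done; // diagonal -> max q end extended
  h = 0; run = 0;
  for (int j = 0; j < n; ++j) {
    if (s[j] >= alpha || s[j] < 0) { run = 0; h = 0; continue; }
    h = (h * alpha + s[j]) % mask;
    if (++run < w) continue;
    auto it = words.find(h);
    if (it == words.end()) continue;
    int js = j - w + 1;
    for (int is : it->second) {
      int d = is - js;
      auto dd = diag_done.find(d);
      if (dd != diag_done.end() && dd->second >= is) continue;
      // seed score
      double sc = 0.0;
      for (int k = 0; k < w; ++k) sc += submat(q[is + k], s[js + k]);
      double cur = sc, mx = sc;
      // extend right
      int ir = is + w, jr = js + w;
      while (ir < m && jr < n) {
        cur += submat(q[ir], s[jr]);
        if (cur > mx) mx = cur;
        if (mx - cur > xdrop) break;
        ++ir; ++jr;
      }
      int right_end = ir;
      // extend left
      cur = mx;
      int il = is - 1, jl = js - 1;
      while (il >= 0 && jl >= 0) {
        cur += submat(q[il], s[jl]);
        if (cur > mx) mx = cur;
        if (mx - cur > xdrop) break;
        --il; --jl;
      }
      if (mx > best) best = mx;
      diag_done[d] = right_end;
    }
  }
  return best;
}

// Candidate pairs sharing at least one exact w-word (all-vs-all screen).
// seqs: list of integer vectors. Returns 2-column matrix of 1-based pair
// indices i < j (plus i == j excluded).
// [[Rcpp::export(name = ".word_pairs_cpp")]]
IntegerMatrix word_pairs_cpp(List seqs, int w, int alpha) {
  const int n = seqs.size();
  std::unordered_map<uint64_t, std::vector<int>> index;
  uint64_t mask = 1;
  for (int k = 0; k < w; ++k) mask *= (uint64_t)alpha;
  for (int t = 0; t < n; ++t) {
    IntegerVector v = seqs[t];
    uint64_t h = 0; int run = 0;
    int last = -1;
    for (int i = 0; i < v.size(); ++i) {
      if (v[i] >= alpha || v[i] < 0) { run = 0; h = 0; continue; }
      h = (h * alpha + v[i]) % mask;
      if (++run >= w) {
        auto &vec = index[h];
        if (vec.empty() || vec.back() != t) vec.push_back(t);
        (void)last;
      }
    }
  }
  std::set<std::pair<int, int>> pairs;
  for (auto &kv : index) {
    auto &vec = kv.second;
    if (vec.size() < 2) continue;
    for (size_t a = 0; a < vec.size(); ++a)
      for (size_t b = a + 1; b < vec.size(); ++b)
        pairs.insert({vec[a], vec[b]});
  }
  IntegerMatrix out(pairs.size(), 2);
  int r = 0;
  for (auto &p : pairs) {
    out(r, 0) = p.first + 1;
    out(r, 1) = p.second + 1;
    ++r;
  }
  return out;
}
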