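// Secondary-structure engine: minimum free energy over pseudoknot-free
// nested structures with simple per-pair energies, and the Boltzmann
// partition function with base-pair probabilities (inside/outside
// recursions). Structure space: minimum hairpin loop `min_loop`, optional
// maximum pairing span `max_span`, no lone-pair prohibition.
//
// The partition recursions run in a rescaled domain (every base carries a
// factor exp(-log_scale)) so that magnitudes stay inside double range for
// long and very stable sequences; probabilities are scale-invariant ratios.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int encode_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return 4; // N or anything else: unpairable
  }
}

// energy lookup table: 5x5, 0 = no pair allowed (energies are <= 0)
static void build_pair_table(double e_gc, double e_au, double e_gu,
                             double tab[5][5]) {
  for (int i = 0; i < 5; ++i)
    for (int j = 0; j < 5; ++j) tab[i][j] = 1.0; // sentinel: forbidden
  tab[2][1] = tab[1][2] = e_gc; // G-C
  tab[0][3] = tab[3][0] = e_au; // A-U
  tab[2][3] = tab[3][2] = e_gu; // G-U
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, double e_gc, double e_au, double e_gu,
                  int min_loop, int max_span) {
  int n = (int)seq.size();
  double pe[5][5];
  build_pair_table(e_gc, e_au, e_gu, pe);
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = encode_base(seq[i]);
  if (n < min_loop + 2) {
    return List::create(_["mfe"] = 0.0,
                        _["structure"] = std::string(n, '.'));
  }
  // E(i,j) over 0-based closed intervals; flat row-major plus a transposed
  // copy so the Q(k+1, j)-style reads stay contiguous. Sentinel row/col
  // make empty-interval reads (j = i - 1) return 0.
  const int N = n + 2;
  std::vector<double> Ev((size_t)N * N, 0.0);
  std::vector<double> Et((size_t)N * N, 0.0);
  auto EI = [&](int i, int j) -> size_t { return (size_t)(i + 1) * N + (j + 1); };
  const int spanlim = (max_span > 0) ? max_span : n;
  for (int i = n - 1; i >= 0; --i) {
    const double *erow_ip1 = &Ev[(size_t)(i + 2) * N + 1]; // E(i+1, j) at [j]
    const int si = s[i];
    const int kmaxall = std::min(n - 1, i + spanlim);
    for (int j = i; j < n; ++j) {
      double best = erow_ip1[j]; // i unpaired (0 for empty via sentinel)
      const int kmax = std::min(j, kmaxall);
      const double *ecol_j = &Et[(size_t)(j + 1) * N + 1]; // E(i', j) at [i']
      for (int k = i + min_loop + 1; k <= kmax; ++k) {
        const double e = pe[si][s[k]];
        if (e > 0.0) continue;
        const double cand = e + erow_ip1[k - 1] + (k < j ? ecol_j[k + 1] : 0.0);
        if (cand < best) best = cand;
      }
      Ev[EI(i, j)] = best;
      Et[(size_t)(j + 1) * N + (i + 1)] = best;
    }
  }
  auto E = [&](int i, int j) -> double { return Ev[EI(i, j)]; };
  // traceback: take the leave-i-unpaired branch whenever it is optimal,
  // otherwise the first pairing partner achieving the optimum
  std::string db(n, '.');
  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, n - 1});
  const double eps = 1e-9;
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    if (std::fabs(E(i, j) - E(i + 1, j)) < eps) {
      stack.push_back({i + 1, j});
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (max_span > 0 && k - i > max_span) break;
      double e = pe[s[i]][s[k]];
      if (e > 0.0) continue;
      double cand = e + (k - i >= 2 ? E(i + 1, k - 1) : 0.0) +
                    (k < j ? E(k + 1, j) : 0.0);
      if (std::fabs(cand - E(i, j)) < eps) {
        db[i] = '(';
        db[k] = ')';
        if (k - i >= 2) stack.push_back({i + 1, k - 1});
        if (k < j) stack.push_back({k + 1, j});
        break;
      }
    }
  }
  return List::create(_["mfe"] = E(0, n - 1), _["structure"] = db);
}

// Inside/outside partition function with per-base rescaling.
// Returns log Q, per-site paired probability, folding strength, and
// optionally the full pair-probability matrix. Flat row-major arrays;
// outside values computed only at pairable (h, l).
// [[Rcpp::export(name = ".fold_partition_cpp")]]
List fold_partition_cpp(std::string seq, double e_gc, double e_au, double e_gu,
                        int min_loop, int max_span, double rt, double log_scale,
                        bool return_matrix) {
  const int n = (int)seq.size();
  double pe[5][5];
  build_pair_table(e_gc, e_au, e_gu, pe);
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = encode_base(seq[i]);

  NumericVector psite(n, 0.0);
  if (n < min_loop + 2) {
    List out = List::create(_["log_q"] = 0.0, _["paired_prob"] = psite,
                            _["folding_strength"] = 0.0,
                            _["overflow"] = false);
    if (return_matrix) out["pair_prob"] = NumericMatrix(n, n);
    return out;
  }

  // scaled pair Boltzmann weights exp(-E/rt - 2*log_scale), precomputed
  double pw[5][5];
  for (int a = 0; a < 5; ++a)
    for (int b = 0; b < 5; ++b)
      pw[a][b] = pe[a][b] > 0.0 ? 0.0
                                : std::exp(-pe[a][b] / rt - 2.0 * log_scale);
  const double unp = std::exp(-log_scale); // scaled weight of an unpaired base
  const double HUGE_LIM = 1e280;
  const int span = (max_span > 0) ? max_span : n;

  // Inside: Q over closed 0-based intervals; empty interval = 1.
  //   Q(i,j) = unp*Q(i+1,j) + sum_k qp(i,k)*Q(i+1,k-1)*Q(k+1,j)
  // Flat (n+2)x(n+2) with sentinel row/col so Q(i, i-1) = 1 reads work.
  // Qv row-major Q(i, *); Qt column-major copy Qt(j, *) for contiguous
  // reads of Q(k+1, j) over k. Both carry empty-interval sentinels.
  const int N = n + 2;
  std::vector<double> Qv((size_t)N * N, 0.0);
  std::vector<double> Qt((size_t)N * N, 0.0);
  auto QI = [&](int i, int j) -> size_t { // j = i-1 (empty) allowed
    return (size_t)(i + 1) * N + (j + 1);
  };
  auto QTI = [&](int i, int j) -> size_t {
    return (size_t)(j + 1) * N + (i + 1);
  };
  for (int i = 0; i <= n; ++i) {
    Qv[QI(i, i - 1)] = 1.0;
    Qt[QTI(i, i - 1)] = 1.0;
  }

  bool too_big = false;
  for (int i = n - 1; i >= 0 && !too_big; --i) {
    const double *qrow_ip1 = &Qv[QI(i + 1, 0)]; // Q(i+1, *) over j
    const int *sp = s.data();
    const int si = sp[i];
    const int kmaxall = std::min(n - 1, i + span);
    for (int j = i; j < n; ++j) {
      double v = unp * qrow_ip1[j];
      const int kmax = std::min(j, kmaxall);
      const double *qcol_j = &Qt[QTI(0, j)]; // Q(*, j) over first index
      for (int k = i + min_loop + 1; k <= kmax; ++k) {
        const double w = pw[si][sp[k]];
        if (w == 0.0) continue;
        // Q(i+1,k-1) * Q(k+1,j)
        v += w * qrow_ip1[k - 1] * qcol_j[k + 1];
      }
      Qv[QI(i, j)] = v;
      Qt[QTI(i, j)] = v;
      if (v > HUGE_LIM || !std::isfinite(v)) { too_big = true; break; }
    }
  }
  const double qtot = Qv[QI(0, n - 1)];
  const bool too_small = !too_big && (qtot <= 1e-250);
  if (too_big || too_small) {
    // caller retries with adjusted scale (direction reported)
    return List::create(_["log_q"] = NA_REAL, _["paired_prob"] = psite,
                        _["folding_strength"] = NA_REAL,
                        _["overflow"] = true,
                        _["direction"] = too_big ? 1.0 : -1.0);
  }

  // Outside, processed in increasing h so all B rows with i < h exist:
  //   Qout(h,l) = Q(0,h-1)*Q(l+1,n-1) + sum_{i<h} Q(i+1,h-1)*B(i,l)
  //   B(i,l)    = sum_{j>l} qp(i,j)*Qout(i,j)*Q(l+1,j-1)
  // B stored transposed (Bt[l*n+h]) so the Qout inner loop is contiguous.
  std::vector<double> Qout((size_t)n * n, 0.0);
  std::vector<double> Bt((size_t)n * n, 0.0);
  NumericMatrix P(return_matrix ? n : 1, return_matrix ? n : 1);
  double fs_sum = 0.0;
  std::vector<int> jlist; jlist.reserve(n);
  std::vector<double> rvals; rvals.reserve(n);

  for (int h = 0; h < n; ++h) {
    const int sh = s[h];
    const int lmax = std::min(n - 1, h + span);
    const double q_left_all = Qv[QI(0, h - 1)]; // Q(0, h-1)
    for (int l = h + min_loop + 1; l <= lmax; ++l) {
      if (pw[sh][s[l]] == 0.0) continue; // only needed at pairable (h,l)
      double v = q_left_all * Qv[QI(l + 1, n - 1)];
      const double *bt_l = &Bt[(size_t)l * n];
      const double *qcol_hm1 = &Qt[QTI(0, h - 1)]; // Q(*, h-1)
      for (int i = 0; i < h; ++i) {
        // Q(i+1, h-1) * B(i, l)
        v += qcol_hm1[i + 1] * bt_l[i];
      }
      Qout[(size_t)h * n + l] = v;
    }
    // pairable partners of h and their qp*Qout products
    jlist.clear(); rvals.clear();
    for (int j = h + min_loop + 1; j <= lmax; ++j) {
      const double w = pw[sh][s[j]];
      if (w == 0.0) continue;
      jlist.push_back(j);
      rvals.push_back(w * Qout[(size_t)h * n + j]);
    }
    // B row for h: B(h,l) = sum over pairable j > l of rvals * Q(l+1, j-1)
    const int m = (int)jlist.size();
    if (m > 0) {
      const int jmax = jlist[m - 1];
      for (int l = jmax - 1; l >= 0; --l) {
        const double *qrow_lp1 = &Qv[QI(l + 1, 0)];
        double acc = 0.0;
        for (int t = m - 1; t >= 0 && jlist[t] > l; --t) {
          acc += rvals[t] * qrow_lp1[jlist[t] - 1];
        }
        Bt[(size_t)l * n + h] = acc;
      }
    }
    // pair probabilities for row h
    for (int t = 0; t < m; ++t) {
      const int l = jlist[t];
      double p = pw[sh][s[l]] * Qv[QI(h + 1, l - 1)] *
                 Qout[(size_t)h * n + l] / qtot;
      if (p < 0.0) p = 0.0;
      if (p > 1.0 && p < 1.0 + 1e-9) p = 1.0;
      psite[h] += p;
      psite[l] += p;
      if (return_matrix) { P(h, l) = p; P(l, h) = p; }
    }
  }
  for (int i = 0; i < n; ++i) {
    if (psite[i] > 1.0 && psite[i] < 1.0 + 1e-9) psite[i] = 1.0;
    fs_sum += psite[i];
  }
  List out = List::create(_["log_q"] = std::log(qtot) + n * log_scale,
                          _["paired_prob"] = psite,
                          _["folding_strength"] = fs_sum / n,
                          _["overflow"] = false);
  if (return_matrix) out["pair_prob"] = P;
  return out;
}
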