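// Dynamic-programming kernels for profile-HMM DNA search.
//
// Model topology (unihit local):
//   start -> N (self-loop eta, emits background) -> B
//   B -> M_k with entry_k; B -> E (no-alignment path, weight 1)
//   core: M_k -> {M_{k+1}, I_k, D_{k+1}}, I_k -> {M_{k+1}, I_k},
//         D_k -> {M_{k+1}, D_{k+1}}
//   M_k -> E for every k (local exit, weight 1)
//   E -> C (self-loop eta, emits background) -> T
//
// All scores are log-odds against the iid null; flank and insert emissions
// therefore score 0. Forward/Backward run in row-scaled linear space (exact
// double arithmetic, no per-cell transcendentals); Viterbi runs in natural
// log space. Public scores are reported in bits.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <cstring>
using namespace Rcpp;

static const double NEGINF = -std::numeric_limits<double>::infinity();
static const double LN2 = 0.6931471805599453;

// transition column order, fixed across the package
enum { MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6 };

// ---------------------------------------------------------------------------
// SSV: per-diagonal best single ungapped segment of match log-odds (bits).
// Kadane along every diagonal, carried in k-indexed slot arrays that shift
// with the band (slot k at row i holds the diagonal d = i - k). The hot
// recurrence is branchless float; per-diagonal records are only kept for
// cells reaching min_score (rare on null sequence), and every reported
// segment is rescored in exact double arithmetic from its coordinates.
// [[Rcpp::export]]
List cpp_ssv(const NumericMatrix& lod_bits, const IntegerVector& x,
             double min_score) {
  const int M = lod_bits.nrow();
  const int L = x.size();
  const float thr = std::isfinite(min_score) ? (float)min_score
                    : (min_score > 0 ? 3.0e38f : -3.0e38f);
  // code-major float score rows, padded so index k runs 1..M
  std::vector<float> S(15 * (M + 1));
  for (int c = 0; c < 15; ++c)
    for (int k = 1; k <= M; ++k) S[c * (M + 1) + k] = (float)lod_bits(k - 1, c);
  std::vector<float> curA(M + 1, -3.0e38f), curB(M + 1, -3.0e38f);
  float* cur = curA.data(); float* prv = curB.data();
  std::map<int, float> flagged;     // diagonal d = i - k -> float best seen
  float gbestf = -3.0e38f;
  int gb_d = 0;

  for (int i = 1; i <= L; ++i) {
    const float* __restrict sc = &S[(size_t)(x[i - 1] - 1) * (M + 1)];
    const float* __restrict po = prv;
    float* __restrict co = cur;
    float rowmax = -3.0e38f;
#pragma omp simd reduction(max:rowmax)
    for (int k = 1; k <= M; ++k) {          // branchless float Kadane shift
      const float p = po[k - 1];
      const float ext = p > 0.0f ? p : 0.0f;
      const float v = ext + sc[k];
      co[k] = v;
      rowmax = rowmax > v ? rowmax : v;
    }
    if (rowmax > gbestf) {                  // rare: record best diagonal
      for (int k = 1; k <= M; ++k)
        if (cur[k] == rowmax) { gb_d = i - k; break; }
      gbestf = rowmax;
    }
    if (rowmax >= thr) {                    // rare on null sequence
      for (int k = 1; k <= M; ++k) {
        if (cur[k] >= thr) {
          auto it = flagged.find(i - k);
          if (it == flagged.end()) flagged[i - k] = cur[k];
          else if (cur[k] > it->second) it->second = cur[k];
        }
      }
    }
    std::swap(cur, prv);
  }

  // Exact double Kadane over one diagonal (at most M cells): returns the
  // maximal segment and its coordinates.
  struct Seg { double score; int start, end; };
  auto diag_best = [&](int d) {
    Seg best{NEGINF, 0, 0};
    double run = 0.0; int run_start = 0;
    const int i0 = std::max(1, d + 1), i1 = std::min(L, d + M);
    for (int i = i0; i <= i1; ++i) {
      const double s = lod_bits(i - d - 1, x[i - 1] - 1);
      if (run > 0) { run += s; } else { run = s; run_start = i; }
      if (run > best.score) best = Seg{run, run_start, i};
    }
    return best;
  };
  std::vector<int> h_ts, h_te, h_ms;
  std::vector<double> h_sc;
  for (auto& kv : flagged) {
    Seg s = diag_best(kv.first);
    if (s.score >= min_score) {
      h_ts.push_back(s.start - 1);            // 0-based half-open
      h_te.push_back(s.end);
      h_ms.push_back(s.start - kv.first);     // model node at segment start
      h_sc.push_back(s.score);
    }
  }
  double gbest = (L > 0 && M > 0 && gbestf > -3.0e38f)
    ? diag_best(gb_d).score : NEGINF;
  return List::create(_["target_start"] = h_ts, _["target_end"] = h_te,
                      _["model_start"] = h_ms, _["score"] = h_sc,
                      _["best"] = gbest);
}

// ---------------------------------------------------------------------------
// Viterbi, natural log space. Returns score (bits) and optional traceback.
// [[Rcpp::export]]
List cpp_viterbi(const NumericMatrix& lodn, const NumericMatrix& ltr,
                 const NumericVector& lentry, const IntegerVector& x,
                 bool traceback) {
  const int M = lodn.nrow();
  const int L = x.size();
  const double eta = (L > 0) ? (double)L / (L + 2) : 0.0;
  const double lg = (L > 0) ? std::log(eta) : NEGINF;
  const double l1g = std::log(1.0 - eta);

  std::vector<double> vm(M + 1, NEGINF), vi(M + 1, NEGINF), vd(M + 1, NEGINF);
  std::vector<double> pm(M + 1), pi(M + 1), pd(M + 1);
  // traceback: 0=B,1=M,2=I,3=D for M-cells; 0=M,1=I for I; 0=M,1=D for D
  std::vector<signed char> tbM, tbI, tbD;
  if (traceback) {
    tbM.assign((size_t)(L + 1) * (M + 1), -1);
    tbI.assign((size_t)(L + 1) * (M + 1), -1);
    tbD.assign((size_t)(L + 1) * (M + 1), -1);
  }
  double n = 0.0, b = l1g;
  // end bookkeeping: best of E(i) + (L-i)*lg over i, with argmax
  double bestEnd = b + (L > 0 ? L * lg : 0.0);  // B->E at i=0, C loops to L
  int bestI = 0, bestK = -1;                    // -1 == B->E (no alignment)

  for (int i = 1; i <= L; ++i) {
    const int xc = x[i - 1] - 1;
    std::swap(vm, pm); std::swap(vi, pi); std::swap(vd, pd);
    const double bprev = b;
    double rowE = NEGINF;
    int rowK = -1;
    for (int k = 1; k <= M; ++k) {
      // match
      double v = bprev + lentry[k - 1]; signed char who = 0;
      if (k >= 2) {
        double t;
        t = pm[k - 1] + ltr(k - 2, MM); if (t > v) { v = t; who = 1; }
        t = pi[k - 1] + ltr(k - 2, IM); if (t > v) { v = t; who = 2; }
        t = pd[k - 1] + ltr(k - 2, DM); if (t > v) { v = t; who = 3; }
      }
      vm[k] = v + lodn(k - 1, xc);
      if (traceback) tbM[(size_t)i * (M + 1) + k] = who;
      // insert (emission log-odds 0)
      if (k < M) {
        double a = pm[k] + ltr(k - 1, MI), c = pi[k] + ltr(k - 1, II);
        vi[k] = (a >= c) ? a : c;
        if (traceback) tbI[(size_t)i * (M + 1) + k] = (a >= c) ? 0 : 1;
      } else vi[k] = NEGINF;
      // delete (same row, k-1 already updated)
      if (k >= 2) {
        double a = vm[k - 1] + ltr(k - 2, MD), c = vd[k - 1] + ltr(k - 2, DD);
        vd[k] = (a >= c) ? a : c;
        if (traceback) tbD[(size_t)i * (M + 1) + k] = (a >= c) ? 0 : 1;
      } else vd[k] = NEGINF;
      if (vm[k] > rowE) { rowE = vm[k]; rowK = k; }
    }
    n = n + lg;       // N self-loop emission
    b = n + l1g;
    if (b > rowE) { rowE = b; rowK = -1; }
    double endv = rowE + (double)(L - i) * lg;
    if (endv > bestEnd) { bestEnd = endv; bestI = i; bestK = rowK; }
  }
  const double score_nat = bestEnd + l1g;  // C->T
  List out = List::create(_["score"] = score_nat / LN2);
  if (traceback) {
    // Reconstruct ops from (bestI, bestK) back to B. Predecessor geometry:
    //   M_k(i) <- B(i-1) | M_{k-1}(i-1) | I_{k-1}(i-1) | D_{k-1}(i-1)
    //   I_k(i) <- M_k(i-1) | I_k(i-1)
    //   D_k(i) <- M_{k-1}(i) | D_{k-1}(i)      (silent)
    std::string ops;
    int iEnd = bestI, kEnd = bestK;
    if (bestK > 0) {
      int i = bestI, k = bestK;
      signed char st = 1;  // 1=M, 2=I, 3=D
      for (;;) {
        if (st == 1) {
          ops.push_back('M');
          signed char who = tbM[(size_t)i * (M + 1) + k];
          if (who == 0) break;
          --i; --k; st = who;
        } else if (st == 2) {
          ops.push_back('I');
          signed char who = tbI[(size_t)i * (M + 1) + k];
          --i; st = (who == 0) ? 1 : 2;
        } else {
          ops.push_back('D');
          signed char who = tbD[(size_t)i * (M + 1) + k];
          --k; st = (who == 0) ? 1 : 3;
        }
      }
      std::reverse(ops.begin(), ops.end());
    }
    // first model node of the alignment = kEnd - (#M + #D ops) + 1
    int nMD = 0; for (char c : ops) if (c != 'I') ++nMD;
    int kStart = (bestK > 0) ? kEnd - nMD + 1 : 0;
    int nEmit = 0; for (char c : ops) if (c != 'D') ++nEmit;
    int iStart = (bestK > 0) ? iEnd - nEmit + 1 : 0;
    out["ops"] = ops; out["i_end"] = iEnd; out["k_end"] = kEnd;
    out["i_start"] = iStart; out["k_start"] = kStart;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Forward, row-scaled linear space. Score only (rolling rows).
// [[Rcpp::export]]
double cpp_forward_score(const NumericMatrix& ol, const NumericMatrix& tr,
                         const NumericVector& entry, const IntegerVector& x) {
  const int M = ol.nrow();
  const int L = x.size();
  const double eta = (L > 0) ? (double)L / (L + 2) : 0.0;
  const double l1 = 1.0 - eta;
  std::vector<double> m(M + 1, 0.0), ins(M + 1, 0.0), d(M + 1, 0.0);
  std::vector<double> pm(M + 1), pi(M + 1), pd(M + 1);
  double n = 1.0, b = l1, c = b;  // row 0: e = b (B->E), c = e
  double logscale = 0.0;
  for (int i = 1; i <= L; ++i) {
    const int xc = x[i - 1] - 1;
    std::swap(m, pm); std::swap(ins, pi); std::swap(d, pd);
    const double bprev = b, cprev = c, nprev = n;
    double e = 0.0, rowmax = 0.0;
    for (int k = 1; k <= M; ++k) {
      double v = bprev * entry[k - 1];
      if (k >= 2)
        v += pm[k - 1] * tr(k - 2, MM) + pi[k - 1] * tr(k - 2, IM) +
             pd[k - 1] * tr(k - 2, DM);
      m[k] = v * ol(k - 1, xc);
      ins[k] = (k < M) ? pm[k] * tr(k - 1, MI) + pi[k] * tr(k - 1, II) : 0.0;
      d[k] = (k >= 2) ? m[k - 1] * tr(k - 2, MD) + d[k - 1] * tr(k - 2, DD)
                      : 0.0;
      e += m[k];
      if (m[k] > rowmax) rowmax = m[k];
    }
    n = nprev * eta;
    b = n * l1;
    e += b;  // B->E
    c = e + cprev * eta;
    if (c > rowmax) rowmax = c;
    if (n > rowmax) rowmax = n;
    if (rowmax <= 0.0) return NEGINF / LN2;  // impossible sequence
    const double inv = 1.0 / rowmax;
    for (int k = 1; k <= M; ++k) { m[k] *= inv; ins[k] *= inv; d[k] *= inv; }
    n *= inv; b *= inv; c *= inv;
    logscale += std::log(rowmax);
  }
  return (std::log(c * l1) + logscale) / LN2;
}

// Full forward matrices (for posterior decoding). Values are row-scaled
// linear; logscale[i] is the cumulative natural-log scale of row i.
// [[Rcpp::export]]
List cpp_forward_mat(const NumericMatrix& ol, const NumericMatrix& tr,
                     const NumericVector& entry, const IntegerVector& x) {
  const int M = ol.nrow();
  const int L = x.size();
  const double eta = (L > 0) ? (double)L / (L + 2) : 0.0;
  const double l1 = 1.0 - eta;
  NumericMatrix Fm(L + 1, M), Fi(L + 1, M), Fd(L + 1, M);
  NumericVector Fn(L + 1), Fb(L + 1), Fc(L + 1), logscale(L + 1);
  Fn[0] = 1.0; Fb[0] = l1; Fc[0] = l1;  // c(0) = e(0) = b(0)
  for (int i = 1; i <= L; ++i) {
    const int xc = x[i - 1] - 1;
    double e = 0.0, rowmax = 0.0;
    for (int k = 1; k <= M; ++k) {
      double v = Fb[i - 1] * entry[k - 1];
      if (k >= 2)
        v += Fm(i - 1, k - 2) * tr(k - 2, MM) + Fi(i - 1, k - 2) * tr(k - 2, IM) +
             Fd(i - 1, k - 2) * tr(k - 2, DM);
      Fm(i, k - 1) = v * ol(k - 1, xc);
      Fi(i, k - 1) = (k < M) ? Fm(i - 1, k - 1) * tr(k - 1, MI) +
                               Fi(i - 1, k - 1) * tr(k - 1, II) : 0.0;
      Fd(i, k - 1) = (k >= 2) ? Fm(i, k - 2) * tr(k - 2, MD) +
                                Fd(i, k - 2) * tr(k - 2, DD) : 0.0;
      e += Fm(i, k - 1);
      if (Fm(i, k - 1) > rowmax) rowmax = Fm(i, k - 1);
    }
    Fn[i] = Fn[i - 1] * eta;
    Fb[i] = Fn[i] * l1;
    e += Fb[i];
    Fc[i] = e + Fc[i - 1] * eta;
    if (Fc[i] > rowmax) rowmax = Fc[i];
    if (Fn[i] > rowmax) rowmax = Fn[i];
    if (rowmax <= 0.0) rowmax = 1.0;
    const double inv = 1.0 / rowmax;
    for (int k = 0; k < M; ++k) { Fm(i, k) *= inv; Fi(i, k) *= inv; Fd(i, k) *= inv; }
    Fn[i] *= inv; Fb[i] *= inv; Fc[i] *= inv;
    logscale[i] = logscale[i - 1] + std::log(rowmax);
  }
  // L == 0: eta = 0, l1 = 1, Fc[0] = 1 -> empty-alignment score 0
  double score = (std::log(Fc[L] * l1) + logscale[L]) / LN2;
  return List::create(_["score"] = score, _["M"] = Fm, _["I"] = Fi,
                      _["D"] = Fd, _["N"] = Fn, _["B"] = Fb, _["C"] = Fc,
                      _["logscale"] = logscale, _["eta"] = eta, _["L"] = L);
}

// Backward matrices, same scaling scheme (scaled per row from the right).
// [[Rcpp::export]]
List cpp_backward_mat(const NumericMatrix& ol, const NumericMatrix& tr,
                      const NumericVector& entry, const IntegerVector& x) {
  const int M = ol.nrow();
  const int L = x.size();
  const double eta = (L > 0) ? (double)L / (L + 2) : 0.0;
  const double l1 = 1.0 - eta;
  NumericMatrix Bm(L + 1, M), Bi(L + 1, M), Bd(L + 1, M);
  NumericVector Bn(L + 1), Bb(L + 1), Bc(L + 1), logscale(L + 1);
  // row L
  Bc[L] = l1;
  for (int k = M; k >= 1; --k) {
    Bm(L, k - 1) = Bc[L];           // M_k -> E -> C, exit weight 1
    Bd(L, k - 1) = 0.0;
    Bi(L, k - 1) = 0.0;
  }
  Bb[L] = Bc[L];                    // B -> E
  Bn[L] = l1 * Bb[L];
  logscale[L] = 0.0;
  for (int i = L - 1; i >= 0; --i) {
    const int xc = x[i] - 1;        // next residue x_{i+1}
    double rowmax = 0.0;
    Bc[i] = eta * Bc[i + 1];
    const double eB = Bc[i];
    for (int k = M; k >= 1; --k) {  // deletes first (need Bd[k+1] same row)
      double dv = 0.0;
      if (k < M) dv = tr(k - 1, DM) * ol(k, xc) * Bm(i + 1, k) +
                      tr(k - 1, DD) * Bd(i, k);
      Bd(i, k - 1) = dv;
    }
    for (int k = 1; k <= M; ++k) {
      double mv = eB;  // exit
      if (k < M)
        mv += tr(k - 1, MM) * ol(k, xc) * Bm(i + 1, k) +
              tr(k - 1, MI) * Bi(i + 1, k - 1) +
              tr(k - 1, MD) * Bd(i, k);
      Bm(i, k - 1) = mv;
      double iv = 0.0;
      if (k < M)
        iv = tr(k - 1, IM) * ol(k, xc) * Bm(i + 1, k) +
             tr(k - 1, II) * Bi(i + 1, k - 1);
      Bi(i, k - 1) = iv;
      if (mv > rowmax) rowmax = mv;
    }
    double bv = eB;
    for (int k = 1; k <= M; ++k)
      bv += entry[k - 1] * ol(k - 1, xc) * Bm(i + 1, k - 1);
    Bb[i] = bv;
    Bn[i] = eta * Bn[i + 1] + l1 * Bb[i];
    if (Bn[i] > rowmax) rowmax = Bn[i];
    if (Bc[i] > rowmax) rowmax = Bc[i];
    if (rowmax <= 0.0) rowmax = 1.0;
    const double inv = 1.0 / rowmax;
    for (int k = 0; k < M; ++k) { Bm(i, k) *= inv; Bi(i, k) *= inv; Bd(i, k) *= inv; }
    Bn[i] *= inv; Bb[i] *= inv; Bc[i] *= inv;
    logscale[i] = logscale[i + 1] + std::log(rowmax);
  }
  double score = (L == 0) ? 0.0 : (std::log(Bn[0]) + logscale[0]) / LN2;
  return List::create(_["score"] = score, _["M"] = Bm, _["I"] = Bi,
                      _["D"] = Bd, _["N"] = Bn, _["B"] = Bb, _["C"] = Bc,
                      _["logscale"] = logscale, _["eta"] = eta, _["L"] = L);
}

// Posterior decode from matched forward/backward matrices.
// Columns: M_1..M_M, I_1..I_M, N, C. Row i sums to 1.
// [[Rcpp::export]]
NumericMatrix cpp_posterior(const List& fwd, const List& bwd,
                            double total_bits) {
  NumericMatrix Fm = fwd["M"], Fi = fwd["I"];
  NumericVector Fn = fwd["N"], Fc = fwd["C"], Fls = fwd["logscale"];
  NumericMatrix Bm = bwd["M"], Bi = bwd["I"];
  NumericVector Bn = bwd["N"], Bc = bwd["C"], Bls = bwd["logscale"];
  const int L = Fm.nrow() - 1, M = Fm.ncol();
  const double eta = as<double>(fwd["eta"]);
  const double T = total_bits * LN2;
  NumericMatrix post(L, 2 * M + 2);
  for (int i = 1; i <= L; ++i) {
    const double w = std::exp(Fls[i] + Bls[i] - T);
    for (int k = 0; k < M; ++k) {
      post(i - 1, k) = Fm(i, k) * Bm(i, k) * w;
      post(i - 1, M + k) = Fi(i, k) * Bi(i, k) * w;
    }
    post(i - 1, 2 * M) = Fn[i] * Bn[i] * w;                       // N
    post(i - 1, 2 * M + 1) = Fc[i - 1] * eta * Bc[i] *
      std::exp(Fls[i - 1] + Bls[i] - T);                          // C
  }
  return post;
}

// ---------------------------------------------------------------------------
// Fused window statistics: Forward score, posterior-usage accumulators and
// the composition-bias (null2) correction in one call, avoiding R-heap
// matrices. Backward runs first into C++ buffers (it also yields the total
// log-odds); Forward then streams row by row and accumulates
//   uM[k], uI[k]  - posterior usage of each emitting model state
//   aligned[i]    - total aligned-state (match+insert) posterior at i
//   null2 bias    - max(0, sum_i aligned[i] * log2(null2(x_i)/null1(x_i)))
// Optionally materializes the full posterior matrix (layout M1..MM,
// I1..IM, N, C) for hit rendering.
// [[Rcpp::export]]
List cpp_window_stats(const NumericMatrix& ol, const NumericMatrix& tr,
                      const NumericVector& entry,
                      const NumericMatrix& match_emit,
                      const NumericVector& null1,
                      const IntegerMatrix& comp,  // 15 x 4 membership
                      const IntegerVector& x, bool want_post) {
  const int M = ol.nrow();
  const int L = x.size();
  const double eta = (L > 0) ? (double)L / (L + 2) : 0.0;
  const double l1 = 1.0 - eta;

  // ---- backward into C++ buffers (same recursion as cpp_backward_mat)
  std::vector<double> Bm((size_t)(L + 1) * M), Bi((size_t)(L + 1) * M),
      Bd((size_t)(L + 1) * M);
  std::vector<double> Bn(L + 1), Bb(L + 1), Bc(L + 1), Bls(L + 1);
  auto bm = [&](int i, int k) -> double& { return Bm[(size_t)i * M + k]; };
  auto bi = [&](int i, int k) -> double& { return Bi[(size_t)i * M + k]; };
  auto bd = [&](int i, int k) -> double& { return Bd[(size_t)i * M + k]; };
  Bc[L] = l1;
  for (int k = 0; k < M; ++k) { bm(L, k) = Bc[L]; bd(L, k) = 0.0; bi(L, k) = 0.0; }
  Bb[L] = Bc[L];
  Bn[L] = l1 * Bb[L];
  Bls[L] = 0.0;
  for (int i = L - 1; i >= 0; --i) {
    const int xc = x[i] - 1;
    double rowmax = 0.0;
    Bc[i] = eta * Bc[i + 1];
    const double eB = Bc[i];
    for (int k = M; k >= 1; --k) {
      double dv = 0.0;
      if (k < M) dv = tr(k - 1, DM) * ol(k, xc) * bm(i + 1, k) +
                      tr(k - 1, DD) * bd(i, k);
      bd(i, k - 1) = dv;
    }
    for (int k = 1; k <= M; ++k) {
      double mv = eB;
      if (k < M)
        mv += tr(k - 1, MM) * ol(k, xc) * bm(i + 1, k) +
              tr(k - 1, MI) * bi(i + 1, k - 1) +
              tr(k - 1, MD) * bd(i, k);
      bm(i, k - 1) = mv;
      double iv = 0.0;
      if (k < M)
        iv = tr(k - 1, IM) * ol(k, xc) * bm(i + 1, k) +
             tr(k - 1, II) * bi(i + 1, k - 1);
      bi(i, k - 1) = iv;
      if (mv > rowmax) rowmax = mv;
    }
    double bv = eB;
    for (int k = 1; k <= M; ++k)
      bv += entry[k - 1] * ol(k - 1, xc) * bm(i + 1, k - 1);
    Bb[i] = bv;
    Bn[i] = eta * Bn[i + 1] + l1 * Bb[i];
    if (Bn[i] > rowmax) rowmax = Bn[i];
    if (Bc[i] > rowmax) rowmax = Bc[i];
    if (rowmax <= 0.0) rowmax = 1.0;
    const double inv = 1.0 / rowmax;
    for (int k = 0; k < M; ++k) { bm(i, k) *= inv; bi(i, k) *= inv; bd(i, k) *= inv; }
    Bn[i] *= inv; Bb[i] *= inv; Bc[i] *= inv;
    Bls[i] = Bls[i + 1] + std::log(rowmax);
  }
  const double total_nat = (L == 0) ? 0.0 : std::log(Bn[0]) + Bls[0];

  // ---- forward streamed, posterior accumulated against backward rows
  std::vector<double> m(M + 1, 0.0), ins(M + 1, 0.0), d(M + 1, 0.0);
  std::vector<double> pm(M + 1), pi_(M + 1), pd(M + 1);
  std::vector<double> uM(M, 0.0), uI(M, 0.0);
  NumericVector aligned(L);
  NumericMatrix post;
  if (want_post) post = NumericMatrix(L, 2 * M + 2);
  double n = 1.0, b = l1, c = b;
  double Fls = 0.0, cprev_scaled = c, Flsprev = 0.0;
  for (int i = 1; i <= L; ++i) {
    const int xc = x[i - 1] - 1;
    std::swap(m, pm); std::swap(ins, pi_); std::swap(d, pd);
    const double bprev = b, cpv = c, npv = n;
    double e = 0.0, rowmax = 0.0;
    for (int k = 1; k <= M; ++k) {
      double v = bprev * entry[k - 1];
      if (k >= 2)
        v += pm[k - 1] * tr(k - 2, MM) + pi_[k - 1] * tr(k - 2, IM) +
             pd[k - 1] * tr(k - 2, DM);
      m[k] = v * ol(k - 1, xc);
      ins[k] = (k < M) ? pm[k] * tr(k - 1, MI) + pi_[k] * tr(k - 1, II) : 0.0;
      d[k] = (k >= 2) ? m[k - 1] * tr(k - 2, MD) + d[k - 1] * tr(k - 2, DD)
                      : 0.0;
      e += m[k];
      if (m[k] > rowmax) rowmax = m[k];
    }
    n = npv * eta;
    b = n * l1;
    e += b;
    c = e + cpv * eta;
    if (c > rowmax) rowmax = c;
    if (n > rowmax) rowmax = n;
    if (rowmax <= 0.0) rowmax = 1.0;
    const double inv = 1.0 / rowmax;
    for (int k = 1; k <= M; ++k) { m[k] *= inv; ins[k] *= inv; d[k] *= inv; }
    n *= inv; b *= inv; c *= inv;
    Flsprev = Fls;
    Fls += std::log(rowmax);
    // posterior row i
    const double w = std::exp(Fls + Bls[i] - total_nat);
    double arow = 0.0;
    for (int k = 0; k < M; ++k) {
      const double pMk = m[k + 1] * bm(i, k) * w;
      const double pIk = ins[k + 1] * bi(i, k) * w;
      uM[k] += pMk; uI[k] += pIk; arow += pMk + pIk;
      if (want_post) { post(i - 1, k) = pMk; post(i - 1, M + k) = pIk; }
    }
    aligned[i - 1] = arow;
    if (want_post) {
      post(i - 1, 2 * M) = n * Bn[i] * w;
      post(i - 1, 2 * M + 1) = cprev_scaled * eta * Bc[i] *
        std::exp(Flsprev + Bls[i] - total_nat);
    }
    cprev_scaled = c;
  }
  const double score = (L == 0) ? 0.0 : (std::log(c * l1) + Fls) / LN2;

  // ---- null2 bias
  double usum = 0.0;
  for (int k = 0; k < M; ++k) usum += uM[k] + uI[k];
  double bias = 0.0;
  if (usum > 0.0 && L > 0) {
    double null2[4] = {0, 0, 0, 0}, z = 0.0;
    for (int a = 0; a < 4; ++a) {
      for (int k = 0; k < M; ++k)
        null2[a] += uM[k] * match_emit(k, a) + uI[k] * null1[a];
      null2[a] /= usum;
      z += null2[a];
    }
    for (int a = 0; a < 4; ++a) null2[a] /= z;
    double lut[15];
    for (int cde = 0; cde < 15; ++cde) {
      double num = 0.0, den = 0.0;
      for (int a = 0; a < 4; ++a) {
        if (comp(cde, a)) { num += null2[a]; den += null1[a]; }
      }
      lut[cde] = std::log2(num / den);
    }
    for (int i = 0; i < L; ++i) bias += aligned[i] * lut[x[i] - 1];
    if (bias < 0.0) bias = 0.0;
  }
  List out = List::create(_["score"] = score, _["bias"] = bias,
                          _["aligned"] = aligned);
  if (want_post) out["post"] = post;
  return out;
}

// ---------------------------------------------------------------------------
// Baum-Welch for a fully-connected discrete-emission HMM (benchmark
// background model). Observations coded 1..4. Scaled forward-backward.
// [[Rcpp::export]]
List cpp_bw_train(const IntegerVector& x, NumericVector start,
                  NumericMatrix trans, NumericMatrix emit,
                  int iterations, double tol) {
  const int L = x.size(), K = start.size();
  std::vector<double> ll_trace;
  NumericMatrix alpha(L, K), beta(L, K);
  std::vector<double> scale(L);
  double prev_ll = NEGINF;
  for (int it = 0; it < iterations; ++it) {
    // forward
    double ll = 0.0;
    for (int j = 0; j < K; ++j) alpha(0, j) = start[j] * emit(j, x[0] - 1);
    double s = 0.0; for (int j = 0; j < K; ++j) s += alpha(0, j);
    for (int j = 0; j < K; ++j) alpha(0, j) /= s;
    scale[0] = s; ll += std::log(s);
    for (int t = 1; t < L; ++t) {
      const int o = x[t] - 1;
      s = 0.0;
      for (int j = 0; j < K; ++j) {
        double v = 0.0;
        for (int i = 0; i < K; ++i) v += alpha(t - 1, i) * trans(i, j);
        v *= emit(j, o);
        alpha(t, j) = v; s += v;
      }
      for (int j = 0; j < K; ++j) alpha(t, j) /= s;
      scale[t] = s; ll += std::log(s);
    }
    ll_trace.push_back(ll);
    // backward
    for (int j = 0; j < K; ++j) beta(L - 1, j) = 1.0;
    for (int t = L - 2; t >= 0; --t) {
      const int o = x[t + 1] - 1;
      for (int i = 0; i < K; ++i) {
        double v = 0.0;
        for (int j = 0; j < K; ++j)
          v += trans(i, j) * emit(j, o) * beta(t + 1, j);
        beta(t, i) = v / scale[t + 1];
      }
    }
    // accumulate
    NumericVector ns(K); NumericMatrix nt(K, K), ne(K, 4);
    for (int t = 0; t < L; ++t) {
      const int o = x[t] - 1;
      for (int j = 0; j < K; ++j) {
        double g = alpha(t, j) * beta(t, j);
        ne(j, o) += g;
        if (t == 0) ns[j] += g;
      }
      if (t < L - 1) {
        const int o2 = x[t + 1] - 1;
        for (int i = 0; i < K; ++i)
          for (int j = 0; j < K; ++j)
            nt(i, j) += alpha(t, i) * trans(i, j) * emit(j, o2) *
                        beta(t + 1, j) / scale[t + 1];
      }
    }
    // normalize (tiny floor keeps rows stochastic)
    double ssum = 0.0; for (int j = 0; j < K; ++j) ssum += ns[j];
    for (int j = 0; j < K; ++j) start[j] = (ns[j] + 1e-12) / (ssum + K * 1e-12);
    for (int i = 0; i < K; ++i) {
      double rs = 0.0; for (int j = 0; j < K; ++j) rs += nt(i, j);
      for (int j = 0; j < K; ++j) trans(i, j) = (nt(i, j) + 1e-12) / (rs + K * 1e-12);
      double es = 0.0; for (int c = 0; c < 4; ++c) es += ne(i, c);
      for (int c = 0; c < 4; ++c) emit(i, c) = (ne(i, c) + 1e-12) / (es + 4e-12);
    }
    if (it > 0 && std::fabs(ll - prev_ll) <
        tol * (std::fabs(prev_ll) + 1e-12)) { prev_ll = ll; break; }
    prev_ll = ll;
  }
  return List::create(_["start"] = start, _["trans"] = trans,
                      _["emit"] = emit, _["loglik"] = wrap(ll_trace));
}

// Sample a length-L observation sequence from a discrete HMM, using R's RNG
// so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_hmm_sample(const NumericVector& start,
                             const NumericMatrix& trans,
                             const NumericMatrix& emit, int L) {
  const int K = start.size();
  IntegerVector out(L);
  if (L == 0) return out;
  auto draw = [](const double* p, int n) {
    double u = unif_rand(), acc = 0.0;
    for (int j = 0; j < n; ++j) { acc += p[j]; if (u <= acc) return j; }
    return n - 1;
  };
  std::vector<double> row(K), erow(4);
  for (int j = 0; j < K; ++j) row[j] = start[j];
  int s = draw(row.data(), K);
  for (int t = 0; t < L; ++t) {
    if (t > 0) {
      for (int j = 0; j < K; ++j) row[j] = trans(s, j);
      s = draw(row.data(), K);
    }
    for (int c = 0; c < 4; ++c) erow[c] = emit(s, c);
    out[t] = draw(erow.data(), 4) + 1;
  }
  return out;
}
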