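#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap dynamic programming kernels (Gotoh three-state recursion).
// A gap of length k costs open + (k-1)*ext; consecutive gap runs in
// opposite sequences each pay their own opening cost, and gap states may
// transition into each other at opening cost. Traceback tie-break is
// fixed (diagonal > up > left; within a cell M > X > Y) so all results
// are deterministic. Score arrays are rolled row-by-row; tracebacks use
// byte backpointer matrices to keep memory traffic low.

static const double NEG_INF = -1e30;

// ---------------------------------------------------------------------------
// Global alignment of two integer-coded sequences (1-based codes) against a
// 20x20 substitution matrix. Returns score and aligned index vectors
// (0 = gap).
// [[Rcpp::export]]
List nw_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                   double open, double ext) {
  const int n = a.size(), m = b.size();
  const int nres = sub.nrow();
  std::vector<double> smat(sub.begin(), sub.end());  // column-major
  std::vector<int> ca(n), cb(m);
  for (int i = 0; i < n; ++i) ca[i] = a[i] - 1;
  for (int j = 0; j < m; ++j) cb[j] = b[j] - 1;

  // rolling rows of scores, full byte backpointers (2 bits per state)
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  std::vector<unsigned char> bp((size_t)(n + 1) * (m + 1), 0);
  auto setbp = [&](int i, int j, int sM, int sX, int sY) {
    bp[(size_t)i * (m + 1) + j] =
        (unsigned char)(sM | (sX << 2) | (sY << 4));
  };
  Mp[0] = 0.0;
  Xp[0] = Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF;
    Xp[j] = NEG_INF;
    Yp[j] = -(open + (j - 1) * ext);
    setbp(0, j, 0, 0, j == 1 ? 0 : 2);
  }
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF;
    Yc[0] = NEG_INF;
    Xc[0] = -(open + (i - 1) * ext);
    setbp(i, 0, 0, i == 1 ? 0 : 1, 0);
    const double *srow = &smat[(size_t)0];
    for (int j = 1; j <= m; ++j) {
      double s = srow[cb[j - 1] * nres + ca[i - 1]];
      double vm = Mp[j - 1], vx = Xp[j - 1], vy = Yp[j - 1];
      int sM = 0;
      double bv = vm;
      if (vx > bv) { bv = vx; sM = 1; }
      if (vy > bv) { bv = vy; sM = 2; }
      double mm = bv + s;
      vm = Mp[j] - open; vx = Xp[j] - ext; vy = Yp[j] - open;
      int sX = 0;
      bv = vm;
      if (vx > bv) { bv = vx; sX = 1; }
      if (vy > bv) { bv = vy; sX = 2; }
      double xx = bv;
      vm = Mc[j - 1] - open; vx = Xc[j - 1] - open; vy = Yc[j - 1] - ext;
      int sY = 0;
      bv = vm;
      if (vx > bv) { bv = vx; sY = 1; }
      if (vy > bv) { bv = vy; sY = 2; }
      double yy = bv;
      Mc[j] = mm; Xc[j] = xx; Yc[j] = yy;
      setbp(i, j, sM, sX, sY);
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  double score = Mp[m];
  int state = 0;
  if (Xp[m] > score) { score = Xp[m]; state = 1; }
  if (Yp[m] > score) { score = Yp[m]; state = 2; }
  std::vector<int> ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char bpc = bp[(size_t)i * (m + 1) + j];
    if (state == 0) {
      ra.push_back(i); rb.push_back(j);
      --i; --j;
      state = bpc & 3;
    } else if (state == 1) {
      ra.push_back(i); rb.push_back(0);
      --i;
      state = (bpc >> 2) & 3;
    } else {
      ra.push_back(0); rb.push_back(j);
      --j;
      state = (bpc >> 4) & 3;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["a_idx"] = wrap(ra),
                      _["b_idx"] = wrap(rb));
}

// Full PSSM-vs-sequence local alignment with traceback bookkeeping.
// [[Rcpp::export]]
List sw_pssm_tb_cpp(NumericMatrix pssm20, IntegerVector tseq, double open,
                    double ext) {
  const int n = pssm20.ncol(), m = tseq.size();
  if (pssm20.nrow() != 20) stop("pssm20 must have 20 rows");
  const double *pm = pssm20.begin();
  std::vector<int> ts(m);
  for (int j = 0; j < m; ++j) ts[j] = tseq[j] - 1;
  std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, NEG_INF), Yp(m + 1, NEG_INF);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  std::vector<unsigned char> bp((size_t)(n + 1) * (m + 1), 3);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const double *col = pm + 20 * (i - 1);
    Mc[0] = 0.0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double s = col[ts[j - 1]];
      double vm = Mp[j - 1], vx = Xp[j - 1], vy = Yp[j - 1];
      int sM = 0;
      double bv = vm;
      if (vx > bv) { bv = vx; sM = 1; }
      if (vy > bv) { bv = vy; sM = 2; }
      double mm = bv + s;
      if (mm < 0.0) { mm = 0.0; sM = 3; }
      vm = Mp[j] - open; vx = Xp[j] - ext; vy = Yp[j] - open;
      int sX = 0;
      bv = vm;
      if (vx > bv) { bv = vx; sX = 1; }
      if (vy > bv) { bv = vy; sX = 2; }
      double xx = bv;
      vm = Mc[j - 1] - open; vx = Xc[j - 1] - open; vy = Yc[j - 1] - ext;
      int sY = 0;
      bv = vm;
      if (vx > bv) { bv = vx; sY = 1; }
      if (vy > bv) { bv = vy; sY = 2; }
      double yy = bv;
      Mc[j] = mm; Xc[j] = xx; Yc[j] = yy;
      bp[(size_t)i * (m + 1) + j] =
          (unsigned char)(sM | (sX << 2) | (sY << 4));
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0, _["aln_len"] = 0,
                        _["n_pairs"] = 0);
  int i = bi, j = bj, state = 0;
  int qs = bi, ts1 = bj, alen = 0, npairs = 0;
  bool done = false;
  while (!done) {
    unsigned char bpc = bp[(size_t)i * (m + 1) + j];
    if (state == 0) {
      int nxt = bpc & 3;
      ++alen; ++npairs;
      qs = i; ts1 = j;
      --i; --j;
      if (nxt == 3) done = true; else state = nxt;
    } else if (state == 1) {
      ++alen; --i;
      state = (bpc >> 2) & 3;
    } else {
      ++alen; --j;
      state = (bpc >> 4) & 3;
    }
    if (!done && (i == 0 || j == 0)) done = true;
  }
  return List::create(_["score"] = best, _["q_start"] = qs, _["q_end"] = bi,
                      _["t_start"] = ts1, _["t_end"] = bj,
                      _["aln_len"] = alen, _["n_pairs"] = npairs);
}

// ---------------------------------------------------------------------------
// Generic DP over a precomputed profile-profile cell-score matrix S
// (n rows = profile-1 columns, m cols = profile-2 columns). gs1/gs2 scale
// gap costs per skipped column (1 - gap fraction). The matrix is
// transposed internally once so the inner loop stays within one cache
// column. local = TRUE: Smith-Waterman; FALSE: global over columns.
struct TransS {
  std::vector<double> st;  // (m x n): st[(i)*m + j] = S(i+1, j+1)
  int n, m;
  TransS(const NumericMatrix &S) : n(S.nrow()), m(S.ncol()) {
    st.resize((size_t)n * m);
    const double *ps = S.begin();
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i)
        st[(size_t)i * m + j] = ps[(size_t)j * n + i];
  }
};

static double dp_local_score_only(const TransS &TS, const double *gs1,
                                  const double *gs2, double open, double ext,
                                  const int *ord,
                                  std::vector<double> &buf) {
  const int n = TS.n, m = TS.m;
  buf.assign(6 * (m + 1), 0.0);
  double *Mp = buf.data(), *Xp = Mp + (m + 1), *Yp = Xp + (m + 1);
  double *Mc = Yp + (m + 1), *Xc = Mc + (m + 1), *Yc = Xc + (m + 1);
  for (int j = 0; j <= m; ++j) { Xp[j] = NEG_INF; Yp[j] = NEG_INF; }
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    const double *srow = &TS.st[(size_t)(i - 1) * m];
    const double og1 = open * gs1[i - 1], eg1 = ext * gs1[i - 1];
    Mc[0] = 0.0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      const int jc = ord ? ord[j - 1] : j - 1;
      double s = srow[jc];
      const double og2 = open * gs2[jc], eg2 = ext * gs2[jc];
      double mm = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1])) + s;
      if (mm < 0.0) mm = 0.0;
      double xx = std::max(std::max(Mp[j], Yp[j]) - og1, Xp[j] - eg1);
      double yy =
          std::max(std::max(Mc[j - 1], Xc[j - 1]) - og2, Yc[j - 1] - eg2);
      Mc[j] = mm; Xc[j] = xx; Yc[j] = yy;
      if (mm > best) best = mm;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return best;
}

// [[Rcpp::export]]
List dp_scoremat_cpp(NumericMatrix S, NumericVector gs1, NumericVector gs2,
                     double open, double ext, bool local, bool traceback,
                     Nullable<IntegerVector> colorder = R_NilValue,
                     int band = 0) {
  const int n = S.nrow(), m = S.ncol();
  std::vector<int> ordv;
  const int *ord = nullptr;
  if (colorder.isNotNull()) {
    IntegerVector co(colorder);
    ordv.resize(m);
    for (int j = 0; j < m; ++j) ordv[j] = co[j] - 1;
    ord = ordv.data();
  }
  TransS TS(S);
  if (local && !traceback) {
    std::vector<double> buf;
    double sc = dp_local_score_only(TS, gs1.begin(), gs2.begin(), open, ext,
                                    ord, buf);
    return List::create(_["score"] = sc);
  }
  // full backpointer DP (local or global)
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  std::vector<unsigned char> bp((size_t)(n + 1) * (m + 1), 3);
  auto gsc2 = [&](int j) { return gs2[ord ? ord[j - 1] : j - 1]; };
  if (local) {
    Mp[0] = 0.0;
    for (int j = 1; j <= m; ++j) Mp[j] = 0.0;
    Xp[0] = Yp[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) { Xp[j] = NEG_INF; Yp[j] = NEG_INF; }
  } else {
    Mp[0] = 0.0; Xp[0] = Yp[0] = NEG_INF;
    double acc = 0.0;
    for (int j = 1; j <= m; ++j) {
      acc -= (j == 1 ? open : ext) * gsc2(j);
      Mp[j] = NEG_INF; Xp[j] = NEG_INF; Yp[j] = acc;
      bp[j] = (unsigned char)(0 | (0 << 2) | ((j == 1 ? 0 : 2) << 4));
    }
  }
  double best = 0.0;
  int bi = 0, bj = 0;
  double xacc = 0.0;
  // banded iteration: rows visit [jlo, jhi] around the interpolated
  // diagonal; cells outside carry NEG_INF (global bands keep column 0
  // reachable so end gaps stay representable)
  auto band_row = [&](int i, int &jlo, int &jhi) {
    if (band <= 0) { jlo = 1; jhi = m; return; }
    int c = (int)((double)i * m / n + 0.5);
    jlo = std::max(1, c - band);
    jhi = std::min(m, c + band);
    if (jlo > jhi) jlo = jhi;
  };
  for (int i = 1; i <= n; ++i) {
    const double *srow = &TS.st[(size_t)(i - 1) * m];
    const double og1 = open * gs1[i - 1], eg1 = ext * gs1[i - 1];
    int jlo, jhi;
    band_row(i, jlo, jhi);
    if (local) {
      Mc[0] = 0.0; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
      if (jlo >= 2) {
        Mc[jlo - 1] = 0.0; Xc[jlo - 1] = NEG_INF; Yc[jlo - 1] = NEG_INF;
        Mp[jlo - 2] = NEG_INF;
      }
    } else {
      xacc -= (i == 1 ? open : ext) * gs1[i - 1];
      Mc[0] = NEG_INF; Yc[0] = NEG_INF; Xc[0] = xacc;
      bp[(size_t)i * (m + 1)] =
          (unsigned char)(0 | ((i == 1 ? 0 : 1) << 2) | (0 << 4));
      if (jlo >= 2) {
        Mc[jlo - 1] = NEG_INF; Xc[jlo - 1] = NEG_INF; Yc[jlo - 1] = NEG_INF;
        Mp[jlo - 2] = NEG_INF;
      }
    }
    for (int j = jlo; j <= jhi; ++j) {
      const int jc = ord ? ord[j - 1] : j - 1;
      double s = srow[jc];
      const double og2 = open * gs2[jc], eg2 = ext * gs2[jc];
      double vm = Mp[j - 1], vx = Xp[j - 1], vy = Yp[j - 1];
      int sM = 0;
      double bv = vm;
      if (vx > bv) { bv = vx; sM = 1; }
      if (vy > bv) { bv = vy; sM = 2; }
      double mm = bv + s;
      if (local && mm < 0.0) { mm = 0.0; sM = 3; }
      vm = Mp[j] - og1; vx = Xp[j] - eg1; vy = Yp[j] - og1;
      int sX = 0;
      bv = vm;
      if (vx > bv) { bv = vx; sX = 1; }
      if (vy > bv) { bv = vy; sX = 2; }
      double xx = bv;
      vm = Mc[j - 1] - og2; vx = Xc[j - 1] - og2; vy = Yc[j - 1] - eg2;
      int sY = 0;
      bv = vm;
      if (vx > bv) { bv = vx; sY = 1; }
      if (vy > bv) { bv = vy; sY = 2; }
      double yy = bv;
      Mc[j] = mm; Xc[j] = xx; Yc[j] = yy;
      bp[(size_t)i * (m + 1) + j] =
          (unsigned char)(sM | (sX << 2) | (sY << 4));
      if (local && mm > best) { best = mm; bi = i; bj = j; }
    }
    {
      int nlo, nhi;
      band_row(std::min(i + 1, n), nlo, nhi);
      for (int j = jhi + 1; j <= nhi; ++j) {
        Mc[j] = NEG_INF; Xc[j] = NEG_INF; Yc[j] = NEG_INF;
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  if (local) {
    if (best <= 0.0)
      return List::create(_["score"] = 0.0, _["q_start"] = 0,
                          _["q_end"] = 0, _["t_start"] = 0, _["t_end"] = 0,
                          _["aln_len"] = 0, _["n_pairs"] = 0);
    int i = bi, j = bj, state = 0;
    int qs = bi, ts1 = bj, alen = 0, npairs = 0;
    bool done = false;
    while (!done) {
      unsigned char bpc = bp[(size_t)i * (m + 1) + j];
      if (state == 0) {
        int nxt = bpc & 3;
        ++alen; ++npairs;
        qs = i; ts1 = j;
        --i; --j;
        if (nxt == 3) done = true; else state = nxt;
      } else if (state == 1) {
        ++alen; --i;
        state = (bpc >> 2) & 3;
      } else {
        ++alen; --j;
        state = (bpc >> 4) & 3;
      }
      if (!done && (i == 0 || j == 0)) done = true;
    }
    return List::create(_["score"] = best, _["q_start"] = qs,
                        _["q_end"] = bi, _["t_start"] = ts1,
                        _["t_end"] = bj, _["aln_len"] = alen,
                        _["n_pairs"] = npairs);
  }
  double score = Mp[m];
  int state = 0;
  if (Xp[m] > score) { score = Xp[m]; state = 1; }
  if (Yp[m] > score) { score = Yp[m]; state = 2; }
  std::vector<int> ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char bpc = bp[(size_t)i * (m + 1) + j];
    if (state == 0) {
      ra.push_back(i); rb.push_back(j);
      --i; --j;
      state = bpc & 3;
    } else if (state == 1) {
      ra.push_back(i); rb.push_back(0);
      --i;
      state = (bpc >> 2) & 3;
    } else {
      ra.push_back(0); rb.push_back(j);
      --j;
      state = (bpc >> 4) & 3;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["a_idx"] = wrap(ra),
                      _["b_idx"] = wrap(rb));
}

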