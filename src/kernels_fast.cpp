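#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Fast score-only alignment cores: single-precision, optionally banded
// around the length-interpolated diagonal. These back the search and
// shuffle-null paths, where only the maximal score is needed; tracebacks
// and the brute-force-checked oracle paths use the exact double-precision
// kernels in kernels.cpp. When a band is set, both observed and null
// scores are computed with the same banded statistic so significance
// estimates stay internally consistent.

static const float FNEG_INF = -1e30f;

// pass 1 of the row update (M and X states), restrict-qualified so the
// compiler can vectorize
static inline void row_pass1(int jlo, int jhi, const float *__restrict__ Mp,
                             const float *__restrict__ Xp,
                             const float *__restrict__ Yp,
                             const float *__restrict__ srow,
                             float *__restrict__ Mc,
                             float *__restrict__ Xc, float og1, float eg1,
                             bool local) {
  if (local) {
    for (int j = jlo; j <= jhi; ++j) {
      float mm = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1])) +
                 srow[j];
      mm = std::max(mm, 0.0f);
      float xx = std::max(std::max(Mp[j], Yp[j]) - og1, Xp[j] - eg1);
      Mc[j] = mm;
      Xc[j] = xx;
    }
  } else {
    for (int j = jlo; j <= jhi; ++j) {
      float mm = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1])) +
                 srow[j];
      float xx = std::max(std::max(Mp[j], Yp[j]) - og1, Xp[j] - eg1);
      Mc[j] = mm;
      Xc[j] = xx;
    }
  }
}

struct BandIter {
  int m, n, B;
  BandIter(int n_, int m_, int band) : m(m_), n(n_), B(band) {}
  inline void row(int i, int &jlo, int &jhi) const {
    if (B <= 0) { jlo = 1; jhi = m; return; }
    int c = (int)((double)i * m / n + 0.5);
    jlo = std::max(1, c - B);
    jhi = std::min(m, c + B);
    if (jlo > jhi) jlo = jhi;
  }
};

// local (Smith-Waterman) over a float score row accessor; the M/X states
// read only the previous row, so they run in a vectorizable first pass,
// and the serial Y scan follows
template <typename ScoreAt>
static double sw_core(int n, int m, ScoreAt score_at, const float *og1v,
                      const float *eg1v, const float *og2v,
                      const float *eg2v, int band,
                      std::vector<float> &buf) {
  BandIter bi(n, m, band);
  buf.assign(7 * (m + 2), FNEG_INF);
  float *Mp = buf.data(), *Xp = Mp + (m + 2), *Yp = Xp + (m + 2);
  float *Mc = Yp + (m + 2), *Xc = Mc + (m + 2), *Yc = Xc + (m + 2);
  float *srow = Yc + (m + 2);
  int plo = 1, phi = m;
  bi.row(0, plo, phi);
  for (int j = plo - 1; j <= phi; ++j) { Mp[j] = 0.0f; }
  float best = 0.0f;
  for (int i = 1; i <= n; ++i) {
    int jlo, jhi;
    bi.row(i, jlo, jhi);
    Mc[jlo - 1] = 0.0f; Xc[jlo - 1] = FNEG_INF; Yc[jlo - 1] = FNEG_INF;
    if (jlo >= 2) { Mp[jlo - 2] = FNEG_INF; }
    const float og1 = og1v[i - 1], eg1 = eg1v[i - 1];
    for (int j = jlo; j <= jhi; ++j) srow[j] = score_at(i - 1, j - 1);
    row_pass1(jlo, jhi, Mp, Xp, Yp, srow, Mc, Xc, og1, eg1, true);
    float yprev = FNEG_INF;
    for (int j = jlo; j <= jhi; ++j) {
      float yy = std::max(std::max(Mc[j - 1], Xc[j - 1]) - og2v[j - 1],
                          yprev - eg2v[j - 1]);
      Yc[j] = yy;
      yprev = yy;
      best = std::max(best, Mc[j]);
    }
    // clear cells the next row may read beyond this row's band
    int nlo, nhi;
    bi.row(std::min(i + 1, n), nlo, nhi);
    for (int j = jhi + 1; j <= nhi; ++j) {
      Mc[j] = FNEG_INF; Xc[j] = FNEG_INF; Yc[j] = FNEG_INF;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return (double)best;
}

// global (Needleman-Wunsch) core, score only
template <typename ScoreAt>
static double nw_core(int n, int m, ScoreAt score_at, float open, float ext,
                      int band, std::vector<float> &buf) {
  BandIter bi(n, m, band);
  buf.assign(7 * (m + 2), FNEG_INF);
  float *Mp = buf.data(), *Xp = Mp + (m + 2), *Yp = Xp + (m + 2);
  float *Mc = Yp + (m + 2), *Xc = Mc + (m + 2), *Yc = Xc + (m + 2);
  float *srow = Yc + (m + 2);
  int plo, phi;
  bi.row(0, plo, phi);
  Mp[0] = 0.0f;
  for (int j = 1; j <= phi; ++j) Yp[j] = -(open + (j - 1) * ext);
  for (int i = 1; i <= n; ++i) {
    int jlo, jhi;
    bi.row(i, jlo, jhi);
    Mc[jlo - 1] = FNEG_INF; Yc[jlo - 1] = FNEG_INF;
    Xc[jlo - 1] = (jlo == 1) ? -(open + (i - 1) * ext) : FNEG_INF;
    if (jlo >= 2) Mp[jlo - 2] = FNEG_INF;
    for (int j = jlo; j <= jhi; ++j) srow[j] = score_at(i - 1, j - 1);
    row_pass1(jlo, jhi, Mp, Xp, Yp, srow, Mc, Xc, open, ext, false);
    float yprev = FNEG_INF;
    for (int j = jlo; j <= jhi; ++j) {
      float yy = std::max(std::max(Mc[j - 1], Xc[j - 1]) - open,
                          yprev - ext);
      Yc[j] = yy;
      yprev = yy;
    }
    int nlo, nhi;
    bi.row(std::min(i + 1, n), nlo, nhi);
    for (int j = jhi + 1; j <= nhi; ++j) {
      Mc[j] = FNEG_INF; Xc[j] = FNEG_INF; Yc[j] = FNEG_INF;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  return (double)std::max(Mp[m], std::max(Xp[m], Yp[m]));
}

// ---------------------------------------------------------------------------
// Batch local scores of a query PSSM (transposed, 20 x L, double) against
// integer-coded targets; `order` permutes query columns (shuffle nulls).
// [[Rcpp::export]]
NumericVector sw_pssm_batch_cpp(NumericMatrix pssm20, List targets,
                                double open, double ext,
                                Nullable<IntegerVector> order = R_NilValue,
                                int band = 0) {
  const int n = pssm20.ncol();
  if (pssm20.nrow() != 20) stop("pssm20 must have 20 rows");
  std::vector<float> pm((size_t)20 * n);
  {
    const double *src = pssm20.begin();
    if (order.isNotNull()) {
      IntegerVector o(order);
      for (int i = 0; i < n; ++i) {
        const double *col = src + (size_t)20 * (o[i] - 1);
        for (int r = 0; r < 20; ++r) pm[(size_t)20 * i + r] = (float)col[r];
      }
    } else {
      for (size_t k = 0; k < pm.size(); ++k) pm[k] = (float)src[k];
    }
  }
  std::vector<float> ones(n, 1.0f);
  std::vector<float> og1(n, (float)open), eg1(n, (float)ext);
  NumericVector out(targets.size());
  std::vector<float> buf;
  for (int k = 0; k < targets.size(); ++k) {
    IntegerVector t(targets[k]);
    const int m = t.size();
    std::vector<int> ts(m);
    for (int j = 0; j < m; ++j) ts[j] = t[j] - 1;
    std::vector<float> og2(m, (float)open), eg2(m, (float)ext);
    const float *pmp = pm.data();
    const int *tsp = ts.data();
    out[k] = sw_core(n, m,
                     [pmp, tsp](int i, int j) {
                       return pmp[(size_t)20 * i + tsp[j]];
                     },
                     og1.data(), eg1.data(), og2.data(), eg2.data(), band,
                     buf);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Batch global scores of one integer-coded query against targets.
// [[Rcpp::export]]
NumericVector nw_batch_cpp(IntegerVector a, List targets, NumericMatrix sub,
                           double open, double ext,
                           Nullable<IntegerVector> order = R_NilValue,
                           int band = 0) {
  const int n = a.size();
  std::vector<int> ca(n);
  if (order.isNotNull()) {
    IntegerVector o(order);
    for (int i = 0; i < n; ++i) ca[i] = a[o[i] - 1] - 1;
  } else {
    for (int i = 0; i < n; ++i) ca[i] = a[i] - 1;
  }
  const int nres = sub.nrow();
  std::vector<float> smat(sub.size());
  for (int k = 0; k < sub.size(); ++k) smat[k] = (float)sub[k];
  NumericVector out(targets.size());
  std::vector<float> buf;
  for (int k = 0; k < targets.size(); ++k) {
    IntegerVector t(targets[k]);
    const int m = t.size();
    std::vector<int> cb(m);
    for (int j = 0; j < m; ++j) cb[j] = t[j] - 1;
    const float *sm = smat.data();
    const int *cap = ca.data();
    const int *cbp = cb.data();
    out[k] = nw_core(n, m,
                     [sm, cap, cbp, nres](int i, int j) {
                       return sm[(size_t)cbp[j] * nres + cap[i]];
                     },
                     (float)open, (float)ext, band, buf);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Banded float local score of a profile-profile cell matrix.
struct FTransS {
  std::vector<float> st;  // row-major: st[i * m + j]
  int n, m;
  FTransS(const NumericMatrix &S) : n(S.nrow()), m(S.ncol()) {
    st.resize((size_t)n * m);
    const double *ps = S.begin();
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i)
        st[(size_t)i * m + j] = (float)ps[(size_t)j * n + i];
  }
};

static double fdp_local(const FTransS &TS, const float *og1,
                        const float *eg1, const float *og2, const float *eg2,
                        const int *ord, int band, std::vector<float> &buf) {
  const float *st = TS.st.data();
  const int m = TS.m;
  if (ord) {
    return sw_core(TS.n, m,
                   [st, m, ord](int i, int j) {
                     return st[(size_t)i * m + ord[j]];
                   },
                   og1, eg1, og2, eg2, band, buf);
  }
  return sw_core(TS.n, m,
                 [st, m](int i, int j) { return st[(size_t)i * m + j]; },
                 og1, eg1, og2, eg2, band, buf);
}

static void scale_gaps(const NumericVector &gs, double open, double ext,
                       std::vector<float> &og, std::vector<float> &eg) {
  og.resize(gs.size());
  eg.resize(gs.size());
  for (int i = 0; i < gs.size(); ++i) {
    og[i] = (float)(open * gs[i]);
    eg[i] = (float)(ext * gs[i]);
  }
}

// [[Rcpp::export]]
double dp_local_score_cpp(NumericMatrix S, NumericVector gs1,
                          NumericVector gs2, double open, double ext,
                          int band = 0) {
  FTransS TS(S);
  std::vector<float> og1, eg1, og2, eg2, buf;
  scale_gaps(gs1, open, ext, og1, eg1);
  scale_gaps(gs2, open, ext, og2, eg2);
  return fdp_local(TS, og1.data(), eg1.data(), og2.data(), eg2.data(),
                   nullptr, band, buf);
}

// Column-shuffle null scores with optional sequential early stopping
// (Besag-Clifford): stop once `h_stop` null scores reach `observed`.
// Returns the null scores drawn, the number drawn, and the exceedance
// count. The permutation for a null must be applied to gs2 as well, which
// happens implicitly because column j of the permuted matrix carries its
// own gap scale; we therefore permute both the score access and the gap
// vectors.
// [[Rcpp::export]]
List dp_local_null_cpp(NumericMatrix S, NumericVector gs1,
                       NumericVector gs2, double open, double ext,
                       IntegerMatrix perms, int band = 0,
                       double observed = NA_REAL, int h_stop = 0) {
  FTransS TS(S);
  const int m = S.ncol();
  if (perms.nrow() != m) stop("perms must have ncol(S) rows");
  std::vector<float> og1, eg1, og2b, eg2b;
  scale_gaps(gs1, open, ext, og1, eg1);
  scale_gaps(gs2, open, ext, og2b, eg2b);
  std::vector<float> og2(m), eg2(m), buf;
  std::vector<int> ord(m);
  std::vector<double> scores;
  scores.reserve(perms.ncol());
  int exceed = 0;
  for (int k = 0; k < perms.ncol(); ++k) {
    for (int j = 0; j < m; ++j) {
      ord[j] = perms(j, k) - 1;
      og2[j] = og2b[ord[j]];
      eg2[j] = eg2b[ord[j]];
    }
    double sc = fdp_local(TS, og1.data(), eg1.data(), og2.data(),
                          eg2.data(), ord.data(), band, buf);
    scores.push_back(sc);
    if (!ISNA(observed) && sc >= observed) {
      ++exceed;
      if (h_stop > 0 && exceed >= h_stop) break;
    }
  }
  return List::create(_["scores"] = wrap(scores),
                      _["n_done"] = (int)scores.size(),
                      _["n_exceed"] = exceed);
}
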