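#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log2-space sum: log2(2^a + 2^b)
static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  double d = (a > b ? b : a) - m;
  return m + std::log2(1.0 + std::exp2(d));
}

// Transition layout: ltr is L x 7 column-major (mm, mi, md, im, ii, dm, dd),
// giving the log2 transitions out of model position j (1-based):
// M_j->M_{j+1}, M_j->I_j, M_j->D_{j+1}, I_j->M_{j+1}, I_j->I_j,
// D_j->M_{j+1}, D_j->D_{j+1}. Row L is unused (M_L->E, D_L->E free).
// Emissions: lm (L x A) and li ((L+1) x A) column-major log2-odds.
// Glocal: global in the model, local in the sequence; flanking residues are
// emitted by a free background loop (log-odds 0). Ties break M > D > I.

// Full Viterbi with traceback.
// [[Rcpp::export(name = ".vit_glocal")]]
List vit_glocal(NumericMatrix lm, NumericMatrix li, NumericVector lbm,
                NumericMatrix ltr, IntegerVector seq, bool traceback) {
  const int L = lm.nrow();
  const int n = seq.size();
  const double *LM = lm.begin();
  const double *LI = li.begin();
  const double *TR = ltr.begin();
  const int *S = seq.begin();
  const size_t W = (size_t)n + 1;
  std::vector<double> VM((size_t)(L + 1) * W, NEG_INF),
      VI((size_t)(L + 1) * W, NEG_INF), VD((size_t)(L + 1) * W, NEG_INF);
  std::vector<signed char> PM, PI, PD;
  if (traceback) {
    PM.assign((size_t)(L + 1) * W, 0);
    PI.assign((size_t)(L + 1) * W, 0);
    PD.assign((size_t)(L + 1) * W, 0);
  }
  double *vm1 = &VM[W], *vd1 = &VD[W];
  for (int i = 1; i <= n; ++i) vm1[i] = lbm[0] + LM[(size_t)S[i - 1] * L];
  for (int i = 0; i <= n; ++i) vd1[i] = lbm[1];
  for (int j = 1; j < L; ++j) {
    const double t_mm = TR[j - 1], t_mi = TR[L + j - 1], t_md = TR[2 * L + j - 1];
    const double t_im = TR[3 * L + j - 1], t_ii = TR[4 * L + j - 1];
    const double t_dm = TR[5 * L + j - 1], t_dd = TR[6 * L + j - 1];
    double *vmj = &VM[(size_t)j * W], *vij = &VI[(size_t)j * W],
           *vdj = &VD[(size_t)j * W];
    double *vmn = &VM[(size_t)(j + 1) * W], *vdn = &VD[(size_t)(j + 1) * W];
    signed char *pij = traceback ? &PI[(size_t)j * W] : NULL;
    signed char *pmn = traceback ? &PM[(size_t)(j + 1) * W] : NULL;
    signed char *pdn = traceback ? &PD[(size_t)(j + 1) * W] : NULL;
    for (int i = 0; i <= n; ++i) {
      double fm = vmj[i] + t_md, fd = vdj[i] + t_dd;
      vdn[i] = fm >= fd ? fm : fd;
      if (traceback) pdn[i] = (fm >= fd) ? 1 : 2;
      if (i >= 1) {
        double gm = vmj[i - 1] + t_mi, gi = vij[i - 1] + t_ii;
        vij[i] = (gm >= gi ? gm : gi) +
                 LI[(size_t)S[i - 1] * (L + 1) + j];
        if (traceback) pij[i] = (gm >= gi) ? 1 : 3;
      }
    }
    const double *em = &LM[0];
    for (int i = 1; i <= n; ++i) {
      double hm = vmj[i - 1] + t_mm;
      double hd = vdj[i - 1] + t_dm;
      double hi = vij[i - 1] + t_im;
      double best = hm; signed char p = 1;
      if (hd > best) { best = hd; p = 2; }
      if (hi > best) { best = hi; p = 3; }
      vmn[i] = best + em[(size_t)S[i - 1] * L + j];
      if (traceback) pmn[i] = p;
    }
  }
  const double *vmL = &VM[(size_t)L * W], *vdL = &VD[(size_t)L * W];
  double score = NEG_INF; int end_i = 0; int end_state = 1;
  for (int i = 0; i <= n; ++i) {
    if (vmL[i] > score) { score = vmL[i]; end_i = i; end_state = 1; }
    if (vdL[i] > score) { score = vdL[i]; end_i = i; end_state = 2; }
  }
  IntegerVector matchmap(L, -1);
  int env_start = -1, env_end = -1;
  if (traceback && score > NEG_INF) {
    int j = L, i = end_i, st = end_state;
    while (j >= 1) {
      if (st == 1) {
        matchmap[j - 1] = i - 1;
        if (env_end < 0) env_end = i;
        env_start = i - 1;
        signed char p = PM[(size_t)j * W + i];
        if (j == 1) break;
        --j; --i; st = p;
      } else if (st == 2) {
        signed char p = PD[(size_t)j * W + i];
        if (j == 1) break;
        --j; st = p;
      } else {
        if (env_end < 0) env_end = i;
        env_start = i - 1;
        signed char p = PI[(size_t)j * W + i];
        --i; st = p;
      }
    }
    if (env_start < 0) { env_start = 0; env_end = 0; }
  }
  return List::create(_["score"] = score, _["start"] = env_start,
                      _["end"] = env_end, _["matchmap"] = matchmap);
}

// Score-only glocal Viterbi with rolling rows.
static double vit_score_only(const double *LM, const double *LI,
                             const double *lbm, const double *TR, int L,
                             const int *S, int n, double *buf) {
  double *M0 = buf, *I0 = buf + (n + 1), *D0 = buf + 2 * (n + 1),
         *M1 = buf + 3 * (n + 1), *D1v = buf + 4 * (n + 1);
  for (int i = 0; i <= n; ++i) {
    M0[i] = (i >= 1) ? lbm[0] + LM[(size_t)S[i - 1] * L] : NEG_INF;
    I0[i] = NEG_INF;
    D0[i] = lbm[1];
  }
  for (int j = 1; j < L; ++j) {
    const double t_mm = TR[j - 1], t_mi = TR[L + j - 1], t_md = TR[2 * L + j - 1];
    const double t_im = TR[3 * L + j - 1], t_ii = TR[4 * L + j - 1];
    const double t_dm = TR[5 * L + j - 1], t_dd = TR[6 * L + j - 1];
    for (int i = 1; i <= n; ++i) {
      double gm = M0[i - 1] + t_mi, gi = I0[i - 1] + t_ii;
      double v = (gm >= gi ? gm : gi);
      I0[i] = v + LI[(size_t)S[i - 1] * (L + 1) + j];
    }
    D1v[0] = std::max(M0[0] + t_md, D0[0] + t_dd);
    M1[0] = NEG_INF;
    for (int i = 1; i <= n; ++i) {
      double fm = M0[i] + t_md, fd = D0[i] + t_dd;
      D1v[i] = fm >= fd ? fm : fd;
      double hm = M0[i - 1] + t_mm;
      double hd = D0[i - 1] + t_dm;
      double hi = I0[i - 1] + t_im;
      double best = hm >= hd ? hm : hd;
      if (hi > best) best = hi;
      M1[i] = best + LM[(size_t)S[i - 1] * L + j];
    }
    std::swap(M0, M1);
    std::swap(D0, D1v);
    std::fill(I0, I0 + n + 1, NEG_INF);
  }
  double sc = NEG_INF;
  for (int i = 0; i <= n; ++i) {
    if (M0[i] > sc) sc = M0[i];
    if (D0[i] > sc) sc = D0[i];
  }
  return sc;
}

// Viterbi scores of many sequences against one model (calibration, scans).
// [[Rcpp::export(name = ".vit_scores_batch")]]
NumericVector vit_scores_batch(NumericMatrix lm, NumericMatrix li,
                               NumericVector lbm, NumericMatrix ltr,
                               List seqs) {
  int m = seqs.size();
  int L = lm.nrow();
  int nmax = 1;
  for (int k = 0; k < m; ++k) {
    IntegerVector s = seqs[k];
    if (s.size() > nmax) nmax = s.size();
  }
  std::vector<double> buf(5 * (size_t)(nmax + 1));
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    IntegerVector s = seqs[k];
    out[k] = vit_score_only(lm.begin(), li.begin(), lbm.begin(),
                            ltr.begin(), L, s.begin(), s.size(), &buf[0]);
  }
  return out;
}

// Forward score under the same glocal architecture (log2-space sum over
// all paths and envelope placements).
// [[Rcpp::export(name = ".fwd_glocal")]]
double fwd_glocal(NumericMatrix lm, NumericMatrix li, NumericVector lbm,
                  NumericMatrix ltr, IntegerVector seq) {
  const int L = lm.nrow();
  const int n = seq.size();
  const double *LM = lm.begin(), *LI = li.begin(), *TR = ltr.begin();
  const int *S = seq.begin();
  const size_t W = (size_t)n + 1;
  std::vector<double> VM((size_t)(L + 1) * W, NEG_INF),
      VI((size_t)(L + 1) * W, NEG_INF), VD((size_t)(L + 1) * W, NEG_INF);
  for (int i = 1; i <= n; ++i) VM[W + i] = lbm[0] + LM[(size_t)S[i - 1] * L];
  for (int i = 0; i <= n; ++i) VD[W + i] = lbm[1];
  for (int j = 1; j < L; ++j) {
    const double t_mm = TR[j - 1], t_mi = TR[L + j - 1], t_md = TR[2 * L + j - 1];
    const double t_im = TR[3 * L + j - 1], t_ii = TR[4 * L + j - 1];
    const double t_dm = TR[5 * L + j - 1], t_dd = TR[6 * L + j - 1];
    double *vmj = &VM[(size_t)j * W], *vij = &VI[(size_t)j * W],
           *vdj = &VD[(size_t)j * W];
    double *vmn = &VM[(size_t)(j + 1) * W], *vdn = &VD[(size_t)(j + 1) * W];
    for (int i = 0; i <= n; ++i) {
      vdn[i] = lse2(vmj[i] + t_md, vdj[i] + t_dd);
      if (i >= 1)
        vij[i] = lse2(vmj[i - 1] + t_mi, vij[i - 1] + t_ii) +
                 LI[(size_t)S[i - 1] * (L + 1) + j];
    }
    for (int i = 1; i <= n; ++i)
      vmn[i] = lse2(lse2(vmj[i - 1] + t_mm, vdj[i - 1] + t_dm),
                    vij[i - 1] + t_im) + LM[(size_t)S[i - 1] * L + j];
  }
  double score = NEG_INF;
  for (int i = 0; i <= n; ++i)
    score = lse2(score, lse2(VM[(size_t)L * W + i], VD[(size_t)L * W + i]));
  return score;
}

// Smith-Waterman local alignment score, affine gaps (a gap of length k
// costs go + k * ge); sub is A x A column-major, sequences 0-based codes.
static double sw_score_one(const int *a, int na, const int *b, int nb,
                           const double *sub, int A, double go, double ge) {
  std::vector<double> H(nb + 1, 0.0), E(nb + 1, 0.0);
  double best = 0.0;
  const double open = go + ge;
  for (int i = 1; i <= na; ++i) {
    double Hdiag = 0.0, F = 0.0, Hprev = 0.0;
    const double *srow = sub + (size_t)a[i - 1] * A;
    for (int j = 1; j <= nb; ++j) {
      double e = H[j] - open, e2 = E[j] - ge;
      e = e >= e2 ? e : e2;
      E[j] = e;
      double f = Hprev - open, f2 = F - ge;
      F = f >= f2 ? f : f2;
      double h = Hdiag + srow[b[j - 1]];
      if (e > h) h = e;
      if (F > h) h = F;
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      Hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score")]]
double sw_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                double go, double ge) {
  return sw_score_one(a.begin(), a.size(), b.begin(), b.size(),
                      sub.begin(), sub.nrow(), go, ge);
}

// All-pairs SW scores; upper triangle in combn(n, 2) order.
// [[Rcpp::export(name = ".sw_allpairs")]]
NumericVector sw_allpairs(List seqs, NumericMatrix sub, double go, double ge) {
  int n = seqs.size();
  std::vector<std::vector<int> > v(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    v[i].assign(s.begin(), s.end());
  }
  NumericVector out((R_xlen_t)n * (n - 1) / 2);
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j, ++k) {
      out[k] = sw_score_one(v[i].data(), (int)v[i].size(), v[j].data(),
                            (int)v[j].size(), sub.begin(), sub.nrow(), go, ge);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Column-weighted p-distance matrix from an integer alignment matrix
// (n x L, residue codes >= 0, negatives = gap/unknown). w gives a
// nonnegative multiplicity per column (bootstrap weights). Entry =
// weighted mismatches / weighted shared non-gap columns; NA when no
// column is shared.
// [[Rcpp::export(name = ".pdist_mat")]]
NumericMatrix pdist_mat(IntegerMatrix aln, NumericVector w) {
  int n = aln.nrow(), L = aln.ncol();
  NumericMatrix out(n, n);
  // rows as contiguous int8-ish arrays, only columns with weight > 0
  std::vector<int> keep;
  keep.reserve(L);
  for (int c = 0; c < L; ++c) if (w[c] > 0) keep.push_back(c);
  const int Lk = keep.size();
  std::vector<signed char> M((size_t)n * Lk);
  std::vector<double> wk(Lk);
  const int *A = aln.begin();
  for (int c = 0; c < Lk; ++c) {
    wk[c] = w[keep[c]];
    const int *col = A + (size_t)keep[c] * n;
    for (int i = 0; i < n; ++i) {
      int x = col[i];
      M[(size_t)i * Lk + c] = (signed char)(x < 0 || x > 126 ? -1 : x);
    }
  }
  for (int i = 0; i < n; ++i) {
    const signed char *ri = &M[(size_t)i * Lk];
    for (int j2 = i + 1; j2 < n; ++j2) {
      const signed char *rj = &M[(size_t)j2 * Lk];
      double shared = 0.0, mism = 0.0;
      for (int c = 0; c < Lk; ++c) {
        if (ri[c] < 0 || rj[c] < 0) continue;
        shared += wk[c];
        if (ri[c] != rj[c]) mism += wk[c];
      }
      double d = shared > 0 ? mism / shared : NA_REAL;
      out(i, j2) = d;
      out(j2, i) = d;
    }
  }
  return out;
}

// Global Needleman-Wunsch over a precomputed column-pair score matrix S
// (LA x LB), affine gaps (gap of length k costs go + k*ge), full
// three-state traceback. Returns merged column maps (1-based source column
// or NA) and the optimal score.
// [[Rcpp::export(name = ".nw_affine_map")]]
List nw_affine_map(NumericMatrix S, double go, double ge) {
  const int la = S.nrow(), lb = S.ncol();
  NumericMatrix H(la + 1, lb + 1), E(la + 1, lb + 1), F(la + 1, lb + 1);
  IntegerMatrix PH(la + 1, lb + 1), PE(la + 1, lb + 1), PF(la + 1, lb + 1);
  H(0, 0) = 0; E(0, 0) = F(0, 0) = NEG_INF;
  for (int i = 1; i <= la; ++i) {
    E(i, 0) = -go - ge * i;
    PE(i, 0) = (i == 1) ? 0 : 1;
    H(i, 0) = E(i, 0); PH(i, 0) = 1;
    F(i, 0) = NEG_INF;
  }
  for (int j = 1; j <= lb; ++j) {
    F(0, j) = -go - ge * j;
    PF(0, j) = (j == 1) ? 0 : 1;
    H(0, j) = F(0, j); PH(0, j) = 2;
    E(0, j) = NEG_INF;
  }
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double eo = H(i - 1, j) - go - ge, ee = E(i - 1, j) - ge;
      E(i, j) = eo >= ee ? eo : ee; PE(i, j) = eo >= ee ? 0 : 1;
      double fo = H(i, j - 1) - go - ge, fe = F(i, j - 1) - ge;
      F(i, j) = fo >= fe ? fo : fe; PF(i, j) = fo >= fe ? 0 : 1;
      double d = H(i - 1, j - 1) + S(i - 1, j - 1);
      double best = d; int p = 0;
      if (E(i, j) > best) { best = E(i, j); p = 1; }
      if (F(i, j) > best) { best = F(i, j); p = 2; }
      H(i, j) = best; PH(i, j) = p;
    }
  }
  std::vector<int> ra, rb;
  int i = la, j = lb, st = PH(la, lb);
  while (i > 0 || j > 0) {
    if (st == 1) {
      ra.push_back(i); rb.push_back(NA_INTEGER);
      int opened = (PE(i, j) == 0);
      --i;
      st = opened ? PH(i, j) : 1;
    } else if (st == 2) {
      ra.push_back(NA_INTEGER); rb.push_back(j);
      int opened = (PF(i, j) == 0);
      --j;
      st = opened ? PH(i, j) : 2;
    } else {
      ra.push_back(i); rb.push_back(j);
      --i; --j;
      if (i > 0 || j > 0) st = PH(i, j);
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["mapA"] = wrap(ra), _["mapB"] = wrap(rb),
                      _["score"] = H(la, lb));
}
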