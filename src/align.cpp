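#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Alignment kernels shared by the profile scan, identity clustering and the
// decay filter.  All coordinates returned to R are 0-based half-open.

static const double NEG = -1e12;

// ---------------------------------------------------------------------------
// Local profile-to-sequence alignment (Smith-Waterman with affine gaps)
// against a position-specific scoring matrix.
//
// seq: residue codes, 0-based rows into pssm; codes < 0 or >= nrow(pssm) are
//      invalid (stop codons, X) and receive a strongly negative score so no
//      local alignment ever spans them.
// pssm: nres x ncol score matrix (columns = profile match columns).
// Gap penalties are positive magnitudes; a gap of length L costs
// gap_open + (L-1)*gap_extend.
//
// Returns a matrix with columns (start, end, score): best-scoring,
// mutually non-overlapping local hits with score >= threshold and
// end - start >= min_len.
// [[Rcpp::export]]
NumericMatrix cpp_pssm_scan(IntegerVector seq, NumericMatrix pssm,
                            double gap_open, double gap_extend,
                            double threshold, int min_len) {
  const int n = seq.size();
  const int C = pssm.ncol();
  const int R = pssm.nrow();
  if (n == 0 || C == 0) return NumericMatrix(0, 3);

  // residue-major copy of the profile: scores of residue a are contiguous
  std::vector<double> prof((R + 1) * C);
  for (int a = 0; a < R; ++a)
    for (int j = 0; j < C; ++j) prof[a * C + j] = pssm(a, j);
  for (int j = 0; j < C; ++j) prof[R * C + j] = NEG;  // invalid residue row

  // per-column state for row i (sequence position), columns 1..C
  std::vector<double> Hp(C + 1, 0.0), Hc(C + 1, 0.0), Fv(C + 1, NEG);
  std::vector<int> SHp(C + 1, -1), SHc(C + 1, -1), SF(C + 1, -1);

  std::vector<double> best_score(n, 0.0);
  std::vector<int> best_start(n, -1);
  const int* sq = &seq[0];

  for (int i = 1; i <= n; ++i) {
    int a = sq[i - 1];
    if (a < 0 || a >= R) a = R;
    if (a == R) {
      // invalid residue (stop codon / X): a hard barrier no local
      // alignment may span, not even through gap states
      std::fill(Hp.begin(), Hp.end(), 0.0);
      std::fill(Fv.begin(), Fv.end(), NEG);
      std::fill(SHp.begin(), SHp.end(), -1);
      best_score[i - 1] = 0.0;
      best_start[i - 1] = -1;
      continue;
    }
    const double* __restrict__ prow = &prof[a * C];
    double* __restrict__ hp = &Hp[0];
    double* __restrict__ hc = &Hc[0];
    double* __restrict__ fv = &Fv[0];
    int* __restrict__ shp = &SHp[0];
    int* __restrict__ shc = &SHc[0];
    int* __restrict__ sf = &SF[0];
    double E = NEG;               // gap consuming profile columns only
    int SE = -1;
    hc[0] = 0.0; shc[0] = -1;
    double rowbest = 0.0; int rowstart = -1;
    for (int j = 1; j <= C; ++j) {
      // F: insertion in sequence (consumes seq residue, stays in column j)
      double f_open = hp[j] - gap_open;
      double f_ext = fv[j] - gap_extend;
      if (f_open >= f_ext) { fv[j] = f_open; sf[j] = shp[j]; }
      else                 { fv[j] = f_ext; }
      // E: deletion of profile column (no seq residue)
      double e_open = hc[j - 1] - gap_open;
      double e_ext = E - gap_extend;
      if (e_open >= e_ext) { E = e_open; SE = shc[j - 1]; }
      else                 { E = e_ext; }
      // M
      double m = hp[j - 1] + prow[j - 1];
      int sm = (shp[j - 1] < 0) ? (i - 1) : shp[j - 1];
      double h = m; int sh = sm;
      if (E > h) { h = E; sh = SE; }
      if (fv[j] > h) { h = fv[j]; sh = sf[j]; }
      if (h <= 0.0) { h = 0.0; sh = -1; }
      hc[j] = h; shc[j] = sh;
      if (h > rowbest) { rowbest = h; rowstart = sh; }
    }
    best_score[i - 1] = rowbest;
    best_start[i - 1] = rowstart;
    std::swap(Hp, Hc);
    std::swap(SHp, SHc);
  }

  // candidate ends above threshold, greedy non-overlap by descending score
  std::vector<int> idx;
  for (int i = 0; i < n; ++i)
    if (best_score[i] >= threshold && best_start[i] >= 0 &&
        (i + 1 - best_start[i]) >= min_len)
      idx.push_back(i);
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (best_score[a] != best_score[b]) return best_score[a] > best_score[b];
    return a < b;
  });
  std::vector<std::pair<int, int>> taken;  // [start, end)
  std::vector<int> keep;
  for (int i : idx) {
    int s = best_start[i], e = i + 1;
    bool clash = false;
    for (auto &t : taken)
      if (s < t.second && t.first < e) { clash = true; break; }
    if (!clash) { taken.push_back({s, e}); keep.push_back(i); }
  }
  std::sort(keep.begin(), keep.end(), [&](int a, int b) {
    return best_start[a] < best_start[b];
  });
  NumericMatrix out(keep.size(), 3);
  for (size_t k = 0; k < keep.size(); ++k) {
    out(k, 0) = best_start[keep[k]];
    out(k, 1) = keep[k] + 1;
    out(k, 2) = best_score[keep[k]];
  }
  colnames(out) = CharacterVector::create("start", "end", "score");
  return out;
}

// ---------------------------------------------------------------------------
// Pairwise alignment score + identity bookkeeping, affine gaps, optional
// free terminal gaps per sequence and optional band on |i - j|.
// free_a: terminal gaps in b (skipping a's ends) are free; free_b likewise
// for a's gaps (skipping b's ends).  With only the longer sequence free
// this is a glocal (fragment-in-full) alignment: the shorter sequence is
// consumed entirely, so identities cannot come from tiny chance overlaps.
//
// Returns c(score, matches, columns) where `columns` counts aligned columns
// on the optimal path excluding free terminal-gap columns.
// Ties broken deterministically (M > E > F).
// [[Rcpp::export]]
NumericVector cpp_align_stats(IntegerVector a, IntegerVector b,
                              double match, double mismatch,
                              double gap_open, double gap_extend,
                              bool free_a, bool free_b, int band) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const bool banded = band > 0;
  const int half = banded ? band + std::abs(n - m) : 0;

  // flat state arrays: score / matches / columns per state (M, E, F)
  std::vector<double> Ms(m + 1, NEG), Es(m + 1, NEG), Fs(m + 1, NEG);
  std::vector<double> Msn(m + 1), Esn(m + 1), Fsn(m + 1);
  std::vector<int> Mm(m + 1, 0), Em(m + 1, 0), Fm(m + 1, 0);
  std::vector<int> Mmn(m + 1), Emn(m + 1), Fmn(m + 1);
  std::vector<int> Mc(m + 1, 0), Ec(m + 1, 0), Fc(m + 1, 0);
  std::vector<int> Mcn(m + 1), Ecn(m + 1), Fcn(m + 1);

  // row 0: gaps in a consuming b's prefix
  Ms[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    if (free_b) { Es[j] = 0.0; Em[j] = 0; Ec[j] = 0; }
    else { Es[j] = -gap_open - (j - 1) * gap_extend; Em[j] = 0; Ec[j] = j; }
  }
  const int* av = &a[0];
  const int* bv = &b[0];
  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (banded) { jlo = std::max(1, i - half); jhi = std::min(m, i + half); }
    for (int j = std::max(0, jlo - 1); j <= jhi; ++j) {
      Msn[j] = NEG; Esn[j] = NEG; Fsn[j] = NEG;
      Mmn[j] = 0; Emn[j] = 0; Fmn[j] = 0;
      Mcn[j] = 0; Ecn[j] = 0; Fcn[j] = 0;
    }
    if (jlo == 1) {  // column 0: gap in b consuming a's prefix
      if (free_a) { Fsn[0] = 0.0; Fmn[0] = 0; Fcn[0] = 0; }
      else { Fsn[0] = -gap_open - (i - 1) * gap_extend; Fmn[0] = 0; Fcn[0] = i; }
    }
    const int ai = av[i - 1];
    for (int j = jlo; j <= jhi; ++j) {
      // M from best of previous diagonal states
      double ds = Ms[j - 1]; int dm = Mm[j - 1]; int dc = Mc[j - 1];
      if (Es[j - 1] > ds) { ds = Es[j - 1]; dm = Em[j - 1]; dc = Ec[j - 1]; }
      if (Fs[j - 1] > ds) { ds = Fs[j - 1]; dm = Fm[j - 1]; dc = Fc[j - 1]; }
      if (ds > NEG / 2) {
        const bool eq = (ai == bv[j - 1]);
        Msn[j] = ds + (eq ? match : mismatch);
        Mmn[j] = dm + (eq ? 1 : 0);
        Mcn[j] = dc + 1;
      }
      // E: gap in a (consumes b)
      double eo = Msn[j - 1]; int eom = Mmn[j - 1]; int eoc = Mcn[j - 1];
      if (Fsn[j - 1] > eo) { eo = Fsn[j - 1]; eom = Fmn[j - 1]; eoc = Fcn[j - 1]; }
      double e1 = eo - gap_open;
      double e2 = Esn[j - 1] - gap_extend;
      if (e1 >= e2) { Esn[j] = e1; Emn[j] = eom; Ecn[j] = eoc + 1; }
      else { Esn[j] = e2; Emn[j] = Emn[j - 1]; Ecn[j] = Ecn[j - 1] + 1; }
      if (i == n && free_b) {  // free trailing gap in a along the last row
        double fs = Msn[j - 1]; int fm = Mmn[j - 1]; int fc = Mcn[j - 1];
        if (Fsn[j - 1] > fs) { fs = Fsn[j - 1]; fm = Fmn[j - 1]; fc = Fcn[j - 1]; }
        if (Esn[j - 1] > fs) { fs = Esn[j - 1]; fm = Emn[j - 1]; fc = Ecn[j - 1]; }
        if (fs > Esn[j]) { Esn[j] = fs; Emn[j] = fm; Ecn[j] = fc; }
      }
      // F: gap in b (consumes a)
      double fo = Ms[j]; int fom = Mm[j]; int foc = Mc[j];
      if (Es[j] > fo) { fo = Es[j]; fom = Em[j]; foc = Ec[j]; }
      double f1 = fo - gap_open;
      double f2 = Fs[j] - gap_extend;
      if (f1 >= f2) { Fsn[j] = f1; Fmn[j] = fom; Fcn[j] = foc + 1; }
      else { Fsn[j] = f2; Fmn[j] = Fm[j]; Fcn[j] = Fc[j] + 1; }
      if (j == m && free_a) {  // free trailing gap in b along the last column
        double gs = Ms[j]; int gm = Mm[j]; int gc = Mc[j];
        if (Es[j] > gs) { gs = Es[j]; gm = Em[j]; gc = Ec[j]; }
        if (Fs[j] > gs) { gs = Fs[j]; gm = Fm[j]; gc = Fc[j]; }
        if (gs > Fsn[j]) { Fsn[j] = gs; Fmn[j] = gm; Fcn[j] = gc; }
      }
    }
    std::swap(Ms, Msn); std::swap(Mm, Mmn); std::swap(Mc, Mcn);
    std::swap(Es, Esn); std::swap(Em, Emn); std::swap(Ec, Ecn);
    std::swap(Fs, Fsn); std::swap(Fm, Fmn); std::swap(Fc, Fcn);
  }
  double bs = Ms[m]; int bm = Mm[m]; int bc = Mc[m];
  if (Es[m] > bs) { bs = Es[m]; bm = Em[m]; bc = Ec[m]; }
  if (Fs[m] > bs) { bs = Fs[m]; bm = Fm[m]; bc = Fc[m]; }
  return NumericVector::create(_["score"] = bs,
                               _["matches"] = (double)bm,
                               _["columns"] = (double)bc);
}

// ---------------------------------------------------------------------------
// Pairwise alignment with traceback (affine; free terminal gaps per
// sequence as in cpp_align_stats).  Returns two integer vectors of equal
// length: 1-based indices into a and b, 0 for gap.
// Intended for modest sequence lengths (center-star alignment inputs).
// [[Rcpp::export]]
List cpp_align_pair(IntegerVector a, IntegerVector b,
                    double match, double mismatch,
                    double gap_open, double gap_extend,
                    bool free_a, bool free_b) {
  const int n = a.size(), m = b.size();
  if ((double)n * (double)m > 1e7) stop("sequences too long for traceback alignment");
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG)),
      E(n + 1, std::vector<double>(m + 1, NEG)),
      F(n + 1, std::vector<double>(m + 1, NEG));
  // pointers: 0=M,1=E,2=F ; packed per state
  std::vector<std::vector<unsigned char>> PM(n + 1, std::vector<unsigned char>(m + 1, 0)),
      PE(n + 1, std::vector<unsigned char>(m + 1, 0)),
      PF(n + 1, std::vector<unsigned char>(m + 1, 0));
  M[0][0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    E[0][j] = free_b ? 0.0 : -gap_open - (j - 1) * gap_extend;
    PE[0][j] = 1;
  }
  for (int i = 1; i <= n; ++i) {
    F[i][0] = free_a ? 0.0 : -gap_open - (i - 1) * gap_extend;
    PF[i][0] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M
      double d = M[i - 1][j - 1]; unsigned char p = 0;
      if (E[i - 1][j - 1] > d) { d = E[i - 1][j - 1]; p = 1; }
      if (F[i - 1][j - 1] > d) { d = F[i - 1][j - 1]; p = 2; }
      if (d > NEG / 2) {
        M[i][j] = d + ((a[i - 1] == b[j - 1]) ? match : mismatch);
        PM[i][j] = p;
      }
      // E (gap in a)
      double eo = M[i][j - 1]; unsigned char pe = 0;
      if (F[i][j - 1] > eo) { eo = F[i][j - 1]; pe = 2; }
      double v1 = eo - gap_open, v2 = E[i][j - 1] - gap_extend;
      bool freeE = free_b && i == n;
      if (freeE) {
        double w = M[i][j - 1]; unsigned char pw = 0;
        if (F[i][j - 1] > w) { w = F[i][j - 1]; pw = 2; }
        if (E[i][j - 1] > w) { w = E[i][j - 1]; pw = 1; }
        E[i][j] = w; PE[i][j] = pw;
      } else if (v1 >= v2) { E[i][j] = v1; PE[i][j] = pe; }
      else { E[i][j] = v2; PE[i][j] = 1; }
      // F (gap in b)
      double fo = M[i - 1][j]; unsigned char pf = 0;
      if (E[i - 1][j] > fo) { fo = E[i - 1][j]; pf = 1; }
      double w1 = fo - gap_open, w2 = F[i - 1][j] - gap_extend;
      bool freeF = free_a && j == m;
      if (freeF) {
        double w = M[i - 1][j]; unsigned char pw = 0;
        if (E[i - 1][j] > w) { w = E[i - 1][j]; pw = 1; }
        if (F[i - 1][j] > w) { w = F[i - 1][j]; pw = 2; }
        F[i][j] = w; PF[i][j] = pw;
      } else if (w1 >= w2) { F[i][j] = w1; PF[i][j] = pf; }
      else { F[i][j] = w2; PF[i][j] = 2; }
    }
  }
  // pick end state
  int st = 0; double bs = M[n][m];
  if (E[n][m] > bs) { bs = E[n][m]; st = 1; }
  if (F[n][m] > bs) { bs = F[n][m]; st = 2; }
  std::vector<int> ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == 0) {
      unsigned char p = PM[i][j];
      ra.push_back(i); rb.push_back(j); --i; --j; st = p;
    } else if (st == 1) {
      unsigned char p = PE[i][j];
      ra.push_back(0); rb.push_back(j); --j; st = p;
    } else {
      unsigned char p = PF[i][j];
      ra.push_back(i); rb.push_back(0); --i; st = p;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = wrap(ra), _["b"] = wrap(rb),
                      _["score"] = bs);
}

// ---------------------------------------------------------------------------
// Best local alignment (Smith-Waterman, affine) between two sequences, with
// identity bookkeeping, used by the IS1341 decay filter.
// Returns c(score, matches, columns, a_start, a_end, b_start, b_end)
// (0-based half-open coordinates of the aligned segments).
// [[Rcpp::export]]
NumericVector cpp_local_stats(IntegerVector a, IntegerVector b,
                              double match, double mismatch,
                              double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  struct Cell { double s; int mt; int cl; int ia; int ib; };
  const Cell Z = {0.0, 0, 0, -1, -1};
  const Cell BAD = {NEG, 0, 0, -1, -1};
  std::vector<Cell> Mp(m + 1, Z), Ep(m + 1, BAD), Fp(m + 1, BAD);
  std::vector<Cell> Mc(m + 1, Z), Ec(m + 1, BAD), Fc(m + 1, BAD);
  Cell best = Z; int be_i = 0, be_j = 0;
  for (int i = 1; i <= n; ++i) {
    Mc[0] = Z; Ec[0] = BAD; Fc[0] = BAD;
    for (int j = 1; j <= m; ++j) {
      Cell d = Mp[j - 1];
      if (Ep[j - 1].s > d.s) d = Ep[j - 1];
      if (Fp[j - 1].s > d.s) d = Fp[j - 1];
      if (d.s < 0.0) d = Z;  // fresh local start
      bool eq = (a[i - 1] == b[j - 1]);
      Cell mcell = {d.s + (eq ? match : mismatch), d.mt + (eq ? 1 : 0),
                    d.cl + 1, d.ia < 0 ? (i - 1) : d.ia,
                    d.ib < 0 ? (j - 1) : d.ib};
      if (mcell.s < 0.0) mcell = Z;  // local reset
      Mc[j] = mcell;
      // E: gap in a
      Cell eo = Mc[j - 1];
      if (Fc[j - 1].s > eo.s) eo = Fc[j - 1];
      Cell e1 = {eo.s - gap_open, eo.mt, eo.cl + 1, eo.ia, eo.ib};
      Cell e2 = {Ec[j - 1].s - gap_extend, Ec[j - 1].mt, Ec[j - 1].cl + 1,
                 Ec[j - 1].ia, Ec[j - 1].ib};
      Ec[j] = (e1.s >= e2.s) ? e1 : e2;
      // F: gap in b
      Cell fo = Mp[j];
      if (Ep[j].s > fo.s) fo = Ep[j];
      Cell f1 = {fo.s - gap_open, fo.mt, fo.cl + 1, fo.ia, fo.ib};
      Cell f2 = {Fp[j].s - gap_extend, Fp[j].mt, Fp[j].cl + 1,
                 Fp[j].ia, Fp[j].ib};
      Fc[j] = (f1.s >= f2.s) ? f1 : f2;
      if (Mc[j].s > best.s) { best = Mc[j]; be_i = i; be_j = j; }
    }
    std::swap(Mp, Mc); std::swap(Ep, Ec); std::swap(Fp, Fc);
  }
  return NumericVector::create(
      _["score"] = best.s, _["matches"] = (double)best.mt,
      _["columns"] = (double)best.cl,
      _["a_start"] = (double)std::max(best.ia, 0), _["a_end"] = (double)be_i,
      _["b_start"] = (double)std::max(best.ib, 0), _["b_end"] = (double)be_j);
}

// ---------------------------------------------------------------------------
// Enumerate maximal subterminal inverted repeats (palindromes).
// s: codes A=0, C=1, G=2, T=3 (others never pair).
// A hit is arm1-loop-arm2 with arm2 = reverse complement of arm1 up to
// max_mm internal mismatches; the outermost and innermost arm pairs must
// pair exactly (mismatched terminal pairs are trimmed).
// Returns matrix (start, end, arm, loop, mismatches); start/end 0-based
// half-open over the whole structure.  One maximal record per
// (inner position, loop length) combination with arm >= min_arm.
// [[Rcpp::export]]
IntegerMatrix cpp_find_palindromes(IntegerVector s, int min_arm,
                                   int loop_min, int loop_max, int max_mm) {
  const int n = s.size();
  std::vector<std::array<int, 5>> hits;
  for (int L = loop_min; L <= loop_max; ++L) {
    for (int i = 0; i + L + 1 < n; ++i) {
      // i = last base of left arm; right arm starts at i+L+1
      int l = i, r = i + L + 1;
      if (s[l] < 0 || s[l] > 3 || s[r] < 0 || s[r] > 3) continue;
      if (s[l] + s[r] != 3) continue;  // innermost pair must match
      // record the maximal arm at <=1 mismatch and at <=max_mm mismatches
      // separately, so callers can trade arm length against cleanliness
      int mm = 0, arm = 0;
      int best_arm1 = 0, best_mm1 = 0, best_arm2 = 0, best_mm2 = 0;
      while (l >= 0 && r < n) {
        bool pair = (s[l] >= 0 && s[l] <= 3 && s[r] >= 0 && s[r] <= 3 &&
                     s[l] + s[r] == 3);
        if (!pair) {
          ++mm;
          if (mm > max_mm) break;
        }
        ++arm;
        if (pair) {  // trim mismatched ends
          if (mm <= 1) { best_arm1 = arm; best_mm1 = mm; }
          best_arm2 = arm; best_mm2 = mm;
        }
        --l; ++r;
      }
      if (best_arm1 >= min_arm) {
        hits.push_back({i - best_arm1 + 1, i + L + best_arm1 + 1,
                        best_arm1, L, best_mm1});
      }
      if (best_arm2 > best_arm1 && best_arm2 >= min_arm) {
        hits.push_back({i - best_arm2 + 1, i + L + best_arm2 + 1,
                        best_arm2, L, best_mm2});
      }
    }
  }
  IntegerMatrix out(hits.size(), 5);
  for (size_t k = 0; k < hits.size(); ++k)
    for (int c = 0; c < 5; ++c) out(k, c) = hits[k][c];
  colnames(out) = CharacterVector::create("start", "end", "arm", "loop",
                                          "mismatches");
  return out;
}

// ---------------------------------------------------------------------------
// Direct-repeat search for IS607-type ends: find tandem-repeated units of
// length unit_min..unit_max occurring >= min_occ times (each occurrence
// within max_mm mismatches of the seed unit and total_budget mismatches
// across all accepted occurrences, non-overlapping, inside a span of at
// most `window` nt.  Returns (start, end, unit_len, n_occ, total_mm) per
// candidate, 0-based half-open over the searched sequence.
// [[Rcpp::export]]
IntegerMatrix cpp_find_direct_repeats(IntegerVector s, int unit_min,
                                      int unit_max, int min_occ,
                                      int max_mm, int total_budget,
                                      int window) {
  const int n = s.size();
  std::vector<std::array<int, 5>> hits;
  for (int L = unit_max; L >= unit_min; --L) {
    for (int i = 0; i + L <= n; ++i) {
      // greedy non-overlapping occurrences of s[i..i+L) within [i, i+window);
      // track both the exact-copies-only span and the mismatch-budgeted
      // span, emitting each as its own candidate: an exact span keeps the
      // repeat edge (and hence the external tetramer) anchored even when a
      // chance near-copy lies a little further out
      int occ = 1, occ_ex = 1;
      int span_end = i + L, span_ex = i + L;
      int tmm = 0;
      int jmax = std::min(n - L, i + window - L);
      for (int j = i + L; j <= jmax; ++j) {
        int mm = 0;
        for (int k = 0; k < L; ++k) {
          if (s[i + k] != s[j + k]) { ++mm; if (mm > max_mm) break; }
        }
        if (mm <= max_mm && tmm + mm <= total_budget) {
          ++occ;
          span_end = j + L;
          tmm += mm;
          if (mm == 0 && tmm == 0) { occ_ex = occ; span_ex = span_end; }
          j += L - 1;  // non-overlapping
        }
      }
      if (occ_ex >= min_occ && (occ_ex != occ || span_ex != span_end)) {
        hits.push_back({i, span_ex, L, occ_ex, 0});
      }
      if (occ >= min_occ) {
        hits.push_back({i, span_end, L, occ, tmm});
      }
    }
  }
  IntegerMatrix out(hits.size(), 5);
  for (size_t k = 0; k < hits.size(); ++k)
    for (int c = 0; c < 5; ++c) out(k, c) = hits[k][c];
  colnames(out) = CharacterVector::create("start", "end", "unit_len",
                                          "n_occ", "total_mm");
  return out;
}
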