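#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman style) alignment of an integer-coded peptide against
// a position-specific scoring matrix, with affine gap penalties in bits.
//
// scores: 20 x M matrix, scores(a-1, j-1) = log-odds of residue a at match
// column j.  seq: residue codes 1..20 (0 = unknown, contributes 0).
// gap_open / gap_ext: positive penalties charged when opening/extending a gap
// in either the query or the profile.
//
// Returns best local score, the query span it covers (1-based inclusive) and,
// when traceback = true, the query position aligned to each match column
// (NA when the column is deleted or outside the local alignment).
// [[Rcpp::export]]
List pssm_align_one(IntegerVector seq, NumericMatrix scores,
                    double gap_open, double gap_ext, bool traceback) {
  const int L = seq.size();
  const int M = scores.ncol();
  const double NEG = -1e100;

  // DP over (column j = 1..M, position i = 1..L); three states.
  // H: best score ending in a match at (j, i); Dg: gap in query (column
  // consumed, no residue); Ig: insertion in query (residue consumed, no
  // column).  Local: H may restart at 0.
  std::vector<double> Hprev(L + 1, NEG), Dprev(L + 1, NEG), Iprev(L + 1, NEG);
  std::vector<double> H(L + 1), D(L + 1), I(L + 1);
  // traceback pointers: 0 start, 1 from H diag, 2 from D diag, 3 from I diag,
  // for D: 1 from H up, 2 from D up; for I: 1 from H left, 2 from I left
  IntegerMatrix ptrH(traceback ? M + 1 : 1, traceback ? L + 1 : 1);
  IntegerMatrix ptrD(traceback ? M + 1 : 1, traceback ? L + 1 : 1);
  IntegerMatrix ptrI(traceback ? M + 1 : 1, traceback ? L + 1 : 1);

  double best = 0.0;
  int best_j = 0, best_i = 0;

  for (int j = 1; j <= M; ++j) {
    H[0] = NEG; D[0] = NEG; I[0] = NEG;
    // gap in query can start at i = 0? a local alignment never benefits from
    // leading deletions, keep NEG.
    for (int i = 1; i <= L; ++i) {
      int a = seq[i - 1];
      double sub = (a >= 1 && a <= 20) ? scores(a - 1, j - 1) : 0.0;
      // match state: diagonal from (j-1, i-1) in any state, or fresh start
      double hdiag = Hprev[i - 1], ddiag = Dprev[i - 1], idiag = Iprev[i - 1];
      double m = 0.0; int pm = 0;
      if (hdiag > m) { m = hdiag; pm = 1; }
      if (ddiag > m) { m = ddiag; pm = 2; }
      if (idiag > m) { m = idiag; pm = 3; }
      H[i] = m + sub;
      // deletion (skip column j): from (j-1, i)
      double dh = Hprev[i] - gap_open, dd = Dprev[i] - gap_ext;
      if (dh >= dd) { D[i] = dh; if (traceback) ptrD(j, i) = 1; }
      else          { D[i] = dd; if (traceback) ptrD(j, i) = 2; }
      // insertion (skip residue i): from (j, i-1)
      double ih = H[i - 1] - gap_open, ii = I[i - 1] - gap_ext;
      if (ih >= ii) { I[i] = ih; if (traceback) ptrI(j, i) = 1; }
      else          { I[i] = ii; if (traceback) ptrI(j, i) = 2; }
      if (traceback) ptrH(j, i) = pm;
      if (H[i] > best) { best = H[i]; best_j = j; best_i = i; }
    }
    std::swap(H, Hprev); std::swap(D, Dprev); std::swap(I, Iprev);
  }

  IntegerVector colmap;
  int qstart = NA_INTEGER, qend = NA_INTEGER;
  if (best > 0.0) qend = best_i;
  if (traceback) {
    colmap = IntegerVector(M, NA_INTEGER);
    if (best > 0.0) {
      int j = best_j, i = best_i, state = 0; // 0 = H
      while (j > 0 && i > 0) {
        if (state == 0) {
          colmap[j - 1] = i;
          int p = ptrH(j, i);
          qstart = i;
          --j; --i;
          if (p == 0) break;
          state = (p == 1) ? 0 : (p == 2) ? 1 : 2;
        } else if (state == 1) { // D: column skipped
          int p = ptrD(j, i);
          --j;
          state = (p == 1) ? 0 : 1;
        } else { // I: residue skipped
          int p = ptrI(j, i);
          --i;
          state = (p == 1) ? 0 : 2;
        }
      }
    }
  } else if (best > 0.0) {
    qstart = 1; // span start not tracked in fast mode
  }

  return List::create(_["score"] = best, _["qstart"] = qstart,
                      _["qend"] = qend, _["colmap"] = colmap);
}

// Score many integer-coded sequences against the profile (no traceback).
// [[Rcpp::export]]
NumericVector pssm_score_batch(List seqs, NumericMatrix scores,
                               double gap_open, double gap_ext) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    List r = pssm_align_one(sq, scores, gap_open, gap_ext, false);
    out[s] = as<double>(r["score"]);
  }
  return out;
}
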