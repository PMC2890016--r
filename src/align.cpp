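#include <Rcpp.h>
using namespace Rcpp;

// Banded affine-gap pairwise alignment over integer-encoded sequences.
//
// a, b: 1-based indices into the rows/cols of `submat`.
// diag_lo/diag_hi: allowed diagonal offsets j - i (b-position minus
// a-position), inclusive. Pass (-n_a, n_b) for an unbanded run.
// mode 0 = local (Smith-Waterman, affine gaps, score floor 0);
// mode 1 = overlap (free end gaps; best dovetail/containment path,
//          alignment must end with an aligned pair on a border).
//
// Returns 0-based half-open coordinates of the aligned region on both
// sequences plus per-column statistics and the traceback operations
// (0 = aligned pair, 1 = gap in b / consume a, 2 = gap in a / consume b).
//
// [[Rcpp::export]]
List cpp_align(IntegerVector a, IntegerVector b, NumericMatrix submat,
               double gap_open, double gap_ext, int mode,
               int diag_lo, int diag_hi) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  if (diag_lo > diag_hi) stop("empty band");
  const int W = diag_hi - diag_lo + 1;

  // band storage: cell (i, j) lives at column k = j - i - diag_lo
  std::vector<double> M((size_t)(n + 1) * W, NEG), X((size_t)(n + 1) * W, NEG),
      Y((size_t)(n + 1) * W, NEG);
  std::vector<signed char> tbM((size_t)(n + 1) * W, 0),
      tbX((size_t)(n + 1) * W, 0), tbY((size_t)(n + 1) * W, 0);
  auto idx = [&](int i, int k) { return (size_t)i * W + k; };
  auto inband = [&](int i, int j) {
    return i >= 0 && i <= n && j >= 0 && j <= m && j - i >= diag_lo &&
           j - i <= diag_hi;
  };

  double best = NEG;
  int bi = -1, bj = -1;

  for (int i = 0; i <= n; ++i) {
    int jlo = std::max(0, i + diag_lo), jhi = std::min(m, i + diag_hi);
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i - diag_lo;
      size_t p = idx(i, k);
      double mM = NEG, mX = NEG, mY = NEG;
      signed char tM = 0, tX = 0, tY = 0;

      if (mode == 1 && (i == 0 || j == 0)) {
        M[p] = 0.0; tbM[p] = 0;  // free leading gaps: path may start here
        // X/Y stay NEG on the borders
        continue;
      }

      if (i > 0 && j > 0) {
        double s = submat(a[i - 1] - 1, b[j - 1] - 1);
        double prior = (mode == 0) ? 0.0 : NEG;  // local: fresh start
        signed char t = 0;
        if (inband(i - 1, j - 1)) {
          size_t q = idx(i - 1, k);  // diagonal move keeps the band column
          if (M[q] > prior) { prior = M[q]; t = 1; }
          if (X[q] > prior) { prior = X[q]; t = 2; }
          if (Y[q] > prior) { prior = Y[q]; t = 3; }
        }
        if (prior > NEG / 2) { mM = prior + s; tM = t; }
      }
      if (i > 0 && inband(i - 1, j)) {
        size_t q = idx(i - 1, k + 1);
        double vo = (M[q] > NEG / 2) ? M[q] - gap_open - gap_ext : NEG;
        double ve = (X[q] > NEG / 2) ? X[q] - gap_ext : NEG;
        if (vo >= ve) { mX = vo; tX = 1; } else { mX = ve; tX = 2; }
      }
      if (j > 0 && inband(i, j - 1)) {
        size_t q = idx(i, k - 1);
        double vo = (M[q] > NEG / 2) ? M[q] - gap_open - gap_ext : NEG;
        double ve = (Y[q] > NEG / 2) ? Y[q] - gap_ext : NEG;
        if (vo >= ve) { mY = vo; tY = 1; } else { mY = ve; tY = 3; }
      }
      M[p] = mM; X[p] = mX; Y[p] = mY;
      tbM[p] = tM; tbX[p] = tX; tbY[p] = tY;

      bool eligible = (mode == 0) || (i == n || j == m);
      if (eligible && mM > best) { best = mM; bi = i; bj = j; }
    }
  }

  if (bi < 0 || best <= (mode == 0 ? 0.0 : NEG / 2)) {
    return List::create(_["score"] = 0.0, _["found"] = false);
  }

  // traceback (always ends in state M: an aligned pair)
  std::vector<int> ops;
  int i = bi, j = bj; char st = 'M';
  int matches = 0, mismatches = 0, gapopens = 0;
  while (true) {
    size_t p = idx(i, j - i - diag_lo);
    if (st == 'M') {
      if (mode == 1 && (i == 0 || j == 0)) break;  // free-gap start cell
      signed char t = tbM[p];
      ops.push_back(0);
      if (a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
      --i; --j;
      if (t == 0) break;  // fresh local start / overlap border start reached
      st = (t == 1) ? 'M' : (t == 2 ? 'X' : 'Y');
      if (st == 'M') continue;
      // fall through into gap states below on next iteration
    } else if (st == 'X') {
      signed char t = tbX[p];
      ops.push_back(1);
      --i;
      if (t == 1) { st = 'M'; ++gapopens; }
    } else {
      signed char t = tbY[p];
      ops.push_back(2);
      --j;
      if (t == 1) { st = 'M'; ++gapopens; }
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(
      _["score"] = best, _["found"] = true,
      _["a_start"] = i, _["a_end"] = bi,
      _["b_start"] = j, _["b_end"] = bj,
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["gapopens"] = gapopens, _["cols"] = (int)ops.size(),
      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
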