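#include <Rcpp.h>
using namespace Rcpp;

// Profile-profile global alignment, affine gaps (Gotoh 3-state DP).
//
// A, B: integer matrices (rows = sequences, cols = profile columns),
//   residue codes 0 = gap, 1..20 = amino acid, 21 = X (scores 0).
// S: 21x21 score table indexed by residue code (row/col 21 and gaps
//   contribute 0 by construction on the R side).
// Column-column score = sum over cross row pairs of S[a][b] divided by
//   nrow(A)*nrow(B) (gap/X entries contribute 0 to the numerator).
// Gap costs: first gap column costs `open`, each further column in the
//   same run costs `extend`; a gap column inserted into a profile is
//   scaled by that profile's occupancy weight (wA / wB).
// free_ends: terminal gap runs cost nothing.
//
// Returns the optimal score and the traceback path as moves
//   1 = align columns, 2 = consume A column (gap column added to B),
//   3 = consume B column (gap column added to A).
// Tie-breaking is fixed: align > consume-A > consume-B, both when
// choosing the final state and within each recurrence, so that forward
// and reversed runs explore opposite extremes of the co-optimal set.

static const double NEG_INF = -1e300;

// [[Rcpp::export]]
List gotoh_profile_align(IntegerMatrix A, IntegerMatrix B, NumericMatrix S,
                         double open, double extend, double wA, double wB,
                         bool free_ends) {
  const int nA = A.nrow(), LA = A.ncol();
  const int nB = B.nrow(), LB = B.ncol();

  // residue counts per column (codes 1..21)
  std::vector<double> CA(21 * LA, 0.0), CB(21 * LB, 0.0);
  for (int j = 0; j < LA; ++j)
    for (int i = 0; i < nA; ++i) {
      int c = A(i, j);
      if (c > 0) CA[(c - 1) + 21 * j] += 1.0;
    }
  for (int j = 0; j < LB; ++j)
    for (int i = 0; i < nB; ++i) {
      int c = B(i, j);
      if (c > 0) CB[(c - 1) + 21 * j] += 1.0;
    }

  // tmp = S * CB ; M(i,j) = CA_i . tmp_j / (nA*nB)
  std::vector<double> tmp(21 * LB, 0.0);
  for (int j = 0; j < LB; ++j)
    for (int a = 0; a < 21; ++a) {
      double cb = CB[a + 21 * j];
      if (cb == 0.0) continue;
      for (int b = 0; b < 21; ++b) tmp[b + 21 * j] += S(b, a) * cb;
    }
  const double denom = (double)nA * (double)nB;
  std::vector<double> M((LA + 1) * (LB + 1), 0.0);
  for (int i = 1; i <= LA; ++i)
    for (int j = 1; j <= LB; ++j) {
      double s = 0.0;
      for (int a = 0; a < 21; ++a) s += CA[a + 21 * (i - 1)] * tmp[a + 21 * (j - 1)];
      M[i * (LB + 1) + j] = s / denom;
    }

  // gap-in-B costs (consume A alone): scaled by wB; gap-in-A by wA
  const double openB = open * wB, extB = extend * wB;
  const double openA = open * wA, extA = extend * wA;

  const int W = LB + 1;
  std::vector<double> VM((LA + 1) * W, NEG_INF), VX((LA + 1) * W, NEG_INF),
      VY((LA + 1) * W, NEG_INF);
  // traceback: source state of each cell per state (0=M,1=X,2=Y, -1 none)
  std::vector<signed char> PM((LA + 1) * W, -1), PX((LA + 1) * W, -1),
      PY((LA + 1) * W, -1);

  VM[0] = 0.0;
  for (int i = 1; i <= LA; ++i) {  // leading gap run in B
    double op = free_ends ? 0.0 : openB, ex = free_ends ? 0.0 : extB;
    VX[i * W] = (i == 1) ? -op : VX[(i - 1) * W] - ex;
    PX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= LB; ++j) {  // leading gap run in A
    double op = free_ends ? 0.0 : openA, ex = free_ends ? 0.0 : extA;
    VY[j] = (j == 1) ? -op : VY[j - 1] - ex;
    PY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= LA; ++i) {
    for (int j = 1; j <= LB; ++j) {
      const int c = i * W + j, dg = (i - 1) * W + (j - 1), up = (i - 1) * W + j,
                lf = i * W + (j - 1);
      // M: align column i of A with column j of B
      {
        double best = VM[dg];
        signed char p = 0;
        if (VX[dg] > best) { best = VX[dg]; p = 1; }
        if (VY[dg] > best) { best = VY[dg]; p = 2; }
        VM[c] = best + M[c];
        PM[c] = p;
      }
      // X: consume A column i, gap column in B
      {
        bool term = free_ends && (j == LB);
        double op = term ? 0.0 : openB, ex = term ? 0.0 : extB;
        double best = VM[up] - op;
        signed char p = 0;
        if (VX[up] - ex > best) { best = VX[up] - ex; p = 1; }
        if (VY[up] - op > best) { best = VY[up] - op; p = 2; }
        VX[c] = best;
        PX[c] = p;
      }
      // Y: consume B column j, gap column in A
      {
        bool term = free_ends && (i == LA);
        double op = term ? 0.0 : openA, ex = term ? 0.0 : extA;
        double best = VM[lf] - op;
        signed char p = 0;
        if (VX[lf] - op > best) { best = VX[lf] - op; p = 1; }
        if (VY[lf] - ex > best) { best = VY[lf] - ex; p = 2; }
        VY[c] = best;
        PY[c] = p;
      }
    }
  }

  const int end = LA * W + LB;
  int state = 0;
  double score = VM[end];
  if (VX[end] > score) { score = VX[end]; state = 1; }
  if (VY[end] > score) { score = VY[end]; state = 2; }

  std::vector<int> path;
  path.reserve(LA + LB);
  int i = LA, j = LB;
  while (i > 0 || j > 0) {
    int c = i * W + j;
    if (state == 0) {
      path.push_back(1);
      state = PM[c];
      --i; --j;
    } else if (state == 1) {
      path.push_back(2);
      state = PX[c];
      --i;
    } else {
      path.push_back(3);
      state = PY[c];
      --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score, _["path"] = wrap(path));
}
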