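#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state recursion) over a
// precomputed column-score matrix M, where M(i, j) is the score of pairing
// position i of sequence/profile A with position j of B.  A gap of length L
// costs gap_open + L * gap_extend; terminal gaps are penalised like internal
// ones.  Ties are resolved deterministically: diagonal, then up (gap in B),
// then left (gap in A), both when choosing the state of a cell and when
// choosing a predecessor state.
//
// Returns the optimal score and the move sequence from (0,0) to (m,n):
// 1 = diagonal, 2 = up (consume A), 3 = left (consume B).
// [[Rcpp::export]]
List gotoh_align(NumericMatrix M, double gap_open, double gap_extend) {
  const int m = M.nrow(), n = M.ncol();
  if (m < 1 || n < 1) stop("gotoh_align requires non-empty inputs");
  const double NEG = -1e100;
  const double og = gap_open + gap_extend;  // cost of the first gap column
  const int W = n + 1;
  std::vector<double> D((m + 1) * W, NEG), P((m + 1) * W, NEG),
      Q((m + 1) * W, NEG);
  // back-pointers: predecessor state 0 = D, 1 = P, 2 = Q
  std::vector<unsigned char> bD((m + 1) * W), bP((m + 1) * W), bQ((m + 1) * W);

  D[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    P[i * W] = -gap_open - i * gap_extend;
    bP[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    Q[j] = -gap_open - j * gap_extend;
    bQ[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j, di = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      // D: (i-1, j-1) -> (i, j), pair A_i with B_j
      double best = D[di];
      unsigned char arg = 0;
      if (P[di] > best) { best = P[di]; arg = 1; }
      if (Q[di] > best) { best = Q[di]; arg = 2; }
      D[c] = best + M(i - 1, j - 1);
      bD[c] = arg;
      // P: gap in B, consume A_i
      best = D[up] - og; arg = 0;
      if (P[up] - gap_extend > best) { best = P[up] - gap_extend; arg = 1; }
      if (Q[up] - og > best) { best = Q[up] - og; arg = 2; }
      P[c] = best;
      bP[c] = arg;
      // Q: gap in A, consume B_j
      best = D[lf] - og; arg = 0;
      if (P[lf] - og > best) { best = P[lf] - og; arg = 1; }
      if (Q[lf] - gap_extend > best) { best = Q[lf] - gap_extend; arg = 2; }
      Q[c] = best;
      bQ[c] = arg;
    }
  }

  const int end = m * W + n;
  double score = D[end];
  int state = 0;
  if (P[end] > score) { score = P[end]; state = 1; }
  if (Q[end] > score) { score = Q[end]; state = 2; }

  std::vector<int> rev;
  rev.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      rev.push_back(1);
      state = bD[c];
      --i; --j;
    } else if (state == 1) {
      rev.push_back(2);
      state = bP[c];
      --i;
    } else {
      rev.push_back(3);
      state = bQ[c];
      --j;
    }
  }
  IntegerVector moves(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) moves[k] = rev[rev.size() - 1 - k];
  return List::create(_["score"] = score, _["moves"] = moves);
}

static double enum_rec(const NumericMatrix& M, int i, int j, int last,
                       double go, double ge) {
  const int m = M.nrow(), n = M.ncol();
  if (i == m && j == n) return 0.0;
  double best = -1e100;
  if (i < m && j < n) {
    double s = M(i, j) + enum_rec(M, i + 1, j + 1, 1, go, ge);
    if (s > best) best = s;
  }
  if (i < m) {
    double s = -((last == 2) ? ge : go + ge) + enum_rec(M, i + 1, j, 2, go, ge);
    if (s > best) best = s;
  }
  if (j < n) {
    double s = -((last == 3) ? ge : go + ge) + enum_rec(M, i, j + 1, 3, go, ge);
    if (s > best) best = s;
  }
  return best;
}

// Independent brute-force reference: enumerates every monotone alignment
// path (no dynamic programming, no shared state) and scores it under the
// same affine gap model.  Only feasible for short sequences.
// [[Rcpp::export]]
double enum_align_score(NumericMatrix M, double gap_open, double gap_extend) {
  if (M.nrow() < 1 && M.ncol() < 1) return 0.0;
  return enum_rec(M, 0, 0, 0, gap_open, gap_extend);
}

// Sum-of-pairs score of a gapped alignment.  rows: integer matrix, one row
// per sequence, residues encoded 1..K into the score matrix S, 0 = gap.
// For each unordered row pair, columns where both rows are gaps are ignored;
// residue-residue columns add S; maximal gap runs (against a residue) cost
// gap_open + len * gap_extend.  weights: one multiplier per row, pair terms
// scaled by w_i * w_j.
// [[Rcpp::export]]
double sp_score_encoded(IntegerMatrix rows, NumericMatrix S, double gap_open,
                        double gap_extend, NumericVector weights) {
  const int k = rows.nrow(), L = rows.ncol();
  double total = 0.0;
  for (int a = 0; a < k; ++a) {
    for (int b = a + 1; b < k; ++b) {
      double s = 0.0;
      bool in_gap_a = false, in_gap_b = false;  // gap run open in row a / b
      for (int c = 0; c < L; ++c) {
        const int ra = rows(a, c), rb = rows(b, c);
        if (ra == 0 && rb == 0) continue;  // gap-gap column: ignored
        if (ra > 0 && rb > 0) {
          s += S(ra - 1, rb - 1);
          in_gap_a = in_gap_b = false;
        } else if (ra == 0) {
          s -= in_gap_a ? gap_extend : gap_open + gap_extend;
          in_gap_a = true;
          in_gap_b = false;
        } else {
          s -= in_gap_b ? gap_extend : gap_open + gap_extend;
          in_gap_b = true;
          in_gap_a = false;
        }
      }
      total += weights[a] * weights[b] * s;
    }
  }
  return total;
}
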