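#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps on a precomputed
// column-score matrix CS (rows = positions of the first profile, columns =
// positions of the second). Gap cost convention: a run of k gapped columns
// costs open + (k-1) * extend; terminal gaps are penalized like internal
// ones. Tie-breaking during traceback prefers the diagonal move, then a gap
// in the first input, then a gap in the second.
//
// Moves in the returned path: 0 = consume both, 1 = consume first only
// (gap in second), 2 = consume second only (gap in first).

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".gotoh_core")]]
List gotoh_core(NumericMatrix CS, double open, double ext) {
  const int n = CS.nrow(), m = CS.ncol();
  // state 0 = M, 1 = Ix (consume i, gap in second), 2 = Iy (consume j)
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  IntegerMatrix pM(n + 1, m + 1), pIx(n + 1, m + 1), pIy(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i,j) = Ix(i,j) = Iy(i,j) = NEG_INF; }
  M(0,0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix(i,0) = -open - (i - 1) * ext;
    pIx(i,0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy(0,j) = -open - (j - 1) * ext;
    pIy(0,j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal from best predecessor (prefer M, then Iy, then Ix)
      double best = M(i-1,j-1); int src = 0;
      if (Iy(i-1,j-1) > best) { best = Iy(i-1,j-1); src = 2; }
      if (Ix(i-1,j-1) > best) { best = Ix(i-1,j-1); src = 1; }
      M(i,j) = best + CS(i-1,j-1);
      pM(i,j) = src;
      // Ix: gap in second input (consume i)
      double a = M(i-1,j) - open, b = Ix(i-1,j) - ext, c = Iy(i-1,j) - open;
      best = a; src = 0;
      if (c > best) { best = c; src = 2; }
      if (b > best) { best = b; src = 1; }
      Ix(i,j) = best; pIx(i,j) = src;
      // Iy: gap in first input (consume j)
      a = M(i,j-1) - open; b = Iy(i,j-1) - ext; c = Ix(i,j-1) - open;
      best = a; src = 0;
      if (c > best) { best = c; src = 1; }
      if (b > best) { best = b; src = 2; }
      Iy(i,j) = best; pIy(i,j) = src;
    }
  }
  // final state: prefer M, then Iy (gap in first), then Ix
  int state = 0; double score = M(n,m);
  if (Iy(n,m) > score) { score = Iy(n,m); state = 2; }
  if (Ix(n,m) > score) { score = Ix(n,m); state = 1; }
  // traceback
  std::vector<int> path;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      path.push_back(0);
      int src = pM(i,j); --i; --j; state = src;
    } else if (state == 1) {
      path.push_back(1);
      int src = pIx(i,j); --i; state = src;
    } else {
      path.push_back(2);
      int src = pIy(i,j); --j; state = src;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}

// Pairwise p-distance on an integer-coded alignment matrix (rows = taxa).
// Codes <= 0 denote gaps/unknowns; pairwise deletion. Pairs with zero
// comparable columns get distance 1.
// [[Rcpp::export(name = ".pdist_core")]]
NumericMatrix pdist_core(IntegerMatrix x) {
  const int n = x.nrow(), L = x.ncol();
  NumericMatrix d(n, n);
  int zero_pairs = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int comp = 0, mism = 0;
      for (int k = 0; k < L; ++k) {
        int a = x(i,k), b = x(j,k);
        if (a > 0 && b > 0) { ++comp; if (a != b) ++mism; }
      }
      double v = comp ? (double)mism / comp : 1.0;
      if (!comp) ++zero_pairs;
      d(i,j) = d(j,i) = v;
    }
  }
  d.attr("zero_comparable_pairs") = zero_pairs;
  return d;
}
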