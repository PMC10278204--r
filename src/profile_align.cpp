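#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment path between two profiles.
// `sim` holds the pre-computed profile-column similarity: sim(i, j) is the
// score for aligning column i+1 of profile A against column j+1 of profile B.
// Gap penalties are positive numbers that get subtracted; terminal gaps are
// penalized like internal ones so the recursion stays uniform.
//
// Returns an integer vector of moves read 5'->3': 1 = match (consume A and
// B), 2 = consume A only (gap in B), 3 = consume B only (gap in A).
// Tie-break order: match, then gap-in-B, then gap-in-A (deterministic).
// [[Rcpp::export(name = ".gotoh_profile_path")]]
IntegerVector gotoh_profile_path(NumericMatrix sim, double gap_open,
                                 double gap_extend) {
  const int n = sim.nrow(), m = sim.ncol();
  const double NEG = -1e30;

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: which of {M=0, X=1, Y=2} fed each cell of each layer
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG;
    Y(i, 0) = NEG;
    X(i, 0) = -gap_open - (i - 1) * gap_extend;
    tX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG;
    X(0, j) = NEG;
    Y(0, j) = -gap_open - (j - 1) * gap_extend;
    tY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // match layer
      double bm = M(i - 1, j - 1);
      int sm = 0;
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); sm = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); sm = 2; }
      M(i, j) = bm + sim(i - 1, j - 1);
      tM(i, j) = sm;
      // gap in B (consume A)
      double ox = M(i - 1, j) - gap_open;
      double ex = X(i - 1, j) - gap_extend;
      if (ox >= ex) { X(i, j) = ox; tX(i, j) = 0; }
      else          { X(i, j) = ex; tX(i, j) = 1; }
      // gap in A (consume B)
      double oy = M(i, j - 1) - gap_open;
      double ey = Y(i, j - 1) - gap_extend;
      if (oy >= ey) { Y(i, j) = oy; tY(i, j) = 0; }
      else          { Y(i, j) = ey; tY(i, j) = 2; }
    }
  }

  int state = 0;
  double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }

  std::vector<int> moves;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tM(i, j);
      moves.push_back(1);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = tX(i, j);
      moves.push_back(2);
      --i;
      state = prev;
    } else {
      int prev = tY(i, j);
      moves.push_back(3);
      --j;
      state = prev;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return wrap(moves);
}
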