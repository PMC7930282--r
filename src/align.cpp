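#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap pairwise alignment.
//
// Sequences arrive as 0-based integer vectors indexing into `sub`, an
// S x S substitution matrix. A gap of length k costs open + (k-1) * ext.
// type: 0 = local (Smith-Waterman), 1 = global (Needleman-Wunsch).
// Ties are broken toward the diagonal (match state), then up (gap in b),
// then left, which makes the reported alignment deterministic.
//
// Returns the optimal score plus one optimal alignment as an operation
// string over {M, D, I}: M consumes one residue of each sequence, D
// consumes a only (gap in b), I consumes b only (gap in a). Start/end
// coordinates are 1-based inclusive positions of the aligned region
// (0 / -1 for an empty local alignment).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List align_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                      double open, double ext, int type) {
  const int n = a.size(), m = b.size();
  const bool local = (type == 0);

  if (n == 0 || m == 0) {
    if (local || (n == 0 && m == 0)) {
      return List::create(_["score"] = 0.0, _["ops"] = "",
                          _["a_start"] = 0, _["a_end"] = -1,
                          _["b_start"] = 0, _["b_end"] = -1);
    }
    const int k = std::max(n, m);
    const double sc = -(open + (k - 1) * ext);
    std::string ops(k, n > 0 ? 'D' : 'I');
    return List::create(_["score"] = sc, _["ops"] = ops,
                        _["a_start"] = n > 0 ? 1 : 0, _["a_end"] = n,
                        _["b_start"] = m > 0 ? 1 : 0, _["b_end"] = m);
  }

  // States: H ends in a match/mismatch, X ends in a gap in b (consumes a,
  // "up"), Y ends in a gap in a (consumes b, "left").
  const size_t sz = (size_t)(n + 1) * (m + 1);
  const int w = m + 1;
  std::vector<double> H(sz, NEG_INF), X(sz, NEG_INF), Y(sz, NEG_INF);
  // tH: predecessor state at (i-1, j-1): 0=H, 1=X, 2=Y, 3=fresh local start
  // tX: 0 = opened from H above, 1 = extended X above, 2 = opened from Y above
  // tY: 0 = opened from H left, 1 = extended Y left, 2 = opened from X left
  std::vector<signed char> tH(sz, -1), tX(sz, -1), tY(sz, -1);

  H[0] = 0.0;
  if (local) {
    for (int i = 1; i <= n; ++i) H[(size_t)i * w] = 0.0;
    for (int j = 1; j <= m; ++j) H[j] = 0.0;
  } else {
    for (int i = 1; i <= n; ++i) {
      X[(size_t)i * w] = -(open + (i - 1) * ext);
      tX[(size_t)i * w] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Y[j] = -(open + (j - 1) * ext);
      tY[j] = (j == 1) ? 0 : 1;
    }
  }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1];
    const size_t row = (size_t)i * w, prow = row - w;
    for (int j = 1; j <= m; ++j) {
      const size_t c = row + j, up = prow + j, left = c - 1, diag = prow + j - 1;

      { // X
        double v = (H[up] == NEG_INF) ? NEG_INF : H[up] - open;
        signed char t = 0;
        double ve = (X[up] == NEG_INF) ? NEG_INF : X[up] - ext;
        if (ve > v) { v = ve; t = 1; }
        double vy = (Y[up] == NEG_INF) ? NEG_INF : Y[up] - open;
        if (vy > v) { v = vy; t = 2; }
        X[c] = v; tX[c] = t;
      }
      { // Y
        double v = (H[left] == NEG_INF) ? NEG_INF : H[left] - open;
        signed char t = 0;
        double ve = (Y[left] == NEG_INF) ? NEG_INF : Y[left] - ext;
        if (ve > v) { v = ve; t = 1; }
        double vx = (X[left] == NEG_INF) ? NEG_INF : X[left] - open;
        if (vx > v) { v = vx; t = 2; }
        Y[c] = v; tY[c] = t;
      }
      { // H
        double v = H[diag]; signed char t = 0;
        if (X[diag] > v) { v = X[diag]; t = 1; }
        if (Y[diag] > v) { v = Y[diag]; t = 2; }
        double hv = (v == NEG_INF) ? NEG_INF : v + sub(ai, b[j - 1]);
        if (local && hv < 0) { hv = 0.0; t = 3; }
        H[c] = hv; tH[c] = t;
        if (local && hv > best) { best = hv; bi = i; bj = j; }
      }
    }
  }

  int st = 0;
  if (!local) {
    const size_t c = (size_t)n * w + m;
    best = H[c]; st = 0;
    if (X[c] > best) { best = X[c]; st = 1; }
    if (Y[c] > best) { best = Y[c]; st = 2; }
    bi = n; bj = m;
  } else if (best <= 0) {
    return List::create(_["score"] = 0.0, _["ops"] = "",
                        _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1);
  }

  std::string ops;
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * w + j;
    if (st == 0) {
      if (local && H[c] <= 0) break; // local alignment starts here
      if (i == 0 || j == 0) break;   // global (0,0) or local boundary
      const signed char t = tH[c];
      if (local && t == 3) break;    // defensive: clamped cell has H == 0
      ops.push_back('M');
      --i; --j;
      st = t;
    } else if (st == 1) {
      const signed char t = tX[c];
      ops.push_back('D');
      --i;
      st = (t == 0) ? 0 : (t == 1 ? 1 : 2);
    } else {
      const signed char t = tY[c];
      ops.push_back('I');
      --j;
      st = (t == 0) ? 0 : (t == 1 ? 2 : 1);
    }
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(_["score"] = best, _["ops"] = ops,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj);
}
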