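#include <Rcpp.h>
using namespace Rcpp;

// Gotoh global alignment with affine gap penalty: a gap of length k costs
// gap_open + k * gap_extend.  End gaps are penalized (true global mode).
//
// The DP runs over a precomputed cell-score matrix C where C(i, j) is the
// score of aligning unit i of sequence/profile A against unit j of B.  This
// lets the same kernel serve residue-vs-residue and profile-vs-profile
// alignment: the caller supplies C = S[a, b] or C = t(Fa) %*% S %*% Fb.
//
// Traceback is deterministic with preference diagonal > up (gap in B) > left
// (gap in A), applied both when selecting the final state and when selecting
// each predecessor state.

static const double NEG_INF = -1e300;

// state codes used in the pointer matrices
enum { FROM_M = 0, FROM_X = 1, FROM_Y = 2, FROM_NONE = 3 };

// [[Rcpp::export]]
List nw_affine_mat_cpp(NumericMatrix C, double gap_open, double gap_extend) {
  const int n = C.nrow(), m = C.ncol();
  if (n < 1 || m < 1) stop("both inputs must be non-empty");
  const double open1 = gap_open + gap_extend; // cost of a gap of length 1

  // three layers: M (diagonal), X (gap in B, consumes A: "up"),
  // Y (gap in A, consumes B: "left")
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> pM((n + 1) * (m + 1), FROM_NONE);
  std::vector<unsigned char> pX((n + 1) * (m + 1), FROM_NONE);
  std::vector<unsigned char> pY((n + 1) * (m + 1), FROM_NONE);
  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IDX(i, 0)] = -(gap_open + i * gap_extend);
    pX[IDX(i, 0)] = (i == 1) ? FROM_M : FROM_X;
  }
  for (int j = 1; j <= m; ++j) {
    Y[IDX(0, j)] = -(gap_open + j * gap_extend);
    pY[IDX(0, j)] = (j == 1) ? FROM_M : FROM_Y;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume one unit of each
      {
        double vm = M[IDX(i - 1, j - 1)], vx = X[IDX(i - 1, j - 1)],
               vy = Y[IDX(i - 1, j - 1)];
        double best = vm; unsigned char who = FROM_M;
        if (vx > best) { best = vx; who = FROM_X; }
        if (vy > best) { best = vy; who = FROM_Y; }
        M[IDX(i, j)] = best + C(i - 1, j - 1);
        pM[IDX(i, j)] = who;
      }
      // X: gap in B (move up); open from M/Y or extend X
      {
        double vm = M[IDX(i - 1, j)] - open1;
        double vx = X[IDX(i - 1, j)] - gap_extend;
        double vy = Y[IDX(i - 1, j)] - open1;
        double best = vm; unsigned char who = FROM_M;
        if (vx > best) { best = vx; who = FROM_X; }
        if (vy > best) { best = vy; who = FROM_Y; }
        X[IDX(i, j)] = best;
        pX[IDX(i, j)] = who;
      }
      // Y: gap in A (move left)
      {
        double vm = M[IDX(i, j - 1)] - open1;
        double vx = X[IDX(i, j - 1)] - open1;
        double vy = Y[IDX(i, j - 1)] - gap_extend;
        double best = vm; unsigned char who = FROM_M;
        if (vx > best) { best = vx; who = FROM_X; }
        if (vy > best) { best = vy; who = FROM_Y; }
        Y[IDX(i, j)] = best;
        pY[IDX(i, j)] = who;
      }
    }
  }

  double score = M[IDX(n, m)]; int state = FROM_M;
  if (X[IDX(n, m)] > score) { score = X[IDX(n, m)]; state = FROM_X; }
  if (Y[IDX(n, m)] > score) { score = Y[IDX(n, m)]; state = FROM_Y; }

  // traceback; ai/bi hold 1-based unit indices, 0 marks a gap
  std::vector<int> ai, bi;
  ai.reserve(n + m); bi.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char prev;
    if (state == FROM_M) {
      prev = pM[IDX(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j;
    } else if (state == FROM_X) {
      prev = pX[IDX(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i;
    } else {
      prev = pY[IDX(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j;
    }
    state = prev;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

#undef IDX
  return List::create(_["score"] = score,
                      _["ai"] = IntegerVector(ai.begin(), ai.end()),
                      _["bi"] = IntegerVector(bi.begin(), bi.end()));
}
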