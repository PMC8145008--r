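#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Gotoh global alignment with affine gaps. A gap of length L costs
// gap_open + L * gap_extend (both positive costs, subtracted from the
// score). Substitution scores come from a square matrix indexed by the
// alphabet in `alphabet`. Traceback is deterministic: at every cell the
// states are preferred in the order M (diagonal) > X (gap in b) > Y
// (gap in a), and within a state the source states in that same order.

// [[Rcpp::export]]
List gotoh_align_cpp(std::string a, std::string b,
                     NumericMatrix submat, std::string alphabet,
                     double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();

  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char)alphabet[i]] = (int)i;
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = idx[(unsigned char)a[i]];
    if (ai[i] < 0) stop("illegal character '%s' in first sequence",
                        std::string(1, a[i]).c_str());
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = idx[(unsigned char)b[j]];
    if (bi[j] < 0) stop("illegal character '%s' in second sequence",
                        std::string(1, b[j]).c_str());
  }

  // state matrices: M = match/mismatch end, X = gap in b (consumes a),
  // Y = gap in a (consumes b)
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG));
  // traceback: source state 0=M,1=X,2=Y; -1 = none
  std::vector<std::vector<signed char>> tM(n + 1, std::vector<signed char>(m + 1, -1));
  std::vector<std::vector<signed char>> tX(n + 1, std::vector<signed char>(m + 1, -1));
  std::vector<std::vector<signed char>> tY(n + 1, std::vector<signed char>(m + 1, -1));

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i][0] = -(gap_open + i * gap_extend);
    tX[i][0] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[0][j] = -(gap_open + j * gap_extend);
    tY[0][j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = submat(ai[i - 1], bi[j - 1]);
      // M: preference M > X > Y on ties
      double best = M[i - 1][j - 1]; signed char src = 0;
      if (X[i - 1][j - 1] > best) { best = X[i - 1][j - 1]; src = 1; }
      if (Y[i - 1][j - 1] > best) { best = Y[i - 1][j - 1]; src = 2; }
      if (best > NEG) { M[i][j] = best + s; tM[i][j] = src; }
      // X: gap in b, consume a[i-1]
      double open = M[i - 1][j] - (gap_open + gap_extend);
      double ext  = X[i - 1][j] - gap_extend;
      double openY = Y[i - 1][j] - (gap_open + gap_extend);
      best = open; src = 0;
      if (ext > best) { best = ext; src = 1; }
      if (openY > best) { best = openY; src = 2; }
      if (best > NEG) { X[i][j] = best; tX[i][j] = src; }
      // Y: gap in a, consume b[j-1]
      open = M[i][j - 1] - (gap_open + gap_extend);
      double extY = Y[i][j - 1] - gap_extend;
      double openX = X[i][j - 1] - (gap_open + gap_extend);
      best = open; src = 0;
      if (openX > best) { best = openX; src = 1; }
      if (extY > best) { best = extY; src = 2; }
      if (best > NEG) { Y[i][j] = best; tY[i][j] = src; }
    }
  }

  double score = M[n][m]; int state = 0;
  if (X[n][m] > score) { score = X[n][m]; state = 1; }
  if (Y[n][m] > score) { score = Y[n][m]; state = 2; }

  std::string ga, gb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char src = tM[i][j];
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j; state = src;
    } else if (state == 1) {
      signed char src = tX[i][j];
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i; state = src;
    } else {
      signed char src = tY[i][j];
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j; state = src;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["score"] = score,
                      _["aligned_a"] = ga,
                      _["aligned_b"] = gb);
}
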