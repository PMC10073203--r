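#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment of two alignment profiles (Gotoh).
//
// prof1, prof2: K x L count matrices (rows = symbols, last row may be the
// gap symbol; its substitution scores encode how residues score against
// existing gaps). Column-column score is the average pairwise substitution
// score: (c1^T S c2) / (n1 * n2) where n1, n2 are the sequence counts.
// A new gap run of length g costs gap_open + (g - 1) * gap_ext.
//
// Returns list(score, path1, path2): path vectors of 1-based column indices
// with 0 marking a gap column, equal length.
// [[Rcpp::export]]
List align_profiles_cpp(NumericMatrix prof1, NumericMatrix prof2,
                        NumericMatrix submat, double gap_open,
                        double gap_ext, double n1, double n2) {
  const int K = prof1.nrow();
  const int L1 = prof1.ncol();
  const int L2 = prof2.ncol();
  const double NEG = -1e30;

  // precompute column-column scores
  NumericMatrix S(L1, L2);
  for (int i = 0; i < L1; ++i) {
    std::vector<double> w(K);
    for (int a = 0; a < K; ++a) {
      double acc = 0.0;
      for (int b = 0; b < K; ++b) acc += submat(a, b) * prof1(b, i);
      w[a] = acc;
    }
    for (int j = 0; j < L2; ++j) {
      double acc = 0.0;
      for (int b = 0; b < K; ++b) acc += w[b] * prof2(b, j);
      S(i, j) = acc / (n1 * n2);
    }
  }

  NumericMatrix M(L1 + 1, L2 + 1), X(L1 + 1, L2 + 1), Y(L1 + 1, L2 + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= L1; ++i) {
    M(i, 0) = NEG;
    X(i, 0) = gap_open + (i - 1) * gap_ext;
    Y(i, 0) = NEG;
  }
  for (int j = 1; j <= L2; ++j) {
    M(0, j) = NEG;
    X(0, j) = NEG;
    Y(0, j) = gap_open + (j - 1) * gap_ext;
  }
  for (int i = 1; i <= L1; ++i) {
    for (int j = 1; j <= L2; ++j) {
      double best = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > best) best = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > best) best = Y(i - 1, j - 1);
      M(i, j) = best + S(i - 1, j - 1);

      double xo = std::max(M(i - 1, j), Y(i - 1, j)) + gap_open;
      double xe = X(i - 1, j) + gap_ext;
      X(i, j) = xo > xe ? xo : xe;

      double yo = std::max(M(i, j - 1), X(i, j - 1)) + gap_open;
      double ye = Y(i, j - 1) + gap_ext;
      Y(i, j) = yo > ye ? yo : ye;
    }
  }

  // traceback with fixed tie preference: M > X > Y
  std::vector<int> p1, p2;
  int i = L1, j = L2;
  int state; // 0 = M, 1 = X, 2 = Y
  {
    double m = M(i, j), x = X(i, j), y = Y(i, j);
    state = (m >= x && m >= y) ? 0 : (x >= y ? 1 : 2);
  }
  double score = state == 0 ? M(i, j) : (state == 1 ? X(i, j) : Y(i, j));
  while (i > 0 || j > 0) {
    if (state == 0) {
      p1.push_back(i); p2.push_back(j);
      double prev = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      p1.push_back(i); p2.push_back(0);
      double cur = X(i, j);
      --i;
      if (std::abs(X(i, j) + gap_ext - cur) < 1e-9 && (i > 0)) state = 1;
      else if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(Y(i, j) + gap_open - cur) < 1e-9) state = 2;
      else state = 1;
      if (i == 0 && j == 0) break;
    } else {
      p1.push_back(0); p2.push_back(j);
      double cur = Y(i, j);
      --j;
      if (std::abs(Y(i, j) + gap_ext - cur) < 1e-9 && (j > 0)) state = 2;
      else if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(X(i, j) + gap_open - cur) < 1e-9) state = 1;
      else state = 2;
      if (i == 0 && j == 0) break;
    }
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());
  return List::create(_["score"] = score,
                      _["path1"] = IntegerVector(p1.begin(), p1.end()),
                      _["path2"] = IntegerVector(p2.begin(), p2.end()));
}
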