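#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global affine-gap alignment of two profiles (Needleman-Wunsch-Gotoh).
//
// A profile is a set of equal-length gapped rows. Column-vs-column score is
// the sum over all residue pairs of the substitution score (gap characters
// contribute nothing). A gap run of length k costs open + k * extend at the
// single-sequence level; for profiles the penalty is scaled by the product
// of the row counts so it stays commensurate with the sum-of-pairs column
// scores. Ties are broken deterministically in the order
// match > delete (gap in B) > insert (gap in A).

static inline int code_of(char c, const std::string &alpha) {
  if (c == '-') return -1;
  size_t p = alpha.find(c);
  if (p == std::string::npos) {
    // unknown residue: treat as X when present in the alphabet, else gap
    p = alpha.find('X');
    if (p == std::string::npos) return -1;
  }
  return (int)p;
}

// column counts: L x K matrix of symbol counts per column
static std::vector<std::vector<double> > column_counts(
    const std::vector<std::string> &rows, int K, const std::string &alpha) {
  size_t L = rows.empty() ? 0 : rows[0].size();
  std::vector<std::vector<double> > cnt(L, std::vector<double>(K, 0.0));
  for (size_t r = 0; r < rows.size(); ++r) {
    for (size_t j = 0; j < L; ++j) {
      int c = code_of(rows[r][j], alpha);
      if (c >= 0) cnt[j][c] += 1.0;
    }
  }
  return cnt;
}

// [[Rcpp::export(name = ".align_profiles_cpp")]]
List align_profiles_cpp(CharacterVector rows_a, CharacterVector rows_b,
                        NumericMatrix scores, std::string alphabet,
                        double gap_open, double gap_extend) {
  std::vector<std::string> A, B;
  for (R_xlen_t i = 0; i < rows_a.size(); ++i) A.push_back(as<std::string>(rows_a[i]));
  for (R_xlen_t i = 0; i < rows_b.size(); ++i) B.push_back(as<std::string>(rows_b[i]));
  const int K = scores.nrow();
  const int La = A.empty() ? 0 : (int)A[0].size();
  const int Lb = B.empty() ? 0 : (int)B[0].size();
  if (La == 0 || Lb == 0) stop("empty profile");

  std::vector<std::vector<double> > ca = column_counts(A, K, alphabet);
  std::vector<std::vector<double> > cb = column_counts(B, K, alphabet);

  // sb[j] = scores %*% cb[j]
  std::vector<std::vector<double> > sb(Lb, std::vector<double>(K, 0.0));
  for (int j = 0; j < Lb; ++j)
    for (int a = 0; a < K; ++a) {
      double acc = 0.0;
      for (int b = 0; b < K; ++b) acc += scores(a, b) * cb[j][b];
      sb[j][a] = acc;
    }

  const double scale = (double)A.size() * (double)B.size();
  const double OPEN = gap_open * scale, EXT = gap_extend * scale;
  const double NEG = -std::numeric_limits<double>::infinity();

  // DP matrices, (La+1) x (Lb+1)
  const int W = Lb + 1;
  std::vector<double> M((La + 1) * W, NEG), X((La + 1) * W, NEG), Y((La + 1) * W, NEG);
  // traceback: which predecessor state fed each cell (0=M,1=X,2=Y)
  std::vector<unsigned char> tM((La + 1) * W, 0), tX((La + 1) * W, 0), tY((La + 1) * W, 0);

  M[0] = 0.0;
  for (int i = 1; i <= La; ++i) {
    X[i * W] = -(OPEN + i * EXT);
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= Lb; ++j) {
    Y[j] = -(OPEN + j * EXT);
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      const int ij = i * W + j, d = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      double s = 0.0;
      const std::vector<double> &fa = ca[i - 1];
      const std::vector<double> &sj = sb[j - 1];
      for (int a = 0; a < K; ++a) if (fa[a] != 0.0) s += fa[a] * sj[a];
      // match state; prefer M, then X, then Y on ties
      double best = M[d]; unsigned char who = 0;
      if (X[d] > best) { best = X[d]; who = 1; }
      if (Y[d] > best) { best = Y[d]; who = 2; }
      M[ij] = best + s; tM[ij] = who;
      // delete: consume column of A, gap in B
      best = M[up] - OPEN - EXT; who = 0;
      if (X[up] - EXT > best) { best = X[up] - EXT; who = 1; }
      if (Y[up] - OPEN - EXT > best) { best = Y[up] - OPEN - EXT; who = 2; }
      X[ij] = best; tX[ij] = who;
      // insert: consume column of B, gap in A
      best = M[lf] - OPEN - EXT; who = 0;
      if (X[lf] - OPEN - EXT > best) { best = X[lf] - OPEN - EXT; who = 1; }
      if (Y[lf] - EXT > best) { best = Y[lf] - EXT; who = 2; }
      Y[ij] = best; tY[ij] = who;
    }
  }

  const int end = La * W + Lb;
  double score = M[end]; unsigned char state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  // traceback
  std::string ops;
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back('M');
      unsigned char prev = tM[i * W + j];
      --i; --j; state = prev;
    } else if (state == 1) {
      ops.push_back('X');
      unsigned char prev = tX[i * W + j];
      --i; state = prev;
    } else {
      ops.push_back('Y');
      unsigned char prev = tY[i * W + j];
      --j; state = prev;
    }
  }
  std::reverse(ops.begin(), ops.end());

  const size_t Lm = ops.size();
  CharacterVector outA(rows_a.size()), outB(rows_b.size());
  for (size_t r = 0; r < A.size(); ++r) {
    std::string s; s.reserve(Lm);
    size_t p = 0;
    for (size_t k = 0; k < Lm; ++k)
      s.push_back((ops[k] == 'Y') ? '-' : A[r][p++]);
    outA[r] = s;
  }
  for (size_t r = 0; r < B.size(); ++r) {
    std::string s; s.reserve(Lm);
    size_t p = 0;
    for (size_t k = 0; k < Lm; ++k)
      s.push_back((ops[k] == 'X') ? '-' : B[r][p++]);
    outB[r] = s;
  }
  return List::create(_["rows_a"] = outA, _["rows_b"] = outB,
                      _["score"] = score, _["ops"] = ops);
}
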