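#include <Rcpp.h>
using namespace Rcpp;

// Optimal-matching (edit) distance between two integer-coded state
// sequences. Dynamic programme over the (|x|+1) x (|y|+1) grid:
//   D[i][j] = min(D[i-1][j] + indel, D[i][j-1] + indel,
//                 D[i-1][j-1] + sub(x_i, y_j)),  sub = 0 on equal states.
// States are 1-based codes indexing the substitution matrix.

static double om_core(const int* x, int nx, const int* y, int ny,
                      double indel, const double* sub, int ns) {
  std::vector<double> prev(ny + 1), cur(ny + 1);
  for (int j = 0; j <= ny; ++j) prev[j] = j * indel;
  for (int i = 1; i <= nx; ++i) {
    cur[0] = i * indel;
    const int xi = x[i - 1] - 1;
    for (int j = 1; j <= ny; ++j) {
      const int yj = y[j - 1] - 1;
      double s = prev[j - 1] + sub[xi + ns * yj];
      double d = prev[j] + indel;
      if (d < s) s = d;
      d = cur[j - 1] + indel;
      if (d < s) s = d;
      cur[j] = s;
    }
    std::swap(prev, cur);
  }
  return prev[ny];
}

static int lcs_core(const int* x, int nx, const int* y, int ny) {
  std::vector<int> prev(ny + 1, 0), cur(ny + 1, 0);
  for (int i = 1; i <= nx; ++i) {
    for (int j = 1; j <= ny; ++j) {
      if (x[i - 1] == y[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), 0);
  }
  return prev[ny];
}

// [[Rcpp::export]]
double cpp_om_distance(IntegerVector x, IntegerVector y, double indel,
                       NumericMatrix sub) {
  return om_core(INTEGER(x), x.size(), INTEGER(y), y.size(), indel,
                 REAL(sub), sub.nrow());
}

// [[Rcpp::export]]
int cpp_lcs_length(IntegerVector x, IntegerVector y) {
  return lcs_core(INTEGER(x), x.size(), INTEGER(y), y.size());
}

// Pairwise OM distances for n equal-length sequences stored as the rows of
// an integer matrix; only the upper triangle is computed and mirrored.
// [[Rcpp::export]]
NumericMatrix cpp_om_matrix(IntegerMatrix seqs, double indel,
                            NumericMatrix sub) {
  const int n = seqs.nrow(), L = seqs.ncol(), ns = sub.nrow();
  // row-major copies so each sequence is contiguous
  std::vector<std::vector<int>> rows(n, std::vector<int>(L));
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < L; ++t) rows[i][t] = seqs(i, t);
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = om_core(rows[i].data(), L, rows[j].data(), L, indel,
                         REAL(sub), ns);
      D(i, j) = d;
      D(j, i) = d;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}
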