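#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Contexts are passed as an n x W integer matrix: rows are flanking
// strings, columns run left-to-right along the flank, values 1..20 are
// residue codes (AA_ALPHABET order) and 0 is the unknown symbol, which
// occupies its slot but is never counted.

static double column_entropy(const std::vector<int> &counts, int col,
                             const NumericMatrix &Q) {
  int nA = 20;
  long tot = 0;
  for (int a = 0; a < nA; ++a) tot += counts[col * nA + a];
  if (tot == 0)
    stop("all residue counts are zero at a shuffled/resampled offset");
  double total = 0.0;
  for (int a = 0; a < nA; ++a) {
    int c = counts[col * nA + a];
    if (c == 0) continue;
    double p = (double)c / (double)tot;
    double q = Q(a, col);
    if (q <= 0.0)
      stop("observed frequency positive where background is zero; "
           "use a pseudocount background");
    total += p * std::log2(p / q);
  }
  return total;
}

// Per-offset relative-entropy totals for `repeats` independent shuffles
// of the context matrix.  per_string = true permutes each row
// independently (default null); otherwise one random permutation of the
// W positions is applied to every row of a repeat.
// [[Rcpp::export]]
NumericVector cpp_shuffle_pool(IntegerMatrix M, NumericMatrix Q,
                               int repeats, bool per_string) {
  int n = M.nrow(), W = M.ncol(), nA = 20;
  if (Q.nrow() != nA || Q.ncol() != W)
    stop("background matrix must be 20 x window");
  if (n == 0) stop("empty context store");
  NumericVector pool(repeats * W);
  std::vector<int> counts(nA * W);
  std::vector<int> row(W), perm(W);
  for (int r = 0; r < repeats; ++r) {
    std::fill(counts.begin(), counts.end(), 0);
    if (per_string) {
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < W; ++j) row[j] = M(i, j);
        for (int k = W - 1; k > 0; --k) {
          int j = (int)(unif_rand() * (k + 1));
          if (j > k) j = k;
          std::swap(row[k], row[j]);
        }
        for (int j = 0; j < W; ++j)
          if (row[j] > 0) ++counts[j * nA + row[j] - 1];
      }
    } else {
      for (int j = 0; j < W; ++j) perm[j] = j;
      for (int k = W - 1; k > 0; --k) {
        int j = (int)(unif_rand() * (k + 1));
        if (j > k) j = k;
        std::swap(perm[k], perm[j]);
      }
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < W; ++j) {
          int v = M(i, perm[j]);
          if (v > 0) ++counts[j * nA + v - 1];
        }
    }
    for (int j = 0; j < W; ++j)
      pool[r * W + j] = column_entropy(counts, j, Q);
  }
  return pool;
}

// Per-offset totals for n_boot bootstrap resamples (rows drawn with
// replacement at the original n).  Returns an n_boot x W matrix.
// [[Rcpp::export]]
NumericMatrix cpp_bootstrap_totals(IntegerMatrix M, NumericMatrix Q,
                                   int n_boot) {
  int n = M.nrow(), W = M.ncol(), nA = 20;
  if (Q.nrow() != nA || Q.ncol() != W)
    stop("background matrix must be 20 x window");
  if (n == 0) stop("empty context store");
  NumericMatrix out(n_boot, W);
  std::vector<int> counts(nA * W);
  for (int b = 0; b < n_boot; ++b) {
    std::fill(counts.begin(), counts.end(), 0);
    for (int i = 0; i < n; ++i) {
      int pick = (int)(unif_rand() * n);
      if (pick >= n) pick = n - 1;
      for (int j = 0; j < W; ++j) {
        int v = M(pick, j);
        if (v > 0) ++counts[j * nA + v - 1];
      }
    }
    for (int j = 0; j < W; ++j)
      out(b, j) = column_entropy(counts, j, Q);
  }
  return out;
}

// One shuffle repeat, materialized: each row permuted (per_string) or a
// single shared permutation applied.  Used for property checks.
// [[Rcpp::export]]
IntegerMatrix cpp_permute_rows(IntegerMatrix M, bool per_string) {
  int n = M.nrow(), W = M.ncol();
  IntegerMatrix out(n, W);
  std::vector<int> row(W), perm(W);
  if (per_string) {
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < W; ++j) row[j] = M(i, j);
      for (int k = W - 1; k > 0; --k) {
        int j = (int)(unif_rand() * (k + 1));
        if (j > k) j = k;
        std::swap(row[k], row[j]);
      }
      for (int j = 0; j < W; ++j) out(i, j) = row[j];
    }
  } else {
    for (int j = 0; j < W; ++j) perm[j] = j;
    for (int k = W - 1; k > 0; --k) {
      int j = (int)(unif_rand() * (k + 1));
      if (j > k) j = k;
      std::swap(perm[k], perm[j]);
    }
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < W; ++j) out(i, j) = M(i, perm[j]);
  }
  return out;
}
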