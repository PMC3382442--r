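#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bhattacharyya coefficient of two weighted count-vector multisets after
// projecting onto a subset of columns. `counts` holds stacked full-pool
// count vectors (rows may repeat across the two classes), `wa`/`wb` the
// per-row class weights (zero where a row belongs to the other class).
// Rows whose projections collide are pooled via an open-addressing hash of
// a radix key over the selected columns. Returns sum_x sqrt(pa(x) * pb(x)).
// [[Rcpp::export]]
double bc_coef_cpp(const IntegerMatrix& counts,
                   const NumericVector& wa,
                   const NumericVector& wb,
                   const IntegerVector& cols) {
  const int n = counts.nrow();
  const int k = cols.size();
  if (k == 0) return 1.0;  // zero-length projection: all mass in one bin
  // radix base must exceed every count in the selected columns
  int maxc = 0;
  for (int jj = 0; jj < k; ++jj) {
    const int* col = &counts[(size_t)(cols[jj] - 1) * n];
    for (int i = 0; i < n; ++i) {
      if (col[i] > maxc) maxc = col[i];
    }
  }
  const long long base = (long long)maxc + 1;
  // open-addressing table, size = power of two >= 2n
  size_t cap = 64;
  while (cap < (size_t)2 * n) cap <<= 1;
  const size_t mask = cap - 1;
  std::vector<long long> keys(cap, -1);
  std::vector<double> sa(cap, 0.0), sb(cap, 0.0);
  for (int i = 0; i < n; ++i) {
    long long key = 0;
    for (int jj = 0; jj < k; ++jj) {
      key = key * base + counts[(size_t)(cols[jj] - 1) * n + i];
    }
    size_t h = ((unsigned long long)key * 0x9E3779B97F4A7C15ULL) & mask;
    while (keys[h] != -1 && keys[h] != key) h = (h + 1) & mask;
    keys[h] = key;
    sa[h] += wa[i];
    sb[h] += wb[i];
  }
  double bc = 0.0;
  for (size_t h = 0; h < cap; ++h) {
    if (keys[h] != -1) bc += std::sqrt(sa[h] * sb[h]);
  }
  return bc;
}

// One-time pooling of identical full-pool rows: returns the row index (1-based
// into the first occurrence) for each input row, so R can sum weights per
// distinct count vector before repeated scoring.
// [[Rcpp::export]]
IntegerVector row_group_cpp(const IntegerMatrix& counts) {
  const int n = counts.nrow();
  const int p = counts.ncol();
  size_t cap = 64;
  while (cap < (size_t)2 * n) cap <<= 1;
  const size_t mask = cap - 1;
  std::vector<int> slot(cap, -1);
  IntegerVector group(n);
  for (int i = 0; i < n; ++i) {
    unsigned long long h = 1469598103934665603ULL;  // FNV-1a over the row
    for (int j = 0; j < p; ++j) {
      h ^= (unsigned long long)(unsigned int)counts[(size_t)j * n + i];
      h *= 1099511628211ULL;
    }
    size_t pos = h & mask;
    for (;;) {
      int s = slot[pos];
      if (s == -1) {
        slot[pos] = i;
        group[i] = i + 1;
        break;
      }
      bool same = true;
      for (int j = 0; j < p; ++j) {
        if (counts[(size_t)j * n + s] != counts[(size_t)j * n + i]) {
          same = false;
          break;
        }
      }
      if (same) {
        group[i] = s + 1;
        break;
      }
      pos = (pos + 1) & mask;
    }
  }
  return group;
}
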