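#include <Rcpp.h>
#include <stack>
using namespace Rcpp;

// Plug-in mutual information (bits) between every pair of columns of an
// integer-coded (1..4) sequence matrix. Diagonal is NA.
// [[Rcpp::export]]
NumericMatrix mi_all_pairs_cpp(const IntegerMatrix& m) {
  const int n = m.nrow(), L = m.ncol();
  NumericMatrix out(L, L);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> marg(L * 4, 0.0);
  for (int j = 0; j < L; ++j)
    for (int r = 0; r < n; ++r) marg[j * 4 + (m(r, j) - 1)] += 1.0;
  const double ln2 = std::log(2.0);
  for (int i = 0; i < L; ++i) {
    for (int j = i + 1; j < L; ++j) {
      double joint[16] = {0.0};
      for (int r = 0; r < n; ++r)
        joint[(m(r, i) - 1) * 4 + (m(r, j) - 1)] += 1.0;
      double mi = 0.0;
      for (int a = 0; a < 4; ++a) {
        const double pa = marg[i * 4 + a] / n;
        if (pa == 0.0) continue;
        for (int b = 0; b < 4; ++b) {
          const double pab = joint[a * 4 + b] / n;
          if (pab == 0.0) continue;
          const double pb = marg[j * 4 + b] / n;
          mi += pab * std::log(pab / (pa * pb)) / ln2;
        }
      }
      if (mi < 0.0) mi = 0.0;  // guard against rounding
      out(i, j) = out(j, i) = mi;
    }
  }
  return out;
}

// Accumulate MI over row subsets (one column of `draws` = one subset of
// 1-based row indices); returns the mean MI matrix over draws.
// [[Rcpp::export]]
NumericMatrix mi_null_mean_cpp(const IntegerMatrix& m,
                               const IntegerMatrix& draws) {
  const int L = m.ncol(), k = draws.nrow(), nd = draws.ncol();
  NumericMatrix acc(L, L);
  IntegerMatrix sub(k, L);
  for (int d = 0; d < nd; ++d) {
    for (int r = 0; r < k; ++r) {
      const int src = draws(r, d) - 1;
      for (int j = 0; j < L; ++j) sub(r, j) = m(src, j);
    }
    NumericMatrix mi = mi_all_pairs_cpp(sub);
    for (int i = 0; i < L; ++i)
      for (int j = 0; j < L; ++j)
        if (i != j) acc(i, j) += mi(i, j);
  }
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j)
      acc(i, j) = (i == j) ? NA_REAL : acc(i, j) / nd;
  return acc;
}

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Nussinov-style maximum base pairing (Watson-Crick + GU wobble, minimum
// hairpin loop of 3 unpaired bases). Returns the pair count and one
// maximizing dot-bracket structure. The reference folding stub scores
// -1 kcal/mol per pair; this is a deterministic stand-in for a
// thermodynamic engine, not thermodynamics.
// [[Rcpp::export]]
List nussinov_cpp(const std::string& rna, const int min_loop = 3) {
  const int n = rna.size();
  std::string db(n, '.');
  if (n < min_loop + 2)
    return List::create(_["pairs"] = 0, _["structure"] = db);
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      int best = M[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (can_pair(rna[i], rna[k])) {
          int v = 1 + (k > i + 1 ? M[i + 1][k - 1] : 0) +
                  (k < j ? M[k + 1][j] : 0);
          if (v > best) best = v;
        }
      }
      M[i][j] = best;
    }
  }
  // traceback
  std::stack<std::pair<int, int> > st;
  st.push(std::make_pair(0, n - 1));
  while (!st.empty()) {
    int i = st.top().first, j = st.top().second;
    st.pop();
    if (i >= j || j - i < min_loop + 1) continue;
    if (M[i][j] == M[i + 1][j]) {
      st.push(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(rna[i], rna[k])) continue;
      int v = 1 + (k > i + 1 ? M[i + 1][k - 1] : 0) +
              (k < j ? M[k + 1][j] : 0);
      if (v == M[i][j]) {
        db[i] = '(';
        db[k] = ')';
        if (k > i + 1) st.push(std::make_pair(i + 1, k - 1));
        if (k < j) st.push(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  return List::create(_["pairs"] = M[0][n - 1], _["structure"] = db);
}
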