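#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard-swap Markov chain over binary matrices with fixed row and
// column sums. A move picks two rows and two columns uniformly; if the 2x2
// submatrix is a checkerboard ([[1,0],[0,1]] or [[0,1],[1,0]]) it is flipped
// (margins are conserved exactly), otherwise the attempt fails and the state
// is unchanged. In stratified mode the two rows must share a stratum, which
// additionally conserves per-stratum column sums. The pairwise co-occurrence
// matrix C(j,k) = sum_i m(i,j) m(i,k) is maintained incrementally: a
// successful swap touches only pairs involving the two flipped columns.
//
// Sampled statistics are the co-occurrence counts of all column pairs
// (j < k, column-major pair order), recorded every `thin` attempts after
// `burn_in` attempts.

static inline void row_contrib(IntegerMatrix &m, IntegerMatrix &C,
                               int r, int c, int sign) {
  // add/remove row r's contribution to co-occurrence pairs involving column
  // c; the row contributes only if it actually carries a 1 in column c
  if (m(r, c) != 1) return;
  int p = m.ncol();
  for (int l = 0; l < p; ++l) {
    if (l == c) continue;
    if (m(r, l) == 1) {
      C(c, l) += sign;
      C(l, c) += sign;
    }
  }
}

// [[Rcpp::export(name = ".swap_chain")]]
List swap_chain(IntegerMatrix mat, IntegerVector stratum,
                double burn_in, int n_samples, double thin,
                bool stratified) {
  IntegerMatrix m = clone(mat);
  int n = m.nrow(), p = m.ncol();
  if (n < 2 || p < 2) stop("matrix must be at least 2 x 2");
  long long nburn = (long long) burn_in;
  long long nthin = (long long) thin;
  if (nthin < 1) stop("thin must be >= 1");
  if (n_samples < 1) stop("n_samples must be >= 1");

  // stratum bookkeeping: rows grouped by stratum id (0-based)
  std::vector< std::vector<int> > strata_rows;
  if (stratified) {
    int ns = 0;
    for (int i = 0; i < n; ++i) ns = std::max(ns, stratum[i] + 1);
    strata_rows.assign(ns, std::vector<int>());
    for (int i = 0; i < n; ++i) strata_rows[stratum[i]].push_back(i);
  }

  // initial co-occurrence matrix
  IntegerMatrix C(p, p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) {
      if (m(i, j) != 1 && m(i, j) != 0) stop("matrix cells must be 0/1");
      if (m(i, j) == 1) {
        for (int k = j + 1; k < p; ++k) {
          if (m(i, k) == 1) { C(j, k) += 1; C(k, j) += 1; }
        }
      }
    }
  }

  int npairs = p * (p - 1) / 2;
  IntegerMatrix samples(n_samples, npairs);
  long long total = nburn + (long long) n_samples * nthin;
  long long accepted = 0;
  int sample_idx = 0;

  RNGScope scope;
  for (long long t = 1; t <= total; ++t) {
    int r1, r2;
    if (stratified) {
      r1 = (int) (unif_rand() * n);
      if (r1 >= n) r1 = n - 1;
      const std::vector<int> &rows = strata_rows[stratum[r1]];
      if (rows.size() >= 2) {
        int k = (int) (unif_rand() * (rows.size() - 1));
        if (k >= (int) rows.size() - 1) k = rows.size() - 2;
        // pick uniformly among the stratum's rows excluding r1
        int cand = rows[k];
        if (cand == r1) cand = rows[rows.size() - 1];
        r2 = cand;
      } else {
        r2 = r1;  // singleton stratum: guaranteed failure
      }
    } else {
      r1 = (int) (unif_rand() * n); if (r1 >= n) r1 = n - 1;
      r2 = (int) (unif_rand() * (n - 1)); if (r2 >= n - 1) r2 = n - 2;
      if (r2 >= r1) r2 += 1;
    }
    int c1 = (int) (unif_rand() * p); if (c1 >= p) c1 = p - 1;
    int c2 = (int) (unif_rand() * (p - 1)); if (c2 >= p - 1) c2 = p - 2;
    if (c2 >= c1) c2 += 1;

    if (r1 != r2) {
      int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
      if ((a + d == 2 && b + c == 0) || (a + d == 0 && b + c == 2)) {
        // remove contributions of the four cells' rows for the two columns
        row_contrib(m, C, r1, c1, -1);
        row_contrib(m, C, r1, c2, -1);
        row_contrib(m, C, r2, c1, -1);
        row_contrib(m, C, r2, c2, -1);
        m(r1, c1) = 1 - a; m(r1, c2) = 1 - b;
        m(r2, c1) = 1 - c; m(r2, c2) = 1 - d;
        row_contrib(m, C, r1, c1, +1);
        row_contrib(m, C, r1, c2, +1);
        row_contrib(m, C, r2, c1, +1);
        row_contrib(m, C, r2, c2, +1);
        accepted += 1;
      }
    }

    if (t > nburn && (t - nburn) % nthin == 0) {
      int idx = 0;
      for (int j = 0; j < p; ++j) {
        for (int k = j + 1; k < p; ++k) {
          samples(sample_idx, idx) = C(j, k);
          ++idx;
        }
      }
      ++sample_idx;
      if (sample_idx >= n_samples) {
        // record any remaining burn-only attempts? loop ends naturally
      }
    }
  }

  return List::create(
    _["samples"] = samples,
    _["final_matrix"] = m,
    _["accepted"] = (double) accepted,
    _["attempts"] = (double) total
  );
}
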