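#include <Rcpp.h>
using namespace Rcpp;

// Kernel Gram machinery for the generalized discrepancy
//   D_K(X1, X0)^2 = n1^-2 sum K(X1,X1) - 2 (n1 n0)^-1 sum K(X1,X0) + n0^-2 sum K(X0,X0)
// and the exchange heuristic minimizing it over balanced partitions.
// Double sums include the diagonal throughout.

static inline double energy_kernel_ij(const NumericMatrix& X, int i, int j) {
  double s = 0.0;
  const int p = X.ncol();
  for (int k = 0; k < p; ++k) {
    const double d = X(i, k) - X(j, k);
    s += d * d;
  }
  return -std::sqrt(s);
}

static inline double centered_l2_kernel_ij(const NumericMatrix& X,
                                           const NumericMatrix& Y,
                                           int i, int j) {
  double prod = 1.0;
  const int p = X.ncol();
  for (int k = 0; k < p; ++k) {
    const double a = X(i, k), b = Y(j, k);
    prod *= 1.0 + 0.5 * std::fabs(a - 0.5) + 0.5 * std::fabs(b - 0.5) -
            0.5 * std::fabs(a - b);
  }
  return prod;
}

// [[Rcpp::export]]
NumericMatrix gram_energy_cpp(NumericMatrix X) {
  const int n = X.nrow();
  NumericMatrix G(n, n);
  for (int i = 0; i < n; ++i) {
    G(i, i) = 0.0;
    for (int j = i + 1; j < n; ++j) {
      const double v = energy_kernel_ij(X, i, j);
      G(i, j) = v;
      G(j, i) = v;
    }
  }
  return G;
}

// [[Rcpp::export]]
NumericMatrix cross_gram_energy_cpp(NumericMatrix X, NumericMatrix Y) {
  const int n = X.nrow(), m = Y.nrow(), p = X.ncol();
  NumericMatrix G(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        const double d = X(i, k) - Y(j, k);
        s += d * d;
      }
      G(i, j) = -std::sqrt(s);
    }
  return G;
}

// [[Rcpp::export]]
NumericMatrix gram_centered_l2_cpp(NumericMatrix X) {
  const int n = X.nrow();
  NumericMatrix G(n, n);
  for (int i = 0; i < n; ++i) {
    G(i, i) = centered_l2_kernel_ij(X, X, i, i);
    for (int j = i + 1; j < n; ++j) {
      const double v = centered_l2_kernel_ij(X, X, i, j);
      G(i, j) = v;
      G(j, i) = v;
    }
  }
  return G;
}

// [[Rcpp::export]]
NumericMatrix cross_gram_centered_l2_cpp(NumericMatrix X, NumericMatrix Y) {
  const int n = X.nrow(), m = Y.nrow();
  NumericMatrix G(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      G(i, j) = centered_l2_kernel_ij(X, Y, i, j);
  return G;
}

// Squared group-vs-group discrepancy from a full Gram matrix; idx1/idx0 are
// 0-based, disjoint, and together cover any subset of rows of G.
// [[Rcpp::export]]
double disc2_from_gram_cpp(NumericMatrix G, IntegerVector idx1, IntegerVector idx0) {
  const int m1 = idx1.size(), m0 = idx0.size();
  double s11 = 0.0, s00 = 0.0, s10 = 0.0;
  for (int a = 0; a < m1; ++a)
    for (int b = 0; b < m1; ++b) s11 += G(idx1[a], idx1[b]);
  for (int a = 0; a < m0; ++a)
    for (int b = 0; b < m0; ++b) s00 += G(idx0[a], idx0[b]);
  for (int a = 0; a < m1; ++a)
    for (int b = 0; b < m0; ++b) s10 += G(idx1[a], idx0[b]);
  return s11 / ((double)m1 * m1) - 2.0 * s10 / ((double)m1 * m0) +
         s00 / ((double)m0 * m0);
}

// Exchange heuristic: sweeps over treated units; for each treated unit the
// best improving swap with a control unit is applied. Incremental O(1) swap
// deltas via cached kernel row sums; stops when a sweep applies no swap or
// max_passes sweeps are done. Returns 0-based treated indices, the final
// squared discrepancy, and evaluation/swap counts.
// [[Rcpp::export]]
List exchange_sweeps_cpp(NumericMatrix G, IntegerVector treated, int max_passes) {
  const int n = G.nrow();
  std::vector<int> grp(n, 0);
  std::vector<int> idx1(treated.begin(), treated.end());
  for (size_t a = 0; a < idx1.size(); ++a) grp[idx1[a]] = 1;
  std::vector<int> idx0;
  idx0.reserve(n - idx1.size());
  for (int i = 0; i < n; ++i)
    if (!grp[i]) idx0.push_back(i);
  const int m1 = (int)idx1.size(), m0 = (int)idx0.size();

  // r1[k] = sum_{l in g1} K(k,l); r0[k] = sum_{l in g0} K(k,l)
  std::vector<double> r1(n, 0.0), r0(n, 0.0);
  for (int k = 0; k < n; ++k) {
    double a1 = 0.0, a0 = 0.0;
    for (int l = 0; l < n; ++l) {
      if (grp[l]) a1 += G(k, l); else a0 += G(k, l);
    }
    r1[k] = a1;
    r0[k] = a0;
  }
  double S11 = 0.0, S00 = 0.0, S10 = 0.0;
  for (int a = 0; a < m1; ++a) { S11 += r1[idx1[a]]; S10 += r0[idx1[a]]; }
  for (int a = 0; a < m0; ++a) S00 += r0[idx0[a]];

  const double c11 = 1.0 / ((double)m1 * m1);
  const double c00 = 1.0 / ((double)m0 * m0);
  const double c10 = 2.0 / ((double)m1 * m0);
  double cur = S11 * c11 - S10 * c10 + S00 * c00;

  long long n_eval = 0;
  int n_swaps = 0;
  for (int pass = 0; pass < max_passes; ++pass) {
    bool swapped_this_pass = false;
    for (int a = 0; a < m1; ++a) {
      const int i = idx1[a];
      int best_b = -1;
      double best_val = cur;
      for (int b = 0; b < m0; ++b) {
        const int j = idx0[b];
        ++n_eval;
        const double s11 = S11 - 2.0 * r1[i] + G(i, i) + 2.0 * r1[j] -
                           2.0 * G(j, i) + G(j, j);
        const double s00 = S00 - 2.0 * r0[j] + G(j, j) + 2.0 * r0[i] -
                           2.0 * G(i, j) + G(i, i);
        const double s10 = S10 - r0[i] + r0[j] -
                           (r1[j] - G(j, i) + G(j, j)) +
                           (r1[i] - G(i, i) + G(i, j));
        const double cand = s11 * c11 - s10 * c10 + s00 * c00;
        if (cand < best_val - 1e-13 * (1.0 + std::fabs(best_val))) {
          best_val = cand;
          best_b = b;
        }
      }
      if (best_b >= 0) {
        const int j = idx0[best_b];
        // commit the swap: recompute sums from the same O(1) formulas
        const double s11 = S11 - 2.0 * r1[i] + G(i, i) + 2.0 * r1[j] -
                           2.0 * G(j, i) + G(j, j);
        const double s00 = S00 - 2.0 * r0[j] + G(j, j) + 2.0 * r0[i] -
                           2.0 * G(i, j) + G(i, i);
        const double s10 = S10 - r0[i] + r0[j] -
                           (r1[j] - G(j, i) + G(j, j)) +
                           (r1[i] - G(i, i) + G(i, j));
        S11 = s11; S00 = s00; S10 = s10;
        for (int k = 0; k < n; ++k) {
          const double gki = G(k, i), gkj = G(k, j);
          r1[k] += gkj - gki;
          r0[k] += gki - gkj;
        }
        idx1[a] = j;
        idx0[best_b] = i;
        grp[i] = 0;
        grp[j] = 1;
        cur = S11 * c11 - S10 * c10 + S00 * c00;
        swapped_this_pass = true;
        ++n_swaps;
      }
    }
    if (!swapped_this_pass) break;
  }

  return List::create(_["treated"] = IntegerVector(idx1.begin(), idx1.end()),
                      _["disc2"] = cur,
                      _["n_evaluations"] = (double)n_eval,
                      _["n_swaps"] = n_swaps);
}

// Twinning-style sequential allocation. Starting from `start` (0-based), a
// unit goes to the treated half and its nearest unallocated neighbour (in the
// metric implied by the Gram matrix: nearest = largest kernel value) to the
// control half; the walk continues at the unallocated unit nearest to that
// neighbour. An odd leftover unit joins the treated half. Ties break on the
// smallest index. Returns 0/1 labels.
// [[Rcpp::export]]
IntegerVector twin_alloc_cpp(NumericMatrix G, int start) {
  const int n = G.nrow();
  IntegerVector lab(n, NA_INTEGER);
  std::vector<bool> done(n, false);
  int left = n;
  int cur = start;
  while (left > 0) {
    lab[cur] = 1;
    done[cur] = true;
    --left;
    if (left == 0) break;
    // nearest unallocated to cur
    int nb = -1;
    double best = -std::numeric_limits<double>::infinity();
    for (int k = 0; k < n; ++k)
      if (!done[k] && G(cur, k) > best) { best = G(cur, k); nb = k; }
    lab[nb] = 0;
    done[nb] = true;
    --left;
    if (left == 0) break;
    int nxt = -1;
    best = -std::numeric_limits<double>::infinity();
    for (int k = 0; k < n; ++k)
      if (!done[k] && G(nb, k) > best) { best = G(nb, k); nxt = k; }
    cur = nxt;
  }
  return lab;
}
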