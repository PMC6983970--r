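// Stable-PC skeleton phase with Gaussian (Fisher-z) conditional
// independence tests. Hub nodes make the subset enumeration exponential in
// the neighbourhood size, so this loop lives in C++; orientation (fast) is
// done in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Partial correlation of (i, j) given S from a correlation matrix.
// Returns NA on a singular conditioning submatrix.
static double pcor(const arma::mat& C, int i, int j,
                   const std::vector<int>& S) {
  const int l = S.size();
  if (l == 0) return C(i, j);
  if (l == 1) {
    double ci = C(i, S[0]), cj = C(j, S[0]);
    double den = (1.0 - ci * ci) * (1.0 - cj * cj);
    if (den <= 0) return NA_REAL;
    return (C(i, j) - ci * cj) / std::sqrt(den);
  }
  arma::mat CSS(l, l);
  arma::vec ci(l), cj(l);
  for (int a = 0; a < l; ++a) {
    ci(a) = C(S[a], i);
    cj(a) = C(S[a], j);
    for (int b = 0; b < l; ++b) CSS(a, b) = C(S[a], S[b]);
  }
  arma::mat B;
  arma::mat rhs = arma::join_rows(ci, cj);
  if (!arma::solve(B, CSS, rhs, arma::solve_opts::no_approx))
    return NA_REAL;
  double qii = arma::dot(ci, B.col(0));
  double qjj = arma::dot(cj, B.col(1));
  double qij = arma::dot(ci, B.col(1));
  double den = (1.0 - qii) * (1.0 - qjj);
  if (den <= 0) return NA_REAL;
  return (C(i, j) - qij) / std::sqrt(den);
}

// independent iff sqrt(n - l - 3) * |atanh(r)| < z_crit; untestable
// (NA / non-finite) counts as independent (non-significant).
static bool indep(const arma::mat& C, int i, int j,
                  const std::vector<int>& S, int n, double z_crit) {
  double r = pcor(C, i, j, S);
  if (!std::isfinite(r)) return true;
  if (r > 1.0 - 1e-12) r = 1.0 - 1e-12;
  if (r < -1.0 + 1e-12) r = -1.0 + 1e-12;
  double stat = std::sqrt((double)(n - (int)S.size() - 3)) *
    std::fabs(std::atanh(r));
  return stat < z_crit;
}

// [[Rcpp::export(name = ".pc_skeleton_gauss")]]
List pc_skeleton_gauss(const arma::mat& corr, int n_samples, double z_crit,
                       int max_cond_size) {
  const int p = corr.n_rows;
  std::vector<char> adj((size_t)p * p, 1);
  for (int i = 0; i < p; ++i) adj[(size_t)i * p + i] = 0;
  List sepset((size_t)p * p);           // flat (i, j) -> S, 0-based fill

  int l = 0;
  bool any_tested = true;
  while (any_tested && l <= max_cond_size) {
    any_tested = false;
    // stable variant: neighbourhoods frozen at the start of the level
    std::vector<std::vector<int>> nb(p);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        if (adj[(size_t)i * p + j]) nb[i].push_back(j);
    for (int i = 0; i < p; ++i) {
      for (int j : nb[i]) {
        if (!adj[(size_t)i * p + j]) continue;  // removed this level
        std::vector<int> cand;
        for (int k : nb[i]) if (k != j) cand.push_back(k);
        const int m = cand.size();
        if (m < l) continue;
        any_tested = true;
        // enumerate l-subsets of cand in lexicographic order
        std::vector<int> idx(l);
        for (int a = 0; a < l; ++a) idx[a] = a;
        bool removed = false;
        while (!removed) {
          std::vector<int> S(l);
          for (int a = 0; a < l; ++a) S[a] = cand[idx[a]];
          if (indep(corr, i, j, S, n_samples, z_crit)) {
            adj[(size_t)i * p + j] = 0;
            adj[(size_t)j * p + i] = 0;
            IntegerVector Sv(l);
            for (int a = 0; a < l; ++a) Sv[a] = S[a] + 1;  // 1-based for R
            sepset[(size_t)i * p + j] = Sv;
            sepset[(size_t)j * p + i] = Sv;
            removed = true;
            break;
          }
          // next combination
          int a = l - 1;
          while (a >= 0 && idx[a] == m - l + a) --a;
          if (a < 0) break;
          ++idx[a];
          for (int b = a + 1; b < l; ++b) idx[b] = idx[b - 1] + 1;
          if (l == 0) break;            // single empty subset
        }
      }
    }
    ++l;
  }
  LogicalMatrix adj_out(p, p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      adj_out(i, j) = adj[(size_t)i * p + j] != 0;
  return List::create(_["adj"] = adj_out, _["sepset"] = sepset);
}
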