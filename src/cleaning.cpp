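// Permutation null for the cleaning-stage ridge statistics.
//
// For candidate group g the statistic is ||theta_g||^2 from the group-
// weighted ridge on the cleaning half. The null permutes the rows of that
// group's columns only (conditional permutation: association with both the
// response and the other candidate groups is broken, their joint fit is
// preserved). theta_g under a permuted X_g is obtained from the Schur
// complement against the unpermuted blocks, so each permutation costs
// O(n k_u k_g) instead of a full refit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat ridge_perm_stats_cpp(const arma::mat& X, const arma::vec& y,
                               const arma::vec& pen_diag, double lam,
                               const arma::ivec& grp_start,
                               const arma::ivec& grp_len,
                               const arma::imat& perms) {
  const uword K = grp_start.n_elem, B = perms.n_cols, k = X.n_cols;
  mat stats(K, B);
  for (uword g = 0; g < K; ++g) {
    uword a = grp_start(g), m = grp_len(g);
    uvec jj = regspace<uvec>(a, a + m - 1);
    uvec oth(k - m);
    uword t = 0;
    for (uword j = 0; j < k; ++j) if (j < a || j >= a + m) oth(t++) = j;
    mat Xg = X.cols(jj);
    mat Gg = Xg.t() * Xg;                  // invariant under row permutation
    vec Dg = lam * pen_diag(jj);
    vec yres;
    mat AuI, Xu;
    bool have_others = oth.n_elem > 0;
    if (have_others) {
      Xu = X.cols(oth);
      mat Au = Xu.t() * Xu;
      Au.diag() += lam * pen_diag(oth);
      AuI = inv_sympd(Au);
      yres = y - Xu * (AuI * (Xu.t() * y)); // residual of y on other blocks
    } else {
      yres = y;
    }
    for (uword b = 0; b < B; ++b) {
      uvec pi = conv_to<uvec>::from(perms.col(b)) - 1; // 1-based from R
      mat Xp = Xg.rows(pi);
      mat M = Gg;
      M.diag() += Dg;
      vec rhs = Xp.t() * yres;
      if (have_others) {
        mat E = Xu.t() * Xp;               // k_u x k_g
        M -= E.t() * (AuI * E);
      }
      vec th = solve(M, rhs, solve_opts::likely_sympd);
      stats(g, b) = dot(th, th);
    }
  }
  return stats;
}
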