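// Compiled kernels: iterative proportional scaling (IPS) for graph-constrained
// Gaussian covariance estimation, James-Stein-type shrinkage of a sample
// covariance, and the permutation loop computing the two-sample statistic
// bundle (whole-pathway concentration and mean tests plus per-clique tests)
// for every label permutation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---------------------------------------------------------------------------
// IPS core. K kept exactly zero off the clique blocks (the graph's support);
// Sigma tracked by a Woodbury update within a sweep and recomputed exactly at
// the end of each sweep. Cliques should cover every vertex.
// ---------------------------------------------------------------------------
static bool ips_core(const mat& S, const std::vector<uvec>& cliques,
                     double tol, int maxit,
                     mat& Sigma, mat& K, int& iters, double& delta_out,
                     std::vector<double>* lltrace)
{
  const uword P = S.n_rows;
  K.zeros(P, P);
  K.diag() = 1.0 / S.diag();
  Sigma.zeros(P, P);
  Sigma.diag() = S.diag();

  double delta = datum::inf;
  iters = 0;
  while (iters < maxit) {
    ++iters;
    mat Sigma_old = Sigma;
    for (size_t ci = 0; ci < cliques.size(); ++ci) {
      const uvec& C = cliques[ci];
      mat Scc = S.submat(C, C);
      mat Wcc = Sigma.submat(C, C);
      mat D = inv_sympd(Scc) - inv_sympd(Wcc);
      if (abs(D).max() < 1e-15) continue;
      K.submat(C, C) += D;
      // (K + U_C D U_C')^{-1} = Sigma - Sigma[,C] (D^{-1} + Wcc)^{-1} Sigma[C,]
      // written as D (I + Wcc D)^{-1} so a singular D is harmless.
      mat M = D * inv(eye(C.n_elem, C.n_elem) + Wcc * D);
      mat SC = Sigma.cols(C);
      Sigma -= SC * M * SC.t();
    }
    K = symmatu(K);
    Sigma = inv_sympd(K);  // exact resync, kills Woodbury drift
    if (lltrace) {
      double ld = log_det_sympd(K);
      lltrace->push_back(ld - accu(K % S));
    }
    delta = abs(Sigma - Sigma_old).max();
    if (delta < tol) break;
  }
  delta_out = delta;
  return delta < tol;
}

// [[Rcpp::export]]
Rcpp::List ips_cpp(const arma::mat& S, const Rcpp::List& cliques,
                   double tol, int maxit, bool trace_loglik)
{
  std::vector<uvec> cl(cliques.size());
  for (R_xlen_t i = 0; i < cliques.size(); ++i) {
    Rcpp::IntegerVector v = cliques[i];
    uvec u(v.size());
    for (int j = 0; j < v.size(); ++j) u[j] = v[j] - 1;  // 1-based from R
    cl[i] = u;
  }
  mat Sigma, K;
  int iters = 0;
  double delta = NA_REAL;
  std::vector<double> lltrace;
  bool conv = ips_core(S, cl, tol, maxit, Sigma, K, iters, delta,
                       trace_loglik ? &lltrace : nullptr);
  return Rcpp::List::create(
      Rcpp::Named("sigma") = Sigma,
      Rcpp::Named("concentration") = K,
      Rcpp::Named("converged") = conv,
      Rcpp::Named("iterations") = iters,
      Rcpp::Named("tolerance_reached") = delta,
      Rcpp::Named("loglik_trace") = lltrace);
}

// ---------------------------------------------------------------------------
// Shrinkage of a covariance built from column-centered data Xc (P x m) with
// df degrees of freedom: correlations shrunk toward the identity with the
// analytic optimal intensity, variances left untouched, i.e.
// S* = (1 - lambda) S + lambda diag(S).
// ---------------------------------------------------------------------------
static mat shrink_centered(const mat& Xc, double df, double& lambda)
{
  const uword P = Xc.n_rows;
  const double m = (double) Xc.n_cols;
  mat S = (Xc * Xc.t()) / df;
  if (P == 1) { lambda = 1.0; return S; }
  vec sd = sqrt(S.diag());
  mat Z = Xc.each_col() / sd;
  mat ZZ = Z * Z.t();          // sum_k w_kij,  r_ij = ZZ_ij / df
  mat Z2 = square(Z);
  mat W2 = Z2 * Z2.t();        // sum_k w_kij^2
  double num = 0.0, den = 0.0;
  for (uword i = 0; i < P; ++i) {
    for (uword j = i + 1; j < P; ++j) {
      double sw = ZZ(i, j);
      num += W2(i, j) - sw * sw / m;
      double r = sw / df;
      den += r * r;
    }
  }
  num *= m / ((m - 1.0) * df * df);
  lambda = (den > 0.0) ? num / den : 1.0;
  if (lambda < 0.0) lambda = 0.0;
  if (lambda > 1.0) lambda = 1.0;
  mat Sstar = (1.0 - lambda) * S;
  Sstar.diag() = S.diag();
  return Sstar;
}

// [[Rcpp::export]]
Rcpp::List shrink_cpp(const arma::mat& Xc, double df)
{
  double lambda = NA_REAL;
  mat S = shrink_centered(Xc, df, lambda);
  return Rcpp::List::create(Rcpp::Named("sigma") = S,
                            Rcpp::Named("lambda") = lambda);
}

// fixed-intensity shrinkage toward the diagonal
static mat shrink_fixed(const mat& Xc, double df, double lambda)
{
  mat S = (Xc * Xc.t()) / df;
  mat Sstar = (1.0 - lambda) * S;
  Sstar.diag() = S.diag();
  return Sstar;
}

// Shrunken covariances of a split after centering each group. One intensity
// is estimated from the pooled within-group residuals and shared by the two
// class-specific estimates, so the likelihood-ratio comparison of the three
// matrices is not driven by jitter in separately estimated intensities.
struct SplitCov {
  mat S1, S2, Sw;
  double n1, n2, n, lambda;
};

static SplitCov split_cov(const mat& X, const uvec& idx1, const uvec& idx2,
                          vec& m1, vec& m2)
{
  SplitCov sc;
  sc.n1 = (double) idx1.n_elem;
  sc.n2 = (double) idx2.n_elem;
  sc.n = sc.n1 + sc.n2;
  mat X1 = X.cols(idx1), X2 = X.cols(idx2);
  m1 = mean(X1, 1);
  m2 = mean(X2, 1);
  mat X1c = X1.each_col() - m1;
  mat X2c = X2.each_col() - m2;
  mat Ec = join_rows(X1c, X2c);
  sc.Sw = shrink_centered(Ec, sc.n - 2.0, sc.lambda);
  sc.S1 = shrink_fixed(X1c, sc.n1 - 1.0, sc.lambda);
  sc.S2 = shrink_fixed(X2c, sc.n2 - 1.0, sc.lambda);
  return sc;
}

// scale each row to unit "sd" without centering (for mean-free rotated data)
static mat scale_rows(const mat& M, double df)
{
  vec sd = sqrt(sum(square(M), 1) / df);
  return M.each_col() / sd;
}

// ---------------------------------------------------------------------------
// Concentration-family statistics for one split of the rotated residual
// matrix Z (P x (n-2)). Z's columns are, under the Gaussian null of equal
// concentration matrices, iid N(0, Sigma) whatever the class means are (each
// class's samples were Helmert-rotated onto its mean-orthogonal complement),
// so permuting them is exactly exchangeable and the test compares the
// strength of gene-gene links free of mean or variance nuisance: the
// statistics are computed on rows scaled to unit variance within each group
// (shrunken correlation matrices, one intensity per split, constrained to
// the graph by IPS). Single-gene cliques use the variance-ratio LRT.
// out[0] = whole-pathway concentration LRT; out[1..K] = clique stats.
// ---------------------------------------------------------------------------
static void conc_stats(const mat& Z, const uvec& idx1, const uvec& idx2,
                       const std::vector<uvec>& gcliq,
                       const std::vector<uvec>& tcliq,
                       double tol, int maxit,
                       vec& out, int& bad_fits)
{
  const uword P = Z.n_rows;
  const double m1 = (double) idx1.n_elem;   // df of group 1 (= n1 - 1)
  const double m2 = (double) idx2.n_elem;
  const double m = m1 + m2;

  mat Z1 = Z.cols(idx1), Z2 = Z.cols(idx2);
  vec v1 = sum(square(Z1), 1) / m1;
  vec v2 = sum(square(Z2), 1) / m2;
  vec vw = (sum(square(Z1), 1) + sum(square(Z2), 1)) / m;
  auto var_lrt = [&](uword g) {
    // expressed with per-group dfs (the rotated sample sizes)
    return m * std::log(vw[g]) - m1 * std::log(v1[g]) - m2 * std::log(v2[g]);
  };

  if (P < 2) { out[0] = var_lrt(0); out[1] = var_lrt(0); return; }

  mat U1 = scale_rows(Z1, m1);
  mat U2 = scale_rows(Z2, m2);
  double lam;
  mat Rw = shrink_centered(join_rows(U1, U2), m, lam);
  mat R1 = shrink_fixed(U1, m1, lam);
  mat R2 = shrink_fixed(U2, m2, lam);

  mat Sig1, K1, Sig2, K2, Sigw, Kw;
  int it;
  double dd;
  if (!ips_core(R1, gcliq, tol, maxit, Sig1, K1, it, dd, nullptr)) ++bad_fits;
  if (!ips_core(R2, gcliq, tol, maxit, Sig2, K2, it, dd, nullptr)) ++bad_fits;
  if (!ips_core(Rw, gcliq, tol, maxit, Sigw, Kw, it, dd, nullptr)) ++bad_fits;
  double ld1 = log_det_sympd(K1);
  double ld2 = log_det_sympd(K2);
  double ldw = log_det_sympd(Kw);
  out[0] = m1 * (ld1 - accu(K1 % R1)) + m2 * (ld2 - accu(K2 % R2))
         - (m1 * (ldw - accu(Kw % R1)) + m2 * (ldw - accu(Kw % R2)));

  const size_t KK = tcliq.size();
  for (size_t k = 0; k < KK; ++k) {
    const uvec& C = tcliq[k];
    if (C.n_elem >= 2) {
      out[1 + k] = m * log_det_sympd(Rw.submat(C, C))
                 - m1 * log_det_sympd(R1.submat(C, C))
                 - m2 * log_det_sympd(R2.submat(C, C));
    } else {
      out[1 + k] = var_lrt(C[0]);
    }
  }
}

// ---------------------------------------------------------------------------
// Mean-family statistics for one split of the raw data X: homoschedastic and
// heteroschedastic quadratic forms of the group mean difference in the
// metric of graph-constrained covariance-scale fits, plus per-clique
// versions. out = [mean_homo, mean_hetero, clique mean stats...].
// ---------------------------------------------------------------------------
static void mean_stats(const mat& X, const uvec& idx1, const uvec& idx2,
                       const std::vector<uvec>& gcliq,
                       const std::vector<uvec>& tcliq,
                       double tol, int maxit,
                       vec& out, int& bad_fits)
{
  vec m1, m2;
  SplitCov cx = split_cov(X, idx1, idx2, m1, m2);
  const double n1 = cx.n1, n2 = cx.n2, n = cx.n;

  mat SigM1, KM1, SigM2, KM2, SigMw, KMw;
  int it;
  double dd;
  if (!ips_core(cx.S1, gcliq, tol, maxit, SigM1, KM1, it, dd, nullptr)) ++bad_fits;
  if (!ips_core(cx.S2, gcliq, tol, maxit, SigM2, KM2, it, dd, nullptr)) ++bad_fits;
  if (!ips_core(cx.Sw, gcliq, tol, maxit, SigMw, KMw, it, dd, nullptr)) ++bad_fits;

  vec d12 = m1 - m2;
  out[0] = (n1 * n2 / n) * as_scalar(d12.t() * KMw * d12);
  mat V = SigM1 / n1 + SigM2 / n2;
  out[1] = as_scalar(d12.t() * solve(V, d12));

  const size_t KK = tcliq.size();
  for (size_t k = 0; k < KK; ++k) {
    const uvec& C = tcliq[k];
    vec dC = d12.elem(C);
    out[2 + k] =
        (n1 * n2 / n) * as_scalar(dC.t() * solve(cx.Sw.submat(C, C), dC));
  }
}

// X: raw data (P x n) with raw-label permutations permsX (n x R, 1-based
// orders; the first n1 entries of a column form group 1). Z: Helmert-rotated
// residuals (P x (n-2)) with permutations permsZ ((n-2) x R; first n1-1
// entries form group 1). Column 1 of both is the identity (observed split).
// Returns an R x (3 + 2K) matrix: concentration, mean_homo, mean_hetero,
// K clique concentration stats, K clique mean stats.
// [[Rcpp::export]]
Rcpp::List perm_stats_cpp(const arma::mat& X, const arma::imat& permsX,
                          int n1,
                          const arma::mat& Z, const arma::imat& permsZ,
                          int mz1,
                          const Rcpp::List& graph_cliques,
                          const Rcpp::List& test_cliques,
                          double tol, int maxit)
{
  auto to_uvec = [](const Rcpp::List& L) {
    std::vector<uvec> out(L.size());
    for (R_xlen_t i = 0; i < L.size(); ++i) {
      Rcpp::IntegerVector v = L[i];
      uvec u(v.size());
      for (int j = 0; j < v.size(); ++j) u[j] = v[j] - 1;
      out[i] = u;
    }
    return out;
  };
  std::vector<uvec> gcliq = to_uvec(graph_cliques);
  std::vector<uvec> tcliq = to_uvec(test_cliques);

  const uword R = permsX.n_cols;
  const uword n = permsX.n_rows;
  const uword nz = permsZ.n_rows;
  const size_t KK = tcliq.size();
  mat stats(R, 3 + 2 * KK);
  int bad_splits = 0, bad_fits_total = 0;

  auto split_of = [](const imat& P, uword col, uword k1, uvec& i1, uvec& i2) {
    const uword nn = P.n_rows;
    i1.set_size(k1);
    i2.set_size(nn - k1);
    for (uword i = 0; i < nn; ++i) {
      uword s = (uword) P(i, col) - 1;
      if (i < k1) i1[i] = s; else i2[i - k1] = s;
    }
  };

  for (uword r = 0; r < R; ++r) {
    uvec ix1, ix2, iz1, iz2;
    split_of(permsX, r, (uword) n1, ix1, ix2);
    split_of(permsZ, r, (uword) mz1, iz1, iz2);
    int bad = 0;
    vec oc(1 + KK, fill::zeros), om(2 + KK, fill::zeros);
    conc_stats(Z, iz1, iz2, gcliq, tcliq, tol, maxit, oc, bad);
    mean_stats(X, ix1, ix2, gcliq, tcliq, tol, maxit, om, bad);
    if (bad > 0) { ++bad_splits; bad_fits_total += bad; }
    stats(r, 0) = oc[0];
    stats(r, 1) = om[0];
    stats(r, 2) = om[1];
    for (size_t k = 0; k < KK; ++k) {
      stats(r, 3 + k) = oc[1 + k];
      stats(r, 3 + KK + k) = om[2 + k];
    }
  }
  return Rcpp::List::create(Rcpp::Named("stats") = stats,
                            Rcpp::Named("bad_splits") = bad_splits,
                            Rcpp::Named("bad_fits") = bad_fits_total);
}
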