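// Numerical core: exact simplex-constrained weighted least squares
// (active-set QP), the per-window inference sweep, and founder-dosage
// tallies over mosaic segment lists. Hot paths only; all user-facing
// validation lives in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve  min_p  p'Gp - 2c'p  s.t.  sum(p) = 1, p >= 0,
// where G = A'WA, c = A'Wy.  Active-set method: maintain a feasible
// iterate, solve the equality-constrained KKT system on the free set,
// step to the first bound when infeasible (Lawson-Hanson style), and
// free the bound variable with the most negative multiplier at
// convergence.  Singular KKT systems (founders identical over the
// window) fall back to the pseudoinverse, which yields the
// minimum-norm solution, i.e. ties split proportion equally.
static vec simplex_qp(const mat& G, const vec& c) {
  const uword F = G.n_rows;
  std::vector<bool> free_(F, true);
  vec p(F, fill::value(1.0 / F));
  const double tol = 1e-10;

  for (int outer = 0; outer < 100; ++outer) {
    uvec S(F);
    uword k = 0;
    for (uword i = 0; i < F; ++i) if (free_[i]) S(k++) = i;
    S.resize(k);

    mat K(k + 1, k + 1, fill::zeros);
    K.submat(0, 0, k - 1, k - 1) = 2.0 * G.submat(S, S);
    for (uword j = 0; j < k; ++j) { K(j, k) = 1.0; K(k, j) = 1.0; }
    vec rhs(k + 1, fill::zeros);
    rhs.head(k) = 2.0 * c.elem(S);
    rhs(k) = 1.0;

    vec sol;
    bool ok = solve(sol, K, rhs, solve_opts::no_approx);
    if (!ok) sol = pinv(K) * rhs;
    vec pS = sol.head(k);
    double nu = sol(k);

    if (pS.min() >= -tol) {
      p.zeros();
      for (uword j = 0; j < k; ++j) p(S(j)) = std::max(pS(j), 0.0);
      // KKT multipliers for variables at the zero bound
      vec grad = 2.0 * (G * p - c);
      int worst_i = -1;
      double worst = -1e-8;
      for (uword i = 0; i < F; ++i) {
        if (free_[i]) continue;
        double mu = grad(i) + nu;
        if (mu < worst) { worst = mu; worst_i = (int)i; }
      }
      if (worst_i < 0) break;
      free_[worst_i] = true;
    } else {
      // partial step from the current feasible point to the first bound
      vec pOld = p.elem(S);
      double alpha = 1.0;
      int drop = -1;
      for (uword j = 0; j < k; ++j) {
        if (pS(j) < -tol) {
          double a = pOld(j) / (pOld(j) - pS(j));
          if (a < alpha) { alpha = a; drop = (int)S(j); }
        }
      }
      p.zeros();
      for (uword j = 0; j < k; ++j)
        p(S(j)) = std::max(pOld(j) + alpha * (pS(j) - pOld(j)), 0.0);
      if (drop >= 0) { free_[drop] = false; p(drop) = 0.0; }
      if (k <= 1) break;  // cannot drop below one free variable
    }
  }
  p.transform([](double v) { return v < 0 ? 0.0 : v; });
  double s = accu(p);
  if (s > 0) p /= s;
  return p;
}

// [[Rcpp::export]]
arma::vec simplex_wls_cpp(const arma::mat& A, const arma::vec& y,
                          const arma::vec& w) {
  mat Aw = A.each_col() % w;
  mat G = A.t() * Aw;       // A' W A
  vec c = A.t() * (w % y);  // A' W y
  return simplex_qp(G, c);
}

// Sweep all windows x samples on one chromosome.  founders: L x F 0/1
// matrix (cleaned); snp_cM ascending; ref/depth: L x S counts.
// Returns proportions as an (nwin*S) x F matrix (row-major by window
// then sample), n_snps and rss as nwin x S matrices; missing windows
// (fewer than min_snps usable SNPs) carry NA proportions.
// [[Rcpp::export]]
Rcpp::List infer_windows_cpp(const arma::mat& founders,
                             const arma::vec& snp_cM,
                             const arma::imat& ref,
                             const arma::imat& depth,
                             const arma::vec& win_start,
                             const arma::vec& win_end,
                             const int min_depth,
                             const int min_snps,
                             const bool depth_weights) {
  const uword L = founders.n_rows, F = founders.n_cols;
  const uword S = ref.n_cols, W = win_start.n_elem;
  mat props(W * S, F);
  props.fill(datum::nan);
  imat nsnp(W, S, fill::zeros);
  mat rss(W, S);
  rss.fill(datum::nan);

  const double* cm = snp_cM.memptr();
  // Sliding windows overlap heavily, so accumulate prefix sums of the
  // per-SNP normal-equation terms once per sample; any window's
  // G = A'WA, c = A'Wy then falls out as a difference of prefixes.
  const uword P = F * (F + 1) / 2;  // packed upper triangle
  mat csG(P, L + 1, fill::zeros);
  mat csc(F, L + 1, fill::zeros);
  rowvec csy(L + 1, fill::zeros);
  urowvec csn(L + 1, fill::zeros);

  for (uword s = 0; s < S; ++s) {
    for (uword i = 0; i < L; ++i) {
      csG.col(i + 1) = csG.col(i);
      csc.col(i + 1) = csc.col(i);
      csy(i + 1) = csy(i);
      csn(i + 1) = csn(i);
      const int d = depth(i, s);
      if (d < min_depth || d == 0) continue;
      const double wgt = depth_weights ? (double)d : 1.0;
      const double yv = (double)ref(i, s) / (double)d;
      uword k = 0;
      for (uword f1 = 0; f1 < F; ++f1) {
        const double a1 = founders(i, f1);
        csc(f1, i + 1) += wgt * a1 * yv;
        for (uword f2 = f1; f2 < F; ++f2, ++k)
          csG(k, i + 1) += wgt * a1 * founders(i, f2);
      }
      csy(i + 1) += wgt * yv * yv;
      csn(i + 1) += 1;
    }
    for (uword wi = 0; wi < W; ++wi) {
      const uword i0 = std::lower_bound(cm, cm + L, win_start(wi) - 1e-9) - cm;
      const uword i1 = std::upper_bound(cm, cm + L, win_end(wi) + 1e-9) - cm;
      if (i1 <= i0) continue;
      const int n = (int)(csn(i1) - csn(i0));
      if (n < min_snps) continue;
      mat G(F, F);
      vec c = csc.col(i1) - csc.col(i0);
      uword k = 0;
      for (uword f1 = 0; f1 < F; ++f1)
        for (uword f2 = f1; f2 < F; ++f2, ++k)
          G(f1, f2) = G(f2, f1) = csG(k, i1) - csG(k, i0);
      const double yty = csy(i1) - csy(i0);
      vec p = simplex_qp(G, c);
      props.row(wi * S + s) = p.t();
      nsnp(wi, s) = n;
      rss(wi, s) = std::max(as_scalar(p.t() * G * p - 2.0 * c.t() * p) + yty,
                            0.0);
    }
  }
  return Rcpp::List::create(Rcpp::Named("props") = props,
                            Rcpp::Named("n_snps") = nsnp,
                            Rcpp::Named("rss") = rss);
}

// Tally founder dosage of a set of homologs at sorted query positions.
// Mosaics are concatenated segment lists: seg_start (cM), seg_founder
// (1..F); offsets (0-based, length n_homologs+1) delimit homologs.
// Segment k of a homolog spans [seg_start[k], seg_start[k+1]) and the
// last segment extends to +Inf.  Returns an F x Q count matrix.
// [[Rcpp::export]]
arma::mat founder_counts_cpp(const arma::vec& seg_start,
                             const arma::ivec& seg_founder,
                             const arma::ivec& offsets,
                             const arma::vec& query,
                             const int F) {
  const uword Q = query.n_elem;
  const uword H = offsets.n_elem - 1;
  mat diffs(F, Q + 1, fill::zeros);
  const double* q = query.memptr();
  for (uword h = 0; h < H; ++h) {
    const uword a = (uword)offsets(h), b = (uword)offsets(h + 1);
    for (uword k = a; k < b; ++k) {
      const double lo = seg_start(k);
      const double hi = (k + 1 < b) ? seg_start(k + 1) : datum::inf;
      const uword qlo = std::lower_bound(q, q + Q, lo) - q;
      const uword qhi = std::lower_bound(q, q + Q, hi) - q;
      if (qhi > qlo) {
        const int f = seg_founder(k) - 1;
        diffs(f, qlo) += 1.0;
        diffs(f, qhi) -= 1.0;
      }
    }
  }
  mat counts = cumsum(diffs, 1);
  return counts.cols(0, Q - 1);
}
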