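# Independent oracles used by the solver and interval tests. These are
# deliberately naive (exhaustive enumeration) and share no code with the
# package's computational path.

# All k-part compositions of n (rows sum to n).
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  if (k == 2) return(cbind(0:n, n:0))
  if (k == 3) {
    i <- rep(0:n, times = n:0 + 1L)
    j <- sequence(n:0 + 1L) - 1L
    return(cbind(i, j, n - i - j))
  }
  do.call(rbind, lapply(0:n, function(i) cbind(i, compositions(n - i, k - 1))))
}

# Every simplex point with coordinates on a grid of the given step.
simplex_grid <- function(k, step = 0.005) {
  compositions(round(1 / step), k) * step
}

# Weighted least-squares objective at each row of P.
wls_objective <- function(P, A, y, w) {
  G <- crossprod(A, A * w)
  cvec <- crossprod(A, w * y)
  rowSums((P %*% G) * P) - 2 * drop(P %*% cvec) + sum(w * y^2)
}

# Exhaustive grid search: minimum objective and its argmin.
grid_search_oracle <- function(A, y, w, step = 0.005) {
  P <- simplex_grid(ncol(A), step)
  obj <- wls_objective(P, A, y, w)
  i <- which.min(obj)
  list(objective = obj[i], p = P[i, ])
}

# Brute-force interval overlap count (1-based inclusive).
overlap_count_oracle <- function(gene_start, gene_end, q_start, q_end) {
  sum(gene_start <= q_end & gene_end >= q_start)
}
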