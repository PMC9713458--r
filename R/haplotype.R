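#' Clean a founder panel for haplotype inference
#'
#' Inbred founders should be fixed at every SNP, but variant calling
#' leaves occasional intermediate frequencies. SNPs are retained only if
#' (i) every founder frequency is within `tol` of 0 or 1 (then rounded
#' to exactly 0/1) and (ii) the founders are not all identical after
#' rounding (a monomorphic SNP carries no haplotype information).
#'
#' @param panel a [founder_panel()].
#' @param tol distance from 0/1 tolerated before a SNP is dropped.
#' @return The cleaned panel; attribute `n_dropped` counts removals.
#' @export
clean_founder_panel <- function(panel, tol = 0.05) {
  founders <- founder_cols(panel)
  fa <- as.matrix(panel[founders])
  near_fixed <- fa <= tol | fa >= 1 - tol
  rounded <- round(fa)
  keep <- rowSums(near_fixed) == ncol(fa) &
    !(rowSums(rounded) %in% c(0, ncol(fa)))
  out <- panel[keep, , drop = FALSE]
  out[founders] <- rounded[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "founders") <- founders
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- class(panel)
  out
}

#' Assemble the regression system for one window
#'
#' For SNPs inside `[start_cM, end_cM]` of a cleaned panel that have
#' depth `>= min_depth` in the sample, builds the design matrix `A`
#' (SNPs x founders, entries 0/1), observations `y` (REF read
#' frequency), and weights `w` (read depth, or all 1 with
#' `weights = "equal"`). SNPs failing the founder-fixation or
#' monomorphism rules are dropped here if the panel was not pre-cleaned.
#'
#' @param panel a [founder_panel()] (cleaned or raw).
#' @param sample a [pooled_sample()] aligned to the panel's SNPs.
#' @param window one row of a [build_window_grid()] grid (or any list
#'   with `chrom`, `start_cM`, `end_cM`).
#' @param min_depth minimum read depth per SNP.
#' @param weights `"depth"` (default) or `"equal"`.
#' @param founder_tol fixation tolerance, see [clean_founder_panel()].
#' @return `list(A, y, w)`; zero-row `A` when no SNP qualifies.
#' @export
select_window_snps <- function(panel, sample, window, min_depth = 1,
                               weights = c("depth", "equal"),
                               founder_tol = 0.05) {
  weights <- match.arg(weights)
  founders <- founder_cols(panel)
  fa <- as.matrix(panel[founders])
  if (any(fa != round(fa)))
    panel <- clean_founder_panel(panel, founder_tol)
  in_win <- panel$chrom == window$chrom &
    panel$cM >= window$start_cM - 1e-9 & panel$cM <= window$end_cM + 1e-9
  sub <- panel[in_win, , drop = FALSE]
  key <- paste(sub$chrom, sub$pos)
  idx <- match(key, paste(sample$counts$chrom, sample$counts$pos))
  ok <- !is.na(idx)
  sub <- sub[ok, , drop = FALSE]
  idx <- idx[ok]
  depth <- sample$counts$ref_count[idx] + sample$counts$alt_count[idx]
  keep <- depth >= max(min_depth, 1)
  A <- as.matrix(sub[keep, founders, drop = FALSE])
  dimnames(A) <- list(NULL, founders)
  y <- sample$counts$ref_count[idx][keep] / depth[keep]
  w <- if (weights == "depth") depth[keep] else rep(1, sum(keep))
  list(A = A, y = as.numeric(y), w = as.numeric(w))
}

#' Constrained least-squares haplotype frequency estimate
#'
#' Finds the founder proportion vector p minimizing
#' `sum_i w_i (y_i - sum_f A_if p_f)^2` subject to `p_f >= 0` and
#' `sum_f p_f = 1`: the weighted least-squares projection of the
#' window's observed SNP frequencies onto the simplex spanned by the
#' founder haplotypes. Solved exactly by an active-set quadratic
#' program; flat directions from founders that are indistinguishable
#' over the window are resolved by the minimum-norm solution (tied
#' founders share their summed proportion equally).
#'
#' @param A design matrix (SNPs x founders).
#' @param y observed REF frequencies.
#' @param w positive weights.
#' @return Named proportion vector of length F.
#' @examples
#' A <- cbind(f1 = c(1, 0, 1), f2 = c(0, 1, 1))
#' estimate_haplotype_freqs(A, c(1, 0, 1), c(1, 1, 1))  # all on f1
#' @export
estimate_haplotype_freqs <- function(A, y, w = rep(1, length(y))) {
  A <- as.matrix(A)
  if (nrow(A) != length(y) || nrow(A) != length(w))
    stop("A, y, w dimensions disagree")
  if (nrow(A) == 0) stop("empty design matrix")
  if (any(w < 0)) stop("weights must be non-negative")
  p <- as.numeric(simplex_wls_cpp(A, as.numeric(y), as.numeric(w)))
  names(p) <- colnames(A)
  p
}

#' Infer founder haplotype frequencies in all windows
#'
#' Runs the window pipeline for every (window, sample) pair: SNP
#' selection ([select_window_snps()] semantics, executed in compiled
#' code) followed by the constrained least-squares estimate. Windows
#' with fewer than `min_snps` usable SNPs are flagged missing rather
#' than estimated.
#'
#' @param panel a [founder_panel()].
#' @param samples list of [pooled_sample()] objects sharing the panel's
#'   SNP universe (extra SNPs on either side are dropped by
#'   intersection).
#' @param grid a [build_window_grid()] grid.
#' @param min_snps minimum SNPs per window for a non-missing estimate.
#' @param min_depth minimum per-SNP read depth.
#' @param weights `"depth"` or `"equal"`.
#' @param founder_tol fixation tolerance for panel cleaning.
#' @param verbose emit one message per chromosome.
#' @return A `window_freqs` data frame in long form: `chrom`,
#'   `center_cM`, `center_bp`, `sample_id`, `founder`, `proportion`,
#'   `n_snps`, `rss`; missing windows carry NA proportions.
#' @export
infer_all_windows <- function(panel, samples, grid, min_snps = 10,
                              min_depth = 1,
                              weights = c("depth", "equal"),
                              founder_tol = 0.05, verbose = FALSE) {
  weights <- match.arg(weights)
  founders <- founder_cols(panel)
  clean <- clean_founder_panel(panel, founder_tol)
  sids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(sids)) stop("duplicate sample ids")
  # intersect SNP universe across panel and all samples
  key <- paste(clean$chrom, clean$pos)
  sample_idx <- lapply(samples, function(s) {
    match(key, paste(s$counts$chrom, s$counts$pos))
  })
  shared <- Reduce(`&`, lapply(sample_idx, function(i) !is.na(i)))
  clean <- clean[shared, , drop = FALSE]
  sample_idx <- lapply(sample_idx, function(i) i[shared])
  out <- list()
  for (ch in unique(grid$chrom)) {
    g <- grid[grid$chrom == ch, ]
    pi <- which(clean$chrom == ch)
    o <- pi[order(clean$cM[pi])]
    fmat <- as.matrix(clean[o, founders, drop = FALSE])
    refm <- vapply(seq_along(samples), function(j) {
      as.numeric(samples[[j]]$counts$ref_count[sample_idx[[j]][o]])
    }, numeric(length(o)))
    depm <- vapply(seq_along(samples), function(j) {
      cc <- samples[[j]]$counts
      as.numeric((cc$ref_count + cc$alt_count)[sample_idx[[j]][o]])
    }, numeric(length(o)))
    res <- infer_windows_cpp(fmat, clean$cM[o],
                             matrix(as.integer(refm), ncol = length(samples)),
                             matrix(as.integer(depm), ncol = length(samples)),
                             g$start_cM, g$end_cM,
                             as.integer(min_depth), as.integer(min_snps),
                             weights == "depth")
    nw <- nrow(g)
    ns <- length(samples)
    nf <- length(founders)
    # props rows are ordered window-major then sample
    out[[ch]] <- data.frame(
      chrom = ch,
      center_cM = rep(g$center_cM, each = ns * nf),
      center_bp = rep(g$center_bp, each = ns * nf),
      sample_id = rep(rep(sids, each = nf), times = nw),
      founder = rep(founders, times = nw * ns),
      proportion = as.vector(t(res$props)),
      n_snps = rep(as.vector(t(res$n_snps)), each = nf),
      rss = rep(as.vector(t(res$rss)), each = nf))
    n_missing <- sum(res$n_snps < min_snps)
    if (verbose)
      message(sprintf("chromosome %s: %d windows x %d samples, %d missing",
                      ch, nw, ns, n_missing))
    if (n_missing == nw * ns)
      warning("chromosome '", ch, "': all windows missing")
  }
  freqs <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(freqs, "founders") <- founders
  attr(freqs, "samples") <- sample_metadata(samples)
  class(freqs) <- c("window_freqs", "data.frame")
  freqs
}
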