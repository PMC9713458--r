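#' Arcsine square-root transform
#'
#' The variance-stabilizing transform for proportions,
#' `asin(sqrt(p))`, applied to haplotype frequencies before the scan
#' ANOVA. Values outside `[0, 1]` by more than 1e-9 are an error;
#' within that tolerance they are clamped.
#'
#' @param p proportions in `[0, 1]` (vectorized).
#' @return Transformed values in `[0, pi/2]`.
#' @examples
#' asf_transform(c(0, 0.5, 1))  # 0, pi/4, pi/2
#' @export
asf_transform <- function(p) {
  if (any(p < -1e-9 | p > 1 + 1e-9, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(pmin(pmax(p, 0), 1)))
}

#' Replicated ANOVA for one window
#'
#' Tests for consistent haplotype-frequency differentiation between
#' treatments: with transformed frequencies `ASF[r, h, t]` for
#' replicate r = 1..R, haplotype h = 1..F and treatment t in
#' {control, selected}, fits the balanced factorial decomposition and
#' tests the haplotype-by-treatment interaction. Under the default
#' `"three-way"` error stratum the statistic is
#' `F = MS(HxT) / MS(RxHxT)` on `(F-1)(T-1)` and `(R-1)(F-1)(T-1)`
#' degrees of freedom (7 and 21 for R = 4, F = 8, T = 2); the
#' `"pooled"` alternative pools every replicate-involving stratum into
#' the denominator (df2 = (R-1)FT).
#'
#' @param asf numeric 3-d array, dimensions (replicate, haplotype,
#'   treatment), balanced with one observation per cell.
#' @param error_stratum `"three-way"` (default) or `"pooled"`.
#' @return `list(Fstat, df1, df2, neglog10p, p)`.
#' @export
anova_window <- function(asf, error_stratum = c("three-way", "pooled")) {
  error_stratum <- match.arg(error_stratum)
  d <- dim(asf)
  if (length(d) != 3) stop("asf must be a 3-d array (R x H x T)")
  R <- d[1]; H <- d[2]; Tt <- d[3]
  if (R < 2) stop("need R >= 2 replicates (error stratum undefined)")
  if (H < 2 || Tt < 2) stop("need >= 2 haplotypes and 2 treatments")
  if (anyNA(asf)) stop("asf array contains missing cells")
  m <- mean(asf)
  m_r <- apply(asf, 1, mean); m_h <- apply(asf, 2, mean)
  m_t <- apply(asf, 3, mean)
  m_rh <- apply(asf, c(1, 2), mean); m_rt <- apply(asf, c(1, 3), mean)
  m_ht <- apply(asf, c(2, 3), mean)
  ss_ht <- R * sum((m_ht - outer(m_h, rep(1, Tt)) -
                      outer(rep(1, H), m_t) + m)^2)
  resid3 <- asf
  for (r in seq_len(R)) for (t in seq_len(Tt))
    resid3[r, , t] <- asf[r, , t] - m_rh[r, ] - m_rt[r, t] - m_ht[, t] +
      m_r[r] + m_h + m_t[t] - m
  ss_rht <- sum(resid3^2)
  df1 <- (H - 1) * (Tt - 1)
  if (error_stratum == "three-way") {
    ss_err <- ss_rht
    df2 <- (R - 1) * (H - 1) * (Tt - 1)
  } else {
    ss_r <- H * Tt * sum((m_r - m)^2)
    ss_rh <- Tt * sum((m_rh - outer(m_r, rep(1, H)) -
                         outer(rep(1, R), m_h) + m)^2)
    ss_rt <- H * sum((m_rt - outer(m_r, rep(1, Tt)) -
                        outer(rep(1, R), m_t) + m)^2)
    ss_err <- ss_r + ss_rh + ss_rt + ss_rht
    df2 <- (R - 1) * H * Tt
  }
  if (ss_err <= 0) {
    if (ss_ht <= 1e-300)
      return(list(Fstat = 0, df1 = df1, df2 = df2, neglog10p = 0, p = 1))
    return(list(Fstat = Inf, df1 = df1, df2 = df2, neglog10p = Inf, p = 0))
  }
  Fstat <- (ss_ht / df1) / (ss_err / df2)
  logp <- pf(Fstat, df1, df2, lower.tail = FALSE, log.p = TRUE)
  list(Fstat = Fstat, df1 = df1, df2 = df2,
       neglog10p = -logp / log(10), p = exp(logp))
}

# Full balanced decomposition, used by the property tests.
anova_decompose <- function(asf) {
  d <- dim(asf); R <- d[1]; H <- d[2]; Tt <- d[3]
  m <- mean(asf)
  m_r <- apply(asf, 1, mean); m_h <- apply(asf, 2, mean)
  m_t <- apply(asf, 3, mean)
  m_rh <- apply(asf, c(1, 2), mean); m_rt <- apply(asf, c(1, 3), mean)
  m_ht <- apply(asf, c(2, 3), mean)
  resid3 <- asf
  for (r in seq_len(R)) for (t in seq_len(Tt))
    resid3[r, , t] <- asf[r, , t] - m_rh[r, ] - m_rt[r, t] - m_ht[, t] +
      m_r[r] + m_h + m_t[t] - m
  c(R = H * Tt * sum((m_r - m)^2),
    H = R * Tt * sum((m_h - m)^2),
    T = R * H * sum((m_t - m)^2),
    RH = Tt * sum((m_rh - outer(m_r, rep(1, H)) -
                     outer(rep(1, R), m_h) + m)^2),
    RT = H * sum((m_rt - outer(m_r, rep(1, Tt)) -
                    outer(rep(1, R), m_t) + m)^2),
    HT = R * sum((m_ht - outer(m_h, rep(1, Tt)) -
                    outer(rep(1, H), m_t) + m)^2),
    RHT = sum(resid3^2),
    total = sum((asf - m)^2))
}

#' Genome scan for treatment-driven haplotype differentiation
#'
#' Assembles, for every window with complete haplotype calls in all
#' samples, the R x F x 2 array of arcsine square-root transformed
#' founder frequencies -- each (experimental replicate, sex) pair is
#' one independent replicate r -- and runs [anova_window()], producing
#' the -log10(P) track along the genome. Windows missing in any sample
#' are skipped (and counted in attribute `n_skipped`).
#'
#' @param freqs a `window_freqs` table from [infer_all_windows()].
#' @param meta sample metadata data frame (`sample_id`, `replicate`,
#'   `sex`, `treatment`); defaults to the metadata recorded on `freqs`.
#' @param error_stratum passed to [anova_window()].
#' @return A `scan_track` data frame: `chrom`, `center_bp`,
#'   `center_cM`, `Fstat`, `df1`, `df2`, `neglog10p_raw`.
#' @export
scan_genome <- function(freqs, meta = attr(freqs, "samples"),
                        error_stratum = c("three-way", "pooled")) {
  error_stratum <- match.arg(error_stratum)
  if (is.null(meta)) stop("sample metadata required")
  meta$rep_unit <- paste(meta$replicate, meta$sex, sep = ":")
  units <- sort(unique(meta$rep_unit))
  for (u in units) {
    trts <- sort(meta$treatment[meta$rep_unit == u])
    if (!identical(trts, c("control", "selected")))
      stop("replicate unit ", u,
           " lacks a control/selected pair")
  }
  founders <- attr(freqs, "founders") %||% sort(unique(freqs$founder))
  nf <- length(founders)
  if (nf < 2) stop("need >= 2 founders")
  R <- length(units)
  sids <- meta$sample_id
  ns <- length(sids)
  key <- paste(freqs$chrom, freqs$center_cM)
  wkeys <- unique(key[order(match(freqs$chrom, unique(freqs$chrom)),
                            freqs$center_cM)])
  nW <- length(wkeys)
  wi <- match(key, wkeys)
  si <- match(freqs$sample_id, sids)
  fi <- match(freqs$founder, founders)
  ok <- !is.na(si) & !is.na(fi)
  arr <- array(NA_real_, dim = c(nf, ns, nW))
  arr[cbind(fi[ok], si[ok], wi[ok])] <- freqs$proportion[ok]
  first_row <- match(wkeys, key)
  chrom_w <- freqs$chrom[first_row]
  bp_w <- freqs$center_bp[first_row]
  cm_w <- freqs$center_cM[first_row]
  keep <- colSums(is.na(matrix(arr, nf * ns, nW))) == 0
  n_skipped <- sum(!keep)
  if (!any(keep)) stop("no complete windows to scan")
  asf <- asf_transform(arr[, , keep, drop = FALSE])
  r_of <- match(meta$rep_unit, units)
  t_of <- ifelse(meta$treatment == "control", 1L, 2L)
  nk <- sum(keep)
  if (error_stratum == "three-way") {
    # For T = 2, both interaction strata depend only on the per-(r, h)
    # treatment difference y: SS_HT = (R/2) sum_h (ybar_h - ybar)^2 and
    # SS_RHT = (1/2) sum_rh (y - ybar_h - ybar_r + ybar)^2 -- the
    # two-way decomposition of y, halved. Verified against
    # anova_window() in the tests.
    y <- matrix(0, nf * R, nk)  # rows indexed (h, r)
    for (j in seq_len(ns)) {
      rows <- (r_of[j] - 1L) * nf + seq_len(nf)
      sgn <- if (t_of[j] == 2L) 1 else -1
      y[rows, ] <- y[rows, ] + sgn * matrix(asf[, j, ], nf, nk)
    }
    dim(y) <- c(nf, R, nk)
    ybar_h <- rowMeans(aperm(y, c(1, 3, 2)), dims = 2)   # nf x nk
    ybar_r <- rowMeans(aperm(y, c(2, 3, 1)), dims = 2)   # R x nk
    ybar <- colMeans(ybar_h)
    ss_ht <- (R / 2) * colSums((ybar_h - rep(ybar, each = nf))^2)
    resid <- y
    for (r in seq_len(R))
      resid[, r, ] <- y[, r, ] - ybar_h -
        rep(ybar_r[r, ] - ybar, each = nf)
    ss_rht <- (1 / 2) * colSums(matrix(resid^2, nf * R, nk))
    df1 <- (nf - 1)
    df2 <- (R - 1) * (nf - 1)
    Fv <- ifelse(ss_rht > 0, (ss_ht / df1) / (ss_rht / df2),
                 ifelse(ss_ht <= 1e-300, 0, Inf))
    logp <- pf(Fv, df1, df2, lower.tail = FALSE, log.p = TRUE)
    nlp <- ifelse(is.finite(Fv), -logp / log(10),
                  ifelse(Fv == 0, 0, Inf))
    nlp[Fv == 0] <- 0
  } else {
    Fv <- nlp <- numeric(nk)
    for (k in seq_len(nk)) {
      a3 <- array(0, dim = c(R, nf, 2))
      for (j in seq_len(ns))
        a3[r_of[j], , t_of[j]] <- asf[, j, k]
      a <- anova_window(a3, error_stratum)
      Fv[k] <- a$Fstat
      nlp[k] <- a$neglog10p
      df1 <- a$df1; df2 <- a$df2
    }
  }
  track <- data.frame(chrom = chrom_w[keep], center_bp = bp_w[keep],
                      center_cM = cm_w[keep], Fstat = Fv,
                      df1 = df1, df2 = df2, neglog10p_raw = nlp)
  track <- track[order(match(track$chrom, unique(track$chrom)),
                       track$center_cM), ]
  rownames(track) <- NULL
  attr(track, "n_skipped") <- n_skipped
  attr(track, "error_stratum") <- error_stratum
  class(track) <- c("scan_track", "data.frame")
  track
}
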