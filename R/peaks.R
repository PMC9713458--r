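#' LOESS-smooth a scan track
#'
#' Locally weighted quadratic regression of the raw -log10(P) on cM
#' position, fitted independently per chromosome, to absorb
#' window-to-window variation in the test statistic before peaks are
#' called. Fitted values are clamped at 0.
#'
#' @param track a `scan_track` from [scan_genome()].
#' @param span LOESS span as a fraction of each chromosome's windows.
#' @return The track with a `neglog10p_smooth` column added.
#' @export
smooth_track <- function(track, span = 0.04) {
  track$neglog10p_smooth <- NA_real_
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch)
    if (length(i) < 10)
      stop("chromosome '", ch, "' has fewer than 10 windows; ",
           "cannot smooth")
    if (span * length(i) < 5)
      stop("span ", span, " leaves fewer than 5 points in the local ",
           "fit on '", ch, "'; increase span")
    fit <- loess(neglog10p_raw ~ center_cM, data = track[i, ],
                 span = span, degree = 2,
                 control = loess.control(surface = "direct"))
    track$neglog10p_smooth[i] <- pmax(predict(fit), 0)
  }
  class(track) <- c("scan_track", "data.frame")
  track
}

#' Call QTL peaks with LOD-drop confidence intervals
#'
#' Scans the smoothed track for maximal contiguous runs of windows at
#' or above `threshold`. Each run's peak is its maximum smoothed score
#' (ties broken leftmost). The confidence interval extends outward from
#' the peak in both directions -- past the end of the run if needed --
#' to the nearest window whose smoothed score is at least `drop` units
#' below the peak, truncated at chromosome ends. Calls on one
#' chromosome whose intervals overlap are merged (union interval,
#' higher peak retained; a message reports each merge).
#'
#' @param track a smoothed `scan_track` (see [smooth_track()]).
#' @param threshold genomewide -log10(P) significance threshold.
#' @param drop LOD-drop depth defining the interval.
#' @param map a [genetic_map()] for interval widths in cM.
#' @return A `qtl_calls` data frame: `chrom`, `peak_bp`, `peak_cM`,
#'   `ci_start_bp`, `ci_end_bp`, `width_mb`, `width_cM`, `peak_score`.
#' @export
call_peaks <- function(track, threshold = 4, drop = 3, map) {
  if (!"neglog10p_smooth" %in% names(track))
    stop("track must be smoothed first (smooth_track)")
  calls <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    tr <- tr[order(tr$center_cM), ]
    s <- tr$neglog10p_smooth
    above <- s >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    chrom_calls <- list()
    for (k in which(r$values)) {
      run <- starts[k]:ends[k]
      peak <- run[which.max(s[run])]          # leftmost max
      ps <- s[peak]
      cut <- ps - drop
      left <- peak
      while (left > 1 && s[left] > cut) left <- left - 1L
      right <- peak
      while (right < length(s) && s[right] > cut) right <- right + 1L
      chrom_calls[[length(chrom_calls) + 1L]] <-
        data.frame(chrom = ch, peak_bp = tr$center_bp[peak],
                   peak_cM = tr$center_cM[peak],
                   ci_start_bp = tr$center_bp[left],
                   ci_end_bp = tr$center_bp[right],
                   peak_score = ps)
    }
    cc <- do.call(rbind, chrom_calls)
    cc <- cc[order(cc$ci_start_bp), , drop = FALSE]
    merged <- cc[1, , drop = FALSE]
    for (i in seq_len(nrow(cc))[-1]) {
      last <- nrow(merged)
      if (cc$ci_start_bp[i] <= merged$ci_end_bp[last]) {
        message("merging overlapping QTL intervals on ", ch,
                " (peaks at ", merged$peak_bp[last], " and ",
                cc$peak_bp[i], " bp)")
        if (cc$peak_score[i] > merged$peak_score[last]) {
          merged$peak_bp[last] <- cc$peak_bp[i]
          merged$peak_cM[last] <- cc$peak_cM[i]
          merged$peak_score[last] <- cc$peak_score[i]
        }
        merged$ci_end_bp[last] <- max(merged$ci_end_bp[last],
                                      cc$ci_end_bp[i])
      } else {
        merged <- rbind(merged, cc[i, ])
      }
    }
    calls[[ch]] <- merged
  }
  out <- if (length(calls))
    do.call(rbind, c(calls, make.row.names = FALSE)) else
    data.frame(chrom = character(), peak_bp = numeric(),
               peak_cM = numeric(), ci_start_bp = numeric(),
               ci_end_bp = numeric(), peak_score = numeric())
  if (nrow(out)) {
    wm <- t(vapply(seq_len(nrow(out)), function(i) {
      unlist(interval_metrics(out$ci_start_bp[i], out$ci_end_bp[i], map,
                              out$chrom[i]))
    }, c(width_mb = 0, width_cM = 0)))
    out$width_mb <- wm[, "width_mb"]
    out$width_cM <- wm[, "width_cM"]
  } else {
    out$width_mb <- numeric()
    out$width_cM <- numeric()
  }
  out <- out[c("chrom", "peak_bp", "peak_cM", "ci_start_bp", "ci_end_bp",
               "width_mb", "width_cM", "peak_score")]
  rownames(out) <- NULL
  class(out) <- c("qtl_calls", "data.frame")
  out
}

#' Physical and genetic width of a QTL interval
#'
#' Width in Mb is `(ci_end - ci_start) / 1e6` rounded to 2 decimals
#' (the convention used for reporting mapped intervals); width in cM is
#' the genetic-map distance between the endpoints.
#'
#' @param ci_start_bp,ci_end_bp interval endpoints (bp, 1-based).
#' @param map a [genetic_map()].
#' @param chrom chromosome of the interval.
#' @return `list(width_mb, width_cM)`.
#' @examples
#' gmap <- genetic_map("chr2R", c(1, 26e6), c(0, 52))
#' interval_metrics(10966645, 13213848, gmap, "chr2R")  # 2.25 Mb
#' @export
interval_metrics <- function(ci_start_bp, ci_end_bp, map, chrom) {
  if (ci_end_bp < ci_start_bp) stop("ci_end_bp must be >= ci_start_bp")
  a <- map[map$chrom == chrom, ]
  if (nrow(a) == 0) stop("chromosome '", chrom, "' absent from map")
  if (ci_start_bp < min(a$pos) || ci_end_bp > max(a$pos))
    stop("interval endpoints outside the mapped range of '", chrom, "'")
  list(width_mb = round((ci_end_bp - ci_start_bp) / 1e6, 2),
       width_cM = map_cm(map, chrom, ci_end_bp) -
         map_cm(map, chrom, ci_start_bp))
}

#' Per-founder frequency shifts through a QTL interval
#'
#' For every window inside the confidence interval and every founder,
#' the selected-minus-control proportion difference per replicate pair,
#' plus the cross-replicate mean (`rep = "mean"`). Because proportions
#' are simplex points, shifts sum to 0 across founders at every window
#' within each replicate.
#'
#' @param freqs a `window_freqs` table covering the interval.
#' @param qtl one row of a `qtl_calls` data frame.
#' @param meta sample metadata (defaults to the metadata on `freqs`).
#' @return Long data frame `chrom`, `center_cM`, `center_bp`,
#'   `founder`, `rep`, `shift`. Windows missing from `freqs` are
#'   reported in attribute `gaps`.
#' @export
haplotype_shift_table <- function(freqs, qtl,
                                  meta = attr(freqs, "samples")) {
  if (is.null(meta)) stop("sample metadata required")
  meta$rep_unit <- paste(meta$replicate, meta$sex, sep = ":")
  fq <- freqs[freqs$chrom == qtl$chrom &
                freqs$center_bp >= qtl$ci_start_bp &
                freqs$center_bp <= qtl$ci_end_bp, ]
  if (nrow(fq) == 0) stop("no windows inside the QTL interval")
  units <- sort(unique(meta$rep_unit))
  shifts <- list()
  for (u in units) {
    sel_id <- meta$sample_id[meta$rep_unit == u &
                               meta$treatment == "selected"]
    ctl_id <- meta$sample_id[meta$rep_unit == u &
                               meta$treatment == "control"]
    sel <- fq[fq$sample_id == sel_id, ]
    ctl <- fq[fq$sample_id == ctl_id, ]
    kk <- paste(sel$center_cM, sel$founder)
    ctl <- ctl[match(kk, paste(ctl$center_cM, ctl$founder)), ]
    shifts[[u]] <- data.frame(chrom = sel$chrom,
                              center_cM = sel$center_cM,
                              center_bp = sel$center_bp,
                              founder = sel$founder, rep = u,
                              shift = sel$proportion - ctl$proportion)
  }
  long <- do.call(rbind, c(shifts, make.row.names = FALSE))
  mkey <- paste(long$center_cM, long$founder)
  mu <- tapply(long$shift, mkey, mean)
  first <- long[!duplicated(mkey), ]
  mean_rows <- data.frame(chrom = first$chrom,
                          center_cM = first$center_cM,
                          center_bp = first$center_bp,
                          founder = first$founder, rep = "mean",
                          shift = as.numeric(
                            mu[paste(first$center_cM, first$founder)]))
  out <- rbind(long, mean_rows)
  out <- out[order(out$center_cM, out$rep, out$founder), ]
  rownames(out) <- NULL
  gaps <- unique(long$center_cM[is.na(long$shift)])
  attr(out, "gaps") <- gaps
  out
}
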