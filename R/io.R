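#' Read and write the founder panel TSV
#'
#' The founder table is tab-separated with header
#' `chrom pos ref alt <founder1> ... <founderF>`; founder columns hold
#' REF-allele frequencies in `[0, 1]` (~0 or ~1 for inbred founders).
#' Loading interpolates cM from the genetic map and normalizes row
#' order; writing drops the derived `cM` column so the pair round-trips
#' losslessly.
#'
#' @param path TSV path.
#' @param map a [genetic_map()] covering all chromosomes in the file.
#' @return `load_founder_panel()`: a [founder_panel()].
#' @export
load_founder_panel <- function(path, map) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  founder_panel(df, map)
}

#' @rdname load_founder_panel
#' @param panel a [founder_panel()].
#' @export
write_founder_panel <- function(panel, path) {
  out <- as.data.frame(panel)[c("chrom", "pos", "ref", "alt",
                                founder_cols(panel))]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load pooled samples from a sample sheet
#'
#' The sheet is a TSV `sample_id replicate sex treatment counts_path`;
#' each counts file is a TSV `chrom pos ref_count alt_count`. Relative
#' counts paths are resolved against the sheet's directory. Every
#' `(replicate, sex)` cell must contain exactly one control and one
#' selected sample.
#'
#' @param sample_sheet_path path to the sheet.
#' @return List of [pooled_sample()] objects.
#' @export
load_pooled_counts <- function(sample_sheet_path) {
  sheet <- read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate", "sex", "treatment", "counts_path")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = " "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_ids in sample sheet")
  bad <- setdiff(unique(sheet$treatment), c("control", "selected"))
  if (length(bad))
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "))
  cells <- split(sheet$treatment, interaction(sheet$replicate, sheet$sex,
                                              drop = TRUE, sep = ", sex "))
  for (cell in names(cells)) {
    trts <- sort(cells[[cell]])
    if (!identical(trts, c("control", "selected")))
      stop("replicate ", cell,
           ": need exactly one control and one selected sample")
  }
  base <- dirname(sample_sheet_path)
  lapply(seq_len(nrow(sheet)), function(i) {
    p <- sheet$counts_path[i]
    if (!file.exists(p)) p <- file.path(base, sheet$counts_path[i])
    if (!file.exists(p))
      stop("counts file not found: ", sheet$counts_path[i])
    counts <- read.delim(p, stringsAsFactors = FALSE)
    need_c <- c("chrom", "pos", "ref_count", "alt_count")
    if (!all(need_c %in% names(counts)))
      stop("counts file ", p, " must have columns: ",
           paste(need_c, collapse = " "))
    pooled_sample(sheet$sample_id[i], sheet$replicate[i], sheet$sex[i],
                  sheet$treatment[i], counts)
  })
}

#' Write pooled samples and their sample sheet
#'
#' Inverse of [load_pooled_counts()]: one `counts_<sample_id>.tsv` per
#' sample plus `samples.tsv`.
#'
#' @param samples list of [pooled_sample()] objects.
#' @param dir output directory.
#' @return Path of the sample sheet, invisibly.
#' @export
write_xqtl_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- sample_metadata(samples)
  meta$counts_path <- sprintf("counts_%s.tsv", meta$sample_id)
  for (i in seq_along(samples))
    write.table(samples[[i]]$counts, file.path(dir, meta$counts_path[i]),
                sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- file.path(dir, "samples.tsv")
  write.table(meta, sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sheet)
}

#' Export scan track and QTL calls
#'
#' Writes `scan.tsv` (`chrom center_bp center_cM neglog10p_raw
#' neglog10p_smooth`), `qtl.tsv` (one row per call), and `qtl.bed`
#' (0-based half-open BED intervals of the confidence intervals, score =
#' peak score).
#'
#' @param scan a `scan_track` (see [scan_genome()], [smooth_track()]).
#' @param qtls a `qtl_calls` data frame (see [call_peaks()]).
#' @param outdir output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
export_results <- function(scan, qtls, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  scan_path <- file.path(outdir, "scan.tsv")
  cols <- intersect(c("chrom", "center_bp", "center_cM",
                      "neglog10p_raw", "neglog10p_smooth"), names(scan))
  out <- as.data.frame(scan)[cols]
  num <- vapply(out, is.numeric, TRUE) & names(out) != "center_bp"
  out[num] <- lapply(out[num], signif, digits = 6)
  write.table(out, scan_path, sep = "\t", quote = FALSE, row.names = FALSE)

  qtl_path <- file.path(outdir, "qtl.tsv")
  qcols <- c("chrom", "peak_bp", "ci_start_bp", "ci_end_bp",
             "width_mb", "width_cM", "peak_score")
  qdf <- if (nrow(qtls)) as.data.frame(qtls)[qcols] else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(qcols))),
                    qcols)
  write.table(qdf, qtl_path, sep = "\t", quote = FALSE, row.names = FALSE)

  bed_path <- file.path(outdir, "qtl.bed")
  if (nrow(qtls)) {
    bed <- data.frame(chrom = qtls$chrom,
                      start = as.integer(qtls$ci_start_bp) - 1L,
                      end = as.integer(qtls$ci_end_bp),
                      name = sprintf("QTL_%s_%d", qtls$chrom,
                                     as.integer(qtls$peak_bp)),
                      score = round(qtls$peak_score, 3))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bed_path)
  }
  invisible(c(scan = scan_path, qtl = qtl_path, bed = bed_path))
}

#' Read a scan track written by [export_results()]
#'
#' @param path `scan.tsv` path.
#' @return A `scan_track` data frame.
#' @export
load_scan_track <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("scan_track", "data.frame")
  df
}

#' Read window haplotype frequencies written by [write_window_freqs()]
#'
#' @param path `freqs.tsv` path.
#' @return A `window_freqs` data frame.
#' @export
load_window_freqs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("window_freqs", "data.frame")
  df
}

#' @rdname load_window_freqs
#' @param freqs a `window_freqs` table (see [infer_all_windows()]).
#' @export
write_window_freqs <- function(freqs, path) {
  out <- as.data.frame(freqs)
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) signif(x, 7))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
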