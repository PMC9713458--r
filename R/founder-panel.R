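#' Founder allele panel
#'
#' The founder panel records, for every SNP, the REF-allele frequency in
#' each of the F sequenced inbred founder strains (expected ~0 or ~1),
#' plus physical (bp) and genetic (cM) coordinates. Internally it is a
#' data frame with columns `chrom`, `pos`, `ref`, `alt`, `cM`, then one
#' column per founder, sorted by (chrom, pos).
#'
#' @param df data frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   one numeric column per founder.
#' @param map a [genetic_map()] used to fill `cM`.
#' @return A `founder_panel` data frame.
#' @export
founder_panel <- function(df, map) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("founder panel needs columns: ", paste(need, collapse = " "))
  founders <- setdiff(names(df), c(need, "cM"))
  if (length(founders) < 2) stop("founder panel needs >= 2 founder columns")
  if (anyDuplicated(founders)) stop("founder names must be unique")
  fa <- as.matrix(df[founders])
  if (!is.numeric(fa) || anyNA(fa) || any(fa < 0 | fa > 1))
    stop("founder allele frequencies must be numeric in [0, 1]")
  missing_ch <- setdiff(unique(df$chrom), map_chroms(map))
  if (length(missing_ch))
    stop("chromosome(s) absent from genetic map: ",
         paste(missing_ch, collapse = ", "))
  df <- df[order(df$chrom, df$pos), c(need, founders), drop = FALSE]
  if (anyDuplicated(df[c("chrom", "pos")]))
    stop("duplicated SNP positions in founder panel")
  df$cM <- NA_real_
  for (ch in unique(df$chrom)) {
    i <- df$chrom == ch
    df$cM[i] <- map_cm(map, ch, df$pos[i])
  }
  df <- df[c("chrom", "pos", "ref", "alt", "cM", founders)]
  rownames(df) <- NULL
  attr(df, "founders") <- founders
  class(df) <- c("founder_panel", "data.frame")
  df
}

founder_cols <- function(panel) {
  attr(panel, "founders") %||%
    setdiff(names(panel), c("chrom", "pos", "ref", "alt", "cM"))
}

#' Simulate a founder SNP panel
#'
#' SNPs are placed at uniformly spaced bp positions at `snp_density` per
#' Mb; each founder's allele at each SNP is an independent Bernoulli(0.5)
#' draw, with monomorphic sites redrawn so every SNP segregates among
#' the founders. Founders are named A1..AF after the DSPR convention.
#'
#' @param config a [sim_config()].
#' @param map optional [genetic_map()]; defaults to [sim_genetic_map()].
#' @return A [founder_panel()].
#' @export
simulate_founder_panel <- function(config, map = sim_genetic_map(config)) {
  Fn <- config$n_founders
  per_chrom <- lapply(seq_len(nrow(config$chromosomes)), function(k) {
    ch <- config$chromosomes[k, ]
    L <- max(2L, round(ch$length_bp / 1e6 * config$snp_density))
    pos <- unique(round(seq(1, ch$length_bp, length.out = L)))
    alle <- matrix(rbinom(length(pos) * Fn, 1L, 0.5), ncol = Fn)
    repeat {
      mono <- rowSums(alle) %in% c(0L, Fn)
      if (!any(mono)) break
      alle[mono, ] <- rbinom(sum(mono) * Fn, 1L, 0.5)
    }
    colnames(alle) <- paste0("A", seq_len(Fn))
    base <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    alt <- c(A = "T", C = "G", G = "C", T = "A")[base]
    data.frame(chrom = ch$name, pos = pos, ref = base, alt = unname(alt),
               alle)
  })
  founder_panel(do.call(rbind, per_chrom), map)
}

#' Pooled sequencing sample
#'
#' Per-SNP REF/ALT read counts for one pooled DNA sample plus its
#' experimental metadata (replicate, sex, treatment).
#'
#' @param sample_id unique sample label.
#' @param replicate experimental replicate index.
#' @param sex sex label of the pool.
#' @param treatment `"control"` or `"selected"`.
#' @param counts data frame `chrom pos ref_count alt_count`.
#' @return A `pooled_sample`.
#' @export
pooled_sample <- function(sample_id, replicate, sex, treatment, counts) {
  need <- c("chrom", "pos", "ref_count", "alt_count")
  if (!all(need %in% names(counts)))
    stop("counts need columns: ", paste(need, collapse = " "))
  if (any(counts$ref_count < 0) || any(counts$alt_count < 0))
    stop("negative read counts in sample '", sample_id, "'")
  treatment <- match.arg(treatment, c("control", "selected"))
  counts <- counts[order(counts$chrom, counts$pos), need]
  rownames(counts) <- NULL
  structure(list(sample_id = as.character(sample_id),
                 replicate = as.integer(replicate),
                 sex = as.character(sex),
                 treatment = treatment,
                 counts = counts),
            class = "pooled_sample")
}

#' @rdname pooled_sample
#' @param x a `pooled_sample`.
#' @return `ref_freq()`: per-SNP REF read frequency (NA at zero depth).
#' @export
ref_freq <- function(x) {
  d <- x$counts$ref_count + x$counts$alt_count
  ifelse(d > 0, x$counts$ref_count / d, NA_real_)
}

#' @export
print.pooled_sample <- function(x, ...) {
  cat(sprintf("<pooled_sample %s: rep %d, sex %s, %s, %d SNPs>\n",
              x$sample_id, x$replicate, x$sex, x$treatment,
              nrow(x$counts)))
  invisible(x)
}

sample_metadata <- function(samples) {
  data.frame(sample_id = vapply(samples, `[[`, "", "sample_id"),
             replicate = vapply(samples, `[[`, 1L, "replicate"),
             sex = vapply(samples, `[[`, "", "sex"),
             treatment = vapply(samples, `[[`, "", "treatment"),
             stringsAsFactors = FALSE)
}
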