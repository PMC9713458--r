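#' Simulate recombinant founder mosaics
#'
#' A transmitted genome from an advanced-generation multiparent
#' intercross is modeled as a founder mosaic: breakpoints fall as a
#' Poisson process along the cM axis with rate `breakpoint_rate` per cM,
#' the founder of the first segment is uniform on `1..F`, and at every
#' breakpoint the new founder is uniform among the other `F - 1`. The
#' transition "add a uniform step on 1..F-1 modulo F" is exactly this
#' chain, which is what the vectorized implementation uses.
#'
#' `simulate_mosaic()` returns one genome as a `founder_mosaic`: a named
#' list with one segment table per chromosome, columns `start_cM` and
#' `founder`; segment k runs from its start to the next start (the last
#' to the chromosome end). `sim_mosaic_population()` is the flat batch
#' form used internally: `n` homologs for a single chromosome as one
#' data frame with a `homolog` id column.
#'
#' @param map a [genetic_map()].
#' @param config a [sim_config()].
#' @return `simulate_mosaic()`: a `founder_mosaic`.
#' @examples
#' cfg <- sim_config(chromosomes = data.frame(name = "c1",
#'   length_bp = 1e6, cM_per_Mb = 2))
#' m <- simulate_mosaic(sim_genetic_map(cfg), cfg)
#' @export
simulate_mosaic <- function(map, config) {
  out <- lapply(map_chroms(map), function(ch) {
    len <- diff(map_span_cm(map, ch))
    df <- sim_mosaic_population(1L, len, config$breakpoint_rate,
                                config$n_founders)
    df[c("start_cM", "founder")]
  })
  names(out) <- map_chroms(map)
  class(out) <- "founder_mosaic"
  out
}

#' @rdname simulate_mosaic
#' @param n number of homologs to draw.
#' @param len_cM chromosome length in cM.
#' @param rate breakpoints per cM.
#' @param n_founders number of founders F.
#' @return `sim_mosaic_population()`: data frame `homolog`, `start_cM`,
#'   `founder`, sorted by homolog then position.
#' @export
sim_mosaic_population <- function(n, len_cM, rate, n_founders) {
  stopifnot(n >= 1, len_cM > 0, rate > 0, n_founders >= 2)
  nb <- rpois(n, rate * len_cM)
  nseg <- nb + 1L
  homolog <- rep.int(seq_len(n), nseg)
  # breakpoint positions, sorted within homolog
  brk <- runif(sum(nb), 0, len_cM)
  brk_h <- rep.int(seq_len(n), nb)
  o <- order(brk_h, brk)
  brk <- brk[o]
  start <- numeric(length(homolog))
  is_first <- !duplicated(homolog)
  start[!is_first] <- brk
  # founder chain: start uniform, then +uniform(1..F-1) mod F per break
  step <- integer(length(homolog))
  if (sum(nb) > 0)
    step[!is_first] <- sample.int(n_founders - 1L, sum(nb), replace = TRUE)
  cs <- cumsum(step)
  cs <- cs - rep.int(cs[is_first], nseg)
  s0 <- rep.int(sample.int(n_founders, n, replace = TRUE), nseg)
  founder <- ((s0 - 1L + cs) %% n_founders) + 1L
  data.frame(homolog = homolog, start_cM = start, founder = founder)
}

# Flat diploid cohort for one config: per chromosome a segment table for
# 2n homologs (individual i owns homologs 2i-1 and 2i). This is the fast
# internal representation behind the user-facing founder_mosaic lists.
sim_cohort <- function(n_ind, map, config) {
  chs <- map_chroms(map)
  per_chrom <- lapply(chs, function(ch) {
    len <- diff(map_span_cm(map, ch))
    sim_mosaic_population(2L * n_ind, len, config$breakpoint_rate,
                          config$n_founders)
  })
  names(per_chrom) <- chs
  structure(list(n = n_ind, chrom = per_chrom), class = "mosaic_cohort")
}

# Convert a list of diploid individuals (each list(hap1=, hap2=) of
# founder_mosaic) to the flat cohort form.
as_cohort <- function(population) {
  if (inherits(population, "mosaic_cohort")) return(population)
  stopifnot(is.list(population), length(population) > 0)
  chs <- names(population[[1]]$hap1)
  per_chrom <- lapply(chs, function(ch) {
    segs <- lapply(seq_along(population), function(i) {
      ind <- population[[i]]
      rbind(cbind(homolog = 2L * i - 1L, ind$hap1[[ch]]),
            cbind(homolog = 2L * i, ind$hap2[[ch]]))
    })
    do.call(rbind, segs)
  })
  names(per_chrom) <- chs
  structure(list(n = length(population), chrom = per_chrom),
            class = "mosaic_cohort")
}

subset_cohort <- function(cohort, ids) {
  keep_h <- sort(c(2L * ids - 1L, 2L * ids))
  per_chrom <- lapply(cohort$chrom, function(df) {
    df <- df[df$homolog %in% keep_h, , drop = FALSE]
    df$homolog <- match(df$homolog, keep_h)
    rownames(df) <- NULL
    df
  })
  structure(list(n = length(ids), chrom = per_chrom),
            class = "mosaic_cohort")
}

# Founder dosage counts (F x Q) of all homologs in a cohort at sorted
# query cM positions on one chromosome.
cohort_founder_counts <- function(cohort, chrom, query_cM, n_founders) {
  df <- cohort$chrom[[chrom]]
  if (is.null(df)) stop("chromosome '", chrom, "' absent from cohort")
  nseg <- tabulate(df$homolog, nbins = 2L * cohort$n)
  offsets <- c(0L, cumsum(nseg))
  founder_counts_cpp(df$start_cM, as.integer(df$founder),
                     as.integer(offsets), query_cM,
                     as.integer(n_founders))
}

# Founder identity of every homolog at one cM position (length 2n).
founder_at <- function(cohort, chrom, cM) {
  df <- cohort$chrom[[chrom]]
  ok <- df$start_cM <= cM + 1e-12
  idx <- which(ok)
  idx <- idx[!duplicated(df$homolog[idx], fromLast = TRUE)]
  f <- integer(2L * cohort$n)
  f[df$homolog[idx]] <- df$founder[idx]
  f
}

#' Truncation selection at a planted causal site
#'
#' Each individual survives independently with probability
#' `invlogit(baseline_logit + e[f1] + e[f2])`, where `f1`/`f2` are its
#' founder haplotypes at the causal position. Returns all survivors as
#' the selected set, a simple random sample of `config$pool_size_control`
#' individuals from the full pre-selection cohort as the control set,
#' and the realized survival fraction.
#'
#' @param population a list of diploid individuals (each
#'   `list(hap1 =, hap2 =)` of [simulate_mosaic()] genomes) or an
#'   internal flat cohort.
#' @param causal a [causal_spec()].
#' @param map a [genetic_map()] (to place the causal bp on the cM axis).
#' @param config a [sim_config()].
#' @return `list(selected_ids, control_ids, survival_fraction)`.
#' @export
apply_selection <- function(population, causal, map, config) {
  cohort <- as_cohort(population)
  anchors <- map[map$chrom == causal$chrom, ]
  if (nrow(anchors) == 0 || causal$position_bp < min(anchors$pos) ||
      causal$position_bp > max(anchors$pos))
    stop("causal position outside chromosome '", causal$chrom, "'")
  pos_cm <- map_cm(map, causal$chrom, causal$position_bp)
  eff <- causal$founder_effects
  if (length(eff) != config$n_founders)
    stop("founder_effects must have length n_founders")
  f <- founder_at(cohort, causal$chrom, pos_cm)
  f1 <- f[seq(1, length(f), by = 2)]
  f2 <- f[seq(2, length(f), by = 2)]
  pr <- invlogit(causal$baseline_logit + eff[f1] + eff[f2])
  alive <- rbinom(cohort$n, 1L, pr) == 1L
  if (!any(alive))
    stop("no survivors: raise baseline_logit or cohort size")
  list(selected_ids = which(alive),
       control_ids = sort(sample.int(cohort$n,
                                     min(config$pool_size_control,
                                         cohort$n))),
       survival_fraction = mean(alive))
}

#' Sequence a pool of individuals
#'
#' Pool-seq read sampling at every SNP of the founder panel: the true
#' pooled REF frequency q is the mean founder allele over all 2n
#' homologs, depth is Poisson(`coverage`), and the REF count is
#' Binomial(depth, q). No sequencing-error model.
#'
#' @param panel a founder panel (see [simulate_founder_panel()]).
#' @param pool list of diploid individuals or an internal cohort.
#' @param coverage mean depth.
#' @param sample_id,replicate,sex,treatment sample metadata.
#' @return A `pooled_sample`: metadata plus a counts data frame
#'   `chrom pos ref_count alt_count`.
#' @export
sequence_pool <- function(panel, pool, coverage, sample_id = "pool",
                          replicate = 1L, sex = "F",
                          treatment = "control") {
  cohort <- as_cohort(pool)
  if (cohort$n == 0) stop("empty pool")
  founders <- founder_cols(panel)
  Fn <- length(founders)
  counts <- lapply(split(seq_len(nrow(panel)), panel$chrom), function(ii) {
    ch <- panel$chrom[ii[1]]
    q_cm <- panel$cM[ii]
    cnt <- cohort_founder_counts(cohort, ch, q_cm, Fn)      # F x L
    allele <- t(as.matrix(panel[ii, founders, drop = FALSE]))  # F x L
    q <- colSums(cnt * allele) / (2 * cohort$n)
    d <- rpois(length(ii), coverage)
    r <- rbinom(length(ii), d, q)
    data.frame(chrom = ch, pos = panel$pos[ii],
               ref_count = r, alt_count = d - r)
  })
  counts <- do.call(rbind, counts[unique(panel$chrom)])
  rownames(counts) <- NULL
  pooled_sample(sample_id, replicate, sex, treatment, counts)
}
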