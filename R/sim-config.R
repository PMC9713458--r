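#' Configuration for a synthetic X-QTL experiment
#'
#' Describes the world a simulated extreme-QTL experiment lives in: an
#' F-founder multiparent population, a genome of chromosome arms with a
#' constant cM/Mb rate each, a recombinant mosaic model, truncation
#' selection at optional causal sites, and pooled short-read sequencing.
#' Defaults emulate the 8-founder DSPR-derived design: 8 founders, five
#' ~25 Mb chromosome arms at 2 cM/Mb (~50 cM each), 4 replicate
#' control/selected pool pairs (2 experimental replicates x 2 sexes),
#' pools of 300 flies sequenced to ~40x.
#'
#' @param n_founders number of inbred founder haplotypes (>= 2).
#' @param chromosomes data frame with columns `name`, `length_bp`,
#'   `cM_per_Mb`.
#' @param snp_density SNPs per Mb segregating among founders.
#' @param breakpoint_rate expected recombination breakpoints per cM per
#'   transmitted genome; captures the accumulated generations of
#'   intercrossing in the outbred base population.
#' @param cohort_size individuals reared per replicate before selection.
#' @param pool_size_selected,pool_size_control individuals pooled for
#'   sequencing per treatment.
#' @param coverage mean sequencing depth per SNP (Poisson).
#' @param n_replicates number of control/selected pool pairs.
#' @param seed integer seed; one RNG stream drives the experiment.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(chromosomes = data.frame(name = "chr2L",
#'   length_bp = 5e6, cM_per_Mb = 2), cohort_size = 100,
#'   pool_size_selected = 30, pool_size_control = 30)
#' @export
sim_config <- function(n_founders = 8,
                       chromosomes = data.frame(
                         name = c("chrX", "chr2L", "chr2R", "chr3L", "chr3R"),
                         length_bp = 25e6,
                         cM_per_Mb = 2),
                       snp_density = 100,
                       breakpoint_rate = 0.5,
                       cohort_size = 700,
                       pool_size_selected = 300,
                       pool_size_control = 300,
                       coverage = 40,
                       n_replicates = 4,
                       seed = 1L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp", "cM_per_Mb") %in% names(chromosomes)))
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (snp_density <= 0) stop("snp_density must be > 0")
  if (breakpoint_rate <= 0) stop("breakpoint_rate must be > 0")
  if (coverage < 0) stop("coverage must be >= 0")
  if (any(chromosomes$length_bp <= 0) || any(chromosomes$cM_per_Mb <= 0))
    stop("chromosome lengths and cM/Mb rates must be > 0")
  if (cohort_size <= 0 || pool_size_selected <= 0 || pool_size_control <= 0)
    stop("cohort and pool sizes must be > 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  cfg <- list(n_founders = as.integer(n_founders),
              chromosomes = chromosomes,
              snp_density = snp_density,
              breakpoint_rate = breakpoint_rate,
              cohort_size = as.integer(cohort_size),
              pool_size_selected = as.integer(pool_size_selected),
              pool_size_control = as.integer(pool_size_control),
              coverage = coverage,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Specify a causal site for truncation selection
#'
#' Survival of individual i under selection is
#' `invlogit(baseline_logit + e[f1] + e[f2])` where `f1`, `f2` are the
#' founder haplotypes carried at the causal position on the two homologs
#' and `e` is `founder_effects` (log-odds scale). A zero effect vector
#' encodes the null model (survival independent of genotype).
#'
#' @param chrom chromosome name.
#' @param position_bp causal position (bp, 1-based).
#' @param founder_effects numeric length-F vector of log-odds effects.
#' @param baseline_logit scalar baseline log-odds of survival.
#' @return A `causal_spec` list.
#' @export
causal_spec <- function(chrom, position_bp, founder_effects,
                        baseline_logit = 0) {
  if (!all(is.finite(founder_effects)) || !is.finite(baseline_logit))
    stop("causal effects must be finite")
  cs <- list(chrom = as.character(chrom),
             position_bp = as.numeric(position_bp),
             founder_effects = as.numeric(founder_effects),
             baseline_logit = as.numeric(baseline_logit))
  class(cs) <- "causal_spec"
  cs
}

#' Default genetic map implied by a simulation config
#'
#' Two anchors per chromosome: (1 bp, 0 cM) and the chromosome end at
#' `length_bp * cM_per_Mb / 1e6` cM, i.e. a constant recombination rate.
#'
#' @param config a [sim_config()].
#' @return A [genetic_map()].
#' @export
sim_genetic_map <- function(config) {
  ch <- config$chromosomes
  genetic_map(chrom = rep(ch$name, each = 2),
              pos = as.vector(rbind(1, ch$length_bp)),
              cM = as.vector(rbind(0, ch$length_bp / 1e6 * ch$cM_per_Mb)))
}
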