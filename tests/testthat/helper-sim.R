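# Shared fixture builders. Everything is generated in code; sizes are
# kept small so the default run stays fast.

tiny_config <- function(seed = 1, ...) {
  args <- list(
    chromosomes = data.frame(name = "c1", length_bp = 5e6, cM_per_Mb = 2),
    cohort_size = 110, pool_size_selected = 30, pool_size_control = 30,
    coverage = 40, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# One 25 Mb / 50 cM arm with the paper-scale pools, strong planted
# effect on founder 3. Used by the recovery tests.
qtl_config <- function(seed = 1, cohort_size = 3000) {
  sim_config(chromosomes = data.frame(name = "c1", length_bp = 25e6,
                                      cM_per_Mb = 2),
             cohort_size = cohort_size, seed = seed)
}

planted_causal <- function(pos_bp = 12.5e6, effect = 2, founder = 3,
                           n_founders = 8, baseline = -2) {
  eff <- rep(0, n_founders)
  eff[founder] <- effect
  causal_spec("c1", pos_bp, eff, baseline_logit = baseline)
}

# Run the full pipeline on a simulated experiment.
run_pipeline <- function(sim, span = 0.04, threshold = 4, drop = 3,
                         min_snps = 10) {
  freqs <- infer_all_windows(sim$panel, sim$samples, sim$grid,
                             min_snps = min_snps)
  track <- smooth_track(scan_genome(freqs), span = span)
  qtls <- suppressMessages(call_peaks(track, threshold, drop, sim$map))
  list(freqs = freqs, track = track, qtls = qtls)
}

# A pool of identical homozygous founder-f individuals.
pure_founder_pool <- function(f, n_ind, map, config) {
  chs <- map_chroms(map)
  per_chrom <- lapply(chs, function(ch) {
    data.frame(homolog = seq_len(2L * n_ind), start_cM = 0,
               founder = as.integer(f))
  })
  names(per_chrom) <- chs
  structure(list(n = n_ind, chrom = per_chrom), class = "mosaic_cohort")
}

expect_simplex <- function(p, tol = 1e-6) {
  expect_true(all(p >= -1e-12))
  expect_equal(sum(p), 1, tolerance = tol)
}
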