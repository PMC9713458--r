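#' Simulate a complete X-QTL experiment
#'
#' End-to-end generator: founder panel, genetic map, `n_replicates`
#' control/selected pooled-sample pairs, and a truth record. Each
#' replicate rears a fresh cohort of `cohort_size` diploid recombinant
#' individuals, applies truncation selection at the causal site (if
#' any), pools `pool_size_selected` survivors and `pool_size_control`
#' randomly drawn cohort members, and sequences both pools. Replicate
#' pairs are labeled with alternating sexes so that, as in the DSPR
#' X-QTL design, `n_replicates = 4` reads as 2 experimental replicates
#' x 2 sexes. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param causal a [causal_spec()] or `NULL` for the null model
#'   (survival probability `invlogit(baseline)` for everyone; default
#'   baseline 0, i.e. 50% survival).
#' @param window_cm,step_cm window grid on which truth frequencies are
#'   recorded.
#' @return A list of class `xqtl_sim` with elements `panel`, `map`,
#'   `samples` (list of [pooled_sample()]), `grid`, and `truth`
#'   (causal spec, per-window true founder frequencies per pool, and
#'   realized survival fraction per replicate).
#' @examples
#' cfg <- sim_config(chromosomes = data.frame(name = "c1",
#'   length_bp = 5e6, cM_per_Mb = 2), cohort_size = 60,
#'   pool_size_selected = 20, pool_size_control = 20, seed = 7)
#' sim <- simulate_experiment(cfg)
#' @export
simulate_experiment <- function(config, causal = NULL,
                                window_cm = 1.5, step_cm = 0.05) {
  set.seed(config$seed)
  map <- sim_genetic_map(config)
  panel <- simulate_founder_panel(config, map)
  grid <- build_window_grid(map, window_cm, step_cm)
  if (is.null(causal))
    causal <- causal_spec(config$chromosomes$name[1], 1,
                          rep(0, config$n_founders), baseline_logit = 0)
  samples <- list()
  truth_freqs <- list()
  survival <- numeric(config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    exp_rep <- (r - 1L) %/% 2L + 1L
    sex <- c("F", "M")[(r - 1L) %% 2L + 1L]
    cohort <- sim_cohort(config$cohort_size, map, config)
    sel <- apply_selection(cohort, causal, map, config)
    survival[r] <- sel$survival_fraction
    if (length(sel$selected_ids) < config$pool_size_selected)
      stop(sprintf(paste0("replicate %d: only %d survivors < pool size %d; ",
                          "raise cohort_size or baseline_logit"),
                   r, length(sel$selected_ids), config$pool_size_selected))
    sel_ids <- sort(sample(sel$selected_ids, config$pool_size_selected))
    for (trt in c("control", "selected")) {
      ids <- if (trt == "control") sel$control_ids else sel_ids
      pool <- subset_cohort(cohort, ids)
      sid <- sprintf("rep%d_%s_%s", exp_rep, sex,
                     if (trt == "control") "ctrl" else "sel")
      samples[[sid]] <- sequence_pool(panel, pool, config$coverage,
                                      sample_id = sid, replicate = exp_rep,
                                      sex = sex, treatment = trt)
      truth_freqs[[sid]] <- pool_truth_freqs(pool, grid, config$n_founders,
                                             sid)
    }
  }
  truth <- list(causal = causal,
                freqs = do.call(rbind, c(truth_freqs,
                                         make.row.names = FALSE)),
                survival_fraction = survival)
  validate_truth(truth)
  structure(list(panel = panel, map = map, samples = unname(samples),
                 grid = grid, truth = truth),
            class = "xqtl_sim")
}

# True founder frequencies of a pool at the window-grid centers.
pool_truth_freqs <- function(pool, grid, n_founders, sample_id) {
  cohort <- as_cohort(pool)
  per_chrom <- lapply(unique(grid$chrom), function(ch) {
    g <- grid[grid$chrom == ch, ]
    cnt <- cohort_founder_counts(cohort, ch, g$center_cM, n_founders)
    freq <- cnt / (2 * cohort$n)
    data.frame(chrom = ch,
               center_cM = rep(g$center_cM, each = n_founders),
               sample_id = sample_id,
               founder = paste0("A", seq_len(n_founders)),
               freq = as.vector(freq))
  })
  do.call(rbind, per_chrom)
}

validate_truth <- function(truth) {
  s <- tapply(truth$freqs$freq,
              interaction(truth$freqs$chrom, truth$freqs$center_cM,
                          truth$freqs$sample_id, drop = TRUE), sum)
  if (any(abs(s - 1) > 1e-9) || any(truth$freqs$freq < 0))
    stop("internal error: truth frequencies are not simplex points")
  if (any(truth$survival_fraction < 0 | truth$survival_fraction > 1))
    stop("internal error: survival fraction outside [0, 1]")
  invisible(truth)
}

#' Write the outputs of a simulated experiment to disk
#'
#' Materializes exactly the files the pipeline reads back: founder
#' panel TSV, genetic map TSV, one read-count TSV per pooled sample, a
#' sample sheet, and `truth.json` (causal spec, per-window truth
#' frequencies, realized survival fractions).
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_founder_panel(sim$panel, file.path(dir, "founders.tsv"))
  write_genetic_map(sim$map, file.path(dir, "map.tsv"))
  write_xqtl_samples(sim$samples, dir)
  jsonlite::write_json(
    list(causal = unclass(sim$truth$causal),
         survival_fraction = sim$truth$survival_fraction,
         freqs = sim$truth$freqs),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
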