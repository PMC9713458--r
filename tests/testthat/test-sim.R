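test_that("simulated founder panel meets its construction contract", {
  set.seed(1)
  cfg <- tiny_config(snp_density = 100,
                     chromosomes = data.frame(name = "c1", length_bp = 1e6,
                                              cM_per_Mb = 2))
  panel <- simulate_founder_panel(cfg)
  expect_s3_class(panel, "founder_panel")
  expect_equal(nrow(panel), 100)
  fa <- as.matrix(panel[founder_cols(panel)])
  expect_true(all(fa %in% c(0, 1)))
  # polymorphism: both alleles present at every SNP
  expect_true(all(rowSums(fa) > 0 & rowSums(fa) < ncol(fa)))
  expect_false(is.unsorted(panel$pos))
})

test_that("two-founder panels are forced to (0,1) or (1,0)", {
  set.seed(2)
  cfg <- tiny_config(n_founders = 2,
                     chromosomes = data.frame(name = "c1", length_bp = 1e6,
                                              cM_per_Mb = 2))
  panel <- simulate_founder_panel(cfg)
  fa <- as.matrix(panel[founder_cols(panel)])
  expect_true(all(rowSums(fa) == 1))
})

test_that("founder alleles are Bernoulli(0.5) overall", {
  set.seed(3)
  cfg <- tiny_config(snp_density = 400,
                     chromosomes = data.frame(name = "c1", length_bp = 25e6,
                                              cM_per_Mb = 2))
  panel <- simulate_founder_panel(cfg)  # 10,000 SNPs x 8 founders
  fa <- as.matrix(panel[founder_cols(panel)])
  expect_gt(nrow(fa), 9000)
  expect_equal(mean(fa), 0.5, tolerance = 0.02)
  expect_error(tiny_config(snp_density = 0), "snp_density")
})

test_that("mosaic breakpoints follow the Poisson process", {
  set.seed(4)
  # 1,000 mosaics on a 50 cM chromosome at 0.5/cM: mean breaks = 25
  pop <- sim_mosaic_population(1000, 50, 0.5, 8)
  nseg <- tabulate(pop$homolog, 1000)
  expect_equal(mean(nseg - 1), 25, tolerance = 1.5)
  # segments tile [0, len): starts sorted within homolog, first at 0
  first <- !duplicated(pop$homolog)
  expect_true(all(pop$start_cM[first] == 0))
  expect_true(all(pop$start_cM >= 0 & pop$start_cM < 50))
  expect_true(all(diff(pop$start_cM)[diff(pop$homolog) == 0] > 0))
  # consecutive segments always switch founder
  same <- diff(pop$homolog) == 0
  expect_true(all(diff(pop$founder)[same] != 0))
})

test_that("marginal founder identity is uniform along the chromosome", {
  set.seed(5)
  cfg <- tiny_config()
  map <- sim_genetic_map(cfg)
  pop <- sim_mosaic_population(10000, 10, 0.5, 8)
  cohort <- structure(list(n = 5000, chrom = list(c1 = pop)),
                      class = "mosaic_cohort")
  for (cm in c(0, 4.3, 9.9)) {
    f <- xqtl:::founder_at(cohort, "c1", cm)
    expect_equal(unname(tabulate(f, 8) / 10000), rep(1 / 8, 8),
                 tolerance = 0.16)  # 1/8 +- 0.02 absolute
    expect_true(all(abs(tabulate(f, 8) / 10000 - 1 / 8) < 0.02))
  }
})

test_that("breakpoint rate near zero gives single-segment mosaics", {
  set.seed(6)
  cfg <- tiny_config(breakpoint_rate = 1e-9)
  m <- simulate_mosaic(sim_genetic_map(cfg), cfg)
  expect_s3_class(m, "founder_mosaic")
  expect_equal(nrow(m$c1), 1)
  expect_equal(m$c1$start_cM, 0)
})

test_that("selection matches the logistic survival model", {
  cfg <- tiny_config(cohort_size = 1000)
  map <- sim_genetic_map(cfg)
  # null: effects 0, baseline 0 -> survival ~ 0.5
  set.seed(7)
  cohort <- xqtl:::sim_cohort(1000, map, cfg)
  res <- apply_selection(cohort, causal_spec("c1", 2.5e6, rep(0, 8), 0),
                         map, cfg)
  expect_equal(res$survival_fraction, 0.5, tolerance = 0.1)
  expect_equal(length(res$control_ids), cfg$pool_size_control)
  # near-infinite effect for founder 1: survivors carry founder 1
  set.seed(8)
  eff <- c(20, rep(0, 7))
  res2 <- apply_selection(cohort, causal_spec("c1", 2.5e6, eff, -20),
                          map, cfg)
  pos_cm <- map_cm(map, "c1", 2.5e6)
  f <- xqtl:::founder_at(cohort, "c1", pos_cm)
  carriers <- which(f[seq(1, 2000, 2)] == 1 | f[seq(2, 2000, 2)] == 1)
  expect_true(all(res2$selected_ids %in% carriers))
  # baseline -2.944 -> survival 0.050
  set.seed(9)
  big <- xqtl:::sim_cohort(10000, map, tiny_config(cohort_size = 10000))
  res3 <- apply_selection(big, causal_spec("c1", 2.5e6, rep(0, 8), -2.944),
                          map, cfg)
  expect_equal(res3$survival_fraction, 0.050, tolerance = 0.14)
  expect_true(abs(res3$survival_fraction - 0.05) < 0.007)
  # impossible survival errors with advice
  set.seed(10)
  small <- xqtl:::sim_cohort(5, map, cfg)
  expect_error(
    apply_selection(small, causal_spec("c1", 2.5e6, rep(0, 8), -30),
                    map, cfg),
    "raise baseline_logit")
  expect_error(
    apply_selection(small, causal_spec("c1", 9e9, rep(0, 8), 0), map, cfg),
    "outside")
})

test_that("pooled sequencing reproduces pool allele frequencies", {
  set.seed(11)
  cfg <- tiny_config(snp_density = 20)
  map <- sim_genetic_map(cfg)
  panel <- simulate_founder_panel(cfg, map)
  # single homozygous founder-2 individual: REF freq equals its allele
  pool <- pure_founder_pool(2, 1, map, cfg)
  s <- sequence_pool(panel, pool, coverage = 30)
  d <- s$counts$ref_count + s$counts$alt_count
  obs <- ref_freq(s)[d > 0]
  expect_equal(obs, panel$A2[d > 0])
  # coverage 0: all depths zero (missing downstream)
  s0 <- sequence_pool(panel, pool, coverage = 0)
  expect_true(all(s0$counts$ref_count + s0$counts$alt_count == 0))
  # 50/50 mix of two founders differing at every SNP -> freq 0.5
  cfg2 <- tiny_config(n_founders = 2, snp_density = 20)
  panel2 <- simulate_founder_panel(cfg2, map)
  mix <- pure_founder_pool(1, 2, map, cfg2)
  mix$chrom$c1$founder[mix$chrom$c1$homolog > 2] <- 2L
  s2 <- sequence_pool(panel2, mix, coverage = 1000)
  expect_true(all(abs(ref_freq(s2) - 0.5) < 0.05))
})

test_that("simulate_experiment is deterministic and internally consistent", {
  cfg <- tiny_config(seed = 42)
  sim1 <- simulate_experiment(cfg)
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim1, sim2)
  expect_length(sim1$samples, 2 * cfg$n_replicates)
  meta <- xqtl:::sample_metadata(sim1$samples)
  expect_equal(sum(meta$treatment == "control"), cfg$n_replicates)
  expect_equal(sum(meta$treatment == "selected"), cfg$n_replicates)
  expect_equal(anyDuplicated(meta$sample_id), 0L)
  # truth frequencies are simplex points
  tf <- sim1$truth$freqs
  sums <- tapply(tf$freq, paste(tf$chrom, tf$center_cM, tf$sample_id), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(tf$freq >= 0))
})

test_that("null experiments show no systematic truth-level shift", {
  cfg <- tiny_config(seed = 77, cohort_size = 200, pool_size_selected = 80,
                     pool_size_control = 80)
  sim <- simulate_experiment(cfg)
  tf <- sim$truth$freqs
  meta <- xqtl:::sample_metadata(sim$samples)
  sel <- meta$sample_id[meta$treatment == "selected"]
  ctl <- meta$sample_id[meta$treatment == "control"]
  key <- function(d) paste(d$chrom, d$center_cM, d$founder)
  diffs <- unlist(lapply(seq_along(sel), function(i) {
    a <- tf[tf$sample_id == sel[i], ]
    b <- tf[tf$sample_id == ctl[i], ]
    a$freq - b$freq[match(key(a), key(b))]
  }))
  expect_gt(length(diffs), 200)
  se <- sd(diffs) / sqrt(length(diffs) / 8)  # windows overlap; crude n
  expect_lt(abs(mean(diffs)), 3 * max(se, 1e-3))
})

test_that("stronger effects shift the causal-window truth more", {
  shifts <- vapply(c(0.5, 1.5, 3), function(e) {
    out <- numeric(10)
    for (k in seq_len(10)) {
      cfg <- tiny_config(seed = 1000 * e + k, cohort_size = 650,
                         pool_size_selected = 150,
                         pool_size_control = 150)
      cs <- planted_causal(pos_bp = 2.5e6, effect = e, baseline = -1)
      sim <- simulate_experiment(cfg, cs)
      tf <- sim$truth$freqs
      at_pk <- tf[abs(tf$center_cM - 5) < 0.026 & tf$founder == "A3", ]
      meta <- xqtl:::sample_metadata(sim$samples)
      sel <- mean(at_pk$freq[at_pk$sample_id %in%
                               meta$sample_id[meta$treatment == "selected"]])
      ctl <- mean(at_pk$freq[at_pk$sample_id %in%
                               meta$sample_id[meta$treatment == "control"]])
      out[k] <- sel - ctl
    }
    mean(out)
  }, 0)
  expect_true(all(diff(shifts) > 0))
  expect_gt(shifts[3], 0.1)
})
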