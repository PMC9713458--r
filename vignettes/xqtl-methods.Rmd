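---
title: "Methods: haplotype-based extreme-QTL mapping from pooled sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based extreme-QTL mapping from pooled sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xqtl)
```

## The design this package analyses

Extreme-QTL (X-QTL) mapping discovers quantitative trait loci by
comparing allele or haplotype frequencies between pools of
phenotypically extreme individuals and matched control pools, instead
of phenotyping genotyped lines one by one. The concrete design `xqtl`
targets is the multiparent version used with DSPR-derived *Drosophila*
populations: an outbred, highly recombinant population descends from
F (typically 8) sequenced inbred founder strains, so every genomic
position in every fly carries one of at most F ancestral founder
haplotypes. A cohort is subjected to truncation selection (here the
motivating application is survival of a timed insecticide exposure),
survivors form the "selected" pool, an arbitrary sample of the same
cohort forms the "control" pool, and each pool is sequenced as bulk
DNA at modest depth (30--50x). Replicate pairs — in the motivating
design, 2 experimental replicates x 2 sexes, giving R = 4 — provide
the error stratum for inference.

The pipeline has four computational stages, each its own module:

1. **Window haplotype inference** — founder haplotype frequencies of
   every pool in sliding genetic-map windows, by constrained weighted
   least squares.
2. **Genome scan** — a replicated ANOVA per window on arcsine
   square-root transformed frequencies, testing for consistent
   treatment-driven differentiation.
3. **Peak calling** — LOESS smoothing of the score track, thresholding,
   and LOD-drop confidence intervals with per-founder shift summaries.
4. **Synthetic data** — a first-class generator for the whole design,
   used to calibrate and validate stages 1--3 without any external
   data.

## Window haplotype inference

Windows of `window_cm` = 1.5 cM step along each chromosome in
`step_cm` = 0.05 cM increments on the genetic-map axis; physical
coordinates come from piecewise-linear interpolation of the map
anchors. The grid is anchored at each chromosome's first mapped cM
(the origin is not identifiable from the design, so the first window
starts exactly at the map start).

Within a window, for one pooled sample, let `A` be the SNPs x founders
matrix of founder REF alleles, `y` the observed per-SNP REF read
frequencies, and `w` per-SNP weights. The frequency estimate is

```
p-hat = argmin sum_i w_i (y_i - sum_f A_if p_f)^2
        s.t.   p_f >= 0,  sum_f p_f = 1
```

solved exactly by an active-set quadratic program (not by penalized
augmentation), so the sum-to-one constraint holds to machine
precision. Founders that are identical across a whole window leave the
objective flat in their difference direction; the solver resolves such
ties by the minimum-norm solution, which splits the tied set's summed
proportion equally. Tests verify the optimum against an exhaustive
simplex grid search at 0.005 resolution.

Tunable parameters, with defaults and reasoning:

* `founder_tol` = 0.05 — inbred founders should be fixed (REF
  frequency 0 or 1) at every SNP; sites where any founder is further
  than 0.05 from fixation are residual heterozygosity or caller noise
  and are dropped, the rest rounded to exactly 0/1. SNPs monomorphic
  across founders carry no haplotype information and are dropped too.
* `min_depth` = 1 read — a SNP with no reads in a sample contributes
  nothing and is excluded for that sample.
* `min_snps` = 10 — below this the window is reported *missing* rather
  than estimated; with default simulated densities a 1.5 cM window
  holds ~75 usable SNPs.
* `weights` = `"depth"` — per-SNP read depth. The binomial sampling
  variance of `y_i` is `q(1-q)/d_i`; depth is its dominant,
  frequency-free driver. The exact weight definition used historically
  for this design is inherited from prior work and not restated, so an
  `"equal"` option is provided; both are exercised in tests, and the
  estimator is insensitive to the choice at the simulated depths.

## Genome scan

Per window, the F founder proportions of each pool are arcsine
square-root transformed (`asin(sqrt(p))`), the standard
variance-stabilizing transform for proportions; exact 0 and 1 map to 0
and pi/2 with no continuity correction. With replicates r = 1..R
(each experimental-replicate x sex pair is one unit, a deliberate
choice that gears the test toward effects consistent in both sexes),
haplotypes h = 1..F and treatments t in {control, selected}, the
balanced factorial decomposition of `ASF[r, h, t]` is computed and the
haplotype-by-treatment interaction is tested with the
replicate-by-haplotype-by-treatment stratum as error:

```
F = MS(HxT) / MS(RxHxT),   df = (F-1)(T-1), (R-1)(F-1)(T-1)
```

i.e. (7, 21) for the R = 4, F = 8, T = 2 design. The model sentence
this implements names the three-way interaction explicitly as the
error term; because a pooled-residual reading is also defensible, a
config switch (`error_stratum = "pooled"`, df2 = (R-1)FT = 48) is
provided. The default is the three-way stratum. Windows missing in any
sample are excluded from the track, not imputed: imputation would
manufacture replicate agreement exactly where the data are weakest.

Under the null the raw per-window p-values are well calibrated: over
well-separated windows (>= 3 cM apart) of simulated null genomes the
fraction below 0.05 is 0.05 within binomial tolerance (this is a
property test; a 2,400-window development run measured 0.054).

## Peak calling

The raw −log10(P) track is smoothed per chromosome by local quadratic
(LOESS) regression on the cM axis, then maximal runs of windows with
smoothed score >= `threshold` (default 4) become candidate QTL. The
peak is the run maximum (ties leftmost, deterministically); the
confidence interval walks outward from the peak — past the run
boundary if necessary, truncated at chromosome ends — to the nearest
window whose smoothed score has dropped `drop` (default 3) units below
the peak, at grid resolution with no sub-grid interpolation.
Overlapping intervals on one chromosome are merged (union interval,
higher peak kept, each merge logged) so one locus is not reported
twice. Interval width is reported as Mb rounded to two decimals and as
map cM.

**Smoothing span.** The span is the one genuinely open numerical
choice. The default is `span = 0.04` of each chromosome's windows:
with the default 0.05 cM step this makes the local fit cover ~2 cM,
i.e. smoothing mild relative to the 1.5 cM estimation window — enough
to absorb window-to-window jitter of the statistic without flattening
real peaks. This was validated against the design's two calibration
facts (a genomewide false-positive rate of roughly 5% at threshold 4
under the null, and ~95% coverage of the causal position by 3-drop
intervals): substantially wider spans (e.g. 0.10, a ~5 cM local fit)
over-smooth — in 200-genome null calibration runs they drive the
genomewide false-positive rate from ~5% to ~0% and inflate interval
coverage toward 100% — because they average the score over several
times the window scale. Users smoothing very dense or very sparse
grids should adjust the span to keep the local fit near ~2 cM.

## The synthetic generator: what it states, and what it omits

`simulate_experiment()` generates the full design. Its defaults *are*
the stated world of the motivating experiment, and the calibration
tests run at exactly this scale:

* 8 founders; five 25 Mb chromosome arms at a constant 2 cM/Mb
  (~50 cM each, ~250 cM total — a fly-genome-scale autosomal
  complement).
* SNP density 100/Mb segregating among founders, alleles i.i.d.
  Bernoulli(0.5) with monomorphic sites redrawn. Real founder panels
  are denser (~10x) with correlated ancestry; 100/Mb keeps ~75 SNPs
  per window, far above `min_snps`, at desk cost.
* Transmitted genomes are founder mosaics from a Poisson breakpoint
  process at `breakpoint_rate` = 0.5/cM, founder of each new segment
  uniform among the other F−1. A single per-cM rate stands in for the
  full multigeneration intercross pedigree: the pipeline consumes only
  window-level haplotype frequencies, which this matches
  distributionally at far lower cost. The realized recombination
  density of a decades-maintained cage population is not published;
  0.5/cM (segments ~2 cM, comfortably spanning the 1.5 cM windows) is
  the modeling choice, exposed in the config.
* Individuals are diploid (two independent mosaics); pools count
  homologs. Survival under selection is logistic:
  `invlogit(baseline_logit + e[f1] + e[f2])` with additive founder
  effects at the causal site. Selected pools subsample the survivors
  to the configured pool size; controls are a simple random sample of
  the cohort.
* Sequencing is Poisson depth (mean `coverage` = 40) with binomial REF
  counts at the pool's true frequency. No sequencing error, mapping
  bias, or X-chromosome dosage: error at fixed founder sites is
  absorbed by the least-squares residual and is outside the model
  being tested.
* One RNG stream per experiment, seeded from the config; runs are
  byte-identical given the seed.

For the calibration suites, two scenario worlds are fixed: the *null*
world (no causal effect, baseline 0, cohorts of 700, pools of 300)
for false-positive calibration on the five-arm genome, and the
*single-QTL* world (one causal site, +2 log-odds on one founder over
baseline −2 — i.e. 12% background survival, truncation intensity
comparable to the motivating assay — cohorts of 3000, pools of 300,
one 50 cM arm) for interval coverage. The +2 effect was tuned once,
up front, to put smoothed peak scores in the 5--8 band that the
coverage claim refers to; the recovery tests use +3 as the "strong"
effect. Interval coverage concerns the causal chromosome only, so the
coverage suite simulates a single arm; the null suite, whose target is
genomewide, simulates all five.

A green calibration test therefore establishes that *under these
assumptions* the pipeline's p-values, threshold and intervals behave
as designed. It does not establish robustness to mapping bias, founder
mis-sequencing, density-dependent selection, or non-additive survival
effects — none of which the generator emulates.

## Numerical choices and degenerate inputs

* Simplex feasibility: estimates are clamped at 0 and renormalized
  after the active-set solve; deviations are below 1e-12 and the
  sum-to-one invariant is asserted at 1e-6 in tests.
* Singular windows (identical founders): pseudoinverse KKT solve,
  minimum-norm tie-break, degeneracy visible as equal shares.
* `asf_transform` clamps inputs within 1e-9 of [0, 1] and errors
  beyond; constant ANOVA arrays return p = 1 (0/0 convention), and a
  zero error stratum with nonzero effect returns p = 0.
* Zero-depth SNPs are missing for that sample; windows below
  `min_snps` are missing; chromosomes shorter than one window yield
  zero windows with a warning; chromosomes with fewer than 10 windows
  refuse to smooth.
* Half-up rounding (not banker's) for reported survival percentages,
  matching how such percentages are conventionally printed.
* Death times observed only as periodic counts are imputed at
  interval midpoints, with deaths before the first count assigned the
  midpoint of (0, t1) — the assay start is time 0 — and animals alive
  at the last count censored there. The Welch t-test takes
  already-filtered samples, so no policy about censored individuals is
  baked in.

## Known limitations

* The window estimator reports marginal founder proportions per
  window; it does not reconstruct individual mosaic genomes (no HMM)
  and does not impute missing windows.
* The scan assumes a balanced complete design; unbalanced designs
  (a lost pool) currently drop the window rather than refit.
* BED export is the only interval interchange format; no liftover,
  no multi-allelic SNPs, no CRAM/BAM ingestion — REF/ALT count tables
  are the pipeline's upstream boundary.
* The CLI accepts JSON configs (the environment provides no YAML
  parser); the schema mirrors `sim_config()` exactly.
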