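# rerrs

Profiling microbial communities from **restriction-enzyme
reduced-representation sequencing** (RE-RRS): the genotyping-by-sequencing
library design applied to metagenomes. Digesting community DNA with a
restriction enzyme and sequencing only the 65–195 bp fragments samples a
fixed, enzyme-determined fraction of every genome present, giving a cheap,
high-throughput community profile for hundreds of samples per lane. The
package is aimed at quantitative geneticists and microbiologists who want
to link such profiles to host traits — the motivating application is rumen
microbial profiles and methane yield (g CH4/kg dry-matter intake) in
sheep, measured twice per animal in cohorts.

It implements, end to end:

- **in-silico digestion** with ApeKI (`G|CWGC`) or PstI (`CTGCA|G`),
  inclusive 65–195 bp size selection, and per-genome capture statistics;
- **preprocessing**: inline-barcode demultiplexing anchored on the
  cut-site remnant, adapter/quality trimming with a 40 bp floor, a
  100,000-read sample QC rule, and host-mapping summaries from SAM flags
  (0/16);
- a **reference-free pipeline**: fixed-length tags (default 65 bp)
  starting at the cut site, a samples × tags count matrix, and prevalence
  filtering (default: present in ≥ 25% of samples);
- a **reference-based pipeline**: bitscore filtering (floor 50, top-10%
  window) of BLAST-style tabular hits and MEGAN-style
  lowest-common-ancestor assignment, genus profiles and hit-rate-by-rank
  summaries;
- **profile statistics**: log10 proportions, equal-weight (correlation)
  PCA, the within-cohort-standardised microbial relationship matrix
  (MRM), and contemporary-group scaling of methane yield to a 16.0 mean;
- **REML variance components** (average-information algorithm with EM
  warm start): repeatability `t = σ²_pe/(σ²_pe+σ²_e)`, bivariate
  phenotypic correlation
  `r_p = (σ_pe12+σ_e12)/√((σ²_pe1+σ²_e1)(σ²_pe2+σ²_e2))`, and
  microbiability `m² = σ²_m/(σ²_m+σ²_pe+σ²_e)` with `g ~ (0, MRM·σ²_m)`;
- **depth sensitivity**: Bernoulli subsampling at
  p = 0.5 … 0.001, DEFLATE compression efficiency
  `(original−compressed)/original` on sequences only, and knee detection
  for the lowest safe sequencing depth;
- a **synthetic community simulator** (genomes with controlled GC,
  repeated-measures designs, cohort/animal/methane structure, multiplexed
  FASTQ with truth tables) so the whole system is testable offline.

## Worked example

A fully synthetic run — 20 genomes, 8 animals × 2 samples in 2 cohorts,
20,000 ApeKI reads per sample — through the complete pipeline:

```r
library(rerrs)
cfg <- default_config(seed = 7, n_genomes = 20, n_animals = 8,
                      n_cohorts = 2, reads_per_sample = 20000,
                      min_reads = 1000, out_dir = "run1")
res <- run_pipeline(cfg)

ncol(res$counts_full)   # 14868 distinct 65 bp tags
ncol(res$counts)        # 558 tags present in >= 25% of samples
round(100 * mean(captured_fraction(res$counts_full, res$counts)), 1)
#> 94.3                 # % of reads captured by the filtered catalog
round(res$pca$pct_variance, 1)
#> 18.2 16.0            # % variance explained by PC1, PC2
res$fits$repeatability_pc1
#> REML fit: repeatability
#> repeatability = 0.754 (SE 0.165)
#> Cohort % variance = 1.4
```

The tag counts, PC scores, QC table, depth curve and a JSON manifest
(parameters, seeds, read-conservation counts, output checksums) are
written under `out_dir`. Interpretation: 94% of reads fall in tags shared
by ≥ 25% of samples; PC1 of the log10-proportion profile has an estimated
repeatability of 0.75 across the two sampling rounds (small-design SE
0.17), i.e. the profile axis is largely an animal-level signal. At this
shallow desk-scale depth the compression-efficiency curve is already
declining from the top, so `res$p_star` reports the largest probability —
deeper libraries show the plateau-then-knee shape (see the vignette).

Individual stages are exported (`find_cut_positions()`, `demultiplex()`,
`build_counts()`, `lca_assign()`, `build_mrm()`, `fit_microbiability()`,
`depth_curve()`, …) and a thin CLI wrapper lives at `inst/cli/rerrs.R`.

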