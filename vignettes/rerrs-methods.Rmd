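---
title: "Methods: restriction-enzyme reduced-representation metagenome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restriction-enzyme reduced-representation metagenome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rerrs)
```

## The problem

Restriction-enzyme reduced-representation sequencing (RE-RRS) applies the
genotyping-by-sequencing (GBS) library design to community DNA: genomic DNA
is digested with a restriction enzyme, fragments in a size window
(65–195 bp here) are sequenced as short single-end reads that begin at the
cut-site remnant, and inline barcodes multiplex a hundred or more samples
per lane. Because every genome in the community is sampled at a fixed,
enzyme-determined subset of its sequence, read counts over cut-site
fragments act as a cheap, high-throughput community profile. The package
implements the full analysis path for such data — from multiplexed FASTQ to
variance-component estimates linking rumen microbial profiles to methane
yield — plus a synthetic-community simulator so every stage can be tested
without external data.

Two enzymes with very different site densities are built in. ApeKI
(`G|CWGC`, a degenerate 5-mer) cuts roughly once per ~700 bp in 45–50% GC
sequence and therefore captures a large share of each genome at low
per-fragment depth; PstI (`CTGCA|G`, a 6-mer) cuts an order of magnitude
less often and concentrates depth on few fragments. On uniform random
genomes this contrast is extreme: a 50 kb genome typically yields several
ApeKI fragments in the 65–195 bp window but only ~0.25 expected PstI
fragments, so synthetic PstI studies need Mb-scale genomes. The package's
desk-scale defaults therefore use ApeKI; PstI paths are exercised on longer
genomes.

## Pipeline model

**Digestion.** Sites are matched on the top strand only; both built-in
recognition sequences are palindromic over IUPAC, so one strand suffices
and double counting is avoided. Overlapping sites all cut; `N` never
matches. Coordinates are 0-based half-open; fragments partition the
sequence at cut coordinates, and terminal fragments (lacking a cut site on
one end) are excluded from size selection by default because library
molecules need ligatable ends on both sides. The size window is inclusive
at both ends. `capture_fraction()` is the summed length of selected
internal fragments over genome length.

**Demultiplexing.** A read is assigned to a sample iff it starts with the
sample's barcode (up to a configurable number of substitutions, default 0)
*immediately followed by the enzyme remnant matched exactly* (`W` accepts
A or T). Requiring the remnant even when barcode mismatches are tolerated
prevents barcode bleed between samples. Barcode sets must be prefix-free;
the barcode is stripped and the remnant retained, so downstream reads all
commence at the cut site.

**Trimming.** Adapter trimming removes 3' bases from the first exact match
of the full adapter internally, or of an adapter prefix of at least 5 bp
reaching the read end. Quality trimming then strips trailing bases below
Q20. This simple trailing-base rule (rather than a running-sum rule) is
used because the pipeline's contract only fixes the length floor: reads
shorter than 40 bp after trimming are discarded. Samples with fewer than
100,000 trimmed reads are dropped; the floor applies after trimming, and
counts are summed across lanes first.

**Reference-free tags.** A tag is the first `L` bases of a demultiplexed
read (L = 16, 32 or 65; default 65), so tags are anchored at the cut site
and include the remnant. Reads shorter than `L` and tags containing `N`
are skipped — padding would fabricate sequence. Tag counting streams one
sample at a time, holding only per-sample tag tables plus the merged
catalog. The prevalence filter retains tags present (count ≥ 1) in at
least a fraction of samples (default 25%, boundary inclusive), computed on
the samples that survive QC.

**Reference-based assignment.** Alignment hits (12-column tabular format)
are filtered per query by a minimum bitscore of 50, then by a window
keeping hits within 10% of the surviving maximum (both comparisons
inclusive; the window is applied after the floor, the MEGAN default
ordering). The read is assigned to the lowest common ancestor of the
distinct taxa among retained hits; duplicate hits to one subject collapse,
and no minimum-support parameter is applied. A read assigned at a node
counts at that node's rank and every ancestor rank, which makes hit rates
non-increasing from kingdom to species by construction.

## Profile statistics

Counts become log10 proportions by dividing by the sample's row sum.
Zero counts are the one genuinely open step: with ~60 genus features zeros
are rare, but tag matrices certainly contain them, and log10 of zero is
undefined. The default `add_one` policy uses Laplace smoothing,
`log10((count + 1) / (rowsum + n_features))`; policy `none` uses raw
proportions and refuses zeros. This choice is consequential for sparse tag
matrices and is therefore configurable and prominently documented.

PCA gives every feature equal weight by standardising columns before the
eigen-analysis (correlation PCA, computed by SVD via `prcomp(scale. =
TRUE)`). Zero-variance features are dropped with a warning. Scores are
defined up to sign, so tests compare absolute correlations.

The microbial relationship matrix (MRM) standardises each feature within
cohort (mean 0, sd 1; zero within-cohort variance gives standardised 0)
and correlates samples. Within-cohort centring makes the MRM invariant to
cohort-constant shifts in any feature. Because row-centring makes the
correlation matrix rank-deficient, the smallest eigenvalue is routinely at
numerical zero; if it falls below `1e-6` the diagonal is inflated by the
deficit and the matrix renormalised to unit diagonal (bending), keeping it
usable as a REML covariance. Methane yield is scaled by contemporary-group
mean and restored to the population mean of 16.0 g CH4/kg dry-matter
intake, preserving within-group rank order.

## Variance components

All three mixed models share one REML engine for linear variance
structures `V(θ) = Σ θ_i V_i`: ten EM-style multiplicative warm-start
iterations followed by average-information (AI) updates with step halving,
variances floored at `1e-6 · var(y)`, convergence at relative
log-likelihood change `< 1e-8` and parameter change `< 1e-6`, maximum 200
iterations. Standard errors of ratios come from the delta method on the
inverse AI matrix. Near a positive-definiteness boundary the AI matrix can
be singular; the engine then tries Levenberg–Marquardt-ridged steps and
finally plain gradient ascent, and flags a stall if no improving step
exists.

- **Repeatability**: `y = cohort (fixed) + animal PE (random) + residual`;
  `t = σ²_pe / (σ²_pe + σ²_e)`. The "percent of variance explained by
  cohort" for a fixed effect has no unique definition; the convention used
  is `100 · var(fitted cohort effects) / (var(fitted cohort effects) +
  σ²_pe + σ²_e)`.
- **Bivariate correlation**: fixed cohort per trait, unstructured 2×2
  animal-PE and residual covariances (both estimated);
  `r_p = (σ_pe12 + σ_e12) / sqrt((σ²_pe1 + σ²_e1)(σ²_pe2 + σ²_e2))`. When
  a stall is flagged the fit is polished by BFGS on a Cholesky
  parameterisation of the two 2×2 blocks, which reaches the boundary
  smoothly. Exactly collinear traits are a degenerate input — the REML
  likelihood is then unbounded along several boundary directions because
  the PE design is rank-deficient — so they are detected up front and
  reported directly as `r_p = ±1` with a boundary flag.
- **Microbiability**: `y = mean + g + pe + e` with `g ~ (0, MRM·σ²_m)`;
  `m² = σ²_m / (σ²_m + σ²_pe + σ²_e)`. With an identity MRM and i.i.d.
  data the `m`/`e` split is unidentified and the result carries a
  boundary/non-convergence flag rather than an arbitrary answer.

## Depth sensitivity

Reads are Bernoulli-subsampled at probabilities
0.5, 0.25, 0.1, 0.05, 0.01, 0.005, 0.002, 0.001 — sampling at probability
`p` corresponds to sequencing `1/p` times as many samples per lane.
Compression efficiency serialises sequences only (no identifiers or
qualities, one per line), compresses with DEFLATE in a gzip container at
the zlib default level 6 (the base-R `memCompress` setting), and reports
`(original − compressed) / original` bytes: a proxy for non-redundant
sequence information. Means and standard deviations are taken across five
replicates of the per-sample mean, with replicate seeds derived as
`seed + replicate index`. "Begins to drop" is operationalised as the
smallest `p` whose mean CE stays within 1% (relative, configurable) of the
largest-`p` plateau value. The knee's location depends on per-tag
coverage: it sits near the depth where coverage approaches 1, so shallow
desk-scale libraries knee at larger `p` than a production lane.

## What the simulator emulates — and what it does not

The generator reproduces the study conditions the statistics need: 118
animals by default, two samples per animal two weeks apart, four cohorts
(split as evenly as possible), prefix-free inline barcodes of 4–9 bp,
101 bp reads starting at the cut-site remnant with reverse-complement
emission from either fragment end at probability 1/2, a fixed adapter
suffix on molecules shorter than the read, constant Q30 qualities, and
uniform per-base substitution errors. Community log-abundance is
`base + cohort + animal + sample` with independent normal effects, so a
taxon's true log-abundance repeatability is
`σ²_animal / (σ²_animal + σ²_sample)` (0.5 at the defaults). Methane yield
is `16.0 · (1 + cv·u)` (cv = 0.15) where `u` mixes a microbial term — the
projection of the within-cohort-standardised log10 composition on a random
per-taxon methane axis — an animal PE term and residual noise; the
components are empirically orthogonalised so the microbial variance share
equals the requested microbiability exactly, and the realised share is
recorded.

Not emulated: PCR/GC amplification bias (fragments are drawn uniformly
within genome), indel errors, quality decay along the read, skewed tag
abundance distributions within a genome, chimeras, and real taxonomic
structure. Passing tests therefore demonstrate the correctness of the
algorithms and the identifiability of the statistical quantities under the
designed generating process — not robustness to the biases of real
libraries.

## Problem sizes and seeds

Unit and property tests run at small fixed sizes (tens of samples, 50 kb
genomes, hundreds to tens of thousands of reads) with fixed seeds; the
digestion and LCA oracles each check 1,000 random cases. Parameter
recovery runs 20 replicates at the full design size (118 animals × 2
samples); the reported recovery bands (±0.1 for repeatability at 95% of
replicates, ±0.15 for the correlation and microbiability at 90%) reflect
the sampling error a 236-record design implies. The acceptance script
re-runs the recoveries at 5 replicates and a full synthetic
16-sample × 20,000-read pipeline. All randomness flows from explicit
seeds through a helper that restores the caller's RNG state.

## Known limitations

- The REML engine is specialised to dense linear variance structures at a
  few hundred records; it is not a general mixed-model interface.
- Perfectly collinear traits and identity-MRM designs are reported as
  degenerate rather than estimated (see above).
- Alignment itself (BLAST, BWA) is out of scope: hit tables and SAM flags
  are ingested, not produced.
- The Laplace pseudo-count denominator `rowsum + n_features` shrinks
  proportions slightly for very sparse matrices; with policy `none` the
  profile reconstructs proportions exactly but requires strictly positive
  counts.
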