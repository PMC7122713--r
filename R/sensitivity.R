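# Sequencing-depth sensitivity analysis: Bernoulli read subsampling, the
# DEFLATE compression-efficiency statistic, depth curves with replicate
# spread, and lower-bound (knee) detection.

#' Bernoulli-subsample reads
#'
#' Each read is kept independently with probability `p`; order is
#' preserved and the subset is deterministic given the seed.
#'
#' @param reads a reads data.frame or a character vector of sequences.
#' @param p keep probability in `(0, 1]`.
#' @param seed integer RNG seed.
#' @return The retained reads (same type as the input).
#' @export
subsample_reads <- function(reads, p, seed = 1L) {
  if (p <= 0 || p > 1) stop_fmt("p must lie in (0, 1]")
  n <- if (is.data.frame(reads)) nrow(reads) else length(reads)
  keep <- with_seed(seed, stats::runif(n) < p)
  if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
}

#' Compression efficiency of a set of reads
#'
#' Serialises the sequences only -- one per line, no identifiers or
#' qualities -- compresses with DEFLATE in a gzip container (zlib default
#' level 6, the base `memCompress` setting) and returns
#' `(original - compressed) / original` in bytes: a proxy for the
#' non-redundant sequence information present.
#'
#' @param reads a reads data.frame or character vector of sequences.
#' @return Real in `[0, 1)`.
#' @export
compression_efficiency <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (!length(seqs)) stop_fmt("compression efficiency needs at least one read")
  raw <- charToRaw(paste0(paste(seqs, collapse = "\n"), "\n"))
  comp <- memCompress(raw, type = "gzip")
  (length(raw) - length(comp)) / length(raw)
}

#' Compression-efficiency depth curve
#'
#' For each subsampling probability, every sample's reads are subsampled
#' and compressed; the per-replicate statistic is the mean compression
#' efficiency across samples, and `n_replicates` replicates (seeds derived
#' as `seed + replicate index`) give the reported mean and standard
#' deviation. A replicate in which a sample's subsample is empty skips that
#' sample.
#'
#' @param per_sample_reads named list of per-sample sequence vectors (or
#'   reads data.frames).
#' @param probabilities subsampling probabilities, sorted descending, each
#'   in `(0, 1]` (default: the 8-point grid 0.5 ... 0.001).
#' @param n_replicates replicates per probability (default 5).
#' @param seed integer base seed.
#' @return data.frame of class `rerrs_depth_curve`: `p`, `mean_ce`,
#'   `sd_ce`, `n_replicates`.
#' @export
depth_curve <- function(per_sample_reads,
                        probabilities = c(0.5, 0.25, 0.1, 0.05, 0.01,
                                          0.005, 0.002, 0.001),
                        n_replicates = 5L, seed = 1L) {
  if (any(probabilities <= 0 | probabilities > 1)) {
    stop_fmt("probabilities must lie in (0, 1]")
  }
  if (is.unsorted(rev(probabilities))) {
    stop_fmt("probabilities must be sorted descending")
  }
  out <- lapply(seq_along(probabilities), function(pi) {
    p <- probabilities[pi]
    reps <- vapply(seq_len(n_replicates), function(r) {
      ces <- vapply(seq_along(per_sample_reads), function(si) {
        sub <- subsample_reads(per_sample_reads[[si]], p,
                               seed = seed + r + 1000L * pi + 100000L * si)
        n <- if (is.data.frame(sub)) nrow(sub) else length(sub)
        if (!n) return(NA_real_)
        compression_efficiency(sub)
      }, numeric(1))
      mean(ces, na.rm = TRUE)
    }, numeric(1))
    data.frame(p = p, mean_ce = mean(reps), sd_ce = stats::sd(reps),
               n_replicates = n_replicates)
  })
  structure(do.call(rbind, out), class = c("rerrs_depth_curve", "data.frame"))
}

#' Lower-bound sequencing depth from a compression-efficiency curve
#'
#' The plateau reference is the curve's largest probability; the lower
#' bound `p_star` is the smallest probability whose mean compression
#' efficiency is still within `epsilon` (relative) of the plateau -- the
#' depth at which compression efficiency "begins to drop".
#'
#' @param curve data.frame from [depth_curve()].
#' @param epsilon relative drop tolerance (default 0.01).
#' @return The lower-bound probability `p_star`.
#' @export
find_lower_bound <- function(curve, epsilon = 0.01) {
  if (!nrow(curve)) stop_fmt("empty depth curve")
  ref <- curve$mean_ce[which.max(curve$p)]
  qualifying <- curve$p[curve$mean_ce >= (1 - epsilon) * ref]
  min(qualifying)
}

#' Depth multiplier of a subsampling probability
#'
#' Sampling reads with probability `p` corresponds to sequencing `1/p`
#' times as many samples per lane at the same total output.
#'
#' @param p subsampling probability in `(0, 1]`.
#' @return `1 / p`.
#' @export
depth_multiplier <- function(p) {
  if (any(p <= 0 | p > 1)) stop_fmt("p must lie in (0, 1]")
  1 / p
}
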