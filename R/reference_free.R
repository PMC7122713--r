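# Reference-free profiling: cut-site-anchored tags, the cross-sample tag
# catalog / count matrix, and prevalence filtering.
#
# A "tag" is the first L bases of a demultiplexed read -- the read commences
# at the restriction cut site, so tags are anchored at cut sites and include
# the remnant bases. Tags with N, and reads shorter than L, are skipped
# (padding would fabricate sequence).

#' Extract cut-site tags from reads
#'
#' @param seqs character vector of post-barcode read sequences (or a reads
#'   data.frame, whose `seq` column is used).
#' @param L tag length in bp (the study grid is 16, 32 or 65; default 65).
#' @return Character vector of tags, `NA` where the read is shorter than
#'   `L` or its first `L` bases contain `N`.
#' @export
extract_tags <- function(seqs, L = 65L) {
  if (L <= 0L) stop_fmt("tag length must be positive")
  if (is.data.frame(seqs)) seqs <- seqs$seq
  tag <- substr(seqs, 1L, L)
  tag[nchar(tag) < L | grepl("N", tag, fixed = TRUE)] <- NA_character_
  tag
}

#' Build the samples x tags count matrix
#'
#' Counts, per sample, the reads whose extracted tag equals each tag in the
#' union of observed tags. Tags (features) are sorted lexicographically for
#' determinism. Reads are processed one sample at a time, so memory holds
#' only per-sample tag tables plus the merged catalog.
#'
#' @param per_sample_reads named list, sample id -> character vector of
#'   post-barcode read sequences (or reads data.frames).
#' @param L tag length in bp.
#' @return A count matrix ([count_matrix()]), samples in rows, tags in
#'   columns.
#' @export
build_counts <- function(per_sample_reads, L = 65L) {
  if (!length(per_sample_reads)) stop_fmt("at least one sample is required")
  if (is.null(names(per_sample_reads))) {
    stop_fmt("per_sample_reads must be named by sample id")
  }
  tabs <- lapply(per_sample_reads, function(r) {
    tags <- extract_tags(r, L)
    table(tags[!is.na(tags)])
  })
  catalog <- sort(unique(unlist(lapply(tabs, names), use.names = FALSE)))
  m <- matrix(0L, length(tabs), length(catalog),
              dimnames = list(names(tabs), catalog))
  for (s in names(tabs)) {
    t <- tabs[[s]]
    if (length(t)) m[s, names(t)] <- as.integer(t)
  }
  count_matrix(m)
}

#' Tag prevalence across samples
#'
#' @param m a count matrix.
#' @return Named integer vector: number of samples with count >= 1 per tag.
#' @export
tag_prevalence <- function(m) {
  colSums(m >= 1L)
}

#' Prevalence-filter a tag count matrix
#'
#' Retains tags present (count >= 1) in at least `min_prevalence` of the
#' samples; the boundary is inclusive. Sample rows are unchanged.
#'
#' @param m a count matrix.
#' @param min_prevalence required sample fraction in `(0, 1]` (the study
#'   grid is 0.10, 0.25, 0.50, 1.00; default 0.25).
#' @return The filtered count matrix.
#' @export
prevalence_filter <- function(m, min_prevalence = 0.25) {
  if (min_prevalence <= 0 || min_prevalence > 1) {
    stop_fmt("min_prevalence must lie in (0, 1]")
  }
  keep <- tag_prevalence(m) / nrow(m) >= min_prevalence
  m[, keep, drop = FALSE]
}

#' Fraction of reads captured by a tag catalog
#'
#' Share of per-sample reads whose tag survives filtering -- the statistic
#' reported per enzyme/pipeline as "% of reads captured".
#'
#' @param m_full unfiltered count matrix.
#' @param m_filtered prevalence-filtered count matrix.
#' @return Named numeric vector: per-sample captured fraction.
#' @export
captured_fraction <- function(m_full, m_filtered) {
  rowSums(m_filtered) / pmax(rowSums(m_full), 1L)
}
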