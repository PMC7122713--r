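# Pipeline front end: demultiplexing, trimming, sample QC, host-mapping
# summary.

#' Demultiplex reads by inline barcode and cut-site remnant
#'
#' A read is assigned to a sample iff it begins with that sample's barcode
#' (up to `max_mismatch` substitutions) immediately followed by the enzyme's
#' cut-site remnant, matched exactly (W in the remnant accepts A or T). The
#' barcode is stripped; the remnant is retained, so assigned reads begin at
#' the cut site. Everything else lands in the unassigned stream. Requiring
#' an exact remnant even when barcode mismatches are allowed prevents
#' barcode bleed.
#'
#' @param reads a reads data.frame ([reads_df()]).
#' @param barcode_map named character vector, barcode -> sample id; must be
#'   prefix-free.
#' @param enz an `rerrs_enzyme` supplying the remnant.
#' @param max_mismatch maximum barcode substitutions (default 0).
#' @return list with `assigned` (reads with `sample` filled and barcode
#'   stripped) and `unassigned`.
#' @export
demultiplex <- function(reads, barcode_map, enz, max_mismatch = 0L) {
  bcs <- names(barcode_map)
  if (is.null(bcs) || !length(bcs)) stop_fmt("barcode_map must be named")
  for (i in seq_along(bcs)) {
    clash <- startsWith(bcs[-i], bcs[i])
    if (any(clash)) {
      stop_fmt("barcode set is not prefix-free: %s is a prefix of %s",
               bcs[i], bcs[-i][clash][1L])
    }
  }
  remnant_re <- paste0("^", iupac_to_regex(enz$read_remnant))
  n <- nrow(reads)
  assigned_to <- rep(NA_character_, n)
  bc_len <- integer(n)
  for (b in bcs) {
    len <- nchar(b)
    open <- is.na(assigned_to)
    if (!any(open)) break
    pre <- substr(reads$seq[open], 1L, len)
    if (max_mismatch == 0L) {
      hit <- pre == b
    } else {
      hit <- mismatches(pre, b) <= max_mismatch & nchar(pre) == len
    }
    rem <- grepl(remnant_re, substr(reads$seq[open], len + 1L,
                                    len + nchar(enz$read_remnant)))
    ok <- hit & rem
    ii <- which(open)[ok]
    assigned_to[ii] <- barcode_map[[b]]
    bc_len[ii] <- len
  }
  hit <- !is.na(assigned_to)
  assigned <- reads[hit, , drop = FALSE]
  if (nrow(assigned)) {
    assigned$seq <- substr(assigned$seq, bc_len[hit] + 1L,
                           nchar(assigned$seq))
    assigned$qual <- substr(assigned$qual, bc_len[hit] + 1L,
                            nchar(assigned$qual))
    assigned$sample <- assigned_to[hit]
  }
  list(assigned = assigned, unassigned = reads[!hit, , drop = FALSE])
}

# Hamming distance between equal-length string vectors and one pattern.
mismatches <- function(x, pat) {
  pc <- strsplit(pat, "", fixed = TRUE)[[1]]
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    if (length(ch) != length(pc)) return(length(pc) + 1L)
    sum(ch != pc)
  }, integer(1))
}

#' Adapter and quality trimming
#'
#' 3' bases are removed from the first exact match of an adapter prefix --
#' either the full adapter internally, or at least `min_overlap` bases of
#' the adapter's start reaching the read end. Trailing bases with quality
#' below `quality_cutoff` are then removed, and reads shorter than
#' `min_len` are discarded. Idempotent.
#'
#' @param reads a reads data.frame.
#' @param adapter adapter sequence (non-empty).
#' @param min_len minimum retained read length (default 40).
#' @param quality_cutoff Phred cutoff for 3' quality trimming (default 20).
#' @param min_overlap minimum adapter-prefix overlap at the read end
#'   (default 5).
#' @return The trimmed reads data.frame (discarded reads removed).
#' @export
trim_reads <- function(reads, adapter, min_len = 40L, quality_cutoff = 20L,
                       min_overlap = 5L) {
  if (!nzchar(adapter)) stop_fmt("adapter must be non-empty")
  n <- nrow(reads)
  if (!n) return(reads)
  len <- nchar(reads$seq)
  cut_at <- rep(Inf, n) # first adapter position (1-based); Inf = none
  # full adapter anywhere
  pos <- regexpr(adapter, reads$seq, fixed = TRUE)
  cut_at[pos > 0L] <- pos[pos > 0L]
  # adapter prefix of length k .. reaching exactly the read end
  overlaps <- if (nchar(adapter) - 1L >= min_overlap) {
    min_overlap:(nchar(adapter) - 1L)
  } else integer(0)
  for (k in overlaps) {
    pre <- substr(adapter, 1L, k)
    hit <- endsWith(reads$seq, pre)
    cand <- len - k + 1L
    upd <- hit & cand < cut_at
    cut_at[upd] <- cand[upd]
  }
  keep_len <- ifelse(is.finite(cut_at), cut_at - 1L, len)
  seqs <- substr(reads$seq, 1L, keep_len)
  quals <- substr(reads$qual, 1L, keep_len)
  # 3' quality trimming: drop trailing bases with Q < cutoff
  q <- lapply(quals, function(s) utf8ToInt(s) - 33L)
  keep_len2 <- vapply(q, function(v) {
    i <- length(v)
    while (i > 0L && v[i] < quality_cutoff) i <- i - 1L
    i
  }, integer(1))
  seqs <- substr(seqs, 1L, keep_len2)
  quals <- substr(quals, 1L, keep_len2)
  ok <- keep_len2 >= min_len
  out <- reads[ok, , drop = FALSE]
  out$seq <- seqs[ok]
  out$qual <- quals[ok]
  out
}

#' Sample-level read-count QC
#'
#' Samples with fewer than `min_reads` trimmed reads (summed across lanes
#' beforehand) are flagged for removal; the floor is strict (`count >=
#' min_reads` keeps the sample).
#'
#' @param counts named integer vector, sample id -> trimmed read count.
#' @param min_reads minimum read count to retain a sample (default 100000).
#' @param raw_counts optional named vector of pre-trimming counts.
#' @return data.frame `sample_id`, `raw_reads`, `trimmed_reads`, `kept`.
#' @export
sample_qc <- function(counts, min_reads = 100000L, raw_counts = NULL) {
  if (is.null(names(counts))) stop_fmt("counts must be named by sample")
  raw <- if (is.null(raw_counts)) counts else raw_counts[names(counts)]
  if (any(counts > raw)) stop_fmt("trimmed counts exceed raw counts")
  data.frame(
    sample_id = names(counts),
    raw_reads = as.integer(raw),
    trimmed_reads = as.integer(counts),
    kept = as.integer(counts) >= min_reads,
    stringsAsFactors = FALSE
  )
}

#' Host-mapped read fraction from SAM records
#'
#' Counts alignment records whose FLAG is exactly 0 or exactly 16 (uniquely
#' mapped, forward or reverse orientation) and divides by the sample's total
#' read count. Accepts a path to a text SAM file or a numeric vector of
#' flags.
#'
#' @param sam path to a SAM file, or an integer vector of FLAG values.
#' @param total_reads total reads for the sample (> 0).
#' @return Real in `[0, 1]`.
#' @export
host_fraction <- function(sam, total_reads) {
  if (total_reads <= 0) stop_fmt("total_reads must be positive")
  flags <- if (is.numeric(sam)) {
    as.integer(sam)
  } else {
    lines <- readLines(sam, warn = FALSE)
    lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
    if (!length(lines)) integer(0) else {
      as.integer(vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 2L))
    }
  }
  sum(flags == 0L | flags == 16L) / total_reads
}
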