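# In-silico restriction digestion and fragment size selection.
#
# RE-RRS libraries sequence only fragments cut on both ends and falling in a
# size window, so the digestion model here drives both enzyme evaluation
# (capture statistics) and the read simulator. Coordinates are 0-based
# half-open throughout; scanning is top-strand only, which suffices for the
# built-in enzymes because their sites are palindromic over IUPAC.

#' Define a restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition IUPAC recognition sequence (A/C/G/T/W supported).
#' @param cut_offset cut position within the site: the cut falls between
#'   offsets `cut_offset - 1` and `cut_offset` of the site on the top strand.
#' @param read_remnant the site remnant that begins every sequenced read
#'   after barcode removal (may contain W).
#' @return An object of class `rerrs_enzyme`.
#' @export
enzyme <- function(name, recognition, cut_offset, read_remnant) {
  if (!grepl("^[ACGTW]+$", recognition)) {
    stop_fmt("recognition sequence must be over {A,C,G,T,W}")
  }
  if (cut_offset < 0 || cut_offset > nchar(recognition)) {
    stop_fmt("cut_offset must lie in 0..len(recognition)")
  }
  if (!grepl("^[ACGTW]+$", read_remnant)) {
    stop_fmt("read remnant must be over {A,C,G,T,W}")
  }
  structure(
    list(name = name, recognition = recognition,
         cut_offset = as.integer(cut_offset), read_remnant = read_remnant),
    class = "rerrs_enzyme"
  )
}

#' @export
print.rerrs_enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "|",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat("Restriction enzyme", x$name, ":", site,
      "(read remnant", paste0(x$read_remnant, ")"), "\n")
  invisible(x)
}

#' Built-in enzymes
#'
#' `ApeKI` cuts `G|CWGC` (5-bp site, W = A/T) and leaves remnant `CWGC`;
#' `PstI` cuts `CTGCA|G` (6-bp site) and leaves remnant `TGCAG`. ApeKI's
#' shorter, degenerate site cuts far more often, capturing more of each
#' genome at lower per-fragment depth than PstI.
#'
#' @param name `"ApeKI"` or `"PstI"` (case-insensitive).
#' @return An `rerrs_enzyme`.
#' @export
get_enzyme <- function(name) {
  switch(toupper(name),
    "APEKI" = enzyme("ApeKI", "GCWGC", 1L, "CWGC"),
    "PSTI"  = enzyme("PstI", "CTGCAG", 5L, "TGCAG"),
    stop_fmt("unknown enzyme '%s' (built-ins: ApeKI, PstI)", name)
  )
}

#' Find restriction cut positions in a sequence
#'
#' Scans the top strand for every (possibly overlapping) match of the
#' recognition site; `N` in the sequence never matches. Returns the 0-based
#' cut coordinates (`site_start + cut_offset`), strictly increasing.
#'
#' @param seq a DNA string over `A,C,G,T,N`.
#' @param enz an `rerrs_enzyme`.
#' @return Integer vector of cut coordinates (possibly empty).
#' @export
find_cut_positions <- function(seq, enz) {
  stopifnot(inherits(enz, "rerrs_enzyme"))
  if (!is_dna(seq)) stop_fmt("sequence must be over {A,C,G,T,N}")
  # lookahead regex reports overlapping site starts
  pat <- paste0("(?=", iupac_to_regex(enz$recognition), ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L + enz$cut_offset
}

#' Digest a sequence into fragments
#'
#' Partitions `[0, len(seq))` at the enzyme's cut coordinates. The first and
#' last fragments are flagged as terminal (they lack a cut site on one end
#' and cannot enter a sequencing library).
#'
#' @inheritParams find_cut_positions
#' @param genome_id label recorded on each fragment.
#' @return data.frame with columns `genome_id`, `start`, `end` (0-based
#'   half-open), `length`, `sequence`, `terminal`.
#' @export
digest_sequence <- function(seq, enz, genome_id = "genome") {
  cuts <- find_cut_positions(seq, enz)
  n <- nchar(seq)
  bounds <- unique(c(0L, cuts[cuts > 0L & cuts < n], n))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  data.frame(
    genome_id = genome_id, start = starts, end = ends,
    length = ends - starts,
    sequence = substring(seq, starts + 1L, ends),
    terminal = seq_along(starts) == 1L | seq_along(starts) == length(starts),
    stringsAsFactors = FALSE
  )
}

#' Size-select digestion fragments
#'
#' Retains fragments whose length lies in `[min_len, max_len]` (both ends
#' inclusive, matching a 65-195 bp gel/Pippin window). Terminal fragments
#' are excluded by default because library molecules need a cut site at both
#' ends.
#'
#' @param frags data.frame from [digest_sequence()].
#' @param min_len,max_len inclusive length window in bp.
#' @param internal_only drop terminal fragments (default `TRUE`).
#' @return The retained rows of `frags`.
#' @export
size_select <- function(frags, min_len = 65L, max_len = 195L,
                        internal_only = TRUE) {
  if (min_len > max_len) stop_fmt("min_len must not exceed max_len")
  keep <- frags$length >= min_len & frags$length <= max_len
  if (internal_only) keep <- keep & !frags$terminal
  frags[keep, , drop = FALSE]
}

#' Fraction of a genome captured by an enzyme and size window
#'
#' The capture fraction is the summed length of selected internal fragments
#' divided by genome length -- the in-silico analogue of the share of a
#' genome an RE-RRS library samples.
#'
#' @param genome a DNA string.
#' @param enz an `rerrs_enzyme`.
#' @param min_len,max_len inclusive size window in bp.
#' @param internal_only drop terminal fragments (default `TRUE`).
#' @return A real in `[0, 1]`.
#' @export
capture_fraction <- function(genome, enz, min_len = 65L, max_len = 195L,
                             internal_only = TRUE) {
  if (!nchar(genome)) stop_fmt("genome must be non-empty")
  frags <- size_select(digest_sequence(genome, enz), min_len, max_len,
                       internal_only = internal_only)
  sum(frags$length) / nchar(genome)
}

#' Read genomes from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` returning plain upper
#' case character sequences named by record id.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genomes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}
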