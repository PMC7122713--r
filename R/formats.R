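# Readers/writers for the external formats the pipeline touches.
#
# Reads are held as a plain data.frame with columns id, seq, qual and
# (optionally) sample; count matrices are integer matrices with sample ids as
# rownames and feature ids as colnames. Keeping base containers makes every
# operation vectorisable and the fixtures trivially printable.

#' Construct a validated set of sequencing reads
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of DNA sequences over `A,C,G,T,N`.
#' @param qual character vector of Phred+33 quality strings, same lengths as
#'   `seq`.
#' @param sample optional character vector of sample labels (NA when
#'   unassigned).
#' @return A data.frame with columns `id`, `seq`, `qual`, `sample`.
#' @export
reads_df <- function(id, seq, qual, sample = NA_character_) {
  if (length(id) != length(seq) || length(seq) != length(qual)) {
    stop_fmt("id, seq and qual must have equal length")
  }
  if (length(seq) && any(!is_dna(seq))) {
    stop_fmt("sequences must be over {A,C,G,T,N}")
  }
  if (any(nchar(seq) == 0L)) stop_fmt("empty sequences are not allowed")
  if (any(nchar(seq) != nchar(qual))) {
    stop_fmt("quality length must equal sequence length")
  }
  data.frame(
    id = as.character(id), seq = as.character(seq),
    qual = as.character(qual),
    sample = rep_len(as.character(sample), length(id)),
    stringsAsFactors = FALSE
  )
}

#' Read a FASTQ file
#'
#' Parses 4-line-per-record FASTQ (plain or gzip-compressed), decoding
#' qualities as Phred+33. Malformed records raise an error naming the
#' offending line.
#'
#' @param path path to a FASTQ file (`.gz` handled transparently).
#' @return A reads data.frame (see [reads_df()]).
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) {
    return(reads_df(character(0), character(0), character(0)))
  }
  if (n %% 4L != 0L) {
    stop_fmt("truncated FASTQ record starting at line %d", (n %/% 4L) * 4L + 1L)
  }
  hdr <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop_fmt("missing '@' header at line %d", (bad[1L] - 1L) * 4L + 1L)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop_fmt("missing '+' separator at line %d", (bad[1L] - 1L) * 4L + 3L)
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop_fmt(
      "sequence/quality length mismatch at line %d",
      (bad[1L] - 1L) * 4L + 2L
    )
  }
  reads_df(sub("^@", "", hdr), toupper(seqs), qual)
}

#' Write reads to a FASTQ file
#'
#' @param reads a reads data.frame.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @return Invisibly, the number of records written.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) && any(nchar(reads$seq) != nchar(reads$qual))) {
    stop_fmt("quality length must equal sequence length")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(reads)) {
    out <- paste0(
      "@", reads$id, "\n", reads$seq, "\n+\n", reads$qual,
      collapse = "\n"
    )
    writeLines(out, con, sep = "\n")
  }
  invisible(nrow(reads))
}

#' Read a 12-column BLAST tabular hit file
#'
#' Parses the standard tabular alignment output (query, subject, percent
#' identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end, e-value, bitscore) and groups rows by query. Queries
#' split across non-contiguous blocks are merged; row order within a query is
#' preserved.
#'
#' @param path path to a tab-separated 12-column hit table.
#' @return A named list of data.frames (one per query, in order of first
#'   appearance) with columns `query_id`, `subject_id`, `percent_identity`,
#'   `align_length`, `evalue`, `bitscore`.
#' @export
read_hits_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(structure(list(), names = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 12L)
  if (length(bad)) {
    stop_fmt("hit table row %d has %d columns; 12 required", bad[1L], nf[bad[1L]])
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      stop_fmt("non-numeric %s at hit table row %d", name, which(is.na(v))[1L])
    }
    v
  }
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = num(3L, "percent identity"),
    align_length = as.integer(num(4L, "alignment length")),
    evalue = num(11L, "evalue"),
    bitscore = num(12L, "bitscore"),
    stringsAsFactors = FALSE
  )
  if (any(hits$bitscore < 0)) stop_fmt("negative bitscore in hit table")
  if (any(hits$align_length < 1L)) stop_fmt("alignment length < 1 in hit table")
  split(hits, factor(hits$query_id, levels = unique(hits$query_id)))
}

RANKS <- c("root", "kingdom", "phylum", "class", "order", "family",
           "genus", "species")

#' Load a taxonomy tree and subject-to-node map
#'
#' The nodes file is a 4-column TSV (`node_id`, `parent_id`, `rank`, `name`);
#' the root node has `parent_id` equal to its own id. The map file is a
#' 2-column TSV (`subject_id`, `node_id`). The tree is validated for a unique
#' root, reachability, acyclicity and ranks that deepen monotonically from
#' root to leaves.
#'
#' @param nodes_path path to the nodes TSV.
#' @param map_path path to the subject map TSV (optional, `NULL` to skip).
#' @return A list with `tree` (a `rerrs_taxonomy`) and `map` (a named
#'   character vector, subject id -> node id), or `NULL` map when no map file
#'   is given.
#' @export
load_taxonomy <- function(nodes_path, map_path = NULL) {
  nodes <- utils::read.table(
    nodes_path, sep = "\t", header = FALSE, quote = "",
    col.names = c("node_id", "parent_id", "rank", "name"),
    colClasses = "character"
  )
  tree <- taxonomy_tree(nodes)
  map <- NULL
  if (!is.null(map_path)) {
    m <- utils::read.table(
      map_path, sep = "\t", header = FALSE, quote = "",
      col.names = c("subject_id", "node_id"), colClasses = "character"
    )
    missing <- setdiff(m$node_id, tree$nodes$node_id)
    if (length(missing)) {
      stop_fmt("subject map references unknown node(s): %s",
               paste(utils::head(missing, 3), collapse = ", "))
    }
    map <- stats::setNames(m$node_id, m$subject_id)
  }
  list(tree = tree, map = map)
}

#' Construct and validate a taxonomy tree
#'
#' @param nodes data.frame with columns `node_id`, `parent_id`, `rank`,
#'   `name`.
#' @return An object of class `rerrs_taxonomy`: the node table plus a parent
#'   lookup and per-node depth.
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(all(c("node_id", "parent_id", "rank", "name") %in% names(nodes)))
  nodes <- as.data.frame(lapply(nodes, as.character), stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$node_id)) stop_fmt("duplicate node ids in taxonomy")
  unknown <- setdiff(nodes$rank, RANKS)
  if (length(unknown)) {
    stop_fmt("unknown rank(s): %s", paste(unknown, collapse = ", "))
  }
  root <- nodes$node_id[nodes$parent_id == nodes$node_id]
  if (length(root) != 1L) {
    stop_fmt("taxonomy must have exactly one root (parent_id == node_id)")
  }
  orphan <- setdiff(nodes$parent_id, nodes$node_id)
  if (length(orphan)) {
    stop_fmt("parent id(s) absent from node table: %s",
             paste(utils::head(orphan, 3), collapse = ", "))
  }
  parent <- stats::setNames(nodes$parent_id, nodes$node_id)
  rank_idx <- stats::setNames(match(nodes$rank, RANKS), nodes$node_id)
  depth <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$node_id)
  for (id in nodes$node_id) {
    chain <- id
    cur <- id
    while (cur != root) {
      cur <- parent[[cur]]
      if (cur %in% chain) stop_fmt("cycle in taxonomy involving node %s", id)
      chain <- c(chain, cur)
      if (length(chain) > nrow(nodes)) {
        stop_fmt("node %s does not reach the root", id)
      }
    }
    depth[id] <- length(chain) - 1L
    if (id != root && rank_idx[[id]] <= rank_idx[[parent[[id]]]]) {
      stop_fmt("rank of node %s is not deeper than its parent", id)
    }
  }
  structure(
    list(nodes = nodes, root = root, parent = parent, depth = depth,
         rank = stats::setNames(nodes$rank, nodes$node_id)),
    class = "rerrs_taxonomy"
  )
}

#' @export
print.rerrs_taxonomy <- function(x, ...) {
  cat("Taxonomy tree:", nrow(x$nodes), "nodes, root =", x$root, "\n")
  cat("Ranks:", paste(names(table(x$rank)), table(x$rank), sep = ":",
                      collapse = " "), "\n")
  invisible(x)
}

#' Construct a samples x features count matrix
#'
#' @param counts integer matrix (samples in rows, features in columns).
#' @param sample_ids,feature_ids optional dimnames, taken from `counts` when
#'   omitted.
#' @return A validated integer matrix with dimnames.
#' @export
count_matrix <- function(counts, sample_ids = rownames(counts),
                         feature_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop_fmt("count matrix needs sample and feature ids")
  }
  if (anyDuplicated(sample_ids)) stop_fmt("duplicate sample ids")
  if (anyDuplicated(feature_ids)) stop_fmt("duplicate feature ids")
  storage.mode(counts) <- "integer"
  if (anyNA(counts)) stop_fmt("count matrix contains non-integer entries")
  if (any(counts < 0L)) stop_fmt("count matrix contains negative entries")
  dimnames(counts) <- list(sample_ids, feature_ids)
  counts
}

#' Write / read a count matrix as TSV
#'
#' TSV layout: header row of feature ids with a leading `sample_id` column;
#' one row per sample. Round-trips losslessly.
#'
#' @param m count matrix (see [count_matrix()]).
#' @param path file path.
#' @return `write_count_matrix` invisibly returns `path`;
#'   `read_count_matrix` returns the validated matrix.
#' @export
write_count_matrix <- function(m, path) {
  m <- count_matrix(m)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          quote = "", colClasses = NA, stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id") {
    stop_fmt("count matrix TSV must start with a sample_id column")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  count_matrix(m, sample_ids = df$sample_id, feature_ids = colnames(m))
}
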