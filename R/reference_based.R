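# Reference-based profiling: bitscore filtering of alignment hits,
# MEGAN-style lowest-common-ancestor assignment, genus profiles and
# hit-rate-by-rank summaries. The aligner itself (BLASTN) is external; this
# module ingests its 12-column tabular output via read_hits_table().

#' Filter alignment hits by bitscore
#'
#' Drops hits below `min_bitscore`, then keeps only hits within
#' `top_window` of the surviving maximum bitscore (both comparisons
#' inclusive): with maximum `B`, hits with `bitscore >= (1 - top_window) * B`
#' are retained. The window is applied to the post-minimum survivors, the
#' MEGAN default ordering.
#'
#' @param hits data.frame of hits for one query (columns as produced by
#'   [read_hits_table()]).
#' @param min_bitscore minimum bitscore (default 50).
#' @param top_window retained fraction below the maximum (default 0.10;
#'   0 keeps top-bitscore hits only).
#' @return The retained rows (possibly none).
#' @export
filter_hits <- function(hits, min_bitscore = 50, top_window = 0.10) {
  keep <- hits[hits$bitscore >= min_bitscore, , drop = FALSE]
  if (!nrow(keep)) return(keep)
  keep[keep$bitscore >= (1 - top_window) * max(keep$bitscore), , drop = FALSE]
}

# Path from a node up to the root (node first).
ancestor_path <- function(tree, node) {
  path <- node
  while (node != tree$root) {
    node <- tree$parent[[node]]
    path <- c(path, node)
  }
  path
}

# Lowest common ancestor of a set of nodes.
lca_node <- function(tree, nodes) {
  nodes <- unique(nodes)
  if (length(nodes) == 1L) return(nodes)
  paths <- lapply(nodes, function(n) rev(ancestor_path(tree, n)))
  k <- min(lengths(paths))
  lca <- tree$root
  for (i in seq_len(k)) {
    step <- vapply(paths, `[[`, "", i)
    if (all(step == step[1L])) lca <- step[1L] else break
  }
  lca
}

#' Assign a query to a taxonomic node by lowest common ancestor
#'
#' The node is the LCA of the distinct taxa of the filtered hits (duplicate
#' hits to one subject collapse); an empty hit set yields `UNASSIGNED`. A
#' read assigned to node X counts as assigned at X's rank and at every
#' ancestor rank.
#'
#' @param filtered filtered hits for one query ([filter_hits()]).
#' @param subject_map named character vector, subject id -> taxonomy node.
#' @param tree an `rerrs_taxonomy`.
#' @return list `node` (node id or `NA` for unassigned) and `rank`.
#' @export
lca_assign <- function(filtered, subject_map, tree) {
  if (!nrow(filtered)) return(list(node = NA_character_, rank = NA_character_))
  subj <- unique(filtered$subject_id)
  unknown <- setdiff(subj, names(subject_map))
  if (length(unknown)) {
    stop_fmt("subject(s) missing from taxonomy map: %s",
             paste(utils::head(unknown, 3), collapse = ", "))
  }
  node <- lca_node(tree, unique(subject_map[subj]))
  list(node = node, rank = tree$rank[[node]])
}

#' LCA-assign every query of a hit table
#'
#' @param hit_groups named list of per-query hit data.frames
#'   ([read_hits_table()]).
#' @param subject_map,tree as in [lca_assign()].
#' @param min_bitscore,top_window as in [filter_hits()].
#' @return data.frame `query_id`, `node`, `rank` (NA when unassigned).
#' @export
assign_reads <- function(hit_groups, subject_map, tree, min_bitscore = 50,
                         top_window = 0.10) {
  res <- lapply(hit_groups, function(h) {
    lca_assign(filter_hits(h, min_bitscore, top_window), subject_map, tree)
  })
  data.frame(
    query_id = names(hit_groups) %||% character(0),
    node = vapply(res, function(x) x$node, character(1), USE.NAMES = FALSE),
    rank = vapply(res, function(x) x$rank, character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

# Is `node` equal to or a descendant of `anc`?
is_descendant_or_self <- function(tree, node, anc) {
  anc %in% ancestor_path(tree, node)
}

#' Per-sample profile counts at a rank
#'
#' Counts, for each node of the requested rank, the reads whose assigned
#' node is that node or one of its descendants. Reads assigned above the
#' rank (or unassigned) contribute to no feature.
#'
#' @param assignments data.frame from [assign_reads()] for one sample.
#' @param tree an `rerrs_taxonomy`.
#' @param rank target rank (default `"genus"`).
#' @return Named integer vector over all tree nodes of that rank.
#' @export
profile_counts <- function(assignments, tree, rank = "genus") {
  feats <- tree$nodes$node_id[tree$nodes$rank == rank]
  out <- stats::setNames(integer(length(feats)), feats)
  nodes <- assignments$node[!is.na(assignments$node)]
  if (!length(nodes)) return(out)
  # map each assigned node to its ancestor (or self) at the target rank
  at_rank <- vapply(nodes, function(n) {
    path <- ancestor_path(tree, n)
    hit <- path[tree$rank[path] == rank]
    if (length(hit)) hit[1L] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  tab <- table(at_rank[!is.na(at_rank)])
  out[names(tab)] <- as.integer(tab)
  out
}

#' Hit rate by taxonomic rank
#'
#' Rate at rank r is the percentage of all reads assigned at rank r or
#' deeper; by construction rates are non-increasing from kingdom to
#' species.
#'
#' @param assignments data.frame from [assign_reads()].
#' @param tree an `rerrs_taxonomy`.
#' @param total total read count (assigned + unassigned); defaults to
#'   `nrow(assignments)`.
#' @return Named numeric vector of 7 percentages, kingdom -> species.
#' @export
hit_rate_by_rank <- function(assignments, tree, total = nrow(assignments)) {
  if (is.null(total) || total <= 0) stop_fmt("total read count must be positive")
  ranks <- RANKS[-1L] # kingdom..species
  rank_idx <- match(assignments$rank, RANKS)
  rate <- vapply(seq_along(ranks), function(i) {
    100 * sum(!is.na(rank_idx) & rank_idx >= i + 1L) / total
  }, numeric(1))
  stats::setNames(rate, ranks)
}
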