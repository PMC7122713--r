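# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive -- window scans, ancestor-set intersections, direct
# determinant log-likelihoods -- so they exercise none of the package's own
# code paths.

# Brute-force cut-site scan: slide a window over the sequence and compare
# base by base against the recognition site (W = A or T), no regex.
oracle_cut_positions <- function(seq, recognition, cut_offset) {
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  rc <- strsplit(recognition, "", fixed = TRUE)[[1]]
  k <- length(rc)
  n <- length(sc)
  if (n < k) return(integer(0))
  starts <- 1:(n - k + 1)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(k)) {
    win <- sc[starts + j - 1L]
    ok <- ok & if (rc[j] == "W") win %in% c("A", "T") else win == rc[j]
  }
  starts[ok] - 1L + cut_offset
}

# Random DNA string.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Random taxonomy: a root with `n_internal` internal nodes at random ranks
# along random chains, and species leaves; returns the node table plus a
# parent lookup for the brute-force LCA.
random_taxonomy_nodes <- function(n_taxa = 50) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  nodes <- data.frame(node_id = "root", parent_id = "root", rank = "root",
                      name = "root", stringsAsFactors = FALSE)
  count <- 0L
  # grow chains: each leaf gets a random-length lineage, attaching at a
  # random existing node of a shallower rank
  for (i in seq_len(n_taxa)) {
    depth_target <- sample(2:7, 1)
    eligible <- nodes[match(nodes$rank, c("root", ranks)) <= depth_target, ]
    parent <- eligible[sample(nrow(eligible), 1), ]
    pr <- match(parent$rank, c("root", ranks))
    for (r in (pr + 1):(depth_target + 1)) {
      count <- count + 1L
      id <- sprintf("n%04d", count)
      nodes <- rbind(nodes, data.frame(
        node_id = id, parent_id = parent$node_id, rank = ranks[r - 1],
        name = id, stringsAsFactors = FALSE
      ))
      parent <- nodes[nrow(nodes), ]
    }
  }
  nodes
}

# Brute-force LCA: intersect full ancestor sets, take the deepest member.
oracle_lca <- function(nodes_df, ids) {
  parent <- setNames(nodes_df$parent_id, nodes_df$node_id)
  anc <- function(id) {
    out <- id
    while (id != parent[[id]]) {
      id <- parent[[id]]
      out <- c(out, id)
    }
    out
  }
  sets <- lapply(unique(ids), anc)
  common <- Reduce(intersect, sets)
  depths <- vapply(common, function(id) length(anc(id)), integer(1))
  common[which.max(depths)]
}

# Direct REML log-likelihood via determinants and solve(): independent of
# the package's Cholesky-based implementation.
oracle_reml_loglik <- function(theta, y, X, Vlist) {
  V <- matrix(0, length(y), length(y))
  for (i in seq_along(theta)) V <- V + theta[i] * Vlist[[i]]
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(-Inf)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  -0.5 * (sum(log(ev)) + determinant(XtVX, logarithm = TRUE)$modulus[1] +
            drop(t(y) %*% P %*% y))
}

# Small simulated study used by several statistical tests.
small_study <- function(n_animals = 16, n_cohorts = 2, n_taxa = 40,
                        seed = 11) {
  design <- generate_design(n_animals, n_cohorts, seed = seed)
  truth <- generate_community(design, n_taxa, seed = seed + 1)
  list(design = design, truth = truth)
}
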