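# Reference-based profiling: bitscore filtering, LCA assignment, genus
# profiles and hit-rate summaries.

linear_tree <- function() {
  taxonomy_tree(data.frame(
    node_id = c("root", "k1", "p1", "c1", "o1", "f1", "g1", "g2",
                "s1a", "s1b", "s2a"),
    parent_id = c("root", "root", "k1", "p1", "c1", "o1", "f1", "f1",
                  "g1", "g1", "g2"),
    rank = c("root", "kingdom", "phylum", "class", "order", "family",
             "genus", "genus", "species", "species", "species"),
    name = c("root", "k1", "p1", "c1", "o1", "f1", "g1", "g2",
             "s1a", "s1b", "s2a"),
    stringsAsFactors = FALSE
  ))
}

hit <- function(q, s, bs) {
  data.frame(query_id = q, subject_id = s, percent_identity = 99,
             align_length = 65, evalue = 1e-20, bitscore = bs,
             stringsAsFactors = FALSE)
}

test_that("bitscore filtering applies the floor then the top window", {
  h <- rbind(hit("q", "a", 100), hit("q", "b", 91), hit("q", "c", 89))
  kept <- filter_hits(h)
  expect_equal(kept$bitscore, c(100, 91)) # threshold 0.9 * 100 = 90
  expect_equal(nrow(filter_hits(rbind(hit("q", "a", 49), hit("q", "b", 48)))),
               0L)
  expect_equal(filter_hits(hit("q", "a", 50))$bitscore, 50) # inclusive floor
  # idempotent, output a subset
  expect_identical(filter_hits(kept), kept)
  expect_true(all(kept$subject_id %in% h$subject_id))
  # window anchored on post-floor maximum: 60 survives the floor, 45 dropped,
  # then the window keeps within 10% of 60
  h2 <- rbind(hit("q", "a", 60), hit("q", "b", 55), hit("q", "c", 45))
  expect_equal(filter_hits(h2)$bitscore, c(60, 55))
})

test_that("LCA assignment follows the tree structure", {
  tree <- linear_tree()
  map <- c(A = "s1a", B = "s1b", C = "s2a", G = "g1")
  # two species of one genus -> that genus
  a <- lca_assign(rbind(hit("q", "A", 100), hit("q", "B", 100)), map, tree)
  expect_equal(a$node, "g1")
  expect_equal(a$rank, "genus")
  # two genera of one family -> family
  a2 <- lca_assign(rbind(hit("q", "A", 100), hit("q", "C", 100)), map, tree)
  expect_equal(a2$node, "f1")
  # all hits to one species -> that species
  a3 <- lca_assign(rbind(hit("q", "A", 100), hit("q", "A", 99)), map, tree)
  expect_equal(a3$node, "s1a")
  # empty -> unassigned
  a4 <- lca_assign(hit("q", "A", 100)[0, ], map, tree)
  expect_true(is.na(a4$node))
  # node and its descendant -> the ancestor
  a5 <- lca_assign(rbind(hit("q", "G", 100), hit("q", "A", 100)), map, tree)
  expect_equal(a5$node, "g1")
  expect_error(lca_assign(hit("q", "ZZ", 100), map, tree), "ZZ")
})

test_that("LCA equals the ancestor-set-intersection oracle on random cases", {
  set.seed(61)
  for (case in 1:1000) {
    nodes <- random_taxonomy_nodes(n_taxa = 8)
    tree <- taxonomy_tree(nodes)
    non_root <- nodes$node_id[nodes$node_id != "root"]
    ids <- sample(non_root, sample(1:min(8, length(non_root)), 1),
                  replace = TRUE)
    map <- setNames(ids, paste0("subj", seq_along(ids)))
    h <- do.call(rbind, lapply(names(map), function(s) hit("q", s, 100)))
    got <- lca_assign(h, map, tree)
    expect_identical(got$node, oracle_lca(nodes, ids))
  }
})

test_that("profile counts aggregate species into genera and skip higher ranks", {
  tree <- linear_tree()
  asn <- data.frame(
    query_id = paste0("q", 1:5),
    node = c("s1a", "s1b", "g2", "f1", NA),
    rank = c("species", "species", "genus", "family", NA),
    stringsAsFactors = FALSE
  )
  prof <- profile_counts(asn, tree, rank = "genus")
  expect_equal(prof[["g1"]], 2L) # two species under g1
  expect_equal(prof[["g2"]], 1L)
  fam <- profile_counts(asn, tree, rank = "family")
  expect_equal(fam[["f1"]], 4L) # family-level read counts at family
  empty <- profile_counts(asn[0, ], tree)
  expect_true(all(empty == 0L))
  all_un <- data.frame(query_id = "q", node = NA_character_,
                       rank = NA_character_)
  expect_true(all(profile_counts(all_un, tree) == 0L))
})

test_that("hit rates by rank are percentages, monotone kingdom to species", {
  tree <- linear_tree()
  asn <- data.frame(
    query_id = paste0("q", 1:10),
    node = c(rep("g1", 5), rep("f1", 2), rep(NA, 3)),
    rank = c(rep("genus", 5), rep("family", 2), rep(NA, 3)),
    stringsAsFactors = FALSE
  )
  hr <- hit_rate_by_rank(asn, tree)
  expect_equal(unname(hr[["family"]]), 70)
  expect_equal(unname(hr[["genus"]]), 50)
  expect_equal(unname(hr[["species"]]), 0)
  expect_true(all(diff(hr) <= 0))
  expect_true(all(hit_rate_by_rank(asn[8:10, ], tree) == 0))
  all_sp <- data.frame(query_id = "q", node = "s1a", rank = "species")
  expect_true(all(hit_rate_by_rank(all_sp, tree) == 100))
  expect_error(hit_rate_by_rank(asn, tree, total = 0), "positive")
})

test_that("assignments of error-free simulated reads are ancestors of the source taxon", {
  st <- small_study(n_animals = 4, n_cohorts = 2, n_taxa = 12)
  g <- generate_genomes(12, 50000, 0.5, seed = 62)
  tx <- genome_taxonomy(g)
  enz <- get_enzyme("ApeKI")
  sim <- simulate_reads(g, st$truth, st$design, enz, reads_per_sample = 200,
                        error_rate = 0, seed = 63)
  # construct hit tables from truth: each read hits its own source genome,
  # and with probability ~0.3 also a second genome (forcing an LCA climb)
  set.seed(64)
  reads <- sim$reads[sample(nrow(sim$reads), 300), ]
  src <- vapply(strsplit(reads$id, ":", fixed = TRUE), `[[`, "", 3L)
  groups <- lapply(seq_len(nrow(reads)), function(i) {
    h <- hit(reads$id[i], src[i], 100)
    if (runif(1) < 0.3) {
      other <- sample(setdiff(names(tx$map), src[i]), 1)
      h <- rbind(h, hit(reads$id[i], other, 95))
    }
    h
  })
  names(groups) <- reads$id
  asn <- assign_reads(groups, tx$map, tx$tree)
  for (i in seq_len(nrow(asn))) {
    true_species <- tx$map[[src[i]]]
    path <- c(true_species)
    cur <- true_species
    while (cur != tx$tree$root) {
      cur <- tx$tree$parent[[cur]]
      path <- c(path, cur)
    }
    expect_true(asn$node[i] %in% path)
  }
  hr <- hit_rate_by_rank(asn, tx$tree)
  expect_true(all(diff(hr) <= 0))
})
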