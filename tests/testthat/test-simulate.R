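# Synthetic community and read generator.

test_that("generated genomes hit their GC targets and are deterministic", {
  g <- generate_genomes(10, 50000, 0.5, seed = 21)
  gc <- vapply(g$sequences, function(s) {
    b <- table(strsplit(s, "", fixed = TRUE)[[1]])
    (b[["G"]] + b[["C"]]) / nchar(s)
  }, numeric(1))
  expect_true(all(gc >= 0.47 & gc <= 0.53)) # binomial bound at 50 kb
  g2 <- generate_genomes(10, 50000, 0.5, seed = 21)
  expect_identical(g$sequences, g2$sequences)
  g3 <- generate_genomes(10, 50000, 0.5, seed = 22)
  expect_false(identical(g$sequences, g3$sequences))
  expect_error(generate_genomes(2, 50000, c(0.5, 1.0), seed = 1), "gc")
  expect_error(generate_genomes(2, 5000, 0.5, seed = 1), "10 kb")
})

test_that("genome lineages are 7-rank and share families across genera", {
  g <- generate_genomes(10, 10000, 0.5, seed = 2)
  lin <- g$lineage
  expect_equal(nrow(lin), 10L)
  expect_false(any(duplicated(lin$species)))
  # at least one family holds >= 2 genera (makes LCA non-trivial)
  per_family <- tapply(lin$genus, lin$family, function(x) length(unique(x)))
  expect_gte(max(per_family), 2L)
  tx <- genome_taxonomy(g)
  expect_s3_class(tx$tree, "rerrs_taxonomy")
  expect_setequal(names(tx$map), lin$genome_id)
})

test_that("designs pair samples within animal, balance cohorts and use prefix-free barcodes", {
  d <- generate_design(118, 4, seed = 1)
  expect_equal(nrow(d), 236L) # 118 sheep, two measuring rounds
  expect_true(all(table(d$animal_id) == 2L))
  expect_true(all(abs(table(d$cohort) / 2 - 118 / 4) <= 0.5))
  expect_true(all(nchar(d$barcode) >= 4 & nchar(d$barcode) <= 9))
  expect_false(any(duplicated(d$barcode)))
  for (i in seq_len(nrow(d))) {
    others <- d$barcode[-i]
    expect_false(any(startsWith(others, d$barcode[i])))
  }
  d2 <- generate_design(4, 2, seed = 5)
  expect_equal(nrow(d2), 8L)
  expect_equal(as.integer(table(d2$cohort)), c(4L, 4L))
})

test_that("community log-abundance has the designed intraclass correlation", {
  d <- generate_design(60, 2, seed = 3)
  tr <- generate_community(d, 600, sd_cohort = 0, sd_animal = 1,
                           sd_sample = 1, seed = 4)
  expect_equal(tr$true_repeatability, 0.5)
  expect_true(all(abs(rowSums(tr$composition) - 1) < 1e-9))
  expect_true(all(tr$composition > 0))
  # empirical ICC of log-abundance across duplicates, averaged over taxa
  la <- tr$log_abundance
  r1 <- la[d$round == 1, ]
  r2 <- la[d$round == 2, ]
  icc <- mean(vapply(seq_len(ncol(la)), function(t) cor(r1[, t], r2[, t]),
                     numeric(1)))
  expect_lt(abs(icc - 0.5), 0.05)
})

test_that("zero cohort / animal variance flattens the respective structure", {
  d <- generate_design(40, 2, seed = 6)
  tr0 <- generate_community(d, 400, sd_cohort = 0, sd_animal = 1,
                            sd_sample = 1, seed = 7)
  la <- tr0$log_abundance
  cohort_gap <- colMeans(la[d$cohort == "cohort1", ]) -
    colMeans(la[d$cohort == "cohort2", ])
  expect_lt(abs(mean(cohort_gap)), 0.1) # equal within sampling error

  trA <- generate_community(d, 400, sd_animal = 0, sd_sample = 1, seed = 8)
  laA <- trA$log_abundance
  dup_cor <- mean(vapply(seq_len(ncol(laA)), function(t) {
    cor(laA[d$round == 1, t], laA[d$round == 2, t])
  }, numeric(1)))
  expect_lt(abs(dup_cor), 0.1) # duplicates no more alike than random pairs
})

test_that("phenotypes centre on 16 g CH4/kg DMI with the requested microbial share", {
  d <- generate_design(118, 4, seed = 9)
  tr <- generate_community(d, 300, seed = 10)
  y <- generate_phenotypes(tr, target_m2 = 0.4, seed = 11)
  expect_equal(mean(y), 16.0, tolerance = 1e-6)
  expect_lt(abs(attr(y, "realized_m2") - 0.4), 0.02)

  y0 <- generate_phenotypes(tr, target_m2 = 0, seed = 12)
  proj <- drop(scale(log10(tr$composition)) %*% tr$methane_axis)
  expect_lt(abs(cor(as.numeric(y0), proj)), 0.2) # ~3/sqrt(n)
  expect_error(generate_phenotypes(tr, 1.0), "target_m2")
})

test_that("simulated reads are deterministic, correctly sized and error-free at rate 0", {
  st <- small_study()
  g <- generate_genomes(40, 50000, 0.45, seed = 12)
  enz <- get_enzyme("ApeKI")
  sim <- simulate_reads(g, st$truth, st$design, enz,
                        reads_per_sample = 500, error_rate = 0, seed = 13)
  expect_equal(nrow(sim$reads), 500L * nrow(st$design))
  expect_true(all(nchar(sim$reads$seq) <= 101L))
  expect_equal(nchar(sim$reads$seq), nchar(sim$reads$qual))
  sim2 <- simulate_reads(g, st$truth, st$design, enz,
                         reads_per_sample = 500, error_rate = 0, seed = 13)
  expect_identical(sim$reads, sim2$reads) # byte-identical given seed
  # every read starts with its sample's barcode followed by the remnant
  d <- st$design
  bc <- setNames(d$barcode, d$sample_id)
  truth_sample <- sub(":.*$", "", sim$reads$id)
  expect_true(all(startsWith(sim$reads$seq, bc[truth_sample])))
  after <- substr(sim$reads$seq, nchar(bc[truth_sample]) + 1,
                  nchar(bc[truth_sample]) + 4)
  expect_true(all(grepl("^C[AT]GC$", after)))
})

test_that("read share tracks composition for a two-genome community", {
  g <- generate_genomes(2, 50000, 0.5, seed = 14)
  design <- generate_design(2, 1, seed = 15)
  truth <- generate_community(design, 2, sd_cohort = 0, sd_animal = 0,
                              sd_sample = 0, sd_base = 0, seed = 16)
  # force a 0.9 / 0.1 composition
  truth$composition[] <- rep(c(0.9, 0.1), each = nrow(design))
  sim <- simulate_reads(g, truth, design, get_enzyme("ApeKI"),
                        reads_per_sample = 10000, error_rate = 0, seed = 17)
  share <- mean(grepl(":taxon001:", sim$reads$id, fixed = TRUE))
  expect_lt(abs(share - 0.9), 3 * sqrt(0.9 * 0.1 / 10000) + 0.01)
})

test_that("a genome with abundance but no selectable fragments is an error", {
  g <- generate_genomes(2, 10000, 0.5, seed = 18)
  # PstI on 10 kb: essentially never a 65-195 bp internal fragment
  design <- generate_design(2, 1, seed = 19)
  truth <- generate_community(design, 2, seed = 20)
  expect_error(
    simulate_reads(g, truth, design, get_enzyme("PstI"),
                   reads_per_sample = 100, seed = 21),
    "selectable"
  )
})
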