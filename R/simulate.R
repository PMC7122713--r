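# Synthetic community and read generator.
#
# Emulates the study design the statistical modules expect: multi-genome
# communities with per-taxon GC content, repeated rumen samples per animal
# (2 measuring rounds) in cohorts, a methane-associated axis of composition
# variation, and multiplexed GBS-style reads that start at a restriction cut
# site remnant. Every generator takes an explicit seed and is deterministic
# given it.

#' Generate random genomes with controlled GC content
#'
#' Bases are i.i.d. with `P(G) + P(C) = gc_target`. Each genome carries a
#' full 7-rank lineage; lineages share higher ranks (two genera per family)
#' so that lowest-common-ancestor assignment is non-trivial.
#'
#' @param n_taxa number of genomes.
#' @param length genome length in bp (>= 10000).
#' @param gc_targets GC fraction per genome, each strictly in (0, 1);
#'   recycled if length 1.
#' @param seed integer RNG seed.
#' @return A list of class `rerrs_genomes`: `sequences` (named character),
#'   `gc_target`, and `lineage` (data.frame genome_id, kingdom..species).
#' @export
generate_genomes <- function(n_taxa, length = 50000L, gc_targets = 0.5,
                             seed = 1L) {
  gc_targets <- rep_len(gc_targets, n_taxa)
  if (any(gc_targets <= 0 | gc_targets >= 1)) {
    stop_fmt("gc_targets must lie strictly in (0, 1)")
  }
  if (length < 10000L) stop_fmt("genome length must be >= 10 kb")
  ids <- sprintf("taxon%03d", seq_len(n_taxa))
  seqs <- with_seed(seed, {
    vapply(seq_len(n_taxa), function(i) {
      gc <- gc_targets[i]
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  names(seqs) <- ids
  i <- seq_len(n_taxa)
  lineage <- data.frame(
    genome_id = ids,
    kingdom = sprintf("K%02d", (i - 1) %/% 32 + 1),
    phylum = sprintf("P%02d", (i - 1) %/% 16 + 1),
    class = sprintf("C%02d", (i - 1) %/% 8 + 1),
    order = sprintf("O%02d", (i - 1) %/% 4 + 1),
    family = sprintf("F%02d", (i - 1) %/% 2 + 1),
    genus = sprintf("G%03d", i),
    species = sprintf("S%03d", i),
    stringsAsFactors = FALSE
  )
  structure(list(sequences = seqs, gc_target = gc_targets, lineage = lineage),
            class = "rerrs_genomes")
}

#' Taxonomy tree and subject map for synthetic genomes
#'
#' Builds the `rerrs_taxonomy` implied by the genomes' lineages, plus a
#' subject map sending each genome id to its species node -- the inputs the
#' reference-based pipeline needs.
#'
#' @param genomes an `rerrs_genomes` object.
#' @return list with `tree` and `map` (genome_id -> species node id).
#' @export
genome_taxonomy <- function(genomes) {
  lin <- genomes$lineage
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  rows <- list(data.frame(node_id = "root", parent_id = "root",
                          rank = "root", name = "root",
                          stringsAsFactors = FALSE))
  for (k in seq_along(ranks)) {
    parent <- if (k == 1L) rep("root", nrow(lin)) else lin[[ranks[k - 1L]]]
    rows[[k + 1L]] <- unique(data.frame(
      node_id = lin[[ranks[k]]], parent_id = parent, rank = ranks[k],
      name = lin[[ranks[k]]], stringsAsFactors = FALSE
    ))
  }
  tree <- taxonomy_tree(do.call(rbind, rows))
  list(tree = tree, map = stats::setNames(lin$species, lin$genome_id))
}

#' Generate a repeated-measures sample design
#'
#' Each animal contributes two samples (measuring rounds 1 and 2); animals
#' are split evenly across cohorts; every sample gets a unique, prefix-free
#' inline barcode of 4-9 bp. Each animal is labelled high- or low-methane
#' (balanced split).
#'
#' @param n_animals number of animals (at least `n_cohorts`).
#' @param n_cohorts number of cohorts; animals are split as evenly as
#'   possible (cohort sizes differ by at most 1).
#' @param seed integer RNG seed.
#' @return data.frame with columns `sample_id`, `animal_id`, `cohort`,
#'   `round`, `methane_class`, `barcode`.
#' @export
generate_design <- function(n_animals = 118L, n_cohorts = 4L, seed = 1L) {
  if (n_animals < n_cohorts) {
    stop_fmt("need at least one animal per cohort")
  }
  animals <- sprintf("A%04d", seq_len(n_animals))
  sizes <- rep(n_animals %/% n_cohorts, n_cohorts) +
    (seq_len(n_cohorts) <= n_animals %% n_cohorts)
  cohort <- sprintf("cohort%d", rep(seq_len(n_cohorts), times = sizes))
  design <- data.frame(
    sample_id = paste0(rep(animals, each = 2L), "_R", 1:2),
    animal_id = rep(animals, each = 2L),
    cohort = rep(cohort, each = 2L),
    round = rep(1:2, times = n_animals),
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    cls <- rep(c("high", "low"), length.out = n_animals)
    cls <- sample(cls)
    design$methane_class <- rep(cls, each = 2L)
    design$barcode <- prefix_free_barcodes(nrow(design))
  })
  design
}

# Greedy prefix-free barcode set with lengths in 4..9.
prefix_free_barcodes <- function(n, min_len = 4L, max_len = 9L,
                                 max_tries = 200L) {
  out <- character(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      len <- sample(min_len:max_len, 1L)
      cand <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      clash <- any(startsWith(cand, out) | startsWith(out, cand))
      if (!clash) {
        out <- c(out, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop_fmt("could not build a prefix-free barcode set of size %d", n)
  }
  out
}

#' Generate true community compositions
#'
#' Log-abundance of taxon `t` in sample `s` is
#' `base_t + cohort_{c(s),t} + animal_{a(s),t} + eps_{s,t}`, exponentiated
#' and row-normalised. The intraclass correlation of a taxon's log-abundance
#' across an animal's two samples (after cohort) is
#' `sd_animal^2 / (sd_animal^2 + sd_sample^2)`, recorded as
#' `true_repeatability`. A per-taxon standard-normal `methane_axis` (scaled
#' by `methane_effect_sd`) defines the direction of composition variation
#' that [generate_phenotypes()] ties to methane yield.
#'
#' @param design design data.frame from [generate_design()].
#' @param n_taxa number of taxa.
#' @param sd_cohort,sd_animal,sd_sample standard deviations of the cohort,
#'   animal permanent-environment and sample-level log-scale effects.
#' @param sd_base standard deviation of per-taxon baseline log-abundance
#'   (controls how uneven the community is).
#' @param methane_effect_sd standard deviation of the methane axis loadings.
#' @param seed integer RNG seed.
#' @return list of class `rerrs_community`: `composition` (samples x taxa,
#'   rows sum to 1), `log_abundance`, effect matrices, `methane_axis`,
#'   `true_repeatability`.
#' @export
generate_community <- function(design, n_taxa, sd_cohort = 0.3,
                               sd_animal = 1, sd_sample = 1, sd_base = 1.5,
                               methane_effect_sd = 1, seed = 1L) {
  if (any(c(sd_cohort, sd_animal, sd_sample, sd_base, methane_effect_sd) < 0)) {
    stop_fmt("all standard deviations must be >= 0")
  }
  taxa <- sprintf("taxon%03d", seq_len(n_taxa))
  cohorts <- unique(design$cohort)
  animals <- unique(design$animal_id)
  with_seed(seed, {
    base <- stats::rnorm(n_taxa, 0, sd_base)
    cohort_eff <- matrix(stats::rnorm(length(cohorts) * n_taxa, 0, sd_cohort),
                         length(cohorts), n_taxa,
                         dimnames = list(cohorts, taxa))
    animal_eff <- matrix(stats::rnorm(length(animals) * n_taxa, 0, sd_animal),
                         length(animals), n_taxa,
                         dimnames = list(animals, taxa))
    eps <- matrix(stats::rnorm(nrow(design) * n_taxa, 0, sd_sample),
                  nrow(design), n_taxa,
                  dimnames = list(design$sample_id, taxa))
    axis <- stats::rnorm(n_taxa, 0, methane_effect_sd)
    la <- sweep(eps, 2L, base, "+") +
      cohort_eff[design$cohort, , drop = FALSE] +
      animal_eff[design$animal_id, , drop = FALSE]
    rownames(la) <- design$sample_id
    comp <- exp(la)
    comp <- comp / rowSums(comp)
    structure(
      list(
        composition = comp, log_abundance = la, base = base,
        cohort_effects = cohort_eff, animal_effects = animal_eff,
        methane_axis = stats::setNames(axis, taxa),
        design = design,
        true_repeatability = if (sd_animal + sd_sample > 0) {
          sd_animal^2 / (sd_animal^2 + sd_sample^2)
        } else NA_real_,
        realized_m2 = NA_real_
      ),
      class = "rerrs_community"
    )
  })
}

#' Generate methane-yield phenotypes from a community
#'
#' The microbial term is the projection of each sample's within-cohort
#' standardised log10 composition onto the community's methane axis. Yields
#' are `overall_mean * (1 + cv * u)` where `u` mixes the microbial term, an
#' animal permanent-environment term, and residual noise, each empirically
#' standardised so the microbial share of `var(u)` equals `target_m2` up to
#' component correlation (realised share is recorded on the returned object
#' and in the community's `realized_m2`).
#'
#' @param truth an `rerrs_community`.
#' @param target_m2 target microbial variance share in `[0, 1)`.
#' @param pe_share share of the non-microbial variance given to the animal
#'   permanent-environment term (default 0.2).
#' @param cv coefficient of variation of yield (default 0.15).
#' @param overall_mean population mean yield, g CH4/kg DMI (default 16.0).
#' @param seed integer RNG seed.
#' @return Named numeric vector of per-sample yields with attributes
#'   `realized_m2` and `truth` (the updated community).
#' @export
generate_phenotypes <- function(truth, target_m2 = 0.4, pe_share = 0.2,
                                cv = 0.15, overall_mean = 16.0, seed = 1L) {
  stopifnot(inherits(truth, "rerrs_community"))
  if (target_m2 < 0 || target_m2 >= 1) {
    stop_fmt("target_m2 must lie in [0, 1)")
  }
  design <- truth$design
  z <- standardize_within_cohort(log10(truth$composition), design$cohort)
  g_raw <- drop(z %*% truth$methane_axis) / sqrt(ncol(z))
  with_seed(seed, {
    unit <- function(x) {
      s <- stats::sd(x)
      if (s > 0) (x - mean(x)) / s else x * 0
    }
    g <- if (target_m2 > 0) sqrt(target_m2) * unit(g_raw) else rep(0, nrow(design))
    # orthogonalise the noise components against g (and each other) so the
    # realised variance shares match the targets exactly
    animals <- unique(design$animal_id)
    pe_a <- stats::rnorm(length(animals))
    gbar <- tapply(g, design$animal_id, mean)[animals]
    if (stats::sd(gbar) > 0) pe_a <- stats::residuals(stats::lm(pe_a ~ gbar))
    names(pe_a) <- animals
    pe <- sqrt(pe_share * (1 - target_m2)) * unit(pe_a[design$animal_id])
    e_raw <- stats::rnorm(nrow(design))
    e_raw <- stats::residuals(stats::lm(e_raw ~ g + pe))
    e <- sqrt((1 - pe_share) * (1 - target_m2)) * unit(e_raw)
    u <- g + pe + e
    y <- overall_mean * (1 + cv * u)
    names(y) <- design$sample_id
    realized <- if (stats::var(u) > 0) stats::var(g) / stats::var(u) else 0
    attr(y, "realized_m2") <- realized
    truth$realized_m2 <- realized
    attr(y, "truth") <- truth
    y
  })
}

# Standardise columns of a matrix to mean 0 / sd 1 within cohort; columns
# with zero within-cohort variance are set to 0 for that cohort.
standardize_within_cohort <- function(m, cohort) {
  out <- m
  for (co in unique(cohort)) {
    idx <- which(cohort == co)
    sub <- m[idx, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- Inf # zero-variance -> standardised 0
    out[idx, ] <- sweep(sweep(sub, 2L, mu, "-"), 2L, sdv, "/")
  }
  out
}

#' Simulate multiplexed RE-RRS reads
#'
#' Each read is `barcode + cut-site remnant + downstream molecule sequence`,
#' truncated to `read_length`; molecules shorter than the read get a fixed
#' adapter suffix (exercising the trimmer). Fragments are drawn with
#' probability proportional to the sample's composition for the fragment's
#' genome, uniformly among that genome's size-selected internal fragments,
#' and are sequenced from either cut-site end with probability 1/2
#' (reverse-complement emission, orientation recorded in the read id).
#' Substitution errors are applied per base at `error_rate`; qualities are
#' constant Q30.
#'
#' @param genomes an `rerrs_genomes`.
#' @param truth an `rerrs_community` (compositions over the same taxa).
#' @param design design data.frame (provides barcodes).
#' @param enz an `rerrs_enzyme`.
#' @param min_len,max_len fragment size-selection window in bp.
#' @param reads_per_sample reads emitted per sample.
#' @param error_rate per-base substitution probability.
#' @param read_length total read length including the barcode (default 101).
#' @param adapter adapter sequence appended to short molecules.
#' @param seed integer RNG seed.
#' @return list with `reads` (a reads data.frame, FASTQ-ready), and `truth`
#'   (data.frame sample, genome_id, fragment, orientation, count, and the
#'   error-free post-barcode read sequence) for oracle tests.
#' @export
simulate_reads <- function(genomes, truth, design, enz = get_enzyme("PstI"),
                           min_len = 65L, max_len = 195L,
                           reads_per_sample = 50000L, error_rate = 0.001,
                           read_length = 101L,
                           adapter = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAGACCGATCTCGTATGCCGTCTTCTGCTTG",
                           seed = 1L) {
  stopifnot(inherits(genomes, "rerrs_genomes"),
            inherits(truth, "rerrs_community"))
  comp <- truth$composition
  taxa <- colnames(comp)
  if (!all(taxa %in% names(genomes$sequences))) {
    stop_fmt("community taxa must match genome ids")
  }
  ro <- nchar(enz$recognition) - nchar(enz$read_remnant)
  frag_tab <- do.call(rbind, lapply(taxa, function(g) {
    fr <- size_select(digest_sequence(genomes$sequences[[g]], enz, g),
                      min_len, max_len)
    if (!nrow(fr) && any(comp[, g] > 0)) {
      stop_fmt("genome %s has positive abundance but no selectable fragments", g)
    }
    fr
  }))
  # molecule carries the remnant at both ends (overhang fill-in)
  frag_tab$molecule <- vapply(seq_len(nrow(frag_tab)), function(i) {
    g <- genomes$sequences[[frag_tab$genome_id[i]]]
    a <- frag_tab$start[i] - enz$cut_offset + ro       # 0-based molecule start
    b <- frag_tab$end[i] - enz$cut_offset +
      nchar(enz$recognition) - ro                      # 0-based excl. end
    substr(g, a + 1L, b)
  }, character(1))
  frag_tab$frag_idx <- stats::ave(seq_len(nrow(frag_tab)), frag_tab$genome_id,
                                  FUN = seq_along)
  nfrag <- table(frag_tab$genome_id)[taxa]

  with_seed(seed, {
    all_reads <- vector("list", nrow(design))
    all_truth <- vector("list", nrow(design))
    fwd <- frag_tab$molecule
    rev <- revcomp(frag_tab$molecule)
    for (si in seq_len(nrow(design))) {
      s <- design$sample_id[si]
      bc <- design$barcode[si]
      p_frag <- comp[s, frag_tab$genome_id] / as.numeric(nfrag[frag_tab$genome_id])
      prob <- c(p_frag, p_frag) / 2 # forward then reverse copies
      cnt <- stats::rmultinom(1L, reads_per_sample, prob)[, 1L]
      nfr <- nrow(frag_tab)
      mol <- c(fwd, rev)
      post <- substr(paste0(mol, adapter), 1L,
                     read_length - nchar(bc))
      keep <- cnt > 0L
      idx <- which(keep)
      seqs <- rep(post[idx], cnt[idx])
      src <- rep(idx, cnt[idx])
      if (error_rate > 0 && length(seqs)) {
        nerr <- stats::rbinom(length(seqs), nchar(seqs), error_rate)
        for (j in which(nerr > 0L)) {
          pos <- sample.int(nchar(seqs[j]), nerr[j])
          ch <- strsplit(seqs[j], "", fixed = TRUE)[[1]]
          for (pp in pos) ch[pp] <- sample(setdiff(DNA_BASES, ch[pp]), 1L)
          seqs[j] <- paste(ch, collapse = "")
        }
      }
      orient <- ifelse(src > nfr, "R", "F")
      fidx <- ifelse(src > nfr, src - nfr, src)
      full <- paste0(bc, seqs)
      ids <- sprintf("%s:%06d:%s:%d:%s", s, seq_along(seqs),
                     frag_tab$genome_id[fidx], frag_tab$frag_idx[fidx], orient)
      all_reads[[si]] <- reads_df(ids, full, strrep("?", nchar(full)))
      all_truth[[si]] <- data.frame(
        sample = s,
        genome_id = frag_tab$genome_id[ifelse(idx > nfr, idx - nfr, idx)],
        fragment = frag_tab$frag_idx[ifelse(idx > nfr, idx - nfr, idx)],
        orientation = ifelse(idx > nfr, "R", "F"),
        count = cnt[idx],
        post_barcode_seq = post[idx],
        stringsAsFactors = FALSE
      )
    }
    list(reads = do.call(rbind, all_reads),
         truth = do.call(rbind, all_truth))
  })
}
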