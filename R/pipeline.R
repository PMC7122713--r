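# End-to-end pipeline driver: simulate -> demultiplex -> trim -> QC ->
# tags -> profiles -> variance components -> depth sensitivity, with a JSON
# run manifest. Every stage is also exported on its own; run_pipeline wires
# them together for synthetic studies and integration tests.

#' Default pipeline configuration
#'
#' Desk-scale defaults for a fully synthetic run; any entry can be
#' overridden via `...` or a YAML file ([load_config()]). `min_reads`
#' defaults to 1000 here (the study-scale floor of 100000 presumes millions
#' of reads per sample).
#'
#' @param ... overrides.
#' @return Named list of parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L, out_dir = tempfile("rerrs_run_"),
    n_genomes = 20L, genome_length = 50000L, gc = 0.45,
    n_animals = 8L, n_cohorts = 2L,
    sd_cohort = 0.3, sd_animal = 1, sd_sample = 1, methane_effect_sd = 1,
    target_m2 = 0.4,
    enzyme = "ApeKI", min_len = 65L, max_len = 195L,
    reads_per_sample = 20000L, error_rate = 0.001, read_length = 101L,
    adapter = "AGATCGGAAGAGCGGTTCAGCAGGAATGCCGAGACCGATCTCGTATGCCGTCTTCTGCTTG",
    max_mismatch = 0L, min_read_len = 40L, quality_cutoff = 20L,
    min_reads = 1000L,
    tag_length = 65L, min_prevalence = 0.25,
    pseudo = "add_one", pca_k = 2L,
    probabilities = c(0.5, 0.25, 0.1, 0.05, 0.01, 0.005, 0.002, 0.001),
    n_replicates = 5L, epsilon = 0.01,
    run_depth_curve = TRUE, run_varcomp = TRUE
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file of overrides to [default_config()].
#' @return Named list of parameters.
#' @export
load_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(default_config, over)
}

#' Run the full synthetic RE-RRS pipeline
#'
#' Simulates a community and multiplexed reads, demultiplexes, trims,
#' applies sample QC, builds the prevalence-filtered tag count matrix,
#' computes log10-proportion profiles, equal-weight PCA and the microbial
#' relationship matrix, fits repeatability / bivariate-correlation /
#' microbiability models, runs the compression-efficiency depth curve, and
#' writes all artifacts plus a JSON manifest under `config$out_dir`.
#'
#' @param config list from [default_config()] or [load_config()].
#' @return Invisibly, a list with all intermediate objects, fitted models
#'   and the manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  enz <- get_enzyme(cfg$enzyme)

  genomes <- generate_genomes(cfg$n_genomes, cfg$genome_length, cfg$gc,
                              seed = cfg$seed)
  design <- generate_design(cfg$n_animals, cfg$n_cohorts, seed = cfg$seed + 1L)
  truth <- generate_community(design, cfg$n_genomes,
                              sd_cohort = cfg$sd_cohort,
                              sd_animal = cfg$sd_animal,
                              sd_sample = cfg$sd_sample,
                              methane_effect_sd = cfg$methane_effect_sd,
                              seed = cfg$seed + 2L)
  y <- generate_phenotypes(truth, target_m2 = cfg$target_m2,
                           seed = cfg$seed + 3L)
  sim <- simulate_reads(genomes, truth, design, enz,
                        min_len = cfg$min_len, max_len = cfg$max_len,
                        reads_per_sample = cfg$reads_per_sample,
                        error_rate = cfg$error_rate,
                        read_length = cfg$read_length,
                        adapter = cfg$adapter, seed = cfg$seed + 4L)
  fastq_path <- file.path(cfg$out_dir, "reads.fastq.gz")
  write_fastq(sim$reads, fastq_path)
  utils::write.table(design, file.path(cfg$out_dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  raw <- read_fastq(fastq_path)
  bc_map <- stats::setNames(design$sample_id, design$barcode)
  dmx <- demultiplex(raw, bc_map, enz, max_mismatch = cfg$max_mismatch)
  trimmed <- trim_reads(dmx$assigned, cfg$adapter,
                        min_len = cfg$min_read_len,
                        quality_cutoff = cfg$quality_cutoff)
  counts_per_sample <- table(factor(trimmed$sample,
                                    levels = design$sample_id))
  qc <- sample_qc(stats::setNames(as.integer(counts_per_sample),
                                  design$sample_id),
                  min_reads = cfg$min_reads)
  kept <- qc$sample_id[qc$kept]
  utils::write.table(qc, file.path(cfg$out_dir, "sample_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(kept) < 2L) stop_fmt("fewer than 2 samples survive QC")

  per_sample <- split(trimmed$seq, trimmed$sample)[kept]
  m_full <- build_counts(per_sample, cfg$tag_length)
  m <- prevalence_filter(m_full, cfg$min_prevalence)
  write_count_matrix(m, file.path(cfg$out_dir, "tag_counts.tsv"))

  keep_design <- design[match(rownames(m), design$sample_id), ]
  prof <- log10_proportions(m, pseudo = cfg$pseudo)
  pca <- pca_equal_weight(prof, k = cfg$pca_k)
  mrm <- build_mrm(prof, keep_design$cohort)
  group <- paste(keep_design$cohort, keep_design$round, sep = "_")
  y_scaled <- scale_methane(y[rownames(m)], group)
  utils::write.table(
    data.frame(sample_id = rownames(m), pca$scores, check.names = FALSE),
    file.path(cfg$out_dir, "pc_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  fits <- NULL
  if (isTRUE(cfg$run_varcomp)) {
    fits <- list(
      repeatability_pc1 = fit_repeatability(pca$scores[, 1L],
                                            keep_design$cohort,
                                            keep_design$animal_id),
      repeatability_pc2 = fit_repeatability(pca$scores[, 2L],
                                            keep_design$cohort,
                                            keep_design$animal_id),
      correlation_pc1 = fit_bivariate_correlation(pca$scores[, 1L], y_scaled,
                                                  keep_design$cohort,
                                                  keep_design$animal_id),
      microbiability = fit_microbiability(y_scaled, mrm,
                                          keep_design$animal_id)
    )
  }

  curve <- NULL
  p_star <- NA_real_
  if (isTRUE(cfg$run_depth_curve)) {
    curve <- depth_curve(per_sample, cfg$probabilities,
                         n_replicates = cfg$n_replicates,
                         seed = cfg$seed + 5L)
    p_star <- find_lower_bound(curve, cfg$epsilon)
    utils::write.table(curve, file.path(cfg$out_dir, "depth_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rerrs")),
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    read_conservation = list(
      input = nrow(raw), assigned = nrow(dmx$assigned),
      unassigned = nrow(dmx$unassigned), trimmed = nrow(trimmed)
    ),
    samples_kept = length(kept),
    n_tags_raw = ncol(m_full), n_tags_filtered = ncol(m),
    p_star = p_star,
    checksums = as.list(tools::md5sum(list.files(cfg$out_dir,
                                                 full.names = TRUE,
                                                 pattern = "\\.tsv$")))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    config = cfg, genomes = genomes, design = design, truth = truth,
    phenotypes = y, sim = sim, qc = qc, counts_full = m_full, counts = m,
    profiles = prof, pca = pca, mrm = mrm, y_scaled = y_scaled,
    fits = fits, depth_curve = curve, p_star = p_star,
    manifest = manifest, manifest_path = manifest_path
  ))
}
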