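# Profile matrices and multivariate summaries: log10 proportions,
# equal-weight (correlation) PCA, the microbial relationship matrix, and
# phenotype scaling.

#' Log10-proportion profile matrix
#'
#' Each count is divided by its sample's row sum (the reads assigned for
#' that sample) and log10-transformed. Zero counts are the one step the
#' source procedure leaves open; the default `add_one` policy applies
#' Laplace smoothing, `value = log10((count + 1) / (rowsum + n_features))`,
#' while policy `"none"` uses raw proportions and errors on any zero count.
#'
#' @param m a count matrix.
#' @param pseudo `"add_one"` (default) or `"none"`.
#' @return Numeric matrix of log10 proportions (all entries <= 0) with the
#'   dimnames of `m`.
#' @export
log10_proportions <- function(m, pseudo = c("add_one", "none")) {
  pseudo <- match.arg(pseudo)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop_fmt("sample(s) with zero total count: %s",
             paste(utils::head(rownames(m)[rs == 0], 3), collapse = ", "))
  }
  if (pseudo == "none") {
    if (any(m == 0)) {
      stop_fmt("zero counts present; use pseudo = \"add_one\"")
    }
    log10(m / rs)
  } else {
    log10((m + 1) / (rs + ncol(m)))
  }
}

#' Equal-weight (correlation) principal component analysis
#'
#' Columns are centred and scaled to unit variance before the
#' eigen-analysis, giving every feature (genus or tag) equal weight;
#' computed by singular value decomposition via `stats::prcomp(scale. =
#' TRUE)`. Zero-variance features are dropped with a warning. At most
#' `min(n_samples - 1, n_features)` components are materialised.
#'
#' @param p numeric profile matrix (samples x features).
#' @param k number of components to retain (default all available).
#' @return list of class `rerrs_pca`: `scores` (samples x k), `loadings`,
#'   `pct_variance` (percent of total variance per component, computed over
#'   all components), `dropped` (zero-variance feature ids).
#' @export
pca_equal_weight <- function(p, k = NULL) {
  if (nrow(p) < 2L) stop_fmt("PCA needs at least 2 samples")
  sdv <- apply(p, 2L, stats::sd)
  dropped <- colnames(p)[sdv == 0 | !is.finite(sdv)]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance feature(s) before PCA",
                    length(dropped)))
    p <- p[, !(colnames(p) %in% dropped), drop = FALSE]
  }
  if (!ncol(p)) stop_fmt("no features with positive variance")
  fit <- stats::prcomp(p, center = TRUE, scale. = TRUE)
  ev <- fit$sdev^2
  pct <- 100 * ev / sum(ev)
  k <- min(k %||% length(ev), length(ev))
  structure(
    list(
      scores = fit$x[, seq_len(k), drop = FALSE],
      loadings = fit$rotation[, seq_len(k), drop = FALSE],
      pct_variance = pct[seq_len(k)],
      dropped = dropped
    ),
    class = "rerrs_pca"
  )
}

#' @export
print.rerrs_pca <- function(x, ...) {
  cat("Equal-weight PCA:", nrow(x$scores), "samples,",
      ncol(x$scores), "components\n")
  cat("Percent variance:",
      paste(sprintf("%.1f", utils::head(x$pct_variance, 5)), collapse = ", "),
      if (length(x$pct_variance) > 5) "...", "\n")
  invisible(x)
}

#' Microbial relationship matrix
#'
#' Standardises each feature column of the log10-proportion matrix within
#' cohort (mean 0, sd 1; zero-variance columns set to 0 for that cohort)
#' and correlates samples: `MRM[s, s']` is the Pearson correlation of the
#' two samples' standardised feature vectors. If the smallest eigenvalue
#' falls below `bend_tol`, the diagonal is inflated and the matrix
#' renormalised to unit diagonal (bending), keeping it usable as a REML
#' covariance structure.
#'
#' @param p numeric profile matrix (samples x features).
#' @param cohort character vector of cohort labels per sample (every cohort
#'   needs >= 2 samples).
#' @param bend_tol eigenvalue floor triggering bending (default 1e-6).
#' @return Symmetric n x n matrix of class `rerrs_mrm` with unit diagonal;
#'   attribute `bent` records whether bending was applied.
#' @export
build_mrm <- function(p, cohort, bend_tol = 1e-6) {
  if (length(cohort) != nrow(p)) {
    stop_fmt("cohort must have one label per sample")
  }
  sizes <- table(cohort)
  if (any(sizes < 2L)) {
    stop_fmt("cohort(s) with fewer than 2 samples: %s",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  z <- standardize_within_cohort(p, cohort)
  mrm <- stats::cor(t(z))
  bent <- FALSE
  ev <- eigen(mrm, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < bend_tol) {
    mrm <- mrm + diag(bend_tol - min(ev), nrow(mrm))
    d <- sqrt(diag(mrm))
    mrm <- mrm / tcrossprod(d)
    bent <- TRUE
  }
  dimnames(mrm) <- list(rownames(p), rownames(p))
  structure(mrm, class = c("rerrs_mrm", "matrix", "array"), bent = bent)
}

#' Scale a trait by contemporary-group mean
#'
#' `y_scaled = (y / mean(y within group)) * overall_mean` -- removes
#' contemporary-group level differences while restoring the population
#' mean (16.0 g CH4/kg DMI for methane yield). Preserves within-group rank
#' order.
#'
#' @param y numeric trait vector.
#' @param group contemporary-group label per record.
#' @param overall_mean population mean to restore (default 16.0).
#' @return Numeric vector of scaled values.
#' @export
scale_methane <- function(y, group, overall_mean = 16.0) {
  if (length(group) != length(y)) stop_fmt("group must match y in length")
  gm <- tapply(y, group, mean)
  if (any(gm <= 0)) {
    stop_fmt("non-positive contemporary-group mean(s): %s",
             paste(names(gm)[gm <= 0], collapse = ", "))
  }
  as.numeric(y / gm[as.character(group)] * overall_mean)
}
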