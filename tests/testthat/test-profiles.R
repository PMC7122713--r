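# Profile matrices: log10 proportions, equal-weight PCA, MRM, trait scaling.

test_that("log10 proportions match direct arithmetic under both policies", {
  m <- count_matrix(matrix(c(90L, 10L), 1, 2,
                           dimnames = list("s1", c("f1", "f2"))))
  p <- log10_proportions(m, pseudo = "none")
  expect_equal(unname(p[1, ]), c(log10(0.9), log10(0.1)))
  expect_equal(sum(10^p[1, ]), 1) # proportions reconstruct

  m0 <- count_matrix(matrix(c(100L, 0L), 1, 2,
                            dimnames = list("s1", c("f1", "f2"))))
  expect_error(log10_proportions(m0, pseudo = "none"), "zero")
  p0 <- log10_proportions(m0, pseudo = "add_one")
  expect_equal(unname(p0[1, ]), c(log10(101 / 102), log10(1 / 102)))
  expect_true(all(p0 <= 0))

  eq <- count_matrix(matrix(5L, 2, 4, dimnames = list(c("a", "b"),
                                                      paste0("f", 1:4))))
  peq <- log10_proportions(eq, pseudo = "none")
  expect_true(all(peq == log10(0.25)))

  zz <- count_matrix(matrix(c(0L, 0L, 3L, 4L), 2, 2,
                            dimnames = list(c("a", "b"), c("f1", "f2"))))
  zz[1, ] <- 0L
  expect_error(log10_proportions(zz), "zero total")
})

test_that("equal-weight PCA matches a brute-force correlation eigenanalysis", {
  set.seed(71)
  p <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("s", 1:6),
                                               paste0("f", 1:4)))
  fit <- pca_equal_weight(p)
  # oracle: eigen-decomposition of the feature correlation matrix
  ev <- eigen(cor(p), symmetric = TRUE)
  expect_equal(fit$pct_variance, 100 * ev$values / sum(ev$values),
               tolerance = 1e-10)
  z <- scale(p, center = TRUE, scale = TRUE)
  for (k in 1:3) {
    expect_gt(abs(cor(fit$scores[, k], z %*% ev$vectors[, k])), 1 - 1e-8)
  }
  # scores mutually orthogonal; pct variance non-increasing, sums to 100
  g <- crossprod(fit$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_true(all(diff(fit$pct_variance) <= 1e-12))
  expect_equal(sum(fit$pct_variance), 100)
})

test_that("perfectly correlated features load entirely on PC1", {
  p <- cbind(f1 = c(1, 2, 3, 4), f2 = c(2, 4, 6, 8))
  rownames(p) <- paste0("s", 1:4)
  fit <- pca_equal_weight(p)
  expect_equal(fit$pct_variance[1], 100)
})

test_that("zero-variance features are dropped with a warning", {
  set.seed(72)
  p <- cbind(matrix(rnorm(20), 5, 4), konst = rep(1, 5))
  colnames(p) <- c(paste0("f", 1:4), "konst")
  rownames(p) <- paste0("s", 1:5)
  expect_warning(fit <- pca_equal_weight(p), "zero-variance")
  expect_equal(fit$dropped, "konst")
  expect_error(pca_equal_weight(p[1, , drop = FALSE]), "2 samples")
})

test_that("the MRM equals a naive two-pass computation and is well-formed", {
  set.seed(73)
  p <- matrix(rnorm(8 * 50), 8, 50,
              dimnames = list(paste0("s", 1:8), paste0("f", 1:50)))
  cohort <- rep(c("c1", "c2"), each = 4)
  mrm <- build_mrm(p, cohort, bend_tol = -1) # bending off for the oracle
  # naive oracle: standardise within cohort, then correlate sample rows
  z <- p
  for (co in unique(cohort)) {
    idx <- cohort == co
    for (j in seq_len(ncol(p))) {
      v <- p[idx, j]
      z[idx, j] <- (v - mean(v)) / sd(v)
    }
  }
  oracle <- cor(t(z))
  expect_equal(unclass(mrm), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(diag(mrm)), rep(1, 8))
  expect_true(isSymmetric(unclass(mrm)))
  expect_true(all(mrm >= -1 - 1e-12 & mrm <= 1 + 1e-12))
  ev <- eigen(unclass(mrm), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
})

test_that("identical profiles within a cohort correlate at 1", {
  set.seed(74)
  p <- matrix(rnorm(4 * 30), 4, 30)
  p[2, ] <- p[1, ] # duplicate profile
  rownames(p) <- paste0("s", 1:4)
  mrm <- build_mrm(p, rep("c1", 4), bend_tol = -1)
  expect_equal(unname(mrm[1, 2]), 1, tolerance = 1e-9)
  expect_error(build_mrm(p, c("c1", "c1", "c1", "solo")), "fewer than 2")
})

test_that("MRM is invariant to cohort-constant feature shifts", {
  set.seed(75)
  p <- matrix(rnorm(6 * 20), 6, 20, dimnames = list(paste0("s", 1:6), NULL))
  cohort <- rep(c("c1", "c2"), each = 3)
  mrm1 <- build_mrm(p, cohort)
  p2 <- p
  p2[cohort == "c1", 7] <- p2[cohort == "c1", 7] + 5 # constant within cohort
  p2[cohort == "c2", 7] <- p2[cohort == "c2", 7] - 2
  mrm2 <- build_mrm(p2, cohort)
  expect_equal(unclass(mrm1), unclass(mrm2), tolerance = 1e-12)
})

test_that("methane scaling restores the overall mean within groups", {
  expect_equal(scale_methane(15, "g1"), 16)
  expect_equal(scale_methane(18, "g1", overall_mean = 16), 16) # single record
  y <- c(18, 15, 12, 20, 10)
  g <- c("a", "a", "a", "b", "b")
  ys <- scale_methane(y, g)
  expect_equal(ys[1], 18 / 15 * 16)
  expect_equal(as.numeric(tapply(ys, g, mean)), c(16, 16))
  # within-group rank order preserved
  expect_equal(order(ys[1:3]), order(y[1:3]))
  expect_equal(scale_methane(c(3, 3, 3), rep("g", 3)), rep(16, 3))
  expect_error(scale_methane(c(-2, 0), c("a", "a")), "non-positive")
})
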