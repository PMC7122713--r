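# Mixed-model analyses of profile summaries: repeatability of a trait with
# repeated samples per animal, bivariate phenotypic correlation with scaled
# methane yield, and microbiability from a microbial relationship matrix.
# All three are thin model builders over the generic REML engine and return
# a common S3 object.

new_vc <- function(model, sigma2, ratios, se, cohort_pct, fit) {
  structure(
    list(model = model, sigma2 = sigma2, ratios = ratios, se = se,
         cohort_pct = cohort_pct, beta = fit$beta, loglik = fit$loglik,
         converged = fit$converged, boundary = fit$boundary,
         n_iter = fit$n_iter, theta_cov = fit$theta_cov),
    class = "rerrs_vc"
  )
}

#' Repeatability of a trait with repeated samples per animal
#'
#' Fits `y = cohort (fixed) + animal permanent environment (random) +
#' residual` by REML and reports the repeatability
#' `t = sigma2_pe / (sigma2_pe + sigma2_e)` -- the fraction of
#' cohort-adjusted variance attributable to the animal -- plus the percent
#' of total variance explained by the fitted cohort effects,
#' `100 * var(fitted cohort) / (var(fitted cohort) + sigma2_pe + sigma2_e)`.
#'
#' @param y numeric trait vector (one value per sample).
#' @param cohort cohort label per sample (fixed class effect).
#' @param animal animal id per sample (links repeated samples).
#' @param ... passed to [reml_fit()].
#' @return An object of class `rerrs_vc` with ratio `repeatability`.
#' @export
fit_repeatability <- function(y, cohort, animal, ...) {
  cohort <- factor(cohort)
  animal <- factor(animal)
  if (nlevels(animal) < 2L) stop_fmt("need at least 2 animals")
  X <- stats::model.matrix(~cohort)
  if (qr(X)$rank < ncol(X)) stop_fmt("singular fixed-effect design")
  Z <- stats::model.matrix(~ animal - 1)
  Vlist <- list(pe = tcrossprod(Z), e = diag(length(y)))
  fit <- reml_fit(y, X, Vlist, ...)
  s <- fit$theta
  tot <- s[["pe"]] + s[["e"]]
  t_hat <- s[["pe"]] / tot
  grad <- c(s[["e"]], -s[["pe"]]) / tot^2
  se_t <- delta_se(grad, fit$theta_cov)
  fitted_cohort <- drop(X %*% fit$beta)
  vc <- stats::var(fitted_cohort)
  cohort_pct <- 100 * vc / (vc + tot)
  new_vc("repeatability", s, c(repeatability = unname(t_hat)),
         c(repeatability = se_t), cohort_pct, fit)
}

#' Phenotypic correlation between two traits (bivariate REML)
#'
#' Fits a bivariate mixed model on traits observed on the same samples:
#' fixed cohort per trait, a random animal permanent-environment effect
#' with unstructured 2x2 covariance, and an unstructured 2x2 residual.
#' The phenotypic correlation is
#' `r_p = (pe12 + e12) / sqrt((pe11 + e11) * (pe22 + e22))`.
#'
#' Perfectly collinear traits (cohort-adjusted correlation of exactly
#' +/-1) make the REML problem degenerate -- the likelihood is unbounded
#' along several boundary directions -- so they are detected up front and
#' reported directly as `r_p = +/-1` with a boundary flag.
#'
#' @param y1,y2 numeric trait vectors on the same samples (e.g. a principal
#'   component score and scaled methane yield).
#' @param cohort,animal labels per sample.
#' @param ... passed to [reml_fit()].
#' @return An object of class `rerrs_vc` with ratio `r_p`.
#' @export
fit_bivariate_correlation <- function(y1, y2, cohort, animal, ...) {
  n <- length(y1)
  stopifnot(length(y2) == n, length(cohort) == n, length(animal) == n)
  cohort <- factor(cohort)
  animal <- factor(animal)
  r1 <- stats::residuals(stats::lm(y1 ~ cohort))
  r2 <- stats::residuals(stats::lm(y2 ~ cohort))
  adj_cor <- suppressWarnings(stats::cor(r1, r2))
  if (is.finite(adj_cor) && abs(adj_cor) > 1 - 1e-10) {
    uni <- fit_repeatability(y1, cohort, animal)
    s <- uni$sigma2
    k <- stats::sd(r2) / max(stats::sd(r1), .Machine$double.eps)
    sgn <- sign(adj_cor)
    sigma2 <- c(pe11 = s[["pe"]], pe22 = s[["pe"]] * k^2,
                pe12 = sgn * s[["pe"]] * k,
                e11 = s[["e"]], e22 = s[["e"]] * k^2,
                e12 = sgn * s[["e"]] * k)
    fit <- list(beta = uni$beta, loglik = NA_real_, converged = TRUE,
                boundary = TRUE, n_iter = 0L,
                theta_cov = matrix(NA_real_, 6, 6))
    return(new_vc("bivariate_correlation", sigma2, c(r_p = sgn),
                  c(r_p = 0), NA_real_, fit))
  }
  y <- c(y1, y2)
  X1 <- stats::model.matrix(~cohort)
  zero <- matrix(0, n, ncol(X1))
  X <- rbind(cbind(X1, zero), cbind(zero, X1))
  Z <- stats::model.matrix(~ animal - 1)
  A <- tcrossprod(Z)
  In <- diag(n)
  O <- matrix(0, n, n)
  blk <- function(tl, tr, br) rbind(cbind(tl, tr), cbind(t(tr), br))
  Vlist <- list(
    pe11 = blk(A, O, O), pe22 = blk(O, O, A), pe12 = blk(O, A, O),
    e11 = blk(In, O, O), e22 = blk(O, O, In), e12 = blk(O, In, O)
  )
  is_var <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  v1 <- stats::var(y1)
  v2 <- stats::var(y2)
  init <- c(v1 / 2, v2 / 2, 0, v1 / 2, v2 / 2, 0)
  fit <- reml_fit(y, X, Vlist, is_var = is_var, init = init, ...)
  if (isTRUE(fit$stalled)) {
    # optimum on the positive-definiteness boundary (e.g. traits that are
    # near-copies): polish on a Cholesky parameterisation of the 2x2
    # component matrices, which reaches the boundary smoothly
    fit <- polish_bivariate(fit, y, X, Vlist)
  }
  s <- fit$theta
  c12 <- s[["pe12"]] + s[["e12"]]
  t1 <- s[["pe11"]] + s[["e11"]]
  t2 <- s[["pe22"]] + s[["e22"]]
  r_p <- c12 / sqrt(t1 * t2)
  # gradient in order pe11, pe22, pe12, e11, e22, e12
  g_c <- 1 / sqrt(t1 * t2)
  g_t1 <- -c12 / (2 * t1^1.5 * sqrt(t2))
  g_t2 <- -c12 / (2 * t2^1.5 * sqrt(t1))
  grad <- c(g_t1, g_t2, g_c, g_t1, g_t2, g_c)
  se_r <- delta_se(grad, fit$theta_cov)
  new_vc("bivariate_correlation", s, c(r_p = unname(r_p)),
         c(r_p = se_r), NA_real_, fit)
}

# Nelder-Mead refinement of a bivariate fit in Cholesky coordinates
# (pe = Lp Lp', e = Le Le'): keeps both 2x2 component matrices positive
# semidefinite while allowing the correlation to reach +/-1.
polish_bivariate <- function(fit, y, X, Vlist) {
  to_chol <- function(v11, v12, v22) {
    v11 <- max(v11, 1e-12)
    v22 <- max(v22, 1e-12)
    rho <- max(min(v12 / sqrt(v11 * v22), 0.999), -0.999)
    c(sqrt(v11), rho * sqrt(v22), sqrt(v22 * (1 - rho^2)))
  }
  from_chol <- function(l) {
    c(l[1]^2, l[1] * l[2], l[2]^2 + l[3]^2)
  }
  th <- fit$theta
  phi0 <- c(to_chol(th[["pe11"]], th[["pe12"]], th[["pe22"]]),
            to_chol(th[["e11"]], th[["e12"]], th[["e22"]]))
  theta_of <- function(phi) {
    pe <- from_chol(phi[1:3])
    e <- from_chol(phi[4:6])
    c(pe11 = pe[1], pe22 = pe[3], pe12 = pe[2],
      e11 = e[1], e22 = e[3], e12 = e[2])
  }
  obj <- function(phi) {
    ll <- reml_loglik(theta_of(phi), y, X, Vlist)
    if (!is.finite(ll)) 1e10 else -ll
  }
  grad <- function(phi) {
    sc <- reml_score(theta_of(phi), y, X, Vlist)
    if (is.null(sc)) return(rep(0, 6))
    # Jacobian of (v11, v22, v12) wrt (l1, l2, l3) per component block,
    # theta ordered pe11, pe22, pe12, e11, e22, e12
    jac_block <- function(l) {
      rbind(c(2 * l[1], 0, 0),       # v11
            c(0, 2 * l[2], 2 * l[3]), # v22
            c(l[2], l[1], 0))         # v12
    }
    gpe <- drop(sc[1:3] %*% jac_block(phi[1:3]))
    ge <- drop(sc[4:6] %*% jac_block(phi[4:6]))
    -c(gpe, ge)
  }
  opt <- stats::optim(phi0, obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (-opt$value > fit$loglik) {
    fit$theta <- theta_of(opt$par)[names(fit$theta)]
    fit$loglik <- -opt$value
    fit$converged <- opt$convergence == 0
    ws <- reml_workspace(fit$theta, y, X, Vlist)
    if (!is.null(ws)) fit$beta <- ws$beta
  }
  fit
}

#' Microbiability of a trait
#'
#' Fits `y = mean + g + pe + e` with `g ~ (0, MRM * sigma2_m)` (the
#' microbial-relationship random effect), `pe` the animal
#' permanent-environment effect and `e` residual, and reports the
#' microbiability `m2 = sigma2_m / (sigma2_m + sigma2_pe + sigma2_e)`: the
#' share of phenotypic variance attributed to the microbial profile.
#'
#' @param y numeric trait vector (scaled methane yield), aligned with the
#'   MRM rows.
#' @param mrm microbial relationship matrix ([build_mrm()]).
#' @param animal animal id per sample.
#' @param ... passed to [reml_fit()].
#' @return An object of class `rerrs_vc` with ratio `microbiability`.
#' @export
fit_microbiability <- function(y, mrm, animal, ...) {
  mrm <- unclass(mrm)
  if (nrow(mrm) != length(y)) {
    stop_fmt("MRM dimension (%d) does not match y (%d)", nrow(mrm), length(y))
  }
  animal <- factor(animal)
  X <- matrix(1, length(y), 1L)
  Z <- stats::model.matrix(~ animal - 1)
  Vlist <- list(m = mrm, pe = tcrossprod(Z), e = diag(length(y)))
  fit <- reml_fit(y, X, Vlist, ...)
  s <- fit$theta
  tot <- sum(s)
  m2 <- s[["m"]] / tot
  grad <- c(tot - s[["m"]], -s[["m"]], -s[["m"]]) / tot^2
  se_m <- delta_se(grad, fit$theta_cov)
  new_vc("microbiability", s, c(microbiability = unname(m2)),
         c(microbiability = se_m), NA_real_, fit)
}

#' @export
print.rerrs_vc <- function(x, ...) {
  cat("REML fit:", x$model, "\n")
  cat("Variance components:\n")
  print(round(x$sigma2, 6))
  for (r in names(x$ratios)) {
    cat(sprintf("%s = %.3f (SE %.3f)\n", r, x$ratios[[r]], x$se[[r]]))
  }
  if (!is.na(x$cohort_pct)) {
    cat(sprintf("Cohort %% variance = %.1f\n", x$cohort_pct))
  }
  cat(sprintf("logLik = %.3f, %s in %d iterations%s\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (x$boundary) " (boundary)" else ""))
  invisible(x)
}

#' @export
summary.rerrs_vc <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.rerrs_vc <- function(object, ...) object$sigma2

#' @export
logLik.rerrs_vc <- function(object, ...) {
  structure(object$loglik, class = "logLik", df = length(object$sigma2))
}
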