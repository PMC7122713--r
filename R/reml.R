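# Generic REML engine for linear variance structures V(theta) = sum_i
# theta_i * V_i. Average-information updates with an EM-style multiplicative
# warm start; variance coefficients are kept above a small positive floor,
# covariance coefficients are free. Dense algebra throughout -- the designs
# this package fits are a few hundred records.

#' REML log-likelihood of a linear variance structure
#'
#' `-0.5 * (log|V| + log|X'V^-1 X| + y' P y)` with
#' `V = sum(theta_i * V_i)`; returns `-Inf` when `V` is not positive
#' definite.
#'
#' @param theta numeric coefficient vector.
#' @param y response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param Vlist list of symmetric matrices, one per coefficient.
#' @return The restricted log-likelihood (up to an additive constant).
#' @export
reml_loglik <- function(theta, y, X, Vlist) {
  V <- Reduce(`+`, Map(`*`, theta, Vlist))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  XtVX <- crossprod(X, Vi %*% X)
  ch2 <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch2)) return(-Inf)
  ViX <- Vi %*% X
  P <- Vi - ViX %*% chol2inv(ch2) %*% t(ViX)
  as.numeric(-0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) +
                       crossprod(y, P %*% y)))
}

# P matrix and derived quantities for a given theta; NULL if V not PD.
reml_workspace <- function(theta, y, X, Vlist) {
  V <- Reduce(`+`, Map(`*`, theta, Vlist))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  XtVX <- crossprod(X, Vi %*% X)
  ch2 <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch2)) return(NULL)
  XtVXi <- chol2inv(ch2)
  ViX <- Vi %*% X
  P <- Vi - ViX %*% XtVXi %*% t(ViX)
  Py <- P %*% y
  ll <- as.numeric(-0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) +
                             crossprod(y, Py)))
  beta <- XtVXi %*% crossprod(X, Vi %*% y)
  list(P = P, Py = Py, ll = ll, beta = drop(beta))
}

#' Fit a linear variance structure by REML
#'
#' EM-style warm start (multiplicative updates on the variance
#' coefficients) followed by average-information updates with step halving;
#' variance coefficients are constrained to a small positive floor.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix.
#' @param Vlist named list of symmetric component matrices.
#' @param is_var logical per component: `TRUE` for variances (floored at
#'   `floor_frac * var(y)`), `FALSE` for free covariances.
#' @param init optional initial coefficients.
#' @param max_iter maximum AI iterations (default 200).
#' @param warm_start number of EM-style warm-start iterations (default 10).
#' @param tol_ll,tol_par relative log-likelihood and absolute parameter
#'   convergence tolerances.
#' @param floor_frac variance floor as a fraction of `var(y)`.
#' @return list: `theta`, `theta_cov` (inverse average information),
#'   `loglik`, `beta`, `converged`, `boundary`, `n_iter`.
#' @export
reml_fit <- function(y, X, Vlist, is_var = rep(TRUE, length(Vlist)),
                     init = NULL, max_iter = 200L, warm_start = 10L,
                     tol_ll = 1e-8, tol_par = 1e-6, floor_frac = 1e-6) {
  k <- length(Vlist)
  vy <- stats::var(y)
  floor <- floor_frac * vy
  theta <- init %||% ifelse(is_var, vy / sum(is_var), 0)
  ws <- reml_workspace(theta, y, X, Vlist)
  if (is.null(ws)) stop_fmt("initial variance structure is not positive definite")

  # EM-style warm start: robust multiplicative updates, variances only
  for (it in seq_len(warm_start)) {
    for (i in which(is_var)) {
      num <- as.numeric(crossprod(ws$Py, Vlist[[i]] %*% ws$Py))
      den <- sum(ws$P * Vlist[[i]])
      if (den > 0 && num > 0) {
        theta[i] <- max(theta[i] * sqrt(num / den), floor)
      }
    }
    new_ws <- reml_workspace(theta, y, X, Vlist)
    if (!is.null(new_ws)) ws <- new_ws
  }

  converged <- FALSE
  stalled <- FALSE
  n_iter <- 0L
  AI <- diag(k)
  for (it in seq_len(max_iter)) {
    n_iter <- it
    score <- numeric(k)
    PVy <- vector("list", k)
    for (i in seq_len(k)) {
      ViPy <- Vlist[[i]] %*% ws$Py
      PVy[[i]] <- ws$P %*% ViPy
      score[i] <- -0.5 * (sum(ws$P * Vlist[[i]]) -
                            as.numeric(crossprod(ws$Py, ViPy)))
    }
    for (i in seq_len(k)) {
      for (j in i:k) {
        AI[i, j] <- AI[j, i] <-
          0.5 * as.numeric(crossprod(ws$Py, Vlist[[i]] %*% PVy[[j]]))
      }
    }
    # candidate directions: AI solves with escalating Levenberg-Marquardt
    # ridges (guards near-singular AI at covariance boundaries), then plain
    # scaled gradient ascent as a last resort
    scale0 <- mean(abs(diag(AI))) + 1e-300
    dirs <- lapply(c(0, 1e-6, 1e-3, 1, 1e3), function(lam) {
      tryCatch(solve(AI + diag(lam * scale0, k), score),
               error = function(e) NULL)
    })
    gnorm <- sqrt(sum(score^2))
    if (gnorm > 0) {
      dirs <- c(dirs, list(score / gnorm * max(abs(theta), vy) * 0.1))
    }
    ok <- FALSE
    for (step in dirs) {
      if (is.null(step) || any(!is.finite(step))) next
      for (h in 0:15) {
        cand <- theta + step / 2^h
        cand[is_var] <- pmax(cand[is_var], floor)
        cand_ws <- reml_workspace(cand, y, X, Vlist)
        if (!is.null(cand_ws) && cand_ws$ll >= ws$ll - 1e-10) {
          ok <- TRUE
          break
        }
      }
      if (ok) break
    }
    if (!ok) { # no improving step found: stop, flag a stall if the
      # gradient is still large (optimum on a constraint boundary)
      converged <- TRUE
      stalled <- sqrt(sum(score^2)) > 1e-3 * (1 + abs(ws$ll))
      break
    }
    dll <- cand_ws$ll - ws$ll
    dpar <- max(abs(cand - theta))
    theta <- cand
    ws <- cand_ws
    if (abs(dll) < tol_ll * (1 + abs(ws$ll)) && dpar < tol_par * (1 + max(abs(theta)))) {
      converged <- TRUE
      break
    }
  }
  theta_cov <- tryCatch(solve(AI), error = function(e) {
    solve(AI + diag(1e-8 * max(abs(diag(AI)), 1), k))
  })
  names(theta) <- names(Vlist)
  dimnames(theta_cov) <- list(names(Vlist), names(Vlist))
  list(theta = theta, theta_cov = theta_cov, loglik = ws$ll,
       beta = ws$beta, converged = converged, stalled = stalled,
       boundary = any(is_var & theta <= floor * (1 + 1e-8)),
       n_iter = n_iter)
}

# REML score vector dl/dtheta at theta; NULL when V is not PD.
reml_score <- function(theta, y, X, Vlist) {
  ws <- reml_workspace(theta, y, X, Vlist)
  if (is.null(ws)) return(NULL)
  vapply(Vlist, function(Vi) {
    -0.5 * (sum(ws$P * Vi) - as.numeric(crossprod(ws$Py, Vi %*% ws$Py)))
  }, numeric(1))
}

# Delta-method standard error of g(theta) with gradient `grad`.
delta_se <- function(grad, theta_cov) {
  v <- as.numeric(t(grad) %*% theta_cov %*% grad)
  if (v < 0) return(NA_real_)
  sqrt(v)
}
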