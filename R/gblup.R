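#' Variance components and heritability summaries
#'
#' Collects additive, dominance and residual variance components and fills
#' in the standard derived ratios: total genotypic variance `Vg = Va + Vd`,
#' phenotypic variance `Vp = Va + Vd + Ve`, narrow-sense heritability
#' `h2 = Va/Vp`, broad-sense heritability `H2 = (Va + Vd)/Vp`, proportion of
#' dominance variance `PDV = Vd/Vg`, and `d2 = Vd/Vp`. When `Vg = 0` the PDV
#' is reported as 0 with attribute `pdv_undefined = TRUE`. `Ve = NA` leaves
#' the phenotypic-scale ratios NA (useful for decompositions of noiseless
#' genetic values).
#'
#' @param Va additive variance (trait units squared).
#' @param Vd dominance variance.
#' @param Ve residual variance (NA allowed).
#' @return A list of class `var_components` with elements `Va`, `Vd`, `Ve`,
#'   `Vg`, `Vp`, `h2`, `H2`, `PDV`, `d2`.
#' @export
var_components <- function(Va, Vd = 0, Ve = NA_real_) {
  if (any(c(Va, Vd) < 0) || (!is.na(Ve) && Ve < 0)) {
    stop("variance components must be non-negative")
  }
  Vg <- Va + Vd
  Vp <- Vg + Ve
  pdv_undefined <- Vg <= 0
  out <- list(
    Va = Va, Vd = Vd, Ve = Ve, Vg = Vg, Vp = Vp,
    h2 = Va / Vp, H2 = Vg / Vp,
    PDV = if (pdv_undefined) 0 else Vd / Vg,
    d2 = Vd / Vp
  )
  attr(out, "pdv_undefined") <- pdv_undefined
  class(out) <- "var_components"
  out
}

#' @export
print.var_components <- function(x, digits = 4, ...) {
  cat("variance components\n")
  cat(sprintf("  Va = %.*g  Vd = %.*g  Ve = %.*g\n",
              digits, x$Va, digits, x$Vd, digits, x$Ve))
  cat(sprintf("  h2 = %.*g  H2 = %.*g  PDV = %.*g  d2 = %.*g\n",
              digits, x$h2, digits, x$H2, digits, x$PDV, digits, x$d2))
  invisible(x)
}

# Restricted log-likelihood profile for a single kernel, parameterised by
# delta = Ve/Vg on the natural-log scale, after projecting out the fixed
# effects (EMMA-style eigendecomposition).
reml_single_profile <- function(eta2, lambda) {
  np <- length(eta2)
  function(log_delta) {
    delta <- exp(log_delta)
    denom <- lambda + delta
    0.5 * (np * log(np / (2 * pi)) - np -
             np * log(sum(eta2 / denom)) - sum(log(denom)))
  }
}

reml_single <- function(y, X, K, bracket = c(-10, 10), tol = 1e-8) {
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design X is rank-deficient")
  if (stats::var(y) < 1e-12) {
    return(list(Vg = 0, Ve = 0, beta = rep(0, p), alpha = rep(0, n),
                loglik = NA_real_, converged = FALSE, boundary = TRUE,
                n_iter = 0L, delta = NA_real_,
                eig = NULL))
  }
  # explicit orthonormal complement of the fixed-effect column space, so
  # zero-eigenvalue kernel directions cannot mix with the X null space
  Q2 <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  M <- crossprod(Q2, K %*% Q2)
  M <- (M + t(M)) / 2
  eig <- eigen(M, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  eta <- drop(crossprod(eig$vectors, crossprod(Q2, y)))
  prof <- reml_single_profile(eta^2, lambda)
  opt <- stats::optimize(prof, interval = bracket, maximum = TRUE,
                         tol = tol)
  log_delta <- opt$maximum
  boundary <- min(abs(log_delta - bracket)) < 1e-4
  delta <- exp(log_delta)
  Vg <- sum(eta^2 / (lambda + delta)) / (n - p)
  Ve <- delta * Vg
  Vfull <- Vg * (K + delta * diag(n))
  cV <- chol(Vfull)
  Viy <- backsolve(cV, forwardsolve(t(cV), y))
  ViX <- backsolve(cV, forwardsolve(t(cV), X))
  beta <- solve(crossprod(X, ViX), crossprod(X, Viy))
  resid <- y - X %*% beta
  alpha <- backsolve(cV, forwardsolve(t(cV), resid))
  list(Vg = Vg, Ve = Ve, beta = drop(beta), alpha = drop(alpha),
       loglik = opt$objective, converged = !boundary, boundary = boundary,
       n_iter = 1L, delta = delta, profile = prof,
       lambda = lambda, eta = eta)
}

# Multi-kernel REML: average-information updates with EM fallback steps.
# The residual is treated as an extra identity kernel.
reml_multi <- function(y, X, kernels, tol = 1e-6, max_iter = 500) {
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design X is rank-deficient")
  Ks <- c(kernels, list(diag(n)))
  nk <- length(Ks)
  vy <- stats::var(y)
  theta <- rep(vy / nk, nk)
  floor_v <- 1e-8 * vy
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    V <- matrix(0, n, n)
    for (k in seq_len(nk)) V <- V + theta[k] * Ks[[k]]
    cV <- tryCatch(chol(V), error = function(e) chol(V + floor_v * diag(n)))
    Vi <- chol2inv(cV)
    ViX <- Vi %*% X
    XtViX_i <- solve(crossprod(X, ViX))
    # products with P = Vi - ViX (X'ViX)^{-1} X'Vi without forming P
    Pmult <- function(v) {
      drop(Vi %*% v - ViX %*% (XtViX_i %*% crossprod(ViX, v)))
    }
    Py <- Pmult(y)
    KPy <- lapply(Ks, function(K) drop(K %*% Py))
    PKPy <- lapply(KPy, Pmult)
    score <- numeric(nk)
    trPK <- numeric(nk)
    for (k in seq_len(nk)) {
      KViX <- Ks[[k]] %*% ViX
      trPK[k] <- sum(Vi * Ks[[k]]) -
        sum(XtViX_i * crossprod(ViX, KViX))
      score[k] <- -0.5 * (trPK[k] - sum(Py * KPy[[k]]))
    }
    AI <- matrix(0, nk, nk)
    for (k in seq_len(nk)) {
      for (l in k:nk) {
        AI[k, l] <- AI[l, k] <- 0.5 * sum(KPy[[k]] * PKPy[[l]])
      }
    }
    step_ok <- FALSE
    new_theta <- tryCatch({
      cand <- theta + solve(AI, score)
      if (all(cand > floor_v)) {
        step_ok <- TRUE
        cand
      } else cand
    }, error = function(e) theta)
    if (!step_ok) {
      # EM update: guaranteed to keep components non-negative
      new_theta <- theta + theta^2 * (vapply(
        seq_len(nk), function(k) sum(Py * KPy[[k]]) - trPK[k], numeric(1)
      )) / n
      new_theta <- pmax(new_theta, floor_v)
    }
    delta_rel <- max(abs(new_theta - theta) / pmax(abs(theta), floor_v))
    theta <- new_theta
    if (delta_rel < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  # final quantities at the converged estimates
  V <- matrix(0, n, n)
  for (k in seq_len(nk)) V <- V + theta[k] * Ks[[k]]
  cV <- tryCatch(chol(V), error = function(e) chol(V + floor_v * diag(n)))
  Vi <- chol2inv(cV)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(ViX, y))
  resid <- y - X %*% beta
  alpha <- drop(Vi %*% resid)
  loglik <- -0.5 * (2 * sum(log(diag(cV))) + determinant(XtViX)$modulus +
                      sum(resid * alpha))
  list(theta = theta[-nk], Ve = theta[nk], beta = drop(beta), alpha = alpha,
       loglik = as.numeric(loglik), converged = converged, n_iter = it)
}

#' Fit a GBLUP mixed model by restricted maximum likelihood
#'
#' Fits `y = X beta + sum_k u_k + e` with `u_k ~ N(0, sigma_k^2 K_k)` and
#' `e ~ N(0, sigma_e^2 I)`. With a single kernel the restricted likelihood
#' is profiled over the variance ratio via the eigendecomposition of the
#' projected kernel (EMMA) and maximised by Brent's method on the log-ratio
#' over \[-10, 10\]; with several kernels an average-information scheme with
#' EM fallback steps is iterated to convergence (relative change < 1e-6,
#' at most 500 iterations).
#'
#' The three classical hybrid-prediction models are configurations of this
#' fit: `AM` = single additive kernel, `CADM` = single combined kernel from
#' the dominance-transformed matrix, `ADM` = additive + dominance kernels.
#'
#' @param y numeric response (phenotypes or BLUEs).
#' @param kernels one relationship matrix, or a (optionally named) list of
#'   them, dimensioned like `length(y)`.
#' @param X fixed-effect design matrix; default intercept only.
#' @return An object of class `gblup`: variance components
#'   ([var_components()]; a single non-additive kernel fills `Va` with the
#'   kernel's variance), `beta`, per-kernel training BLUPs `u`, `alpha`
#'   (V^{-1}(y - X beta), used for prediction), `loglik`, `converged`,
#'   `n_iter` and the model inputs.
#' @seealso [predict.gblup()]
#' @export
gblup <- function(y, kernels, X = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.matrix(kernels)) kernels <- list(kernels)
  kinds <- vapply(kernels, function(K) attr(K, "kind") %||% "additive",
                  character(1))
  if (is.null(names(kernels)) || any(names(kernels) == "")) {
    names(kernels) <- make.unique(kinds)
  }
  kernels <- lapply(kernels, function(K) {
    K <- unclass(K)
    stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == n)
    if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K)))) {
      stop("kernel is not symmetric")
    }
    (K + t(K)) / 2
  })
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (length(kernels) == 1L) {
    fit <- reml_single(y, X, kernels[[1]])
    sigma <- stats::setNames(fit$Vg, names(kernels))
    Ve <- fit$Ve
    loglik <- fit$loglik
    converged <- fit$converged
    n_iter <- fit$n_iter
    alpha <- fit$alpha
    beta <- fit$beta
    profile <- fit$profile
  } else {
    fit <- reml_multi(y, X, kernels)
    sigma <- stats::setNames(fit$theta, names(kernels))
    Ve <- fit$Ve
    loglik <- fit$loglik
    converged <- fit$converged
    n_iter <- fit$n_iter
    alpha <- fit$alpha
    beta <- fit$beta
    profile <- NULL
  }
  Va <- sum(sigma[kinds %in% c("additive", "combined")])
  Vd <- sum(sigma[kinds == "dominance"])
  comp <- var_components(Va = Va, Vd = Vd, Ve = max(Ve, 0))
  u <- lapply(seq_along(kernels),
              function(k) sigma[k] * drop(kernels[[k]] %*% alpha))
  names(u) <- names(kernels)
  structure(
    list(
      components = comp, sigma = sigma, beta = beta, u = u, alpha = alpha,
      loglik = loglik, converged = converged, n_iter = n_iter,
      y = y, X = X, kernels = kernels, kernel_kinds = kinds,
      profile = profile
    ),
    class = "gblup"
  )
}

#' @export
print.gblup <- function(x, ...) {
  cat(sprintf("gblup fit: %d individuals, %d kernel(s) [%s]\n",
              length(x$y), length(x$kernels),
              paste(names(x$kernels), collapse = ", ")))
  cat("  sigma^2:", paste(sprintf("%s=%.4g", names(x$sigma), x$sigma),
                          collapse = ", "),
      sprintf(", Ve=%.4g\n", x$components$Ve))
  cat(sprintf("  REML loglik %.4f (%s, %d iterations)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' @export
summary.gblup <- function(object, ...) {
  out <- list(components = object$components, sigma = object$sigma,
              beta = object$beta, loglik = object$loglik,
              converged = object$converged)
  class(out) <- "summary.gblup"
  out
}

#' @export
print.summary.gblup <- function(x, ...) {
  print(x$components)
  cat("fixed effects:\n")
  print(x$beta)
  invisible(x)
}

#' @export
coef.gblup <- function(object, ...) object$beta

#' @export
fitted.gblup <- function(object, ...) {
  drop(object$X %*% object$beta) + Reduce(`+`, object$u)
}

#' @export
residuals.gblup <- function(object, ...) object$y - fitted(object)

#' Predict genetic values of held-out individuals from a GBLUP fit
#'
#' Conditional-mean prediction: for each kernel,
#' `g_hat_test = sigma_k^2 K_k[test, train] V_train^{-1} (y - X beta)`, with
#' the total prediction being the sum of kernel contributions plus the
#' fixed-effect part. Equivalent to solving the full mixed-model equations
#' with the test records missing.
#'
#' @param object a [gblup()] fit obtained from the training rows only.
#' @param kernels full relationship matrices (same order/names as the fit's
#'   kernels) covering training and test individuals, or pre-sliced
#'   `K[test, train]` blocks when `train`/`test` are omitted.
#' @param train,test row indices of the training and test individuals in
#'   `kernels` (training order must match the order used in the fit).
#' @param X_test fixed-effect design for the test individuals (default
#'   intercept).
#' @param ... unused.
#' @return Numeric vector of predicted values for the test individuals.
#' @export
predict.gblup <- function(object, kernels, train = NULL, test = NULL,
                          X_test = NULL, ...) {
  if (is.matrix(kernels)) kernels <- list(kernels)
  stopifnot(length(kernels) == length(object$kernels))
  blocks <- lapply(kernels, function(K) {
    K <- unclass(K)
    if (!is.null(train)) K[test, train, drop = FALSE] else K
  })
  n_test <- nrow(blocks[[1]])
  if (is.null(X_test)) {
    X_test <- matrix(1, n_test, ncol(object$X))
    if (ncol(object$X) > 1) {
      stop("fit has non-intercept fixed effects; supply X_test")
    }
  }
  ghat <- rep(0, n_test)
  for (k in seq_along(blocks)) {
    stopifnot(ncol(blocks[[k]]) == length(object$alpha))
    ghat <- ghat + object$sigma[k] * drop(blocks[[k]] %*% object$alpha)
  }
  ghat + drop(as.matrix(X_test) %*% object$beta)
}

#' Simulate responses from a fitted GBLUP model
#'
#' Draws new phenotype vectors from the fitted multivariate normal
#' `N(X beta, sum_k sigma_k^2 K_k + Ve I)`.
#'
#' @param object a [gblup()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return A matrix with `length(y)` rows and `nsim` columns.
#' @export
simulate.gblup <- function(object, nsim = 1, seed = NULL, ...) {
  n <- length(object$y)
  V <- matrix(0, n, n)
  for (k in seq_along(object$kernels)) {
    V <- V + object$sigma[k] * object$kernels[[k]]
  }
  V <- V + object$components$Ve * diag(n)
  cV <- chol(V + 1e-10 * mean(diag(V)) * diag(n))
  mu <- drop(object$X %*% object$beta)
  draw <- function() mu + drop(crossprod(cV, stats::rnorm(n)))
  if (!is.null(seed)) {
    with_seed(seed, vapply(seq_len(nsim), function(i) draw(), numeric(n)))
  } else {
    vapply(seq_len(nsim), function(i) draw(), numeric(n))
  }
}
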