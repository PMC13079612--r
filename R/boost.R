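# Gradient-boosted tree models on raw and dominance-transformed marker
# matrices, with Gaussian-process Bayesian hyperparameter optimisation.

#' Default XGBoost search space
#'
#' Number of trees 100-1000, learning rate 0.01-0.3 (log scale), max depth
#' 2-10, row subsample 0.5-1, column subsample 0.3-1, L2 regularisation
#' 1e-3 to 10 (log scale). Each entry is `list(type, lower, upper, log)`;
#' integer parameters are rounded after decoding.
#'
#' @return Named list of parameter specifications, overridable entry-wise.
#' @export
default_search_space <- function() {
  list(
    nrounds = list(type = "int", lower = 100, upper = 1000, log = FALSE),
    eta = list(type = "num", lower = 0.01, upper = 0.3, log = TRUE),
    max_depth = list(type = "int", lower = 2, upper = 10, log = FALSE),
    subsample = list(type = "num", lower = 0.5, upper = 1, log = FALSE),
    colsample_bytree = list(type = "num", lower = 0.3, upper = 1, log = FALSE),
    lambda = list(type = "num", lower = 1e-3, upper = 10, log = TRUE)
  )
}

# unit-hypercube point -> named parameter list
decode_params <- function(u, space) {
  out <- list()
  for (i in seq_along(space)) {
    sp <- space[[i]]
    val <- if (isTRUE(sp$log)) {
      exp(log(sp$lower) + u[i] * (log(sp$upper) - log(sp$lower)))
    } else {
      sp$lower + u[i] * (sp$upper - sp$lower)
    }
    if (sp$type == "int") val <- as.integer(round(val))
    out[[names(space)[i]]] <- val
  }
  out
}

# Matern 5/2 correlation on a fixed length-scale in normalised space
matern52 <- function(D, ls) {
  r <- sqrt(5) * D / ls
  (1 + r + r^2 / 3) * exp(-r)
}

gp_ei <- function(U_obs, y_obs, U_cand, ls = 0.25, nugget = 1e-6) {
  mu_y <- mean(y_obs); sd_y <- stats::sd(y_obs)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  z <- (y_obs - mu_y) / sd_y
  Dxx <- as.matrix(stats::dist(U_obs))
  Kxx <- matern52(Dxx, ls) + nugget * diag(nrow(U_obs))
  cK <- chol(Kxx)
  a <- backsolve(cK, forwardsolve(t(cK), z))
  cross_dist <- function(A, B) {
    sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
  }
  Kxc <- matern52(cross_dist(U_cand, U_obs), ls)
  mu <- drop(Kxc %*% a)
  v <- backsolve(cK, forwardsolve(t(cK), t(Kxc)))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  best <- min(z)
  imp <- best - mu
  zz <- imp / s
  imp * stats::pnorm(zz) + s * stats::dnorm(zz)
}

#' Bayesian hyperparameter optimisation for XGBoost regression
#'
#' Gaussian-process surrogate optimisation of the inner-cross-validated mean
#' squared error. The training rows are split once into `inner_folds` folds;
#' every candidate configuration is scored by the mean held-out MSE over
#' those folds, so all iterations see identical fold assignments. The first
#' `min(5, n_iterations)` configurations come from a Latin-hypercube design;
#' subsequent ones maximise expected improvement under a Matern-5/2 GP over
#' the normalised search space. Deterministic given `seed`.
#'
#' Tuning must only ever see training individuals; callers are responsible
#' for passing training rows (the benchmark harness does).
#'
#' @param X_train feature matrix (training rows).
#' @param y_train response (training rows).
#' @param space search space as in [default_search_space()].
#' @param n_iterations total number of evaluated configurations.
#' @param inner_folds number of inner CV folds.
#' @param seed seed controlling folds, design and model fits.
#' @param nthread threads per XGBoost fit.
#' @return An object of class `xgb_tuning`: `best_params`, `best_mse`,
#'   `history` (data.frame of decoded parameters and CV MSE),
#'   `n_iterations`, `seed`, `inner_assignment`.
#' @export
xgb_bayes_tune <- function(X_train, y_train, space = default_search_space(),
                           n_iterations = 20, inner_folds = 3, seed = 1,
                           nthread = 1) {
  if (length(space) == 0) stop("empty search space")
  n <- nrow(X_train)
  if (n < inner_folds) stop("fewer training rows than inner folds")
  d <- length(space)
  assign_folds <- with_seed(derive_seed(seed, "inner_folds"),
                            sample(rep(seq_len(inner_folds), length.out = n)))
  score <- function(params) {
    mses <- numeric(inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- assign_folds != f
      pred <- xgb_fit_predict(X_train[tr, , drop = FALSE], y_train[tr],
                              X_train[!tr, , drop = FALSE], params,
                              seed = derive_seed(seed, paste0("inner", f)),
                              nthread = nthread)
      mses[f] <- mean((pred - y_train[!tr])^2)
    }
    mean(mses)
  }
  n_init <- min(5L, n_iterations)
  U <- matrix(NA_real_, n_iterations, d)
  U[seq_len(n_init), ] <- with_seed(derive_seed(seed, "design"),
                                    lhs::randomLHS(n_init, d))
  mse <- rep(NA_real_, n_iterations)
  for (i in seq_len(n_init)) mse[i] <- score(decode_params(U[i, ], space))
  if (n_iterations > n_init) {
    for (i in (n_init + 1L):n_iterations) {
      cand <- with_seed(derive_seed(seed, paste0("cand", i)),
                        matrix(stats::runif(512 * d), ncol = d))
      ei <- gp_ei(U[seq_len(i - 1L), , drop = FALSE], mse[seq_len(i - 1L)],
                  cand)
      U[i, ] <- cand[which.max(ei), ]
      mse[i] <- score(decode_params(U[i, ], space))
    }
  }
  history <- cbind(
    as.data.frame(do.call(rbind, lapply(seq_len(n_iterations), function(i) {
      unlist(decode_params(U[i, ], space))
    }))),
    mse = mse
  )
  best <- which.min(mse)
  structure(
    list(best_params = decode_params(U[best, ], space), best_mse = mse[best],
         history = history, n_iterations = n_iterations, seed = seed,
         inner_assignment = assign_folds),
    class = "xgb_tuning"
  )
}

#' @export
print.xgb_tuning <- function(x, ...) {
  cat(sprintf("xgb_tuning: %d iterations, best CV MSE %.5g\n",
              x$n_iterations, x$best_mse))
  cat("  best:", paste(sprintf("%s=%.4g", names(x$best_params),
                               unlist(x$best_params)), collapse = ", "), "\n")
  invisible(x)
}

#' Fit an XGBoost regressor and predict held-out rows
#'
#' Squared-error gradient-boosted trees with the given hyperparameters;
#' histogram tree method, single-threaded by default. The reproducibility
#' contract is: identical inputs (including feature-column order) and the
#' same `seed` give bit-identical predictions. Predictions are NOT invariant
#' to consistent column permutation — split-gain ties (common for ternary
#' genotype features) and column subsampling are resolved by column index —
#' although held-out accuracy is statistically unaffected.
#'
#' @param X_train,y_train training features and response.
#' @param X_test feature rows to predict (same columns as `X_train`).
#' @param params named list with `nrounds`, `eta`, `max_depth`, `subsample`,
#'   `colsample_bytree`, `lambda` (missing entries fall back to XGBoost
#'   defaults, `nrounds` to 500).
#' @param seed seed for the stochastic parts of tree construction.
#' @param nthread threads.
#' @return Numeric vector of predictions for `X_test`.
#' @export
xgb_fit_predict <- function(X_train, y_train, X_test, params, seed = 1,
                            nthread = 1) {
  if (!all(is.finite(X_train)) || !all(is.finite(X_test)) ||
      !all(is.finite(y_train))) {
    stop("non-finite feature or response values")
  }
  nrounds <- params$nrounds %||% 500
  xp <- list(
    objective = "reg:squarederror",
    eta = params$eta %||% 0.3,
    max_depth = params$max_depth %||% 6,
    subsample = params$subsample %||% 1,
    colsample_bytree = params$colsample_bytree %||% 1,
    lambda = params$lambda %||% 1,
    tree_method = "hist",
    nthread = nthread
  )
  bst <- with_seed(derive_seed(seed, "xgb"), {
    dtrain <- xgboost::xgb.DMatrix(as.matrix(X_train), label = y_train,
                                   nthread = nthread)
    xgboost::xgb.train(params = xp, data = dtrain, nrounds = nrounds,
                       verbose = 0)
  })
  stats::predict(bst, xgboost::xgb.DMatrix(as.matrix(X_test),
                                           nthread = nthread))
}
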