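# Multi-environment trial pipeline: synthetic trial generator, residual
# outlier removal, two-step BLUEs, and marker quality control.

#' Simulate multi-environment trial records
#'
#' Emulates a modified randomized complete block design: every hybrid is
#' observed in `n_reps` replicates within each environment (location x
#' year). `y = true value + environment effect + replicate-within-environment
#' effect + residual`; a fraction `outlier_rate` of records additionally
#' receives a gross error of +/- 6 residual SDs.
#'
#' @param true_values named numeric vector of per-hybrid true values.
#' @param n_locations,n_years numbers of locations and years.
#' @param n_reps replicates per environment.
#' @param env_sd,rep_sd,resid_sd standard deviations of the environment,
#'   replicate-within-environment and residual effects.
#' @param outlier_rate fraction of records receiving a gross error.
#' @param seed master seed.
#' @return data.frame with columns `hybrid_id`, `location`, `year`,
#'   `replicate`, `value` and logical `is_outlier` (the planted gross
#'   errors, for validation).
#' @export
simulate_trials <- function(true_values, n_locations, n_years, n_reps = 2,
                            env_sd = 1, rep_sd = 0.5, resid_sd = 1,
                            outlier_rate = 0, seed = 1) {
  stopifnot(n_locations > 0, n_years > 0, n_reps > 0,
            env_sd >= 0, rep_sd >= 0, resid_sd >= 0,
            outlier_rate >= 0, outlier_rate < 1)
  ids <- names(true_values) %||% paste0("H", seq_along(true_values))
  with_seed(derive_seed(seed, "trials"), {
    grid <- expand.grid(
      hybrid_id = ids,
      location = paste0("loc", seq_len(n_locations)),
      year = 2000L + seq_len(n_years),
      replicate = seq_len(n_reps),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    env_key <- paste(grid$location, grid$year)
    envs <- unique(env_key)
    env_eff <- stats::setNames(stats::rnorm(length(envs), 0, env_sd), envs)
    rep_key <- paste(env_key, grid$replicate)
    reps <- unique(rep_key)
    rep_eff <- stats::setNames(stats::rnorm(length(reps), 0, rep_sd), reps)
    e <- stats::rnorm(nrow(grid), 0, resid_sd)
    grid$value <- true_values[grid$hybrid_id] + env_eff[env_key] +
      rep_eff[rep_key] + e
    grid$is_outlier <- FALSE
    n_out <- round(outlier_rate * nrow(grid))
    if (n_out > 0) {
      idx <- sample(nrow(grid), n_out)
      grid$value[idx] <- grid$value[idx] +
        sample(c(-6, 6), n_out, replace = TRUE) * resid_sd
      grid$is_outlier[idx] <- TRUE
    }
    rownames(grid) <- NULL
    grid
  })
}

# within-environment two-way fixed-effects fit used by outlier removal and
# step-1 BLUEs
fit_env_model <- function(df) {
  df$hybrid_id <- factor(df$hybrid_id)
  df$replicate <- factor(df$replicate)
  has_rep <- nlevels(df$replicate) > 1
  form <- if (has_rep) value ~ hybrid_id + replicate else value ~ hybrid_id
  stats::lm(form, data = df,
            contrasts = if (has_rep) {
              list(hybrid_id = "contr.sum", replicate = "contr.sum")
            } else {
              list(hybrid_id = "contr.sum")
            })
}

#' Remove residual outliers within each environment
#'
#' Within each environment (location x year), fits the two-way fixed-effects
#' model `y_ij = mu + H_i + R_j + e_ij` by least squares and removes records
#' whose residual exceeds `k` residual standard deviations in absolute
#' value. A single pass — the model is not refitted after removal.
#' Environments with fewer records than model parameters are skipped with a
#' warning.
#'
#' @param records trial records as from [simulate_trials()].
#' @param k threshold in residual standard deviations (default 2).
#' @return A list: `records` (retained rows), `removed` (dropped rows),
#'   `report` (per-environment residual SD and removal count).
#' @export
remove_outliers <- function(records, k = 2) {
  env <- paste(records$location, records$year)
  keep <- rep(TRUE, nrow(records))
  rep_list <- list()
  for (e in unique(env)) {
    idx <- which(env == e)
    df <- records[idx, , drop = FALSE]
    n_par <- length(unique(df$hybrid_id)) + length(unique(df$replicate)) - 1
    if (nrow(df) <= n_par) {
      warning(sprintf("environment %s has too few records; skipped", e))
      next
    }
    fit <- fit_env_model(df)
    r <- stats::residuals(fit)
    sig <- stats::sd(r)
    out <- is.finite(k) & abs(r) > k * sig
    keep[idx[out]] <- FALSE
    rep_list[[e]] <- data.frame(environment = e, sigma = sig,
                                n_records = nrow(df), n_removed = sum(out))
  }
  list(records = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE],
       report = do.call(rbind, rep_list))
}

#' Step-1 BLUEs from fixed-effects models
#'
#' Least-squares estimates of hybrid means from
#' `y = mu + H_i + R_j + e` with sum-to-zero constraints, fitted within each
#' group. The reported BLUE is `mu_hat + H_hat_i`, i.e. on the trait scale;
#' in a balanced complete design it equals the hybrid's raw mean. By default
#' groups are individual environments (location x year) so that the step-2
#' model can carry a location-x-year random effect; `scope = "location"`
#' pools years within each location instead.
#'
#' @param records trial records (after outlier removal).
#' @param scope `"location_year"` (default) or `"location"`.
#' @return data.frame of class `blue_table` with columns `hybrid_id`,
#'   `blue`, `n_obs`, `location`, `year` (NA when pooled), `step`.
#'   Hybrids whose effect is inestimable in a group are flagged via
#'   `estimable = FALSE` and carry NA.
#' @export
blues_step1 <- function(records, scope = c("location_year", "location")) {
  scope <- match.arg(scope)
  grp <- if (scope == "location_year") {
    paste(records$location, records$year, sep = "\r")
  } else {
    records$location
  }
  out <- list()
  for (g in unique(grp)) {
    df <- records[grp == g, , drop = FALSE]
    fit <- fit_env_model(df)
    cf <- stats::coef(fit)
    hy <- factor(df$hybrid_id)
    lv <- levels(hy)
    hcoef_names <- paste0("hybrid_id", seq_len(length(lv) - 1))
    h_eff <- cf[hcoef_names]
    h_eff <- c(h_eff, -sum(h_eff, na.rm = TRUE))
    names(h_eff) <- lv
    estimable <- !is.na(h_eff) & !is.na(cf["(Intercept)"])
    blue <- cf["(Intercept)"] + h_eff
    n_obs <- as.integer(table(hy)[lv])
    loc <- df$location[1]
    yr <- if (scope == "location_year") df$year[1] else NA
    out[[g]] <- data.frame(
      hybrid_id = lv, blue = unname(blue), n_obs = n_obs,
      location = loc, year = yr, step = "step1",
      estimable = estimable, row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("blue_table", class(res))
  res
}

#' Step-2 BLUEs across environments
#'
#' Mixed model `y_ik = mu + H_i + E_k + e_ik` on the step-1 BLUEs, with
#' hybrid fixed and environment (location x year) random. The environment
#' variance is estimated by REML using the package's kernel solver with the
#' environment incidence cross-product `Z Z'` as the covariance structure.
#' With a single environment the model reduces to fixed-effects means (with
#' a warning).
#'
#' @param step1 a [blues_step1()] table (location-year scope).
#' @return data.frame of class `blue_table` with one row per hybrid:
#'   `hybrid_id`, `blue`, `n_obs`, `step = "step2"`. The environment and
#'   residual variance estimates are attached as attributes `Venv`, `Ve`.
#' @export
blues_step2 <- function(step1) {
  df <- step1[!is.na(step1$blue), , drop = FALSE]
  env <- factor(paste(df$location, df$year))
  hyb <- factor(df$hybrid_id)
  y <- df$blue
  if (nlevels(env) < 2) {
    warning("single environment: returning fixed-effects hybrid means")
    blue <- tapply(y, hyb, mean)
    res <- data.frame(hybrid_id = names(blue), blue = unname(blue),
                      n_obs = as.integer(table(hyb)), step = "step2")
    class(res) <- c("blue_table", class(res))
    return(res)
  }
  X <- stats::model.matrix(~hyb, contrasts.arg = list(hyb = "contr.sum"))
  Z <- stats::model.matrix(~ 0 + env)
  K <- tcrossprod(Z)
  fit <- gblup(y, kernels = list(environment = K), X = X)
  cf <- fit$beta
  h_eff <- cf[-1]
  h_eff <- c(h_eff, -sum(h_eff))
  blue <- cf[1] + h_eff
  res <- data.frame(
    hybrid_id = levels(hyb), blue = unname(blue),
    n_obs = as.integer(table(hyb)), step = "step2"
  )
  attr(res, "Venv") <- unname(fit$sigma[1])
  attr(res, "Ve") <- fit$components$Ve
  class(res) <- c("blue_table", class(res))
  res
}

#' Filter markers on minor allele frequency and missingness
#'
#' Drops loci whose minor allele frequency (computed on non-missing calls)
#' is strictly below `maf_min`, or whose missing fraction strictly exceeds
#' `missing_max` (a locus at exactly the MAF threshold or exactly the
#' missingness threshold is retained).
#'
#' @param markers a [marker_matrix()] (may contain NA).
#' @param maf_min minimum minor allele frequency (exclusive bound below).
#' @param missing_max maximum missing fraction (exclusive bound above).
#' @return A list: `markers` (filtered [marker_matrix()]), `report` (list
#'   with per-criterion counts, JSON-serialisable).
#' @export
filter_markers <- function(markers, maf_min = 0.05, missing_max = 0.2) {
  dos <- markers$dosages
  miss_frac <- colMeans(is.na(dos))
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_maf <- maf < maf_min
  drop_miss <- miss_frac > missing_max
  keep <- !(drop_maf | drop_miss)
  if (!any(keep)) stop("all loci removed by QC filters")
  report <- list(
    n_loci_in = ncol(dos),
    n_loci_out = sum(keep),
    n_dropped_maf = sum(drop_maf),
    n_dropped_missing = sum(drop_miss),
    maf_min = maf_min, missing_max = missing_max,
    rule = "drop if MAF < maf_min or missing fraction > missing_max"
  )
  list(markers = markers[, keep], report = report)
}
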