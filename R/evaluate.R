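# Cross-validated benchmarking of the five prediction models and the
# accompanying significance testing.

#' Cross-validation fold assignments
#'
#' Per repeat, a random partition of `n` individuals into `k` folds whose
#' sizes differ by at most one. Repeats use distinct seeds derived from the
#' master seed, so the full assignment is reproducible from
#' `(n, k, repeats, seed)` alone.
#'
#' @param n number of individuals.
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param seed master seed.
#' @return Integer matrix `n x repeats` of fold labels in `1..k`.
#' @export
make_folds <- function(n, k = 5, repeats = 10, seed = 1) {
  if (n < k) stop("need at least as many individuals as folds")
  out <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    out[, r] <- with_seed(derive_seed(seed, paste0("fold_rep", r)),
                          sample(rep(seq_len(k), length.out = n)))
  }
  out
}

#' Pearson predictive ability
#'
#' Product-moment correlation between predictions and observations, with the
#' domain checks the benchmark needs (length >= 3, non-zero variance on both
#' sides).
#'
#' @param pred,obs numeric vectors of equal length.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) < 3) {
    stop("need at least 3 paired values")
  }
  if (stats::var(pred) == 0 || stats::var(obs) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(pred, obs)
}

#' Benchmark configuration
#'
#' @param tune_iterations Bayesian-optimisation iterations for the ML models.
#' @param inner_folds inner CV folds during tuning.
#' @param tune_schedule when to retune: `"per_repeat"` (default; tuned on
#'   the first fold's training set of each repeat and reused across folds),
#'   `"per_trait"` (tuned once on the first repeat's first fold), or
#'   `"per_fold"`.
#' @param search_space see [default_search_space()].
#' @param combined_scaling scaling rule for the combined kernel
#'   (see [K_combined()]).
#' @param nthread threads for XGBoost.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(tune_iterations = 20, inner_folds = 3,
                             tune_schedule = c("per_repeat", "per_trait",
                                               "per_fold"),
                             search_space = default_search_space(),
                             combined_scaling = "2pq",
                             nthread = 1) {
  structure(
    list(tune_iterations = tune_iterations, inner_folds = inner_folds,
         tune_schedule = match.arg(tune_schedule),
         search_space = search_space,
         combined_scaling = combined_scaling, nthread = nthread),
    class = "benchmark_config"
  )
}

#' Cross-validated benchmark of the five prediction models
#'
#' For every repeat x fold, builds the inputs honouring the leakage rule —
#' the dominance profile is estimated from training rows only (phenotypes
#' are leakage-sensitive), while allele frequencies for kernel construction
#' use the full genotype matrix (genotypes of unphenotyped candidates are
#' legitimately available in genomic selection) — then fits the requested
#' models on the training rows and records the Pearson predictive ability on
#' the test rows.
#'
#' Models: `AM` (additive-kernel GBLUP), `ADM` (additive + dominance
#' kernels), `CADM` (single combined kernel from the dominance-transformed
#' matrix), `ML` (XGBoost on raw dosages), `ML_Transformed` (XGBoost on the
#' transformed matrix). A model failure on a fold is recorded as NA with the
#' error message and the run continues.
#'
#' @param y phenotypes (or BLUEs).
#' @param markers a [marker_matrix()] of SNP dosages.
#' @param models character subset of
#'   `c("AM", "ADM", "CADM", "ML", "ML_Transformed")`.
#' @param folds fold assignment matrix from [make_folds()].
#' @param config a [benchmark_config()].
#' @param seed master seed for the ML fits and tuning.
#' @param trait label stored with the results.
#' @return data.frame of class `cv_result` with columns `trait`, `rep`,
#'   `fold`, `model`, `r`, `n_test`, `error`; the fold assignment and config
#'   are kept as attributes.
#' @export
run_benchmark <- function(y, markers, models, folds,
                          config = benchmark_config(), seed = 1,
                          trait = "trait") {
  models <- match.arg(models, c("AM", "ADM", "CADM", "ML", "ML_Transformed"),
                      several.ok = TRUE)
  dos <- markers$dosages
  n <- length(y)
  stopifnot(nrow(dos) == n, nrow(folds) == n)
  need_classic <- any(models %in% c("AM", "ADM", "CADM"))
  G <- if (any(models %in% c("AM", "ADM"))) G_vanraden(markers) else NULL
  D <- if ("ADM" %in% models) D_vitezica(markers) else NULL
  tuned <- list()  # cache keyed by model / schedule scope
  rows <- list()
  for (r in seq_len(ncol(folds))) {
    fold_of <- folds[, r]
    k <- max(fold_of)
    for (f in seq_len(k)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      profile <- NULL
      Tmat <- NULL
      Kc <- NULL
      if (any(models %in% c("CADM", "ML_Transformed"))) {
        profile <- estimate_dominance(dos[train, , drop = FALSE],
                                      y[train] - mean(y[train]))
        Tmat <- apply_dominance(dos, profile)
        if ("CADM" %in% models) {
          Kc <- K_combined(Tmat, scaling = config$combined_scaling, raw = dos)
        }
      }
      for (mod in models) {
        res <- tryCatch({
          pred <- switch(mod,
            AM = {
              fit <- gblup(y[train], list(additive = unclass(G)[train, train]))
              predict(fit, list(unclass(G)), train = train, test = test)
            },
            ADM = {
              fit <- gblup(y[train],
                           list(additive = unclass(G)[train, train],
                                dominance = unclass(D)[train, train]))
              predict(fit, list(unclass(G), unclass(D)),
                      train = train, test = test)
            },
            CADM = {
              fit <- gblup(y[train], list(combined = unclass(Kc)[train, train]))
              predict(fit, list(unclass(Kc)), train = train, test = test)
            },
            ML = ,
            ML_Transformed = {
              X <- if (mod == "ML") dos else Tmat
              key <- switch(config$tune_schedule,
                            per_trait = mod,
                            per_repeat = paste(mod, r),
                            per_fold = paste(mod, r, f))
              if (is.null(tuned[[key]])) {
                tuned[[key]] <- xgb_bayes_tune(
                  X[train, , drop = FALSE], y[train],
                  space = config$search_space,
                  n_iterations = config$tune_iterations,
                  inner_folds = config$inner_folds,
                  seed = derive_seed(seed, paste0("tune_", key)),
                  nthread = config$nthread
                )$best_params
              }
              xgb_fit_predict(X[train, , drop = FALSE], y[train],
                              X[test, , drop = FALSE], tuned[[key]],
                              seed = derive_seed(seed,
                                                 paste0("fit_", mod, r, f)),
                              nthread = config$nthread)
            }
          )
          list(r = pearson_r(pred, y[test]), error = NA_character_)
        }, error = function(e) list(r = NA_real_, error = conditionMessage(e)))
        rows[[length(rows) + 1L]] <- data.frame(
          trait = trait, rep = r, fold = f, model = mod, r = res$r,
          n_test = length(test), error = res$error
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fold_assignment") <- folds
  attr(out, "config") <- config
  class(out) <- c("cv_result", class(out))
  out
}

#' Summarise a benchmark: mean predictive ability per model
#'
#' @param object a [run_benchmark()] result (or several rbind-ed together).
#' @param ... unused.
#' @return data.frame with per-trait, per-model mean and SD of the fold-level
#'   predictive abilities.
#' @export
summary.cv_result <- function(object, ...) {
  ag <- stats::aggregate(r ~ trait + model, data = object,
                         FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(trait = ag$trait, model = ag$model,
                    mean_r = ag$r[, "mean"], sd_r = ag$r[, "sd"])
  out[order(out$trait, -out$mean_r), ]
}

#' Model comparison: per-trait ANOVA, BH adjustment, Tukey HSD
#'
#' For each trait, a one-way analysis of variance of fold-level predictive
#' abilities on the model factor; trait-level p-values are adjusted across
#' traits by the Benjamini-Hochberg step-up procedure, and traits with
#' adjusted p below `alpha` get all-pairs Tukey honest-significant-difference
#' comparisons.
#'
#' @param results long data.frame with columns `trait`, `model`, `r`
#'   (e.g. rbind-ed [run_benchmark()] outputs).
#' @param alpha FDR threshold for running the post hoc tests.
#' @return A list: `anova` (per-trait F, p, BH-adjusted p), `tukey`
#'   (pairwise differences for significant traits).
#' @export
compare_models <- function(results, alpha = 0.05) {
  traits <- unique(results$trait)
  an_rows <- list()
  fits <- list()
  for (tr in traits) {
    df <- results[results$trait == tr & !is.na(results$r), , drop = FALSE]
    df$model <- factor(df$model)
    if (nlevels(df$model) < 2 || min(table(df$model)) < 2) {
      warning(sprintf("trait %s skipped: degenerate model groups", tr))
      next
    }
    fit <- stats::aov(r ~ model, data = df)
    tab <- summary(fit)[[1]]
    an_rows[[tr]] <- data.frame(
      trait = tr, F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
      p = tab$`Pr(>F)`[1]
    )
    fits[[tr]] <- fit
  }
  anova_tab <- do.call(rbind, an_rows)
  if (is.null(anova_tab)) return(list(anova = NULL, tukey = NULL))
  anova_tab$p_adj <- stats::p.adjust(anova_tab$p, method = "BH")
  rownames(anova_tab) <- NULL
  tk_rows <- list()
  for (tr in anova_tab$trait[anova_tab$p_adj < alpha]) {
    tk <- stats::TukeyHSD(fits[[tr]])$model
    tk_rows[[tr]] <- data.frame(
      trait = tr, comparison = rownames(tk), diff = tk[, "diff"],
      lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
      row.names = NULL
    )
  }
  list(anova = anova_tab, tukey = do.call(rbind, tk_rows))
}
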