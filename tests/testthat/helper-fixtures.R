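# Shared fixture builders: everything is generated in code at test time.

# small factorial hybrid population with configurable dominance/heritability
small_population <- function(nominal_pdv = 0.2, nominal_H2 = 0.6,
                             n_chr = 2, n_snp_per_chr = 60,
                             n_qtl_per_chr = 10, n_founders = 120,
                             n_female = 30, n_male = 6, seed = 11) {
  sc <- sim_scenario(
    architecture = "polygenic", nominal_pdv = nominal_pdv,
    nominal_H2 = nominal_H2, n_chr = n_chr, n_snp_per_chr = n_snp_per_chr,
    n_qtl_per_chr = n_qtl_per_chr, n_founders = n_founders,
    n_female = n_female, n_male = n_male, seed = seed
  )
  simulate_population(sc)
}

# dosage matrix with exact Hardy-Weinberg genotype counts at one locus
hwe_exact_column <- function(n0, n1, n2) {
  rep(c(0, 1, 2), c(n0, n1, n2))
}

# random 0/1/2 matrix
random_dosages <- function(n, m, seed = 1, p = NULL) {
  with_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(s)
    expr
  }
  with_seed(seed, {
    if (is.null(p)) p <- runif(m, 0.1, 0.9)
    sapply(p, function(pp) rbinom(n, 2, pp))
  })
}

# simulate y ~ N(Xb, Vg*K + Ve*I) for REML recovery checks
simulate_kernel_trait <- function(K, Vg, Ve, seed, mu = 0) {
  n <- nrow(K)
  set.seed(seed)
  u <- drop(crossprod(chol(K + 1e-8 * mean(diag(K)) * diag(n)),
                      rnorm(n))) * sqrt(Vg)
  mu + u + rnorm(n, 0, sqrt(Ve))
}
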