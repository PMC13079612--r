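#' Simulate a founder population
#'
#' Generates phased founder haplotypes for a biallelic genome. Per-locus
#' ancestral allele frequencies are drawn uniformly on `freq_range`;
#' haplotype alleles are Bernoulli draws at those frequencies, optionally
#' passed through a first-order copying process (`ld_rho`) that induces local
#' linkage disequilibrium decaying with locus index along each chromosome.
#' Loci (SNPs and QTLs interleaved at random) are placed at uniform spacing
#' on a 1 Morgan (100 cM) genetic map per chromosome.
#'
#' @param n_ind number of founder individuals.
#' @param n_chr number of chromosomes.
#' @param n_snp_per_chr SNP loci per chromosome.
#' @param n_qtl_per_chr QTL loci per chromosome.
#' @param seed master seed for this operation.
#' @param freq_range range of ancestral allele frequencies (uniform draw).
#' @param ld_rho per-locus probability that a haplotype copies its allele
#'   from the previous locus on the chromosome instead of drawing fresh;
#'   0 gives linkage equilibrium among founders.
#' @return An object of class `founder_population`: list with `haplotypes`
#'   (2*n_ind x n_loci binary matrix, consecutive row pairs per individual),
#'   `map` (data.frame: locus, chrom, pos_cM, is_qtl, freq), `pool`
#'   (per-individual `"female_pool"`/`"male_pool"` label, first half female),
#'   and `chr_length_M` (map length in Morgans per chromosome).
#' @export
sim_founders <- function(n_ind, n_chr, n_snp_per_chr, n_qtl_per_chr, seed,
                         freq_range = c(0.05, 0.95), ld_rho = 0.98) {
  if (any(c(n_ind, n_chr, n_snp_per_chr) <= 0) || n_qtl_per_chr < 0) {
    stop("population and locus counts must be positive")
  }
  per_chr <- n_snp_per_chr + n_qtl_per_chr
  n_loci <- n_chr * per_chr
  with_seed(derive_seed(seed, "founders"), {
    p <- stats::runif(n_loci, freq_range[1], freq_range[2])
    H <- matrix(0L, nrow = 2L * n_ind, ncol = n_loci)
    for (cc in seq_len(n_chr)) {
      off <- (cc - 1L) * per_chr
      H[, off + 1L] <- stats::rbinom(2L * n_ind, 1L, p[off + 1L])
      for (j in 2L:per_chr) {
        fresh <- stats::rbinom(2L * n_ind, 1L, p[off + j])
        if (ld_rho > 0) {
          copy <- stats::runif(2L * n_ind) < ld_rho
          H[, off + j] <- ifelse(copy, H[, off + j - 1L], fresh)
        } else {
          H[, off + j] <- fresh
        }
      }
    }
    qtl_flag <- logical(n_loci)
    for (cc in seq_len(n_chr)) {
      off <- (cc - 1L) * per_chr
      qtl_flag[off + sort(sample.int(per_chr, n_qtl_per_chr))] <- TRUE
    }
    map <- data.frame(
      locus = paste0("chr", rep(seq_len(n_chr), each = per_chr), "_",
                     rep(seq_len(per_chr), n_chr),
                     ifelse(qtl_flag, "_q", "")),
      chrom = rep(seq_len(n_chr), each = per_chr),
      pos_cM = rep(100 * seq_len(per_chr) / per_chr, n_chr),
      is_qtl = qtl_flag,
      freq = p
    )
    colnames(H) <- map$locus
    structure(
      list(
        haplotypes = H,
        map = map,
        pool = rep(c("female_pool", "male_pool"), c(ceiling(n_ind / 2),
                                                    floor(n_ind / 2))),
        chr_length_M = rep(1, n_chr)
      ),
      class = "founder_population"
    )
  })
}

#' @export
print.founder_population <- function(x, ...) {
  cat(sprintf(
    "founder_population: %d individuals, %d loci (%d QTL) on %d chromosomes\n",
    nrow(x$haplotypes) / 2, nrow(x$map), sum(x$map$is_qtl),
    length(unique(x$map$chrom))
  ))
  invisible(x)
}

#' Founder dosages
#'
#' Sums each individual's two haplotypes into a 0/1/2 dosage row.
#'
#' @param founders a [sim_founders()] object.
#' @return A [marker_matrix()] over all loci (SNPs and QTLs).
#' @export
founder_dosages <- function(founders) {
  H <- founders$haplotypes
  n <- nrow(H) / 2
  dos <- H[2 * seq_len(n) - 1, , drop = FALSE] +
    H[2 * seq_len(n), , drop = FALSE]
  marker_matrix(dos, locus_ids = founders$map$locus,
                chrom = founders$map$chrom, pos_cM = founders$map$pos_cM)
}

# One meiotic gamete from a pair of haplotypes. Crossovers per chromosome are
# Poisson with mean equal to the map length in Morgans, positions uniform on
# the map; the starting strand is a fair coin per chromosome.
make_gamete <- function(hapA, hapB, chrom, pos_cM, chr_ids, chr_len_M,
                        record = FALSE) {
  strand <- integer(length(hapA))
  rec <- if (record) vector("list", length(chr_ids)) else NULL
  for (k in seq_along(chr_ids)) {
    idx <- which(chrom == chr_ids[k])
    n_xo <- stats::rpois(1L, chr_len_M[k])
    xo <- if (n_xo > 0) sort(stats::runif(n_xo, 0, 100 * chr_len_M[k])) else numeric(0)
    start <- sample.int(2L, 1L) - 1L
    strand[idx] <- (start + findInterval(pos_cM[idx], xo)) %% 2L
    if (record) rec[[k]] <- list(start = start, xo = xo)
  }
  g <- ifelse(strand == 0L, hapA, hapB)
  if (record) attr(g, "crossovers") <- rec
  g
}

# Rebuild a gamete from its recorded start strands and crossover points
# (replay oracle used by the test suite).
replay_gamete <- function(hapA, hapB, chrom, pos_cM, chr_ids, rec) {
  strand <- integer(length(hapA))
  for (k in seq_along(chr_ids)) {
    idx <- which(chrom == chr_ids[k])
    strand[idx] <- (rec[[k]]$start + findInterval(pos_cM[idx], rec[[k]]$xo)) %% 2L
  }
  ifelse(strand == 0L, hapA, hapB)
}

#' Sample parents and produce a full-factorial hybrid cross
#'
#' Randomly samples `n_female` individuals from the female pool and `n_male`
#' from the male pool, then crosses every female with every male. Each hybrid
#' receives one independent recombinant gamete from each parent.
#'
#' @param founders a [sim_founders()] object.
#' @param n_female,n_male numbers of parents to sample.
#' @param seed master seed for this operation.
#' @param record_gametes logical; if TRUE, keep each gamete's starting strand
#'   and crossover positions so hybrids can be replayed exactly.
#' @return A list with `markers` (hybrid [marker_matrix()] over all loci),
#'   `parents` (data.frame: hybrid id, female_id, male_id), and, when
#'   requested, `gametes` (per-hybrid recorded crossover structure).
#' @export
sample_and_cross <- function(founders, n_female, n_male, seed,
                             record_gametes = FALSE) {
  pool_f <- which(founders$pool == "female_pool")
  pool_m <- which(founders$pool == "male_pool")
  if (length(pool_f) < n_female || length(pool_m) < n_male) {
    stop("parent pool smaller than requested sample")
  }
  map <- founders$map
  chr_ids <- unique(map$chrom)
  H <- founders$haplotypes
  with_seed(derive_seed(seed, "cross"), {
    females <- sort(sample(pool_f, n_female))
    males <- sort(sample(pool_m, n_male))
    n_h <- n_female * n_male
    dos <- matrix(0L, nrow = n_h, ncol = nrow(map))
    parents <- data.frame(
      id = character(n_h), female_id = integer(n_h), male_id = integer(n_h),
      stringsAsFactors = FALSE
    )
    gam <- if (record_gametes) vector("list", n_h) else NULL
    h <- 0L
    for (f in females) {
      hfA <- H[2L * f - 1L, ]; hfB <- H[2L * f, ]
      for (m in males) {
        h <- h + 1L
        hmA <- H[2L * m - 1L, ]; hmB <- H[2L * m, ]
        gf <- make_gamete(hfA, hfB, map$chrom, map$pos_cM, chr_ids,
                          founders$chr_length_M, record = record_gametes)
        gm <- make_gamete(hmA, hmB, map$chrom, map$pos_cM, chr_ids,
                          founders$chr_length_M, record = record_gametes)
        dos[h, ] <- gf + gm
        parents$id[h] <- paste0("F", f, "xM", m)
        parents$female_id[h] <- f
        parents$male_id[h] <- m
        if (record_gametes) {
          gam[[h]] <- list(female = attr(gf, "crossovers"),
                           male = attr(gm, "crossovers"))
        }
      }
    }
    rownames(dos) <- parents$id
    out <- list(
      markers = marker_matrix(dos, locus_ids = map$locus, chrom = map$chrom,
                              pos_cM = map$pos_cM),
      parents = parents
    )
    if (record_gametes) out$gametes <- gam
    out
  })
}

#' Scenario description for the hybrid breeding simulator
#'
#' Defaults reflect the full-scale study conditions: ten chromosomes with
#' 3000 SNPs each and 300 (polygenic) or 3 (oligogenic) QTLs each, 300 female
#' and 8 male parents giving 2400 full-factorial hybrids.
#'
#' @param architecture `"polygenic"` or `"oligogenic"`.
#' @param nominal_pdv target proportion of dominance variance Vd/Vg in
#'   \[0, 1).
#' @param nominal_H2 target broad-sense heritability in (0, 1\].
#' @param n_chr,n_snp_per_chr,n_qtl_per_chr genome layout.
#' @param n_founders founder population size.
#' @param n_female,n_male parents sampled for the factorial cross.
#' @param seed master scenario seed.
#' @param ld_rho founder LD copying probability (see [sim_founders()]).
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(architecture = c("polygenic", "oligogenic"),
                         nominal_pdv = 0, nominal_H2 = 0.6,
                         n_chr = 10,
                         n_snp_per_chr = 3000,
                         n_qtl_per_chr = NULL,
                         n_founders = 1000,
                         n_female = 300, n_male = 8,
                         seed = 1, ld_rho = 0.98) {
  architecture <- match.arg(architecture)
  if (is.null(n_qtl_per_chr)) {
    n_qtl_per_chr <- if (architecture == "polygenic") 300 else 3
  }
  if (nominal_pdv < 0 || nominal_pdv >= 1) stop("nominal_pdv must be in [0, 1)")
  if (nominal_H2 <= 0 || nominal_H2 > 1) stop("nominal_H2 must be in (0, 1]")
  structure(
    list(architecture = architecture, nominal_pdv = nominal_pdv,
         nominal_H2 = nominal_H2, n_chr = n_chr,
         n_snp_per_chr = n_snp_per_chr, n_qtl_per_chr = n_qtl_per_chr,
         n_founders = n_founders, n_female = n_female, n_male = n_male,
         seed = as.integer(seed), ld_rho = ld_rho),
    class = "sim_scenario"
  )
}

#' Build a trait architecture calibrated to a target dominance proportion
#'
#' Additive QTL effects are standard normal. Dominance degrees are
#' `delta_q = mu + delta_sd * z_q` with fixed standard-normal draws `z_q`;
#' the location `mu` is found by bisection so that the realized proportion of
#' dominance variance (via [realized_components()]) matches `nominal_pdv`
#' within `tol`. The residual variance is then set from the realized genetic
#' variance so that Vg / (Vg + Ve) equals `nominal_H2`.
#'
#' @param qtl_dosages hybrids x QTL dosage matrix (0/1/2).
#' @param nominal_pdv target Vd/Vg in \[0, 1); 0 forces all `delta_q = 0`.
#' @param nominal_H2 target broad-sense heritability in (0, 1\].
#' @param seed seed for the effect draws.
#' @param delta_sd locus-to-locus spread of the dominance degree.
#' @param tol bisection tolerance on the realized PDV.
#' @param max_iter bisection iteration cap.
#' @param intercept trait mean.
#' @return A list of class `trait_architecture`: `qtl_idx` (column indices),
#'   `a`, `delta`, `Ve`, `intercept`, `mu_delta`, `realized` (the calibrated
#'   [var_components()]), and `converged`.
#' @export
build_architecture <- function(qtl_dosages, nominal_pdv, nominal_H2, seed,
                               delta_sd = 0.2, tol = 0.01, max_iter = 40,
                               intercept = 0) {
  if (nominal_pdv < 0 || nominal_pdv >= 1) stop("nominal_pdv must be in [0, 1)")
  if (nominal_H2 <= 0 || nominal_H2 > 1) stop("nominal_H2 must be in (0, 1]")
  X <- as.matrix(qtl_dosages)
  nq <- ncol(X)
  draws <- with_seed(derive_seed(seed, "architecture"),
                     list(a = stats::rnorm(nq), z = stats::rnorm(nq)))
  a <- draws$a
  g_of <- function(delta) {
    drop((X - 1) %*% a + (X == 1) %*% (delta * abs(a))) + intercept
  }
  pdv_of <- function(mu) {
    comp <- realized_components(g_of(mu + delta_sd * draws$z), X)
    comp$Vd / max(comp$Vg, .Machine$double.eps)
  }
  converged <- TRUE
  if (nominal_pdv == 0) {
    delta <- rep(0, nq)
    mu <- 0
  } else {
    lo <- 0; p_lo <- pdv_of(0)
    if (p_lo >= nominal_pdv) {
      # spread alone already produces at least the target; keep mu = 0
      mu <- 0
      converged <- (p_lo - nominal_pdv) <= tol
    } else {
      hi <- 1; p_hi <- pdv_of(hi)
      while (p_hi < nominal_pdv && hi < 32) {
        hi <- hi * 2; p_hi <- pdv_of(hi)
      }
      if (p_hi < nominal_pdv) {
        stop(sprintf(
          "dominance calibration failed: PDV %.3f unreachable (max %.3f at mu=%g)",
          nominal_pdv, p_hi, hi
        ))
      }
      it <- 0
      repeat {
        mu <- (lo + hi) / 2
        p_mid <- pdv_of(mu)
        if (abs(p_mid - nominal_pdv) <= tol || it >= max_iter) break
        if (p_mid < nominal_pdv) lo <- mu else hi <- mu
        it <- it + 1
      }
      if (abs(p_mid - nominal_pdv) > tol) {
        warning(sprintf(
          "dominance bisection stopped at PDV %.3f (target %.3f) after %d iterations",
          p_mid, nominal_pdv, it
        ))
        converged <- FALSE
      }
    }
    delta <- mu + delta_sd * draws$z
  }
  g <- drop((X - 1) %*% a + (X == 1) %*% (delta * abs(a))) + intercept
  comp <- realized_components(g, X)
  Ve <- comp$Vg * (1 - nominal_H2) / nominal_H2
  structure(
    list(
      qtl_idx = seq_len(nq), a = a, delta = delta, Ve = Ve,
      intercept = intercept, mu_delta = if (nominal_pdv == 0) 0 else mu,
      delta_sd = delta_sd, realized = comp, converged = converged
    ),
    class = "trait_architecture"
  )
}

#' True genetic values under a trait architecture
#'
#' `g_i = intercept + sum_q [ a_q (x_iq - 1) + delta_q |a_q| 1\{x_iq = 1\} ]`:
#' the classical biallelic parameterisation where `a_q` is half the
#' difference between homozygote values and the heterozygote deviates from
#' the homozygote midpoint by `delta_q |a_q|`, directed toward the favourable
#' allele.
#'
#' @param qtl_dosages hybrids x QTL dosage matrix (0/1/2).
#' @param arch a [build_architecture()] object (or any list with `a`,
#'   `delta`, `intercept`).
#' @return Numeric vector of genetic values.
#' @export
genetic_values <- function(qtl_dosages, arch) {
  X <- as.matrix(qtl_dosages)
  stopifnot(ncol(X) == length(arch$a))
  drop((X - 1) %*% arch$a + (X == 1) %*% (arch$delta * abs(arch$a))) +
    arch$intercept
}

#' Phenotypes from genetic values
#'
#' Adds i.i.d. normal environmental noise with variance `arch$Ve`.
#'
#' @param g genetic values.
#' @param arch a [build_architecture()] object.
#' @param seed seed for the noise draw.
#' @return Numeric phenotype vector.
#' @export
sim_phenotypes <- function(g, arch, seed) {
  with_seed(derive_seed(seed, "phenotype"),
            g + stats::rnorm(length(g), 0, sqrt(arch$Ve)))
}

#' Realized additive/dominance variance decomposition
#'
#' The additive variance is the variance of fitted values from the joint
#' least-squares regression of the genetic values on the additive dosage
#' codes of all QTLs; the dominance variance is the remainder of the genetic
#' variance. When there are at least as many QTLs as individuals the joint
#' regression is unidentifiable and a per-locus orthogonal decomposition
#' under observed genotype frequencies is used instead (flagged in the
#' output).
#'
#' @param g genetic values.
#' @param qtl_dosages hybrids x QTL dosage matrix, rows aligned with `g`.
#' @return A [var_components()] object with `Va`, `Vd`, `Vg` filled (residual
#'   variance NA) and attribute `method` (`"joint_regression"` or
#'   `"per_locus"`).
#' @export
realized_components <- function(g, qtl_dosages) {
  X <- as.matrix(qtl_dosages)
  stopifnot(length(g) == nrow(X))
  n <- nrow(X)
  if (ncol(X) < n - 1) {
    keep <- which(matrixStats_colVars(X) > 0)
    fit <- stats::lm.fit(cbind(1, X[, keep, drop = FALSE]), g)
    Va <- stats::var(fit$fitted.values)
    Vd <- max(stats::var(g) - Va, 0)
    method <- "joint_regression"
  } else {
    # fallback: per-locus decomposition at observed genotype frequencies
    Va <- 0; Vd <- 0
    for (j in seq_len(ncol(X))) {
      x <- X[, j]
      f0 <- mean(x == 0); f1 <- mean(x == 1); f2 <- mean(x == 2)
      xx <- x - mean(x)
      b <- sum(xx * g) / sum(xx^2)
      Va <- Va + b^2 * stats::var(x)
      resid_cls <- tapply(g - b * x, x, mean)
      frq <- c(f0, f1, f2)[match(names(resid_cls), c("0", "1", "2"))]
      Vd <- Vd + sum(frq * (resid_cls - sum(frq * resid_cls))^2)
    }
    method <- "per_locus"
  }
  out <- var_components(Va = Va, Vd = Vd, Ve = NA_real_)
  attr(out, "method") <- method
  out
}

# colVars without a matrixStats dependency
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

#' Simulate a full hybrid population for one scenario
#'
#' Orchestrates [sim_founders()], [sample_and_cross()],
#' [build_architecture()], [genetic_values()] and [sim_phenotypes()], then
#' splits loci into SNPs (markers handed to prediction models) and QTLs
#' (used only for trait generation and truth bookkeeping).
#'
#' @param scenario a [sim_scenario()].
#' @param founders optional pre-simulated founder population (genotypes are
#'   trait-independent, so one founder set can serve several trait
#'   scenarios); must match the scenario's genome layout.
#' @param cross optional pre-computed [sample_and_cross()] result on
#'   `founders`.
#' @return A list of class `sim_population`: `markers` (SNP-only
#'   [marker_matrix()]), `qtl_dosages`, `g`, `y`, `parents`, `architecture`,
#'   and `truth` (realized [var_components()] including the realized residual
#'   variance of `y - g`).
#' @export
simulate_population <- function(scenario, founders = NULL, cross = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (is.null(founders)) {
    founders <- sim_founders(scenario$n_founders, scenario$n_chr,
                             scenario$n_snp_per_chr, scenario$n_qtl_per_chr,
                             seed = scenario$seed, ld_rho = scenario$ld_rho)
  }
  if (is.null(cross)) {
    cross <- sample_and_cross(founders, scenario$n_female, scenario$n_male,
                              seed = scenario$seed)
  }
  is_qtl <- founders$map$is_qtl
  Xq <- cross$markers$dosages[, is_qtl, drop = FALSE]
  arch <- build_architecture(Xq, scenario$nominal_pdv, scenario$nominal_H2,
                             seed = scenario$seed)
  g <- genetic_values(Xq, arch)
  y <- sim_phenotypes(g, arch, seed = scenario$seed)
  Ve_real <- stats::var(y - g)
  truth <- var_components(Va = arch$realized$Va, Vd = arch$realized$Vd,
                          Ve = Ve_real)
  structure(
    list(
      markers = cross$markers[, !is_qtl],
      qtl_dosages = Xq,
      g = g, y = y,
      parents = cross$parents,
      architecture = arch,
      truth = truth,
      scenario = scenario
    ),
    class = "sim_population"
  )
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(
    "sim_population (%s): %d hybrids, %d SNPs, %d QTLs\n",
    x$scenario$architecture, length(x$y), ncol(x$markers$dosages),
    ncol(x$qtl_dosages)
  ))
  cat(sprintf("  realized PDV %.3f, H2 %.3f (nominal %.2f / %.2f)\n",
              x$truth$PDV, x$truth$H2,
              x$scenario$nominal_pdv, x$scenario$nominal_H2))
  invisible(x)
}
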