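# Genomic relationship matrices: additive (VanRaden method 1), dominance
# (Vitezica), and the combined kernel from the dominance-transformed matrix.

# Shared linear-kernel code path: column-mean centering with a configurable
# scaling constant. Using the same path for the additive and combined
# kernels makes the d == 1 reduction exact by construction.
linear_kernel <- function(M, scaling = c("2pq", "colvar"), kind) {
  scaling <- match.arg(scaling)
  n <- nrow(M)
  mu <- colMeans(M)
  ptilde <- mu / 2
  colvar <- colMeans(M^2) - mu^2
  keep <- which(colvar > 0 &
                  (scaling != "2pq" | (ptilde > 0 & ptilde < 1)))
  if (length(keep) == 0) stop("all loci are monomorphic / zero-variance")
  Z <- sweep(M[, keep, drop = FALSE], 2, mu[keep])
  const <- switch(scaling,
                  "2pq" = 2 * sum(ptilde[keep] * (1 - ptilde[keep])),
                  "colvar" = sum(colvar[keep]))
  if (const <= 0) stop("degenerate scaling constant (no variation)")
  K <- tcrossprod(Z) / const
  structure(K, kind = kind, n_loci_used = length(keep),
            scaling_constant = const, class = c("relmat", class(K)))
}

impute_col_mean <- function(dos) {
  miss <- is.na(dos)
  if (any(miss)) {
    mu <- colMeans(dos, na.rm = TRUE)
    idx <- which(miss)
    dos[idx] <- mu[((idx - 1L) %/% nrow(dos)) + 1L]
    attr(dos, "imputation_rate") <- mean(miss)
  }
  dos
}

#' Additive genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum_j p_j q_j)` where `Z` is the dosage matrix centred by
#' twice the sample allele frequency of each locus. Monomorphic loci are
#' dropped from numerator and denominator; missing dosages are imputed by
#' the column mean first (the imputation rate is recorded as an attribute).
#'
#' @param markers a [marker_matrix()] or plain 0/1/2 dosage matrix.
#' @return An n x n matrix of class `relmat` with attributes `kind`
#'   (`"additive"`), `n_loci_used` and `scaling_constant`.
#' @export
G_vanraden <- function(markers) {
  dos <- if (inherits(markers, "marker_matrix")) markers$dosages else as.matrix(markers)
  dos <- impute_col_mean(dos)
  K <- linear_kernel(dos, scaling = "2pq", kind = "additive")
  attr(K, "imputation_rate") <- attr(dos, "imputation_rate") %||% 0
  K
}

#' Dominance genomic relationship matrix (Vitezica coding)
#'
#' `D = W W' / sum_j (2 p_j q_j)^2` with the per-locus coding
#' `w = -2 p_j^2` (dosage 0), `2 p_j q_j` (dosage 1), `-2 q_j^2` (dosage 2),
#' where `p_j` is the frequency of the counted (A2) allele. Under exact
#' Hardy-Weinberg genotype proportions this coding has mean zero (the
#' genotype frequencies `q^2 : 2pq : p^2` pair with `-2p^2 : 2pq : -2q^2`),
#' making it orthogonal to the additive coding. Monomorphic loci are dropped; missing dosages are imputed to
#' the locus's most frequent genotype class before coding.
#'
#' @param markers a [marker_matrix()] or plain 0/1/2 dosage matrix.
#' @return An n x n matrix of class `relmat` with attributes `kind`
#'   (`"dominance"`), `n_loci_used` and `scaling_constant`.
#' @export
D_vitezica <- function(markers) {
  dos <- if (inherits(markers, "marker_matrix")) markers$dosages else as.matrix(markers)
  imput_rate <- 0
  if (anyNA(dos)) {
    imput_rate <- mean(is.na(dos))
    for (j in seq_len(ncol(dos))) {
      if (anyNA(dos[, j])) {
        tab <- tabulate(dos[, j] + 1L, 3L)
        dos[is.na(dos[, j]), j] <- which.max(tab) - 1L
      }
    }
  }
  p <- colMeans(dos) / 2
  q <- 1 - p
  keep <- which(p > 0 & p < 1)
  if (length(keep) == 0) stop("all loci are monomorphic")
  dos <- dos[, keep, drop = FALSE]
  p <- p[keep]; q <- q[keep]
  W <- matrix(0, nrow(dos), ncol(dos))
  W[dos == 0] <- (-2 * rep(p^2, each = nrow(dos)))[dos == 0]
  W[dos == 1] <- (2 * rep(p * q, each = nrow(dos)))[dos == 1]
  W[dos == 2] <- (-2 * rep(q^2, each = nrow(dos)))[dos == 2]
  const <- sum((2 * p * q)^2)
  K <- tcrossprod(W) / const
  structure(K, kind = "dominance", n_loci_used = length(keep),
            scaling_constant = const, imputation_rate = imput_rate,
            class = c("relmat", class(K)))
}

#' Combined additive + dominance kernel from the transformed matrix
#'
#' Relationship matrix built from the dominance-transformed marker matrix
#' (see [apply_dominance()]): columns are centred by their empirical means
#' and the cross-product is scaled, by default, by
#' `2 sum_j ptilde_j (1 - ptilde_j)` with `ptilde_j = colmean_j / 2` — the
#' VanRaden construction applied to the transformed matrix, computed through
#' the same code path as [G_vanraden()]. With `d = 1` at every locus the
#' transformed matrix equals the raw dosages and the combined kernel is
#' exactly the additive kernel, element for element. `scaling = "colvar"`
#' (sum of empirical column variances) and `scaling = "2pq_raw"` (constant
#' taken from the raw dosage matrix, which must be supplied) are available
#' as alternatives.
#'
#' @param transformed real-valued matrix from [apply_dominance()].
#' @param scaling `"2pq"` (default), `"colvar"`, or `"2pq_raw"`.
#' @param raw raw dosage matrix (only for `scaling = "2pq_raw"`).
#' @return An n x n matrix of class `relmat` with attributes `kind`
#'   (`"combined"`), `n_loci_used` and `scaling_constant`.
#' @export
K_combined <- function(transformed, scaling = c("2pq", "colvar", "2pq_raw"),
                       raw = NULL) {
  scaling <- match.arg(scaling)
  M <- as.matrix(transformed)
  if (scaling == "2pq_raw") {
    if (is.null(raw)) stop("scaling = '2pq_raw' needs the raw dosage matrix")
    raw <- if (inherits(raw, "marker_matrix")) raw$dosages else as.matrix(raw)
    p <- colMeans(raw) / 2
    keep <- which(p > 0 & p < 1)
    if (length(keep) == 0) stop("all loci are monomorphic")
    Z <- sweep(M[, keep, drop = FALSE], 2, colMeans(M[, keep, drop = FALSE]))
    const <- 2 * sum(p[keep] * (1 - p[keep]))
    K <- tcrossprod(Z) / const
    return(structure(K, kind = "combined", n_loci_used = length(keep),
                     scaling_constant = const,
                     class = c("relmat", class(K))))
  }
  linear_kernel(M, scaling = scaling, kind = "combined")
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf(
    "%s relationship matrix: %d x %d, %d loci, mean diagonal %.3f\n",
    attr(x, "kind"), nrow(x), ncol(x), attr(x, "n_loci_used"),
    mean(diag(x))
  ))
  invisible(x)
}

#' Write / read a relationship matrix as square CSV
#'
#' CSV with an id header row and id first column.
#'
#' @param K relationship matrix (ids taken from row names or `ind1..n`).
#' @param path file path.
#' @return `path` invisibly, or the matrix for the reader.
#' @export
write_relmat <- function(K, path) {
  ids <- rownames(K) %||% paste0("ind", seq_len(nrow(K)))
  df <- data.frame(id = ids, unclass(K), check.names = FALSE)
  colnames(df) <- c("id", ids)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = ",", row.names = 1L,
                           check.names = FALSE)
  as.matrix(tab)
}
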