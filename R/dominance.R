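#' Estimate the locus-specific degree of dominance
#'
#' For each locus, computes the mean corrected phenotype of the three
#' genotype classes in the training set and scales the heterozygote mean
#' between the two homozygote means. Two orientations of the scaled
#' position are available:
#'
#' * `orient = "signed"` (default): `d = 2 (xbar_A1A2 - xbar_A1A1) /
#'   (xbar_A2A2 - xbar_A1A1)` — the heterozygote's position along the
#'   dosage code axis (0 to 2). This keeps the transformed code collinear
#'   with the genotypic values whatever the sign of the locus effect: a
#'   locus with additive effect `a` and dominance degree `delta` toward
#'   the favourable allele yields `d = 1 + delta` when A2 is favourable
#'   and `d = 1 - delta` when A1 is, and in both cases replacing the
#'   heterozygote by `d` makes the three class means exactly linear in
#'   the code.
#' * `orient = "minmax"`: `d = 2 (xbar_A1A2 - x_min) / (x_max - x_min)`
#'   with `x_min = min(xbar_A1A1, xbar_A2A2)` — the orientation-free form
#'   in which `d` is always measured from the worse homozygote.
#'
#' The two coincide whenever the A2 homozygote is the better one (as in
#' every standard worked example); they differ (mirror images) when A1 is
#' favourable, where the min/max form breaks the collinearity of the
#' transformed code. Either way, `d = 1` is additive (heterozygote at the
#' midpoint), and values outside \[0, 2\] indicate over/under-dominance —
#' these are kept as-is and flagged, never clamped.
#'
#' To avoid leakage into held-out individuals, call this on training rows
#' only; the result can then transform any matrix over the same loci.
#'
#' Fallback rule: `d` is a ratio whose denominator is the homozygote span
#' `x_max - x_min`; when that span is zero, or statistically
#' indistinguishable from zero (smaller than `span_se_mult` times its
#' standard error, computed from the homozygote class variances), the
#' ratio is unidentified and a single noisy locus can dominate the whole
#' transformed matrix. Such loci — as well as loci where any genotype
#' class has fewer than `min_class_n` training observations — get `d = 1`
#' (left additive) with `fallback` set.
#'
#' @param markers a [marker_matrix()] or plain 0/1/2 dosage matrix
#'   (training rows).
#' @param y_corrected per-individual corrected phenotype (BLUEs or centred
#'   phenotypes); no fixed-effect correction is applied here.
#' @param min_class_n minimum class count for a direct estimate.
#' @param span_se_mult identifiability threshold: fallback when the
#'   homozygote span is below this multiple of its standard error.
#' @param orient `"signed"` (code-axis orientation, default) or
#'   `"minmax"` (measured from the worse homozygote); see Details.
#' @return An object of class `dominance_profile`: `d` (per-locus degree of
#'   dominance), `class_means` (loci x 3 matrix of genotype-class means),
#'   `class_counts`, `x_min`, `x_max`, `fallback` (logical),
#'   `overdominant` (logical, d outside \[0, 2\]).
#' @export
estimate_dominance <- function(markers, y_corrected, min_class_n = 2,
                               span_se_mult = 2,
                               orient = c("signed", "minmax")) {
  orient <- match.arg(orient)
  dos <- if (inherits(markers, "marker_matrix")) markers$dosages else as.matrix(markers)
  y <- as.numeric(y_corrected)
  if (nrow(dos) == 0) stop("no training individuals")
  if (length(y) != nrow(dos)) stop("markers and phenotypes are misaligned")
  means <- counts <- vars <- matrix(NA_real_, ncol(dos), 3,
                                    dimnames = list(colnames(dos),
                                                    c("A1A1", "A1A2", "A2A2")))
  for (cls in 0:2) {
    I <- dos == cls
    n_c <- colSums(I)
    s_c <- drop(crossprod(I, y))
    s2_c <- drop(crossprod(I, y^2))
    counts[, cls + 1] <- n_c
    means[, cls + 1] <- ifelse(n_c > 0, s_c / n_c, NA_real_)
    vars[, cls + 1] <- ifelse(n_c > 1,
                              (s2_c - s_c^2 / pmax(n_c, 1)) / (n_c - 1),
                              NA_real_)
  }
  x_min <- pmin(means[, 1], means[, 3])
  x_max <- pmax(means[, 1], means[, 3])
  span <- x_max - x_min
  # standard error of the homozygote span, from the class variances
  span_se <- sqrt(vars[, 1] / counts[, 1] + vars[, 3] / counts[, 3])
  scale_eps <- 1e-12 * pmax(1, abs(x_max))
  fallback <- apply(counts, 1, min) < min_class_n | is.na(span) |
    span <= scale_eps |
    (!is.na(span_se) & span <= span_se_mult * span_se)
  d <- rep(1, ncol(dos))
  ok <- !fallback
  if (orient == "signed") {
    d[ok] <- 2 * (means[ok, 2] - means[ok, 1]) / (means[ok, 3] - means[ok, 1])
  } else {
    d[ok] <- 2 * (means[ok, 2] - x_min[ok]) / span[ok]
  }
  structure(
    list(d = d, class_means = means, class_counts = counts,
         x_min = x_min, x_max = x_max, fallback = fallback,
         overdominant = !fallback & (d < 0 | d > 2),
         orient = orient, locus_ids = colnames(dos)),
    class = "dominance_profile"
  )
}

#' @export
print.dominance_profile <- function(x, ...) {
  cat(sprintf(
    "dominance_profile: %d loci; d in [%.3f, %.3f], %d fallback, %d overdominant\n",
    length(x$d), min(x$d), max(x$d), sum(x$fallback), sum(x$overdominant)
  ))
  invisible(x)
}

#' Apply the degree-of-dominance transformation to a marker matrix
#'
#' Replaces every heterozygote code (1) with that locus's estimated degree
#' of dominance `d`; homozygote codes (0 and 2) are unchanged. The result is
#' a real-valued matrix suitable for the combined relationship kernel or as
#' features for tree models.
#'
#' @param markers a [marker_matrix()] or plain 0/1/2 dosage matrix (any
#'   rows: training and/or test individuals).
#' @param profile a [estimate_dominance()] profile over the same loci.
#' @return A numeric matrix of the same dimension as the input dosages.
#' @export
apply_dominance <- function(markers, profile) {
  dos <- if (inherits(markers, "marker_matrix")) markers$dosages else as.matrix(markers)
  if (ncol(dos) != length(profile$d)) {
    stop("profile and marker loci do not match")
  }
  if (!is.null(profile$locus_ids) && !is.null(colnames(dos)) &&
      !identical(colnames(dos), profile$locus_ids)) {
    stop("profile and marker locus ids do not match")
  }
  out <- dos
  het <- which(dos == 1)
  if (length(het)) {
    cols <- ((het - 1L) %/% nrow(dos)) + 1L
    out[het] <- profile$d[cols]
  }
  out
}
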