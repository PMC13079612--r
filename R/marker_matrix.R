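#' Marker matrix with locus metadata
#'
#' Light container for an individuals x loci allele-dosage matrix together
#' with per-locus metadata. Dosages follow the usual biallelic convention:
#' 0 = A1A1 homozygote, 1 = A1A2 heterozygote, 2 = A2A2 homozygote, so the
#' counted allele is A2 and its frequency is `allele_freq`.
#'
#' @param dosages numeric matrix, individuals in rows, loci in columns;
#'   entries in \{0, 1, 2\} (NA allowed when `allow_missing = TRUE`).
#' @param locus_ids character vector of locus identifiers (defaults to column
#'   names or `L1..Lm`).
#' @param chrom integer vector of per-locus chromosome indices (optional).
#' @param pos_cM numeric vector of genetic-map positions in centimorgans,
#'   non-decreasing within each chromosome (optional).
#' @param allow_missing logical; permit NA dosages (e.g. real genotype data
#'   before imputation/filtering).
#' @return An object of class `marker_matrix`: a list with elements
#'   `dosages`, `locus_ids`, `chrom`, `pos_cM`, `allele_freq`.
#' @export
marker_matrix <- function(dosages, locus_ids = NULL, chrom = NULL,
                          pos_cM = NULL, allow_missing = FALSE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  vals <- dosages[!is.na(dosages)]
  if (!all(vals %in% c(0, 1, 2))) {
    stop("dosages must be coded 0/1/2 (A1A1 / A1A2 / A2A2)")
  }
  if (anyNA(dosages) && !allow_missing) {
    stop("missing dosages present; set allow_missing = TRUE")
  }
  m <- ncol(dosages)
  if (is.null(locus_ids)) {
    locus_ids <- colnames(dosages) %||% paste0("L", seq_len(m))
  }
  stopifnot(length(locus_ids) == m)
  colnames(dosages) <- locus_ids
  if (!is.null(chrom)) {
    stopifnot(length(chrom) == m)
    if (!is.null(pos_cM)) {
      stopifnot(length(pos_cM) == m)
      for (cc in unique(chrom)) {
        if (is.unsorted(pos_cM[chrom == cc])) {
          stop("pos_cM must be non-decreasing within each chromosome")
        }
      }
    }
  }
  structure(
    list(
      dosages = dosages,
      locus_ids = as.character(locus_ids),
      chrom = chrom,
      pos_cM = pos_cM,
      allele_freq = colMeans(dosages, na.rm = TRUE) / 2
    ),
    class = "marker_matrix"
  )
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf(
    "marker_matrix: %d individuals x %d loci (mean A2 frequency %.3f)\n",
    nrow(x$dosages), ncol(x$dosages), mean(x$allele_freq, na.rm = TRUE)
  ))
  if (anyNA(x$dosages)) {
    cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$dosages))))
  }
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$dosages)

#' Subset a marker matrix
#'
#' @param x a [marker_matrix()].
#' @param i row (individual) index.
#' @param j column (locus) index.
#' @param ... unused.
#' @return A `marker_matrix` restricted to the requested rows/columns; the
#'   allele frequencies are recomputed from the subset.
#' @export
`[.marker_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  jj <- seq_len(ncol(x$dosages))[j]
  marker_matrix(
    x$dosages[i, j, drop = FALSE],
    locus_ids = x$locus_ids[jj],
    chrom = x$chrom[jj],
    pos_cM = x$pos_cM[jj],
    allow_missing = TRUE
  )
}

#' Read a dosage matrix from delimited text
#'
#' Expects individuals in rows and loci in columns, with a header of locus
#' ids and row names (first column) of individual ids, as written by
#' [write_dosage()].
#'
#' @param path file path (TSV).
#' @param allow_missing logical, passed to [marker_matrix()].
#' @return A [marker_matrix()].
#' @export
read_dosage <- function(path, allow_missing = TRUE) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  marker_matrix(as.matrix(tab), allow_missing = allow_missing)
}

#' Write a dosage matrix as TSV
#'
#' @param markers a [marker_matrix()].
#' @param path output file path.
#' @param ids optional individual ids (row names).
#' @return `path`, invisibly.
#' @export
write_dosage <- function(markers, path, ids = NULL) {
  d <- markers$dosages
  if (is.null(ids)) ids <- rownames(d) %||% paste0("ind", seq_len(nrow(d)))
  df <- data.frame(id = ids, d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read diploid genotypes from a VCF into a dosage matrix
#'
#' Uses `vcfR` to parse the VCF and converts the GT field to counts of the
#' alternate allele (0/1/2), with missing calls as NA. Individuals end up in
#' rows, loci in columns.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return A [marker_matrix()] with chromosome and (physical) position
#'   metadata carried over from the VCF.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package 'vcfR' is required to read VCF input")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  dos <- apply(gt, 2, count_alt)
  dos <- t(dos)  # individuals x loci
  ids <- paste0(v@fix[, "CHROM"], "_", v@fix[, "POS"])
  chrom <- suppressWarnings(as.integer(factor(v@fix[, "CHROM"])))
  marker_matrix(dos, locus_ids = ids, chrom = chrom, allow_missing = TRUE)
}
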