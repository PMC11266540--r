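#' Genotype matrix container
#'
#' A light container pairing a samples x variants dosage matrix (values 0, 1,
#' 2 or `NA` for missing) with variant and sample metadata tibbles. It is the
#' backbone object passed between the QC, structure, association and IBD
#' stages.
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns. Row
#'   names are sample ids and column names variant ids; both are generated
#'   when absent.
#' @param variants Tibble with one row per variant. Must contain `variant_id`;
#'   typically also `chrom`, `pos`, `ref`, `alt` and a logical `genotyped`
#'   flag (TRUE = directly genotyped, FALSE = imputed).
#' @param samples Tibble with one row per sample; must contain `sample_id`.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, variants = NULL, samples = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0) || any(bad > 2))) {
    stop("dosage values must lie in [0, 2] or be NA", call. = FALSE)
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("v%d", seq_len(ncol(dosage)))
  }
  if (is.null(variants)) {
    variants <- tibble::tibble(variant_id = colnames(dosage))
  }
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = rownames(dosage))
  }
  variants <- tibble::as_tibble(variants)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    "variant metadata must match dosage columns" =
      identical(variants$variant_id, colnames(dosage)),
    "sample metadata must match dosage rows" =
      identical(samples$sample_id, rownames(dosage))
  )
  structure(
    list(dosage = dosage, variants = variants, samples = samples),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d variants (%.2f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param samples,variants Character ids or logical/integer indices; `NULL`
#'   keeps everything.
#' @return A `geno_matrix` restricted to the requested rows/columns.
#' @export
subset_geno <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "geno_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(x$dosage)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(x$dosage)) else variants
  if (is.character(si)) si <- match(si, rownames(x$dosage))
  if (is.character(vi)) vi <- match(vi, colnames(x$dosage))
  if (anyNA(si)) stop("unknown sample id in subset", call. = FALSE)
  if (anyNA(vi)) stop("unknown variant id in subset", call. = FALSE)
  geno_matrix(
    x$dosage[si, vi, drop = FALSE],
    x$variants[vi, , drop = FALSE],
    x$samples[si, , drop = FALSE]
  )
}

#' Per-variant alternate-allele frequencies
#'
#' @param x A [geno_matrix()] or a dosage matrix.
#' @return Named numeric vector of ALT allele frequencies computed from
#'   non-missing dosages.
#' @export
allele_freqs <- function(x) {
  d <- if (inherits(x, "geno_matrix")) x$dosage else x
  colMeans(d, na.rm = TRUE) / 2
}

# variant key "chrom:pos:ref:alt" used across AF tables and reports
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
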