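#' Read genotypes from a VCF file
#'
#' Parses a diploid VCF (via \pkg{vcfR}) and converts unphased/phased GT
#' calls to ALT-dosage values 0/1/2 (missing calls to `NA`). Multi-allelic
#' records are rejected.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return A [geno_matrix()].
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
    stringsAsFactors = FALSE
  ))
  if (any(grepl(",", fix$ALT))) {
    stop("multi-allelic records are not supported; split them first",
      call. = FALSE
    )
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt))
  clean <- gsub("\\|", "/", t(gt))
  dos[clean == "0/0"] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean == "1/1"] <- 2
  variants <- tibble::tibble(
    variant_id = variant_key(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    genotyped = TRUE
  )
  rownames(dos) <- colnames(gt)
  colnames(dos) <- variants$variant_id
  geno_matrix(dos, variants, tibble::tibble(sample_id = colnames(gt)))
}

#' Write genotypes to a VCF 4.2 file
#'
#' Emits one bi-allelic record per variant with an unphased GT field;
#' missing dosages become `./.`.
#'
#' @param genotypes A [geno_matrix()] whose variant metadata has `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_vcf_genotypes <- function(genotypes, path) {
  v <- genotypes$variants
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(v)))
  gt_code <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  d <- genotypes$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=popenrich",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", rownames(d)
    ), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(d))) {
    calls <- gt_code[as.character(d[, j])]
    calls[is.na(calls)] <- "./."
    writeLines(paste(c(
      v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j], v$alt[j],
      ".", "PASS", ".", "GT", calls
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read/write the package's tab-separated tables
#'
#' Thin readr wrappers fixing the column conventions used across the
#' pipeline: allele-frequency tables (`CHROM`, `POS`, `REF`, `ALT`,
#' `AF_<POP>`...), IBD segment tables (`SAMPLE1`, `SAMPLE2`, `CHROM`,
#' `START_BP`, `END_BP`, `START_CM`, `END_CM`, `LOD`) and phenotype tables
#' (sample id, covariates, phenotypes; missing as `NA`).
#'
#' @param path File path.
#' @return A tibble in the package's internal column naming.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_af_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[names(x) == "CHROM"] <- "chrom"
  names(x)[names(x) == "POS"] <- "pos"
  names(x)[names(x) == "REF"] <- "ref"
  names(x)[names(x) == "ALT"] <- "alt"
  x$variant_id <- variant_key(x$chrom, x$pos, x$ref, x$alt)
  x
}

#' @rdname pipeline_io
#' @param af_table Tibble with `chrom`, `pos`, `ref`, `alt` and AF columns.
#' @export
write_af_table <- function(af_table, path) {
  out <- af_table
  out$variant_id <- NULL
  names(out)[names(out) == "chrom"] <- "CHROM"
  names(out)[names(out) == "pos"] <- "POS"
  names(out)[names(out) == "ref"] <- "REF"
  names(out)[names(out) == "alt"] <- "ALT"
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ibd_segments <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(
    sample_a = x$SAMPLE1, sample_b = x$SAMPLE2, chrom = as.character(x$CHROM),
    start_bp = x$START_BP, end_bp = x$END_BP,
    start_cm = x$START_CM, end_cm = x$END_CM, lod = x$LOD
  )
}

#' @rdname pipeline_io
#' @param segments Segment tibble (see [filter_segments()]).
#' @export
write_ibd_segments <- function(segments, path) {
  readr::write_tsv(tibble::tibble(
    SAMPLE1 = segments$sample_a, SAMPLE2 = segments$sample_b,
    CHROM = segments$chrom,
    START_BP = segments$start_bp, END_BP = segments$end_bp,
    START_CM = segments$start_cm, END_CM = segments$end_cm,
    LOD = segments$lod
  ), path)
  invisible(path)
}

#' @rdname pipeline_io
#' @param results A `gwas_result` tibble.
#' @export
write_gwas_results <- function(results, path) {
  out <- tibble::tibble(
    PHENO = results$phenotype,
    CHROM = results$chrom %||% NA, POS = results$pos %||% NA,
    VARIANT = results$variant_id,
    AF = results$af, BETA = results$beta, SE = results$se,
    P = results$p, N = results$n_used
  )
  readr::write_tsv(out, path)
  invisible(path)
}
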