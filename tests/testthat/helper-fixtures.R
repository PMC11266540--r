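# Shared fixtures and independent oracles, all built in code at test time.

# geno_matrix from a bare dosage matrix with evenly spaced positions
toy_geno <- function(dosage, chrom = "1", pos = NULL, genotyped = TRUE) {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = m)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  vid <- sprintf("%s:%d:A:G", chrom, pos)
  colnames(dosage) <- vid
  geno_matrix(
    dosage,
    tibble::tibble(
      variant_id = vid, chrom = chrom, pos = pos,
      ref = "A", alt = "G", genotyped = genotyped
    ),
    tibble::tibble(sample_id = rownames(dosage))
  )
}

# Independent brute-force HWE oracle: enumerate every genotype configuration
# consistent with the observed allele counts and sum exact multinomial
# probabilities directly (no recurrence, no shared code with the package).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_a <- 2 * n_aa + n_Aa
  log_prob <- function(het) {
    aa <- (n_a - het) / 2
    AA <- n - het - aa
    lgamma(n + 1) - lgamma(AA + 1) - lgamma(het + 1) - lgamma(aa + 1) +
      het * log(2) +
      lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  }
  hets <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  probs <- exp(vapply(hets, log_prob, numeric(1)))
  obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# Adjusted Rand index between two labelings (direct contingency formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# IBD segment tibble builder (cM coordinates; bp from a uniform 1 cM/Mb map)
seg_row <- function(start_cm, end_cm, pair = c("A", "B"), chrom = "1",
                    lod = 10) {
  tibble::tibble(
    sample_a = pair[1], sample_b = pair[2], chrom = chrom,
    start_bp = start_cm * 1e6, end_bp = end_cm * 1e6,
    start_cm = start_cm, end_cm = end_cm, lod = lod
  )
}

# small AF table around explicit per-population frequencies
toy_af_table <- function(...) {
  cols <- list(...)
  m <- length(cols[[1]])
  tibble::tibble(
    chrom = "1", pos = seq_len(m) * 100, ref = "A", alt = "G",
    !!!cols
  )
}
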