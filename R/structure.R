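#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, all heterozygote
#' counts of the same parity are enumerated, the probability of each genotype
#' configuration under random mating is computed, and the two-sided p-value
#' is the sum of probabilities not exceeding that of the observed
#' configuration (no mid-p correction). Probabilities use a log-space
#' recurrence over adjacent heterozygote counts for numerical stability.
#'
#' @param n_AA,n_Aa,n_aa Non-negative integer genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(3, 5, 2)
#' hwe_exact_test(0, 100, 0) # extreme heterozygote excess
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1", call. = FALSE)
  n_a <- 2 * n_aa + n_Aa # rare-or-not; conditioning is symmetric
  n_A <- 2 * n_AA + n_Aa
  n_minor <- min(n_a, n_A)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(het = h | allele counts), up to a shared constant:
  # P proportional to 2^h / (nAA! nAa! naa!)
  log_p <- vapply(hets, function(h) {
    aa <- (n_minor - h) / 2
    AA <- (max(n_a, n_A) - h) / 2
    h * log(2) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1)
  }, numeric(1))
  log_p <- log_p - max(log_p)
  p <- exp(log_p)
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Variant quality control by MAF and Hardy-Weinberg
#'
#' Keeps variants whose minor allele frequency strictly exceeds `maf_min` and
#' whose Hardy-Weinberg exact p-value strictly exceeds `hwe_min`. MAF is
#' computed from non-missing dosages; the HWE test uses hard genotype counts
#' (dosages rounded to 0/1/2).
#'
#' @param genotypes A [geno_matrix()].
#' @param maf_min,hwe_min Strict lower bounds.
#' @return A filtered [geno_matrix()]; dropped variants and reasons are in
#'   attribute `qc_log`.
#' @export
variant_qc <- function(genotypes, maf_min = 0.01, hwe_min = 1e-4) {
  d <- genotypes$dosage
  af <- allele_freqs(d)
  maf <- pmin(af, 1 - af)
  hwe_p <- apply(d, 2, function(g) {
    g <- round(g[!is.na(g)])
    if (!length(g)) return(1)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  keep <- maf > maf_min & hwe_p > hwe_min
  keep[is.na(keep)] <- FALSE
  out <- subset_geno(genotypes, variants = which(keep))
  attr(out, "qc_log") <- tibble::tibble(
    variant_id = colnames(d),
    maf = unname(maf), hwe_p = unname(hwe_p), kept = unname(keep)
  )
  out
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window` variants by `step`; within each window, for
#' any pair with squared Pearson correlation at or above `r2_max`, the
#' later-positioned variant is removed. After the pass no retained pair
#' within a window exceeds the threshold. Missing dosages are handled by
#' pairwise-complete correlation.
#'
#' @param genotypes A [geno_matrix()].
#' @param r2_max Squared-correlation threshold (pairs at or above it lose a
#'   member; retained LD is strictly below, matching the usual "R2 < 0.2").
#' @param window,step Window size and slide, in variant counts.
#' @return Character vector of retained `variant_id`s, in genomic order.
#' @export
ld_prune <- function(genotypes, r2_max = 0.2, window = 50, step = 5) {
  d <- genotypes$dosage
  m <- ncol(d)
  keep <- rep(TRUE, m)
  starts <- seq(1, max(1, m - 1), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1, m)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    cc <- suppressWarnings(cor(d[, idx, drop = FALSE],
      use = "pairwise.complete.obs"
    ))
    cc[is.na(cc)] <- 0
    r2 <- cc^2
    for (a in seq_along(idx)) {
      if (!keep[idx[a]]) next
      for (b in seq_along(idx)) {
        if (b <= a || !keep[idx[b]]) next
        if (r2[a, b] >= r2_max) keep[idx[b]] <- FALSE
      }
    }
    if (max(idx) == m) break
  }
  colnames(d)[keep]
}

#' Principal component analysis of a genotype matrix
#'
#' Each variant is centered by twice its allele frequency and scaled by the
#' binomial standard deviation `sqrt(2 p (1 - p))`; missing dosages are
#' mean-imputed (zero after centering); the standardized matrix is then
#' decomposed by SVD. Scores are left singular vectors times singular
#' values; eigenvalues are squared singular values over (n - 1).
#'
#' @param genotypes A [geno_matrix()].
#' @param n_pcs Number of components to return.
#' @return Object of class `geno_pca`: `scores` tibble (`sample_id`, `PC1`
#'   ...), `eigenvalues`, `var_explained`, `n_variants`.
#' @export
pca_genotypes <- function(genotypes, n_pcs = 10) {
  d <- genotypes$dosage
  if (nrow(d) < 2) stop("PCA needs at least two samples", call. = FALSE)
  p <- allele_freqs(d)
  poly <- p > 0 & p < 1 & !is.na(p)
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic variant(s) skipped in PCA", call. = FALSE)
  }
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(d, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  n_pcs <- min(n_pcs, nrow(d) - 1, ncol(d))
  sv <- svd(z, nu = n_pcs, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs, n_pcs)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  eig <- sv$d^2 / (nrow(d) - 1)
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::tibble(sample_id = rownames(d)),
        tibble::as_tibble(scores)
      ),
      eigenvalues = eig[seq_len(n_pcs)],
      var_explained = eig[seq_len(n_pcs)] / sum(eig),
      n_variants = ncol(d)
    ),
    class = "geno_pca"
  )
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf(
    "<geno_pca> %d samples, %d variants; PC1 explains %.1f%% of variance\n",
    nrow(x$scores), x$n_variants, 100 * x$var_explained[1]
  ))
  invisible(x)
}

#' @rdname pca_genotypes
#' @param x,object A `geno_pca`.
#' @param ... Unused.
#' @export
tidy.geno_pca <- function(x, ...) {
  tibble::tibble(
    PC = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    var_explained = x$var_explained
  )
}

#' @rdname pca_genotypes
#' @export
glance.geno_pca <- function(object, ...) {
  tibble::tibble(
    n_samples = nrow(object$scores),
    n_variants = object$n_variants,
    pc1_var_explained = object$var_explained[1]
  )
}

#' Iterative maximum-distance PCA outlier detection
#'
#' Repeatedly removes the sample farthest (Euclidean distance in the top
#' PCs) from the centroid of the remaining samples, recomputing the centroid
#' after each removal. Two stopping rules: remove a fixed count, or stop as
#' soon as the current maximum distance no longer exceeds
#' `mean + c * SD` of the remaining distances.
#'
#' @param scores Tibble with `sample_id` and PC columns (as in
#'   [pca_genotypes()]'s `scores`).
#' @param n_pcs_used Number of leading PCs entering the distance.
#' @param rule Either `list(method = "count", n = <int>)` or
#'   `list(method = "sd", c = 6)`.
#' @return Character vector of outlier sample ids, in removal order.
#' @export
detect_outliers <- function(scores, n_pcs_used = 2,
                            rule = list(method = "sd", c = 6)) {
  pcs <- as.matrix(scores[, paste0("PC", seq_len(n_pcs_used)), drop = FALSE])
  rownames(pcs) <- scores$sample_id
  removed <- character(0)
  repeat {
    if (nrow(pcs) <= 2) stop("outlier rule would remove all samples", call. = FALSE)
    ctr <- colMeans(pcs)
    dists <- sqrt(rowSums(sweep(pcs, 2, ctr)^2))
    worst <- which.max(dists)
    if (identical(rule$method, "count")) {
      if (length(removed) >= rule$n) break
    } else if (identical(rule$method, "sd")) {
      if (dists[worst] <= mean(dists) + rule$c * sd(dists)) break
    } else {
      stop("rule$method must be 'count' or 'sd'", call. = FALSE)
    }
    removed <- c(removed, rownames(pcs)[worst])
    pcs <- pcs[-worst, , drop = FALSE]
  }
  removed
}

#' Assign samples to clusters in PCA space
#'
#' k-means on the top PCs with many random restarts (best within-cluster sum
#' of squares kept), deterministic under the seed. Cluster ids are relabeled
#' by ascending mean PC1 so that, when the optimum is unique, labels do not
#' depend on initialization.
#'
#' @param scores PC-score tibble (`sample_id`, `PC1`, ...), outliers already
#'   excluded.
#' @param k Number of clusters.
#' @param n_pcs_used Leading PCs used.
#' @param seed Integer seed.
#' @param nstart Random restarts.
#' @return Object of class `cluster_assignment`: `assignments` tibble
#'   (`sample_id`, `cluster`), `centers`, `tot_withinss`, `k`.
#' @export
assign_clusters <- function(scores, k = 6, n_pcs_used = 2, seed = 1L,
                            nstart = 100) {
  pcs <- as.matrix(scores[, paste0("PC", seq_len(n_pcs_used)), drop = FALSE])
  if (k > nrow(pcs)) stop("k exceeds the number of samples", call. = FALSE)
  km <- with_seed(seed, kmeans(pcs, centers = k, nstart = nstart, iter.max = 100))
  relabel <- rank(km$centers[, 1], ties.method = "first")
  cluster <- relabel[km$cluster]
  structure(
    list(
      assignments = tibble::tibble(
        sample_id = scores$sample_id,
        cluster = as.integer(cluster)
      ),
      centers = km$centers[order(relabel), , drop = FALSE],
      tot_withinss = km$tot.withinss,
      k = k
    ),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment> k = %d over %d samples; sizes: %s\n",
    x$k, nrow(x$assignments),
    paste(table(x$assignments$cluster), collapse = ", ")
  ))
  invisible(x)
}

fst_components_hudson <- function(pa, pb, na, nb) {
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  list(num = num, den = den)
}

fst_components_wc <- function(pa, pb, na, nb) {
  # Weir & Cockerham (1984) theta-hat for two populations, allele counts
  n_bar <- (na + nb) / 2
  nc <- (na + nb - (na^2 + nb^2) / (na + nb))
  p_bar <- (na * pa + nb * pb) / (na + nb)
  s2 <- (na * (pa - p_bar)^2 + nb * (pb - p_bar)^2) / n_bar
  a <- n_bar / nc * (s2 - 1 / (n_bar - 1) *
    (p_bar * (1 - p_bar) - s2 / 2))
  b <- n_bar / (n_bar - 1) * (p_bar * (1 - p_bar) - s2 / 2)
  list(num = a, den = a + b)
}

#' Pairwise F_ST between two populations
#'
#' Hudson's estimator (default) per variant, with the global value formed as
#' the ratio of summed numerators to summed denominators (ratio of averages,
#' robust to rare variants). The Weir-Cockerham estimator is available as an
#' alternative. `n` counts are sampled allele counts (2 x non-missing
#' samples) per variant.
#'
#' @param genotypes A [geno_matrix()].
#' @param pops Tibble `sample_id`, `population`.
#' @param pop_a,pop_b Population labels to compare.
#' @param estimator `"hudson"` or `"wc"`.
#' @return List of class `fst_result`: `per_variant` tibble (`variant_id`,
#'   `fst`, `num`, `den`), `global`, `estimator`.
#' @export
fst <- function(genotypes, pops, pop_a, pop_b, estimator = c("hudson", "wc")) {
  estimator <- match.arg(estimator)
  lab <- setNames(pops$population, pops$sample_id)[rownames(genotypes$dosage)]
  ia <- which(lab == pop_a)
  ib <- which(lab == pop_b)
  if (length(ia) < 2 || length(ib) < 2) {
    stop("each population needs at least two samples", call. = FALSE)
  }
  da <- genotypes$dosage[ia, , drop = FALSE]
  db <- genotypes$dosage[ib, , drop = FALSE]
  na <- 2 * colSums(!is.na(da))
  nb <- 2 * colSums(!is.na(db))
  pa <- colSums(da, na.rm = TRUE) / na
  pb <- colSums(db, na.rm = TRUE) / nb
  comp <- switch(estimator,
    hudson = fst_components_hudson(pa, pb, na, nb),
    wc = fst_components_wc(pa, pb, na, nb)
  )
  ok <- is.finite(comp$num) & is.finite(comp$den) & comp$den > 0
  per_variant <- tibble::tibble(
    variant_id = colnames(genotypes$dosage)[ok],
    fst = unname(comp$num[ok] / comp$den[ok]),
    num = unname(comp$num[ok]), den = unname(comp$den[ok])
  )
  structure(
    list(
      per_variant = per_variant,
      global = sum(comp$num[ok]) / sum(comp$den[ok]),
      estimator = estimator, pop_a = pop_a, pop_b = pop_b
    ),
    class = "fst_result"
  )
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf(
    "<fst_result> %s vs %s (%s): global F_ST = %.4f over %d variants\n",
    x$pop_a, x$pop_b, x$estimator, x$global, nrow(x$per_variant)
  ))
  invisible(x)
}

#' Robust pairwise kinship coefficient
#'
#' The within-pair robust estimator
#' `(N_het,het - 2 N_opposing_hom) / (N_het_i + N_het_j)` over shared
#' non-missing variants: ~0.5 for duplicates/MZ twins, ~0.25 for
#' parent-offspring, ~0 for unrelateds. Flags use the conventional
#' duplicate (> 0.354) and degree-3 relatedness (> 0.0884) cutoffs.
#'
#' @param genotypes A [geno_matrix()].
#' @param sample_a,sample_b Sample ids.
#' @param min_shared Minimum shared non-missing variant count.
#' @param dup_threshold,rel_threshold Flag cutoffs.
#' @return One-row tibble: `sample_a`, `sample_b`, `kinship`, `n_shared`,
#'   `duplicate`, `related`.
#' @export
kinship_pair <- function(genotypes, sample_a, sample_b, min_shared = 100,
                         dup_threshold = 0.354, rel_threshold = 0.0884) {
  g1 <- genotypes$dosage[match(sample_a, rownames(genotypes$dosage)), ]
  g2 <- genotypes$dosage[match(sample_b, rownames(genotypes$dosage)), ]
  if (anyNA(match(c(sample_a, sample_b), rownames(genotypes$dosage)))) {
    stop("unknown sample id", call. = FALSE)
  }
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < min_shared) {
    stop("fewer than ", min_shared, " shared non-missing variants", call. = FALSE)
  }
  g1 <- g1[ok]
  g2 <- g2[ok]
  n_het_het <- sum(g1 == 1 & g2 == 1)
  n_opp <- sum((g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0))
  n_het_i <- sum(g1 == 1)
  n_het_j <- sum(g2 == 1)
  phi <- (n_het_het - 2 * n_opp) / (n_het_i + n_het_j)
  tibble::tibble(
    sample_a = sample_a, sample_b = sample_b,
    kinship = phi, n_shared = sum(ok),
    duplicate = phi > dup_threshold,
    related = phi > rel_threshold
  )
}

#' Kinship coefficients for all sample pairs
#'
#' @inheritParams kinship_pair
#' @return Tibble with one row per unordered pair (see [kinship_pair()]).
#' @export
kinship_all <- function(genotypes, min_shared = 100,
                        dup_threshold = 0.354, rel_threshold = 0.0884) {
  ids <- rownames(genotypes$dosage)
  pairs <- all_sample_pairs(ids)
  purrr::map2_dfr(
    pairs$sample_a, pairs$sample_b,
    ~ kinship_pair(genotypes, .x, .y, min_shared, dup_threshold, rel_threshold)
  )
}
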