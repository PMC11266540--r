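test_that("HWE exact p-values match the brute-force enumeration oracle", {
  # exhaustive sweep over every genotype configuration with <= 50 alleles
  max_diff <- 0
  for (n in 1:25) {
    for (n_aa in 0:n) {
      for (n_Aa in 0:(n - n_aa)) {
        n_AA <- n - n_aa - n_Aa
        got <- hwe_exact_test(n_AA, n_Aa, n_aa)
        want <- hwe_oracle(n_AA, n_Aa, n_aa)
        max_diff <- max(max_diff, abs(got - want))
      }
    }
  }
  expect_lt(max_diff, 1e-12)

  expect_equal(hwe_exact_test(50, 0, 0), 1) # monomorphic
  expect_lt(hwe_exact_test(0, 100, 0), 1e-10) # extreme het excess
  expect_equal(hwe_exact_test(3, 5, 2), hwe_oracle(3, 5, 2))
  expect_error(hwe_exact_test(-1, 0, 2), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), ">= 1")
})

test_that("variant QC applies strict MAF and HWE bounds", {
  # hand-built dosage columns with known MAF / HWE outcomes
  make_col <- function(n_AA, n_Aa, n_aa) {
    c(rep(0, n_AA), rep(1, n_Aa), rep(2, n_aa))
  }
  n <- 500
  cols <- cbind(
    v_maf_low = make_col(491, 9, 0), # MAF 0.009 -> dropped
    v_keep = make_col(125, 250, 125), # MAF 0.5, HWE p ~ 1 -> kept
    v_hwe_bad = make_col(250, 0, 250), # no hets -> HWE fails
    v_rare_bad = make_col(495, 0, 5), # MAF 0.01 boundary -> dropped
    v_common = make_col(300, 150, 50) # mild excess, kept
  )
  g <- toy_geno(cols)
  qc <- variant_qc(g, maf_min = 0.01, hwe_min = 1e-4)
  log <- attr(qc, "qc_log")
  kept <- log$kept
  names(kept) <- colnames(cols)
  expect_false(kept[["v_maf_low"]])
  expect_true(kept[["v_keep"]])
  expect_false(kept[["v_hwe_bad"]])
  expect_false(kept[["v_rare_bad"]]) # MAF strictly greater than 0.01 required
  # v_common: verify against direct computation
  expect_equal(
    kept[["v_common"]],
    (350 / 1000 > 0.01) && hwe_oracle(300, 150, 50) > 1e-4
  )
})

test_that("LD pruning removes one of each correlated pair", {
  set.seed(23)
  base <- matrix(rbinom(200 * 30, 2, 0.4), 200, 30)
  # duplicate column: r^2 = 1 with its source
  d <- cbind(base[, 1:10], base[, 10], base[, 11:30])
  g <- toy_geno(d)
  kept <- ld_prune(g, r2_max = 0.2)
  expect_false(g$variants$variant_id[11] %in% kept) # later copy removed
  expect_true(g$variants$variant_id[10] %in% kept)

  # independent variants: all retained, and post hoc r^2 below threshold
  g2 <- toy_geno(matrix(rbinom(500 * 40, 2, 0.5), 500, 40))
  kept2 <- ld_prune(g2, r2_max = 0.2)
  cc <- cor(g2$dosage[, kept2])^2
  diag(cc) <- 0
  expect_equal(length(kept2), 40)
  expect_lt(max(cc), 0.2)

  # three variants, r^2(1,2) high: the later one (2) is dropped
  v1 <- rbinom(400, 2, 0.5)
  v2 <- v1
  flip <- sample(400, 40)
  v2[flip] <- rbinom(40, 2, 0.5)
  v3 <- rbinom(400, 2, 0.5)
  g3 <- toy_geno(cbind(v1, v2, v3))
  kept3 <- ld_prune(g3, r2_max = 0.2)
  expect_setequal(kept3, g3$variants$variant_id[c(1, 3)])
})

test_that("PCA separates simulated source populations", {
  cfg <- sim_config(
    n_sources = 2, fst_per_source = 0.1, n_variants = 5000,
    clusters = list(
      list(label = "src1", n_samples = 200, alpha = c(1000, 0.001)),
      list(label = "src2", n_samples = 200, alpha = c(0.001, 1000))
    ),
    enriched_fraction = 0, seed = 61
  )
  sim <- simulate_cohort(cfg)
  pca <- suppressWarnings(pca_genotypes(sim$genotypes, n_pcs = 5))
  pc1 <- pca$scores$PC1
  grp <- sim$genotypes$samples$population
  between <- (mean(pc1[grp == "src1"]) - mean(pc1[grp == "src2"]))^2 / 4 * 2
  within <- mean(tapply(pc1, grp, var))
  expect_gt(between / within, 10)
  # eigenvalues non-increasing and non-negative
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  expect_true(all(pca$eigenvalues >= 0))

  # duplicating every sample leaves the PC1 direction unchanged up to sign
  dup <- geno_matrix(
    rbind(sim$genotypes$dosage,
      `rownames<-`(sim$genotypes$dosage,
        paste0("D", rownames(sim$genotypes$dosage)))),
    sim$genotypes$variants
  )
  pca2 <- suppressWarnings(pca_genotypes(dup, n_pcs = 2))
  o1 <- pca$scores$PC1
  o2 <- pca2$scores$PC1[seq_along(o1)]
  expect_gt(abs(cor(o1, o2)), 0.999)

  expect_error(
    pca_genotypes(toy_geno(matrix(0:1, nrow = 1))), "two samples"
  )
})

test_that("iterative max-distance outlier detection flags planted outliers", {
  set.seed(31)
  scores <- tibble::tibble(
    sample_id = sprintf("S%03d", 1:201),
    PC1 = c(rnorm(200), 20),
    PC2 = c(rnorm(200), 0)
  )
  got <- detect_outliers(scores, n_pcs_used = 2)
  expect_equal(got[1], "S201") # 20-SD sample flagged first

  # fixed-count rule removes exactly n
  got3 <- detect_outliers(scores, rule = list(method = "count", n = 3))
  expect_length(got3, 3)
  expect_equal(got3[1], "S201")

  # homogeneous cloud at c = 6: nearly always no outliers
  n_flagged <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    sc <- tibble::tibble(
      sample_id = as.character(1:200),
      PC1 = rnorm(200), PC2 = rnorm(200)
    )
    length(detect_outliers(sc, rule = list(method = "sd", c = 6)))
  }, numeric(1))
  expect_gte(mean(n_flagged == 0), 0.95)
})

test_that("cluster assignment recovers planted admixture clusters", {
  cfg <- sim_config(
    n_variants = 3000,
    clusters = list(
      list(label = "a", n_samples = 100, alpha = c(60, 1)),
      list(label = "b", n_samples = 100, alpha = c(12, 12)),
      list(label = "c", n_samples = 100, alpha = c(1, 60))
    ),
    fst_per_source = c(0.1, 0.1),
    enriched_fraction = 0, seed = 77
  )
  sim <- simulate_cohort(cfg)
  pca <- suppressWarnings(pca_genotypes(sim$genotypes, n_pcs = 4))
  cl <- assign_clusters(pca$scores, k = 3, n_pcs_used = 2, seed = 5)
  ari <- adjusted_rand(
    cl$assignments$cluster,
    sim$genotypes$samples$population
  )
  expect_gt(ari, 0.9)
  # same seed -> identical assignment
  cl2 <- assign_clusters(pca$scores, k = 3, n_pcs_used = 2, seed = 5)
  expect_identical(cl$assignments, cl2$assignments)
  # labels ordered by mean PC1
  means <- tapply(pca$scores$PC1, cl$assignments$cluster, mean)
  expect_true(all(diff(means) > 0))
  # k = 1: everything in one cluster
  expect_equal(
    unique(assign_clusters(pca$scores, k = 1, seed = 1)$assignments$cluster),
    1L
  )
  expect_error(assign_clusters(pca$scores[1:2, ], k = 5, seed = 1), "exceeds")
})

test_that("Hudson F_ST recovers the simulated divergence", {
  make_two_pop <- function(f, seed, m = 5000, n = 100) {
    with_props <- sim_config(
      n_sources = 2, fst_per_source = c(f, f), n_variants = m,
      clusters = list(
        list(label = "A", n_samples = n, alpha = c(1000, 0.001)),
        list(label = "B", n_samples = n, alpha = c(0.001, 1000))
      ),
      enriched_fraction = 0, seed = seed
    )
    simulate_cohort(with_props)
  }
  sim <- make_two_pop(0.1, seed = 101)
  f <- fst(sim$genotypes, sim$genotypes$samples, "A", "B")
  # two sources each drifted at F from the shared ancestor: the expected
  # Hudson numerator is 2F p(1-p) and the denominator 2 p(1-p), so the
  # ratio-of-averages global recovers F itself
  expect_gt(f$global, 0.08)
  expect_lt(f$global, 0.12)

  # null: two halves of one population
  null_cfg <- sim_config(
    n_sources = 1, fst_per_source = 0.2, n_variants = 5000,
    clusters = list(list(label = "X", n_samples = 200, alpha = 1)),
    enriched_fraction = 0, seed = 103
  )
  nsim <- simulate_cohort(null_cfg)
  pops <- tibble::tibble(
    sample_id = nsim$genotypes$samples$sample_id,
    population = rep(c("L", "R"), each = 100)
  )
  f0 <- fst(nsim$genotypes, pops, "L", "R")
  expect_lt(abs(f0$global), 0.01)

  # fixed difference: per-variant value 1 under both estimators
  fixed <- toy_geno(cbind(c(rep(2, 10), rep(0, 10))))
  pops2 <- tibble::tibble(
    sample_id = rownames(fixed$dosage),
    population = rep(c("A", "B"), each = 10)
  )
  expect_equal(fst(fixed, pops2, "A", "B")$per_variant$fst, 1)
  expect_equal(fst(fixed, pops2, "A", "B", estimator = "wc")$global, 1,
    tolerance = 1e-12
  )
  expect_error(
    fst(fixed, pops2[c(1, 11:20), ], "A", "B"), "at least two"
  )
})

test_that("robust kinship separates duplicates, relatives and unrelateds", {
  cfg <- sim_config(
    n_sources = 1, fst_per_source = 0.05, n_variants = 2000,
    clusters = list(list(label = "X", n_samples = 120, alpha = 1)),
    enriched_fraction = 0, seed = 121
  )
  sim <- simulate_cohort(cfg)
  d <- sim$genotypes$dosage

  # identical vectors -> 0.5 and duplicate flag
  dup <- toy_geno(`rownames<-`(rbind(d[1, ], d[1, ]), c("A", "B")))
  k_dup <- kinship_pair(dup, "A", "B")
  expect_equal(k_dup$kinship, 0.5)
  expect_true(k_dup$duplicate)

  # parent-offspring: one allele copied from the parent
  set.seed(9)
  afs <- sim$truth$source_afs[1, ]
  k_po <- vapply(1:50, function(i) {
    parent <- d[i, ]
    from_parent <- rbinom(ncol(d), 1, parent / 2)
    child <- from_parent + rbinom(ncol(d), 1, afs)
    g <- toy_geno(`rownames<-`(rbind(parent, child), c("P", "C")))
    kinship_pair(g, "P", "C")$kinship
  }, numeric(1))
  expect_gt(mean(k_po), 0.2)
  expect_lt(mean(k_po), 0.3)

  # independent samples: near zero, no flags
  k0 <- kinship_pair(sim$genotypes, "S0001", "S0002")
  expect_lt(abs(k0$kinship), 0.05)
  expect_false(k0$related)

  small <- toy_geno(matrix(c(0, 1, 2, 0), 2, 2))
  expect_error(
    kinship_pair(small, rownames(small$dosage)[1], rownames(small$dosage)[2]),
    "shared non-missing"
  )
  expect_error(kinship_pair(sim$genotypes, "S0001", "nope"), "unknown sample")
})
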