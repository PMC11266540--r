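test_that("inverse rank-normal transform matches the quantile oracle", {
  got <- irnt(c(3, 1, 2))
  want <- qnorm(c(5 / 6, 1 / 6, 3 / 6))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got[3], 0)

  # middle of an odd tie-free vector is exactly 0; mean is 0 by symmetry
  set.seed(2)
  x <- rnorm(101)
  z <- irnt(x)
  expect_equal(z[order(x)][51], 0)
  expect_lt(abs(mean(z)), 1e-12)

  # invariant under strictly monotone transforms (tie-free)
  expect_equal(irnt(exp(x)), z)
  expect_equal(irnt(rank(x)), z)

  # missing preserved; ties averaged
  y <- c(1, 2, 2, NA, 5)
  z2 <- irnt(y)
  expect_true(is.na(z2[4]))
  expect_equal(z2[2], z2[3])
  expect_warning(irnt(c(1, 1, 1)), "constant")
  expect_error(irnt(c(1, NA)), "at least two")
})

test_that("phenotype QC enforces the strict sample-count and trim rules", {
  set.seed(4)
  n <- 400
  tab <- tibble::tibble(
    sample_id = as.character(1:n),
    sex = rbinom(n, 1, 0.5), age = rnorm(n, 50, 8),
    p_drop = c(rnorm(200), rep(NA, 200)), # exactly 200 -> dropped
    p_keep = c(rnorm(201), rep(NA, 199)), # 201 -> kept
    p_trim = c(1:100, rep(NA, 300)),
    p_allmiss = rep(NA_real_, n),
    p_bin = rbinom(n, 1, 0.3)
  )
  specs <- tibble::tibble(
    name = c("p_drop", "p_keep", "p_trim", "p_allmiss", "p_bin"),
    type = c("quantitative", "quantitative", "quantitative", "quantitative",
      "binary"),
    trim = c(FALSE, FALSE, TRUE, FALSE, FALSE)
  )
  out <- phenotype_qc(tab, specs, min_n = 200)
  expect_false("p_drop" %in% names(out))
  expect_true("p_keep" %in% names(out))
  expect_false("p_allmiss" %in% names(out))
  expect_true("p_keep_irnt" %in% names(out))
  expect_false("p_bin_irnt" %in% names(out))

  # trimming with values 1..100: q05 = 5.95, q95 = 95.05 (type 7), so
  # values <= 5 and >= 96 go missing: 90 survivors
  specs_t <- specs[specs$name == "p_trim", ]
  out_t <- phenotype_qc(
    dplyr::select(tab, sample_id, sex, age, p_trim), specs_t,
    min_n = 50
  )
  expect_equal(sum(!is.na(out_t$p_trim)), 90)
  expect_equal(range(out_t$p_trim, na.rm = TRUE), c(6, 95))
  # the IRNT version is computed from the untrimmed values
  expect_equal(sum(!is.na(out_t$p_trim_irnt)), 100)
})

test_that("linear association is calibrated and recovers planted effects", {
  set.seed(11)
  n <- 1000
  covs <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 50, 8))
  # independent (genotype, phenotype) replicates per variant
  p_null <- vapply(1:500, function(j) {
    linear_assoc(rbinom(n, 2, 0.3), rnorm(n), covs)$p
  }, numeric(1))
  # type-I error at alpha = 0.05
  expect_gt(mean(p_null < 0.05), 0.03)
  expect_lt(mean(p_null < 0.05), 0.07)
  # null p-values are uniform (KS)
  expect_gt(suppressWarnings(ks.test(p_null, "punif")$p.value), 0.01)

  # coverage: planted beta = 0.5 recovered within 2 SE in >= 95/100
  hits <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    gj <- rbinom(2000, 2, 0.3)
    yj <- 0.5 * gj + rnorm(2000)
    fit <- linear_assoc(gj, yj, NULL)
    abs(fit$beta - 0.5) <= 2 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # agreement with the reference solver on random designs
  for (i in 1:20) {
    set.seed(400 + i)
    nn <- 150
    gj <- rbinom(nn, 2, runif(1, 0.1, 0.5))
    cc <- data.frame(a = rnorm(nn), b = rbinom(nn, 1, 0.5))
    yy <- rnorm(nn) + 0.2 * gj + 0.3 * cc$a
    fit <- linear_assoc(gj, yy, cc)
    ref <- summary(lm(yy ~ gj + a + b, data = cc))$coefficients
    expect_equal(fit$beta, ref["gj", 1], tolerance = 1e-6)
    expect_equal(fit$se, ref["gj", 2], tolerance = 1e-6)
    expect_equal(fit$p, ref["gj", 4], tolerance = 1e-6)
  }

  expect_error(
    linear_assoc(rep(1, 100), rnorm(100), NULL),
    "dosage"
  )
})

test_that("logistic association is calibrated and recovers planted log-odds", {
  set.seed(13)
  n <- 1000
  p_null <- vapply(1:500, function(j) {
    logistic_assoc(rbinom(n, 2, 0.3), rbinom(n, 1, 0.3), NULL)$p
  }, numeric(1))
  expect_gt(mean(p_null < 0.05), 0.03)
  expect_lt(mean(p_null < 0.05), 0.07)

  hits <- vapply(1:100, function(i) {
    set.seed(5000 + i)
    gj <- rbinom(3000, 2, 0.3)
    pr <- plogis(-1 + 0.4 * gj)
    yj <- rbinom(3000, 1, pr)
    fit <- logistic_assoc(gj, yj, NULL)
    abs(fit$beta - 0.4) <= 2 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # case/control AFs split correctly
  set.seed(14)
  gj <- rbinom(500, 2, 0.25)
  yj <- rbinom(500, 1, 0.4)
  fit <- logistic_assoc(gj, yj, NULL)
  expect_equal(fit$af_cases, mean(gj[yj == 1]) / 2)
  expect_equal(fit$af_controls, mean(gj[yj == 0]) / 2)
  expect_error(logistic_assoc(gj, rep(1, 500), NULL), "both classes")
})

test_that("the GWAS driver applies per-phenotype QC and joins metadata", {
  cfg <- sim_config(
    n_sources = 1, fst_per_source = 0.05, n_variants = 60,
    clusters = list(list(label = "X", n_samples = 600, alpha = 1)),
    enriched_fraction = 0, seed = 31
  )
  sim <- simulate_cohort(cfg)
  pheno <- simulate_phenotypes(
    sim$genotypes,
    list(list(name = "q", type = "quantitative", causal = 5L, beta = 0.6,
      h2 = 0.2)),
    seed = 7
  )
  # second phenotype observed only in a subsample where variant 1 is rare
  d <- sim$genotypes$dosage
  rare_sub <- order(d[, 1]) # carriers last
  pheno$q2 <- NA_real_
  sub_ids <- rownames(d)[rare_sub[1:300]]
  pheno$q2[match(sub_ids, pheno$sample_id)] <- rnorm(300)

  specs <- tibble::tibble(name = c("q", "q2"), type = "quantitative")
  res <- run_gwas(sim$genotypes, pheno, specs,
    covariates = c("sex", "age"),
    maf_min = 0.01, hwe_min = 1e-4
  )
  expect_s3_class(res, "gwas_result")
  expect_true(all(c("phenotype", "variant_id", "beta", "se", "p", "n_used",
    "chrom", "pos") %in% names(res)))

  v1 <- sim$genotypes$variants$variant_id[1]
  af_sub <- mean(d[rare_sub[1:300], 1]) / 2
  in_q2 <- v1 %in% res$variant_id[res$phenotype == "q2"]
  # the variant is QC'd per phenotype: present iff its subsample MAF passes
  expect_equal(in_q2, min(af_sub, 1 - af_sub) > 0.01)

  # planted causal variant is the top hit for q
  rq <- res[res$phenotype == "q", ]
  expect_equal(
    rq$variant_id[which.min(rq$p)],
    sim$genotypes$variants$variant_id[5]
  )

  # missing covariate error; empty phenotype set
  expect_error(
    run_gwas(sim$genotypes, pheno, specs, covariates = c("sex", "PC9")),
    "PC9"
  )
  empty <- run_gwas(sim$genotypes, pheno, specs[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("association on an IRNT phenotype ignores the original scale", {
  set.seed(41)
  n <- 500
  g <- rbinom(n, 2, 0.4)
  y <- exp(rnorm(n) + 0.3 * g)
  f1 <- linear_assoc(g, irnt(y), NULL)
  f2 <- linear_assoc(g, irnt(1000 * y^3), NULL)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
})
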