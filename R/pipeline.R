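#' Default pipeline configuration
#'
#' A nested list (YAML-serializable, versioned schema) driving
#' [run_pipeline()]. Every stage block mirrors the defaults of the
#' corresponding functions; unknown keys are validation errors, not
#' warnings.
#'
#' @param seed Global seed; every stage derives its own child seed from it.
#' @return A list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    schema_version = 1L,
    seed = as.integer(seed),
    stages = c("simulate", "structure", "enrich", "ibd", "gwas", "replicate"),
    simulate = list(
      n_variants = 1500,
      n_per_cluster = 120,
      enriched_fraction = 0.05,
      fst_per_source = c(0.05, 0.15),
      ibd_rate_within = 2, ibd_rate_between = 0.2,
      ibd_mean_length_cM = 3,
      missing_rate = 0
    ),
    structure = list(k = 3, n_pcs = 10, n_pcs_cluster = 2, prune_r2 = 0.2),
    enrich = list(ratio_min = 2, af_band = c(0.01, 0.1), sentinel = -5),
    ibd = list(lod_min = 3, gap_max_cm = 0.6, max_discordant = 1),
    gwas = list(
      min_n = 200, maf_min = 0.01, hwe_min = 1e-4, n_pcs = 4,
      trim_quantiles = c(0.05, 0.95)
    ),
    replicate = list(
      alpha = 0.05, r2_max = 0.1, p_gw = 5e-8, maf_min = 0.01,
      eas_nfe_ratio_max = 2
    )
  ), class = "pipeline_config")
}

known_keys <- list(
  top = c(
    "schema_version", "seed", "stages", "simulate", "structure",
    "enrich", "ibd", "gwas", "replicate"
  ),
  simulate = c(
    "n_variants", "n_per_cluster", "enriched_fraction", "fst_per_source",
    "ibd_rate_within", "ibd_rate_between", "ibd_mean_length_cM",
    "missing_rate"
  ),
  structure = c("k", "n_pcs", "n_pcs_cluster", "prune_r2"),
  enrich = c("ratio_min", "af_band", "sentinel"),
  ibd = c("lod_min", "gap_max_cm", "max_discordant"),
  gwas = c("min_n", "maf_min", "hwe_min", "n_pcs", "trim_quantiles"),
  replicate = c("alpha", "r2_max", "p_gw", "maf_min", "eas_nfe_ratio_max")
)

#' Validate a pipeline configuration
#'
#' @param config A list as from [default_pipeline_config()] (or parsed from
#'   YAML via [yaml::read_yaml()]).
#' @return Tibble of violations (`field`, `message`); zero rows iff the
#'   configuration is runnable.
#' @export
validate_config <- function(config) {
  v <- list()
  complain <- function(field, message) {
    v[[length(v) + 1]] <<- tibble::tibble(field = field, message = message)
  }
  unknown <- setdiff(names(config), known_keys$top)
  for (k in unknown) complain(k, "unknown configuration key")
  for (blk in intersect(names(known_keys)[-1], names(config))) {
    for (k in setdiff(names(config[[blk]]), known_keys[[blk]])) {
      complain(paste(blk, k, sep = "."), "unknown configuration key")
    }
  }
  bad_stages <- setdiff(
    config$stages,
    c("simulate", "structure", "enrich", "ibd", "gwas", "replicate")
  )
  for (s in bad_stages) complain("stages", paste("unknown stage:", s))
  chk <- function(blk, key, test, msg) {
    val <- config[[blk]][[key]]
    if (!is.null(val) && !test(val)) complain(paste(blk, key, sep = "."), msg)
  }
  chk("ibd", "gap_max_cm", function(x) x >= 0, "must be >= 0")
  chk("ibd", "max_discordant", function(x) x >= 0, "must be >= 0")
  chk("structure", "k", function(x) x >= 1, "must be >= 1")
  chk("structure", "prune_r2", function(x) x > 0 && x <= 1, "must be in (0, 1]")
  chk("simulate", "enriched_fraction", function(x) x >= 0 && x <= 1,
    "must be in [0, 1]")
  chk("simulate", "fst_per_source", function(x) all(x > 0 & x < 1),
    "must lie strictly inside (0, 1)")
  chk("simulate", "ibd_mean_length_cM", function(x) x > 0, "must be positive")
  chk("gwas", "maf_min", function(x) x >= 0 && x < 0.5, "must be in [0, 0.5)")
  chk("replicate", "alpha", function(x) x > 0 && x < 1, "must be in (0, 1)")
  if (length(v)) dplyr::bind_rows(v) else tibble::tibble(
    field = character(0), message = character(0)
  )
}

stage_record <- function(manifest, stage, files, seed, elapsed) {
  dplyr::bind_rows(manifest, tibble::tibble(
    stage = stage,
    status = "completed",
    seed = seed,
    n_outputs = length(files),
    outputs = paste(basename(files), collapse = ";"),
    md5 = paste(unname(tools::md5sum(files)), collapse = ";"),
    elapsed_s = round(elapsed, 3)
  ))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate a cohort with
#' ground truth, population structure (QC, LD pruning, PCA, clustering,
#' F_ST), allele-frequency enrichment scoring, IBD filtering/merging and
#' population sharing, covariate-adjusted GWAS, and the Bonferroni
#' replication procedure against a simulated external catalogue — writing
#' each stage's tables under `out_dir` plus a manifest with md5 checksums.
#' Re-running with an identical configuration reproduces byte-identical
#' outputs.
#'
#' @param config A `pipeline_config` list (see [default_pipeline_config()]),
#'   or a path to a YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble, invisibly; all outputs are files under
#'   `out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  violations <- validate_config(config)
  if (nrow(violations)) {
    stop("invalid configuration:\n", paste(
      sprintf("  %s: %s", violations$field, violations$message),
      collapse = "\n"
    ), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble::tibble()
  seed <- config$seed
  path <- function(...) file.path(out_dir, ...)
  stages <- config$stages

  downstream <- setdiff(stages, "simulate")
  if (length(downstream) && !"simulate" %in% stages) {
    stop("downstream stages require the simulate stage in this synthetic ",
      "pipeline", call. = FALSE)
  }

  sim <- NULL
  pheno <- NULL
  pcs <- NULL
  af_table <- NULL
  gwas_res <- NULL

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    sc <- config$simulate
    cfg <- sim_config(
      n_variants = sc$n_variants,
      fst_per_source = sc$fst_per_source,
      clusters = list(
        list(label = "cl1", n_samples = sc$n_per_cluster, alpha = c(20, 1)),
        list(label = "cl2", n_samples = sc$n_per_cluster, alpha = c(10, 4)),
        list(label = "cl3", n_samples = sc$n_per_cluster, alpha = c(4, 10))
      ),
      enriched_fraction = sc$enriched_fraction,
      ibd_rate_within = sc$ibd_rate_within,
      ibd_rate_between = sc$ibd_rate_between,
      ibd_mean_length_cM = sc$ibd_mean_length_cM,
      missing_rate = sc$missing_rate,
      pheno_specs = list(
        list(
          name = "lipid_a", type = "quantitative",
          causal = 1L, beta = 0.5, h2 = 0.3, trim = TRUE
        ),
        list(
          name = "t2d", type = "binary",
          causal = 10L, beta = 0.4, prevalence = 0.2
        )
      ),
      seed = seed
    )
    sim <- simulate_cohort(cfg)
    ibd_sim <- simulate_ibd_segments(
      sim$genotypes$samples$sample_id,
      sim$genotypes$samples$population, cfg
    )
    pheno <- simulate_phenotypes(sim$genotypes, cfg$pheno_specs, seed = seed)
    af_table <- build_synthetic_af_table(sim, seed = seed)

    write_vcf_genotypes(sim$genotypes, path("genotypes.vcf"))
    readr::write_tsv(
      dplyr::bind_cols(
        tibble::tibble(
          sample_id = sim$genotypes$samples$sample_id,
          cluster = sim$truth$cluster_labels
        ),
        tibble::as_tibble(sim$truth$ancestry_proportions,
          .name_repair = ~ paste0("ancestry_", seq_along(.x))
        )
      ),
      path("truth_ancestry.tsv")
    )
    write_af_table(af_table, path("allele_frequencies.tsv"))
    write_ibd_segments(ibd_sim$segments, path("ibd_segments.tsv"))
    readr::write_tsv(pheno, path("phenotypes.tsv"))
    files <- path(c(
      "genotypes.vcf", "truth_ancestry.tsv", "allele_frequencies.tsv",
      "ibd_segments.tsv", "phenotypes.tsv"
    ))
    manifest <- stage_record(manifest, "simulate", files, seed,
      proc.time()[3] - t0)
  }

  if ("structure" %in% stages) {
    t0 <- proc.time()[3]
    st <- config$structure
    geno <- sim$genotypes
    qc <- variant_qc(geno)
    pruned <- ld_prune(qc, r2_max = st$prune_r2)
    pca <- pca_genotypes(subset_geno(qc, variants = pruned),
      n_pcs = st$n_pcs)
    out_ids <- tryCatch(
      detect_outliers(pca$scores, n_pcs_used = st$n_pcs_cluster),
      error = function(e) character(0)
    )
    keep_scores <- pca$scores[!pca$scores$sample_id %in% out_ids, ]
    clus <- assign_clusters(keep_scores,
      k = st$k,
      n_pcs_used = st$n_pcs_cluster, seed = derive_seed(seed, "clusters")
    )
    pops <- sim$genotypes$samples
    f <- fst(qc, pops, "cl1", "cl3")
    pcs <- pca$scores
    readr::write_tsv(pca$scores, path("pca_scores.tsv"))
    readr::write_tsv(tidy(pca), path("pca_eigenvalues.tsv"))
    readr::write_tsv(clus$assignments, path("clusters.tsv"))
    readr::write_tsv(
      tibble::tibble(
        pop_a = f$pop_a, pop_b = f$pop_b, estimator = f$estimator,
        global_fst = f$global, n_variants = nrow(f$per_variant)
      ),
      path("fst_global.tsv")
    )
    files <- path(c(
      "pca_scores.tsv", "pca_eigenvalues.tsv", "clusters.tsv",
      "fst_global.tsv"
    ))
    manifest <- stage_record(manifest, "structure", files, seed,
      proc.time()[3] - t0)
  }

  if ("enrich" %in% stages) {
    t0 <- proc.time()[3]
    en <- config$enrich
    rec <- enrichment_records(af_table, "FIN", "NFE", sentinel = en$sentinel)
    enriched <- classify_finnish_enriched(af_table,
      ratio_min = en$ratio_min,
      af_band = en$af_band, sentinel = en$sentinel
    )
    rec$finnish_enriched <- rec$variant_id %in% enriched
    summ <- enrichment_summary(rec, ratio_min = en$ratio_min)
    reg <- enrichment_regression(af_table, "RUS", "NFE",
      variant_set = enriched
    )
    readr::write_tsv(rec, path("enrichment_records.tsv"))
    readr::write_tsv(summ, path("enrichment_summary.tsv"))
    readr::write_tsv(tidy(reg), path("enrichment_regression.tsv"))
    files <- path(c(
      "enrichment_records.tsv", "enrichment_summary.tsv",
      "enrichment_regression.tsv"
    ))
    manifest <- stage_record(manifest, "enrich", files, seed,
      proc.time()[3] - t0)
  }

  if ("ibd" %in% stages) {
    t0 <- proc.time()[3]
    ib <- config$ibd
    seg <- read_ibd_segments(path("ibd_segments.tsv"))
    kept <- filter_segments(seg, lod_min = ib$lod_min)
    merged <- merge_segments(kept, sim$genotypes,
      gap_max_cm = ib$gap_max_cm, max_discordant = ib$max_discordant
    )
    totals <- pair_totals(
      merged,
      all_sample_pairs(sim$genotypes$samples$sample_id)
    )
    sharing <- population_median_matrix(totals, sim$genotypes$samples)
    dend <- cluster_populations(sharing)
    write_ibd_segments(merged, path("ibd_merged.tsv"))
    readr::write_tsv(totals, path("ibd_pair_totals.tsv"))
    readr::write_tsv(tidy(sharing), path("ibd_population_medians.tsv"))
    writeLines(dend$newick, path("ibd_dendrogram.nwk"))
    files <- path(c(
      "ibd_merged.tsv", "ibd_pair_totals.tsv",
      "ibd_population_medians.tsv", "ibd_dendrogram.nwk"
    ))
    manifest <- stage_record(manifest, "ibd", files, seed,
      proc.time()[3] - t0)
  }

  if ("gwas" %in% stages) {
    t0 <- proc.time()[3]
    gw <- config$gwas
    specs <- tibble::tibble(
      name = c("lipid_a", "t2d"),
      type = c("quantitative", "binary"),
      trim = c(TRUE, FALSE)
    )
    ph <- phenotype_qc(pheno, specs,
      min_n = gw$min_n,
      trim_quantiles = gw$trim_quantiles
    )
    pc_cols <- paste0("PC", seq_len(gw$n_pcs))
    ph <- dplyr::left_join(ph, pcs[, c("sample_id", pc_cols)],
      by = "sample_id"
    )
    specs_run <- specs[specs$name %in% names(ph), ]
    gwas_res <- run_gwas(sim$genotypes, ph, specs_run,
      covariates = c("sex", "age", pc_cols),
      maf_min = gw$maf_min, hwe_min = gw$hwe_min
    )
    write_gwas_results(gwas_res, path("gwas_summary.tsv"))
    files <- path("gwas_summary.tsv")
    manifest <- stage_record(manifest, "gwas", files, seed,
      proc.time()[3] - t0)
  }

  if ("replicate" %in% stages) {
    t0 <- proc.time()[3]
    rp <- config$replicate
    candidates <- select_replicable(af_table,
      maf_min = rp$maf_min,
      eas_nfe_ratio_max = rp$eas_nfe_ratio_max
    )
    external <- build_synthetic_external(
      candidates,
      attr(pheno, "planted_effects"), seed = seed
    )
    matched <- match_external_hits(candidates, external$hits,
      p_gw = rp$p_gw)
    report <- replicate_candidates(
      gwas_res, matched, external$groups, sim$genotypes, candidates,
      alpha = rp$alpha, r2_max = rp$r2_max
    )
    readr::write_tsv(glance(report), path("replication_summary.tsv"))
    readr::write_tsv(tidy(report), path("replication_hits.tsv"))
    jsonlite::write_json(
      list(
        threshold = report$threshold,
        n_candidates = length(report$candidates),
        n_independent = report$n_independent,
        n_groups = report$n_groups,
        replicated = report$replicated$variant_id
      ),
      path("replication_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
    files <- path(c(
      "replication_summary.tsv", "replication_hits.tsv",
      "replication_report.json"
    ))
    manifest <- stage_record(manifest, "replicate", files, seed,
      proc.time()[3] - t0)
  }

  readr::write_tsv(manifest, path("manifest.tsv"))
  invisible(manifest)
}

# Allele-frequency table for the synthetic cohort: the two simulated sources
# play the roles of the bottlenecked (FIN-like) and reference (NFE-like)
# populations; RUS is the realized cohort AF; per-cluster realized AFs give
# the RUS_cl columns; EAS is a synthetic outgroup built so that most planted
# enriched variants pass the EAS/NFE ratio filter, a tenth are unobserved
# (sentinel), and a tenth are planted common in EAS (filtered out).
build_synthetic_af_table <- function(sim, seed) {
  geno <- sim$genotypes
  truth <- sim$truth
  cfg <- truth$config
  m <- ncol(geno$dosage)
  fin <- truth$source_afs[cfg$enriched_source, ]
  nfe <- truth$source_afs[cfg$reference_source, ]
  eas <- with_seed(derive_seed(seed, "external"), {
    base <- simulate_source_afs(truth$ancestral_afs, 0.15,
      seed = derive_seed(seed, "external") + 1
    )
    idx <- match(truth$enriched_variant_ids, geno$variants$variant_id)
    u <- runif(length(idx))
    base[idx] <- nfe[idx] * runif(length(idx), 0.5, 3)
    base[idx[u < 0.1]] <- 0
    common <- u >= 0.1 & u < 0.2
    base[idx[common]] <- pmin(nfe[idx[common]] * 8, 0.5)
    base
  })
  out <- tibble::tibble(
    chrom = geno$variants$chrom, pos = geno$variants$pos,
    ref = geno$variants$ref, alt = geno$variants$alt,
    variant_id = geno$variants$variant_id,
    AF_FIN = fin, AF_NFE = nfe, AF_EAS = eas,
    AF_RUS = unname(allele_freqs(geno))
  )
  for (cl in unique(geno$samples$population)) {
    idx <- geno$samples$population == cl
    out[[paste0("AF_RUS_", cl)]] <-
      unname(allele_freqs(geno$dosage[idx, , drop = FALSE]))
  }
  out
}

# Synthetic external association catalogue: planted causal variants appear as
# genome-wide-significant hits on matching external phenotypes; a handful of
# null candidates get significant external hits whose local signals are null,
# exercising the non-replication path.
build_synthetic_external <- function(candidates, planted_effects, seed) {
  with_seed(derive_seed(seed, "external") + 7, {
    hits <- list()
    if (!is.null(planted_effects) && nrow(planted_effects)) {
      planted_in <- planted_effects[
        planted_effects$variant_id %in% candidates,
      ]
      if (nrow(planted_in)) {
        hits[[1]] <- tibble::tibble(
          variant_id = planted_in$variant_id,
          phenotype = paste0("ext_", planted_in$phenotype),
          p = 1e-20, beta = planted_in$beta, cohort = "external"
        )
      }
    }
    nulls <- setdiff(candidates, planted_effects$variant_id)
    n_null <- min(10, length(nulls))
    if (n_null) {
      pick <- sample(nulls, n_null)
      hits[[length(hits) + 1]] <- tibble::tibble(
        variant_id = pick,
        phenotype = sample(c("ext_null_a", "ext_null_b"), n_null,
          replace = TRUE
        ),
        p = 10^runif(n_null, -12, -9), beta = rnorm(n_null, 0, 0.1),
        cohort = "external"
      )
    }
    hits <- dplyr::bind_rows(hits)
    groups <- tibble::tibble(
      phenotype = unique(hits$phenotype),
      group = ifelse(grepl("null", unique(hits$phenotype)),
        "null_traits", "metabolic"
      )
    )
    list(hits = hits, groups = groups)
  })
}
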