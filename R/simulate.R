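#' Simulation configuration for a synthetic admixed cohort
#'
#' Bundles every knob of the cohort generator. The defaults describe a small
#' two-source admixed cohort: several clusters whose ancestry interpolates
#' between a European-like and an Asian-like source, a band of variants
#' enriched in a designated source (allele frequency 0.01-0.1 there and more
#' than four-fold above the reference source, mimicking bottleneck-enriched
#' variants), elevated within-cluster IBD sharing, and phenotypes with known
#' planted genetic effects.
#'
#' @param n_sources Number of ancestral source populations.
#' @param fst_per_source Numeric vector (recycled) of Balding-Nichols
#'   divergence parameters F per source, each strictly inside (0, 1).
#' @param n_variants Number of variants to simulate.
#' @param ancestral_af_range Interval within (0, 1) from which ancestral
#'   allele frequencies are drawn uniformly.
#' @param clusters List of cluster definitions, each a list with `label`,
#'   `n_samples` (>= 1) and `alpha` (Dirichlet concentration over sources,
#'   all strictly positive).
#' @param enriched_fraction Fraction of variants forced to be enriched in the
#'   designated source.
#' @param enriched_source,reference_source Indices of the source in which
#'   enriched variants are planted and of the source they are measured
#'   against.
#' @param ibd_rate_within,ibd_rate_between Expected IBD segment count per
#'   same-cluster / different-cluster pair.
#' @param ibd_mean_length_cM Mean of the exponential segment length (cM).
#' @param ibd_lod_mean Mean of the exponential LOD distribution; with the
#'   default 4, a known fraction `1 - exp(-3/4)` of segments falls below the
#'   usual LOD > 3 quality filter.
#' @param chrom_length_bp Length of the single simulated chromosome (bp); the
#'   default genetic map is uniform at 1 cM/Mb.
#' @param pheno_specs List of phenotype definitions, each a list with `name`,
#'   `type` ("quantitative" or "binary"), `causal` (variant indices),
#'   `beta` (effect sizes, per-allele on the liability/trait scale), and
#'   `h2` (quantitative, in [0, 1)) or `prevalence` (binary, in (0, 1)).
#' @param missing_rate Genotype missingness injected uniformly at random.
#' @param seed Integer seed; all randomness fans out from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sources = 2,
                       fst_per_source = c(0.05, 0.15),
                       n_variants = 2000,
                       ancestral_af_range = c(0.05, 0.95),
                       clusters = list(
                         list(label = "cl1", n_samples = 120, alpha = c(20, 1)),
                         list(label = "cl2", n_samples = 120, alpha = c(10, 4)),
                         list(label = "cl3", n_samples = 120, alpha = c(4, 10))
                       ),
                       enriched_fraction = 0.05,
                       enriched_source = 1,
                       reference_source = 2,
                       ibd_rate_within = 2,
                       ibd_rate_between = 0.2,
                       ibd_mean_length_cM = 3,
                       ibd_lod_mean = 4,
                       chrom_length_bp = 1e8,
                       pheno_specs = list(),
                       missing_rate = 0,
                       seed = 1L) {
  cfg <- list(
    n_sources = n_sources, fst_per_source = rep_len(fst_per_source, n_sources),
    n_variants = n_variants, ancestral_af_range = ancestral_af_range,
    clusters = clusters, enriched_fraction = enriched_fraction,
    enriched_source = enriched_source, reference_source = reference_source,
    ibd_rate_within = ibd_rate_within, ibd_rate_between = ibd_rate_between,
    ibd_mean_length_cM = ibd_mean_length_cM, ibd_lod_mean = ibd_lod_mean,
    chrom_length_bp = chrom_length_bp, pheno_specs = pheno_specs,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (any(cfg$fst_per_source <= 0) || any(cfg$fst_per_source >= 1)) {
    stop("fst_per_source values must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (cfg$enriched_fraction < 0 || cfg$enriched_fraction > 1) {
    stop("enriched_fraction must lie in [0, 1]", call. = FALSE)
  }
  r <- cfg$ancestral_af_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] >= r[2]) {
    stop("ancestral_af_range must be an interval within (0, 1)", call. = FALSE)
  }
  for (cl in cfg$clusters) {
    if (is.null(cl$label) || is.null(cl$n_samples) || is.null(cl$alpha)) {
      stop("each cluster needs label, n_samples and alpha", call. = FALSE)
    }
    if (cl$n_samples < 1) stop("cluster sample counts must be >= 1", call. = FALSE)
    if (any(cl$alpha <= 0)) {
      stop("dirichlet alpha values must be strictly positive", call. = FALSE)
    }
    if (length(cl$alpha) != cfg$n_sources) {
      stop("cluster alpha length must equal n_sources", call. = FALSE)
    }
  }
  if (cfg$ibd_mean_length_cM <= 0) {
    stop("ibd_mean_length_cM must be positive", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' Draw population allele frequencies under the Balding-Nichols model
#'
#' Each population frequency is drawn as
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` around the ancestral frequency
#' `p`, so that `E[AF] = p` and `Var[AF] = F p (1 - p)`.
#'
#' @param ancestral_afs Numeric vector of ancestral frequencies, each strictly
#'   inside (0, 1).
#' @param fst Divergence parameter F, strictly inside (0, 1).
#' @param seed Integer seed.
#' @return Numeric vector of drifted allele frequencies, one per input.
#' @export
simulate_source_afs <- function(ancestral_afs, fst, seed = 1L) {
  if (!is.numeric(fst) || length(fst) != 1 || fst <= 0 || fst >= 1) {
    stop("fst must be a single value strictly inside (0, 1)", call. = FALSE)
  }
  if (any(ancestral_afs <= 0) || any(ancestral_afs >= 1)) {
    stop("ancestral allele frequencies must be strictly inside (0, 1)",
      call. = FALSE
    )
  }
  shape_scale <- (1 - fst) / fst
  with_seed(seed, {
    rbeta(
      length(ancestral_afs),
      ancestral_afs * shape_scale,
      (1 - ancestral_afs) * shape_scale
    )
  })
}

rdirichlet <- function(n, alpha) {
  g <- matrix(
    rgamma(n * length(alpha), shape = rep(alpha, each = n)),
    nrow = n
  )
  g / rowSums(g)
}

#' Simulate an admixed genotype cohort with known ground truth
#'
#' Source allele frequencies drift from shared ancestral frequencies under
#' Balding-Nichols; each sample's ancestry vector is Dirichlet within its
#' cluster; genotypes are Binomial(2, q' p) draws at the sample's mixed
#' frequency. A configured fraction of variants is planted as enriched in the
#' designated source: allele frequency in [0.01, 0.1] there (rejection
#' sampling, capped at 1000 attempts) and below a quarter of that in the
#' reference source, so the planted log2 frequency ratio always exceeds 2.
#'
#' @param config A [sim_config()].
#' @return A list with `genotypes` (a [geno_matrix()]; sample metadata carries
#'   the cluster label as `population`) and `truth` (class `sim_truth`:
#'   `ancestry_proportions`, `source_afs` (sources x variants),
#'   `enriched_variant_ids`, `ancestral_afs`, cluster labels).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n_samples <- sum(vapply(config$clusters, `[[`, numeric(1), "n_samples"))
  if (n_samples * config$n_variants > 2e8) {
    stop("requested cohort exceeds the 2e8-cell capacity guard", call. = FALSE)
  }
  m <- config$n_variants
  k <- config$n_sources

  ancestral <- with_seed(derive_seed(config$seed, "source_afs"), {
    runif(m, config$ancestral_af_range[1], config$ancestral_af_range[2])
  })
  source_afs <- matrix(NA_real_, nrow = k, ncol = m)
  for (s in seq_len(k)) {
    source_afs[s, ] <- simulate_source_afs(
      ancestral, config$fst_per_source[s],
      seed = derive_seed(config$seed, "source_afs") + s
    )
  }

  # plant enriched variants in the designated source
  n_enriched <- round(config$enriched_fraction * m)
  enriched_idx <- integer(0)
  if (n_enriched > 0) {
    enriched_idx <- seq_len(n_enriched) # deterministic: first block
    with_seed(derive_seed(config$seed, "enriched"), {
      for (j in enriched_idx) {
        af <- ancestral[j]
        shape <- (1 - config$fst_per_source[config$enriched_source]) /
          config$fst_per_source[config$enriched_source]
        target <- NA_real_
        for (attempt in seq_len(1000)) {
          cand <- rbeta(1, 0.055 * shape, (1 - 0.055) * shape)
          if (cand >= 0.01 && cand <= 0.1) {
            target <- cand
            break
          }
        }
        if (is.na(target)) {
          stop("failed to place enriched variant inside [0.01, 0.1] after 1000 attempts",
            call. = FALSE
          )
        }
        source_afs[config$enriched_source, j] <- target
        ref <- NA_real_
        for (attempt in seq_len(1000)) {
          cand <- rbeta(1, 1, 60) # small reference-side frequency
          if (cand > 0 && cand < target / 4) {
            ref <- cand
            break
          }
        }
        if (is.na(ref)) ref <- target / 8
        source_afs[config$reference_source, j] <- ref
      }
    })
  }

  labels <- unlist(lapply(
    config$clusters,
    function(cl) rep(cl$label, cl$n_samples)
  ))
  ancestry <- with_seed(derive_seed(config$seed, "ancestry"), {
    do.call(rbind, lapply(config$clusters, function(cl) {
      rdirichlet(cl$n_samples, cl$alpha)
    }))
  })

  mixed_af <- ancestry %*% source_afs # samples x variants
  dosage <- with_seed(derive_seed(config$seed, "genotypes"), {
    d <- matrix(
      rbinom(length(mixed_af), 2, as.vector(mixed_af)),
      nrow = nrow(mixed_af)
    )
    if (config$missing_rate > 0) {
      d[runif(length(d)) < config$missing_rate] <- NA_real_
    }
    d
  })

  pos <- round(seq(1e4, config$chrom_length_bp - 1e4, length.out = m))
  variants <- tibble::tibble(
    variant_id = sprintf("1:%d:A:G", pos),
    chrom = "1", pos = pos, ref = "A", alt = "G",
    genotyped = TRUE
  )
  rownames(dosage) <- sprintf("S%04d", seq_len(n_samples))
  colnames(dosage) <- variants$variant_id
  samples <- tibble::tibble(
    sample_id = rownames(dosage),
    population = labels
  )
  geno <- geno_matrix(dosage, variants, samples)

  truth <- structure(
    list(
      ancestry_proportions = ancestry,
      source_afs = source_afs,
      ancestral_afs = ancestral,
      enriched_variant_ids = variants$variant_id[enriched_idx],
      cluster_labels = labels,
      config = config
    ),
    class = "sim_truth"
  )
  stopifnot(max(abs(rowSums(ancestry) - 1)) < 1e-12)
  list(genotypes = geno, truth = truth)
}

#' Simulate pairwise IBD segments with planted population structure
#'
#' Per pair, segment counts are Poisson with a rate depending on whether the
#' two samples share a population label; lengths are exponential; positions
#' uniform on a single chromosome with a uniform 1 cM/Mb genetic map; LOD
#' scores are exponential with configurable mean so that a known fraction
#' fails the LOD > 3 quality filter.
#'
#' @param samples Character vector of sample ids.
#' @param pop_labels Character vector of population labels, parallel to
#'   `samples`.
#' @param config A [sim_config()] (uses the `ibd_*` and `chrom_length_bp`
#'   fields and the seed).
#' @return A list with `segments` (tibble: sample_a, sample_b, chrom,
#'   start_bp, end_bp, start_cm, end_cm, lod) and `pair_truth` (tibble of
#'   per-pair total cM after the LOD > 3 filter).
#' @export
simulate_ibd_segments <- function(samples, pop_labels, config) {
  if (config$ibd_mean_length_cM <= 0) {
    stop("ibd_mean_length_cM must be positive", call. = FALSE)
  }
  stopifnot(length(samples) == length(pop_labels))
  n <- length(samples)
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  same <- pop_labels[pair_i] == pop_labels[pair_j]
  rates <- ifelse(same, config$ibd_rate_within, config$ibd_rate_between)
  map_cm_per_bp <- 1e-6 # uniform 1 cM/Mb
  chrom_cm <- config$chrom_length_bp * map_cm_per_bp

  with_seed(derive_seed(config$seed, "ibd"), {
    counts <- rpois(length(rates), rates)
    total <- sum(counts)
    if (total == 0) {
      seg <- tibble::tibble(
        sample_a = character(0), sample_b = character(0),
        chrom = character(0), start_bp = numeric(0), end_bp = numeric(0),
        start_cm = numeric(0), end_cm = numeric(0), lod = numeric(0)
      )
    } else {
      idx <- rep(seq_along(counts), counts)
      len_cm <- rexp(total, rate = 1 / config$ibd_mean_length_cM)
      len_cm <- pmin(len_cm, chrom_cm * 0.9)
      start_cm <- runif(total, 0, chrom_cm - len_cm)
      lod <- rexp(total, rate = 1 / config$ibd_lod_mean)
      seg <- tibble::tibble(
        sample_a = samples[pair_i[idx]],
        sample_b = samples[pair_j[idx]],
        chrom = "1",
        start_bp = round(start_cm / map_cm_per_bp) + 1,
        end_bp = round((start_cm + len_cm) / map_cm_per_bp),
        start_cm = start_cm,
        end_cm = start_cm + len_cm,
        lod = lod
      )
    }
    kept <- seg[seg$lod > 3, ]
    key <- paste(seg$sample_a, seg$sample_b, sep = "|")
    all_keys <- paste(samples[pair_i], samples[pair_j], sep = "|")
    totals <- setNames(numeric(length(all_keys)), all_keys)
    if (nrow(kept)) {
      agg <- tapply(kept$end_cm - kept$start_cm,
        paste(kept$sample_a, kept$sample_b, sep = "|"), sum)
      totals[names(agg)] <- agg
    }
    pair_truth <- tibble::tibble(
      sample_a = samples[pair_i], sample_b = samples[pair_j],
      total_cm = as.numeric(totals)
    )
    list(segments = seg, pair_truth = pair_truth)
  })
}

#' Simulate phenotypes with planted genetic effects
#'
#' Quantitative traits are linear in the planted causal dosages plus small
#' age/sex covariate effects, with Gaussian noise scaled so the genetic
#' variance fraction matches the target heritability. Binary traits use a
#' logistic liability whose intercept is solved numerically to hit the target
#' prevalence.
#'
#' @param genotypes A [geno_matrix()].
#' @param pheno_specs List of phenotype definitions (see [sim_config()]).
#' @param seed Integer seed.
#' @return A tibble: `sample_id`, `sex` (0/1), `age`, then one column per
#'   phenotype, plus attribute `planted_effects` (tibble phenotype/variant_id/
#'   beta).
#' @export
simulate_phenotypes <- function(genotypes, pheno_specs, seed = 1L) {
  n <- nrow(genotypes$dosage)
  covars <- with_seed(derive_seed(seed, "covariates"), {
    tibble::tibble(
      sample_id = rownames(genotypes$dosage),
      sex = rbinom(n, 1, 0.5),
      age = round(rnorm(n, 55, 9))
    )
  })
  covars$age[covars$age < 20] <- 20
  out <- covars
  planted <- list()
  with_seed(derive_seed(seed, "phenotypes"), {
    for (spec in pheno_specs) {
      causal <- spec$causal %||% integer(0)
      if (length(causal) && max(causal) > ncol(genotypes$dosage)) {
        stop("causal variant index outside the genotype matrix", call. = FALSE)
      }
      betas <- spec$beta %||% numeric(0)
      g <- genotypes$dosage[, causal, drop = FALSE]
      g[is.na(g)] <- 0
      genetic <- if (length(causal)) drop(g %*% betas) else numeric(n)
      cov_eff <- 0.01 * (covars$age - mean(covars$age)) + 0.1 * covars$sex
      if (identical(spec$type, "quantitative")) {
        h2 <- spec$h2 %||% 0.2
        if (h2 < 0 || h2 >= 1) {
          stop("heritability must lie in [0, 1)", call. = FALSE)
        }
        vg <- var(genetic)
        noise_sd <- if (h2 > 0 && vg > 0) sqrt(vg * (1 - h2) / h2) else 1
        out[[spec$name]] <- genetic + cov_eff + rnorm(n, 0, noise_sd)
      } else if (identical(spec$type, "binary")) {
        prev <- spec$prevalence %||% 0.2
        if (prev <= 0 || prev >= 1) {
          stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
        }
        eta0 <- genetic + cov_eff
        icpt <- uniroot(
          function(c) mean(plogis(c + eta0)) - prev,
          lower = -30, upper = 30
        )$root
        out[[spec$name]] <- rbinom(n, 1, plogis(icpt + eta0))
      } else {
        stop("phenotype type must be 'quantitative' or 'binary'", call. = FALSE)
      }
      if (length(causal)) {
        planted[[spec$name]] <- tibble::tibble(
          phenotype = spec$name,
          variant_id = colnames(genotypes$dosage)[causal],
          beta = betas
        )
      }
    }
  })
  attr(out, "planted_effects") <- dplyr::bind_rows(planted)
  out
}
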