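#' Select potentially replicable enriched variants
#'
#' From the Finnish-enriched-style candidates, keeps those common enough to
#' test locally (local MAF strictly above `maf_min`) and not better explained
#' by East-Asian ancestry: the log2 EAS/NFE ratio must be strictly below
#' `eas_nfe_ratio_max`. Variants unobserved in EAS carry the sentinel ratio
#' and therefore always pass the ratio condition.
#'
#' @param af_table Allele-frequency tibble with columns for the enrichment
#'   populations, the local population and EAS (see
#'   [enrichment_records()] for naming).
#' @param local_pop Label of the local cohort AF column.
#' @param num_pop,den_pop,ratio_min,af_band Passed to
#'   [classify_finnish_enriched()].
#' @param eas_pop Label of the East-Asian AF column.
#' @param maf_min Strict local MAF bound.
#' @param eas_nfe_ratio_max Strict upper bound on the log2 EAS/NFE ratio.
#' @param sentinel Sentinel for unobserved numerators.
#' @return Character vector of candidate `variant_id`s.
#' @export
select_replicable <- function(af_table, local_pop = "RUS",
                              num_pop = "FIN", den_pop = "NFE",
                              eas_pop = "EAS",
                              ratio_min = 2, af_band = c(0.01, 0.1),
                              maf_min = 0.01, eas_nfe_ratio_max = 2,
                              sentinel = -5) {
  af_table <- tibble::as_tibble(af_table)
  if (!"variant_id" %in% names(af_table)) {
    af_table$variant_id <- variant_key(
      af_table$chrom, af_table$pos, af_table$ref, af_table$alt
    )
  }
  enriched <- classify_finnish_enriched(
    af_table, num_pop, den_pop,
    ratio_min = ratio_min, af_band = af_band, sentinel = sentinel
  )
  eas_rec <- enrichment_records(af_table, eas_pop, den_pop, sentinel)
  local_af <- setNames(
    af_table[[af_column(af_table, local_pop)]],
    af_table$variant_id
  )
  local_maf <- pmin(local_af, 1 - local_af)
  eas_ratio <- setNames(eas_rec$log2_ratio, eas_rec$variant_id)
  keep <- enriched[
    local_maf[enriched] > maf_min &
      !is.na(eas_ratio[enriched]) &
      eas_ratio[enriched] < eas_nfe_ratio_max
  ]
  unname(keep[!is.na(keep)])
}

#' Match candidates against an external association catalogue
#'
#' @param candidates Character vector of candidate `variant_id`s.
#' @param external Tibble: `variant_id`, `phenotype`, `p`, `beta`, optional
#'   `cohort`.
#' @param p_gw Genome-wide significance threshold (strict `p <`).
#' @return Tibble of matched variant-phenotype pairs with attribute
#'   `match_counts` (n_variants, n_traits, n_pairs).
#' @export
match_external_hits <- function(candidates, external, p_gw = 5e-8) {
  external <- tibble::as_tibble(external)
  hits <- external[external$p < p_gw & external$variant_id %in% candidates, ]
  attr(hits, "match_counts") <- tibble::tibble(
    n_variants = length(unique(hits$variant_id)),
    n_traits = length(unique(hits$phenotype)),
    n_pairs = nrow(hits)
  )
  hits
}

#' Greedy LD clumping
#'
#' Sorts variants by ascending p (ties broken by genomic position), keeps the
#' best, discards every remaining variant correlated at `r2 >= r2_max` with a
#' kept one, and repeats. Variants absent from the genotype matrix are
#' excluded with a warning.
#'
#' @param stats Tibble: `variant_id`, `p` (and optionally `pos` for
#'   tie-breaks).
#' @param genotypes A [geno_matrix()] providing dosages for the r2
#'   computation.
#' @param r2_max Squared-correlation threshold.
#' @return Character vector of retained (index) `variant_id`s, best first.
#' @export
ld_clump <- function(stats, genotypes, r2_max = 0.1) {
  stats <- tibble::as_tibble(stats)
  present <- stats$variant_id %in% colnames(genotypes$dosage)
  if (any(!present)) {
    warning(sum(!present), " variant(s) absent from the genotype matrix ",
      "excluded from clumping",
      call. = FALSE
    )
    stats <- stats[present, ]
  }
  if (nrow(stats) == 0) {
    return(character(0))
  }
  if (!"pos" %in% names(stats)) {
    stats$pos <- match(stats$variant_id, colnames(genotypes$dosage))
  }
  stats <- stats[order(stats$p, stats$pos), ]
  d <- genotypes$dosage[, stats$variant_id, drop = FALSE]
  kept <- character(0)
  remaining <- stats$variant_id
  while (length(remaining)) {
    best <- remaining[1]
    kept <- c(kept, best)
    if (length(remaining) == 1) break
    r2 <- suppressWarnings(
      cor(d[, best], d[, remaining[-1], drop = FALSE],
        use = "pairwise.complete.obs"
      )
    )^2
    r2[is.na(r2)] <- 0
    remaining <- remaining[-1][r2 < r2_max]
  }
  kept
}

#' Bonferroni replication threshold
#'
#' `alpha / (n_variants * n_groups)` — the significance level divided by the
#' number of independent variants tested times the number of phenotype
#' groups.
#'
#' @param alpha Family-wise error target.
#' @param n_variants,n_groups Positive integers.
#' @return The threshold as a double.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 11, 8) # ~5.7e-4
bonferroni_threshold <- function(alpha = 0.05, n_variants = 1, n_groups = 1) {
  if (n_variants < 1 || n_groups < 1) {
    stop("n_variants and n_groups must be >= 1", call. = FALSE)
  }
  alpha / (as.double(n_variants) * as.double(n_groups))
}

#' Run the full replication procedure
#'
#' Per phenotype group: clump the matched variants with local LD
#' (independently per group), then compare each independent variant's best
#' local p-value (minimum over the group's local phenotypes) against the
#' Bonferroni threshold `alpha / (n independent variants x n groups)`.
#' All tiers (candidates, matched pairs, clumped variants, replicated hits)
#' are reported.
#'
#' @param local_results A `gwas_result` tibble (local cohort summary
#'   statistics).
#' @param matched_pairs Tibble from [match_external_hits()].
#' @param phenotype_groups Tibble `phenotype`, `group` mapping external
#'   phenotypes to groups; unmapped phenotypes fall into "ungrouped" with a
#'   warning.
#' @param genotypes A [geno_matrix()] for clumping LD.
#' @param candidates Character vector from [select_replicable()].
#' @param local_pheno_map Optional tibble `group`, `phenotype` naming which
#'   local phenotypes represent each group; defaults to all local
#'   phenotypes for every group (cross-phenotype matching within group is
#'   permitted and flagged in the output).
#' @param alpha Family-wise error target.
#' @param r2_max Clumping threshold.
#' @return Object of class `replication_report`.
#' @export
replicate_candidates <- function(local_results, matched_pairs,
                                 phenotype_groups, genotypes, candidates,
                                 local_pheno_map = NULL, alpha = 0.05,
                                 r2_max = 0.1) {
  matched_pairs <- tibble::as_tibble(matched_pairs)
  grouped <- dplyr::left_join(matched_pairs, phenotype_groups,
    by = "phenotype"
  )
  if (anyNA(grouped$group)) {
    warning(sum(is.na(grouped$group)),
      " external phenotype(s) missing from the grouping map; ",
      "assigned to 'ungrouped'",
      call. = FALSE
    )
    grouped$group[is.na(grouped$group)] <- "ungrouped"
  }
  groups <- sort(unique(grouped$group))
  pos_lookup <- setNames(
    seq_len(ncol(genotypes$dosage)),
    colnames(genotypes$dosage)
  )
  clumped <- purrr::map(setNames(groups, groups), function(g) {
    vids <- unique(grouped$variant_id[grouped$group == g])
    st <- tibble::tibble(
      variant_id = vids,
      p = vapply(vids, function(v) {
        min(grouped$p[grouped$group == g & grouped$variant_id == v])
      }, numeric(1)),
      pos = pos_lookup[vids]
    )
    ld_clump(st, genotypes, r2_max)
  })
  n_independent <- sum(lengths(clumped))
  threshold <- if (n_independent > 0) {
    bonferroni_threshold(alpha, n_independent, length(groups))
  } else {
    alpha
  }

  local_results <- tibble::as_tibble(local_results)
  replicated <- purrr::imap_dfr(clumped, function(vids, g) {
    local_ph <- if (is.null(local_pheno_map)) {
      unique(local_results$phenotype)
    } else {
      local_pheno_map$phenotype[local_pheno_map$group == g]
    }
    purrr::map_dfr(vids, function(v) {
      loc <- local_results[
        local_results$variant_id == v &
          local_results$phenotype %in% local_ph & !is.na(local_results$p),
      ]
      if (nrow(loc) == 0) {
        return(NULL)
      }
      best <- loc[which.min(loc$p), ]
      tibble::tibble(
        group = g, variant_id = v,
        local_phenotype = best$phenotype,
        p = best$p, beta = best$beta,
        cross_phenotype = !best$phenotype %in%
          grouped$phenotype[grouped$variant_id == v]
      )
    })
  })
  replicated <- replicated[!is.na(replicated$p) & replicated$p < threshold, ]

  structure(
    list(
      candidates = candidates,
      matched_pairs = grouped,
      clumped = clumped,
      n_independent = n_independent,
      n_groups = length(groups),
      threshold = threshold,
      replicated = replicated
    ),
    class = "replication_report"
  )
}

#' @export
print.replication_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<replication_report> %d candidates -> %d matched pairs -> ",
      "%d independent variants in %d groups; threshold %.3g; %d replicated\n"
    ),
    length(x$candidates), nrow(x$matched_pairs), x$n_independent,
    x$n_groups, x$threshold, nrow(x$replicated)
  ))
  invisible(x)
}

#' @rdname replicate_candidates
#' @param x,object A `replication_report`.
#' @param ... Unused.
#' @export
tidy.replication_report <- function(x, ...) {
  x$replicated
}

#' @rdname replicate_candidates
#' @export
glance.replication_report <- function(object, ...) {
  tibble::tibble(
    n_candidates = length(object$candidates),
    n_matched_pairs = nrow(object$matched_pairs),
    n_matched_variants = length(unique(object$matched_pairs$variant_id)),
    n_independent = object$n_independent,
    n_groups = object$n_groups,
    threshold = object$threshold,
    n_replicated = nrow(object$replicated)
  )
}
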