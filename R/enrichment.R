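#' Log2 allele-frequency ratio with an unobserved-variant sentinel
#'
#' The enrichment statistic for a variant between two populations is
#' `log2(AF_num / AF_den)`. Variants unobserved in the numerator population
#' (AF = 0) receive a fixed sentinel, conventionally -5, marking them as the
#' global minimum of the distribution. Variants with denominator AF = 0 are
#' undefined and must be excluded by the caller.
#'
#' @param af_num,af_den Allele frequencies in [0, 1] (vectorized).
#' @param sentinel Value returned where `af_num` is 0.
#' @return Numeric vector of log2 ratios (or the sentinel).
#' @export
#' @examples
#' log2_af_ratio(0.08, 0.01) # 3
#' log2_af_ratio(0, 0.01) # -5 sentinel
log2_af_ratio <- function(af_num, af_den, sentinel = -5) {
  assert_prob(af_num, "af_num")
  assert_prob(af_den, "af_den")
  if (any(af_den == 0)) {
    stop("af_den contains zeros: variants unobserved in the denominator ",
      "population must be excluded before scoring",
      call. = FALSE
    )
  }
  ifelse(af_num > 0, log2(af_num / af_den), sentinel)
}

af_column <- function(table, pop) {
  for (cand in c(pop, paste0("AF_", pop))) {
    if (cand %in% names(table)) {
      return(cand)
    }
  }
  stop(sprintf("allele-frequency column for population '%s' not found", pop),
    call. = FALSE
  )
}

qc_pass <- function(table, call_rate_min = 0.97) {
  pass <- rep(TRUE, nrow(table))
  if ("filter_pass" %in% names(table)) pass <- pass & table$filter_pass
  if ("call_rate" %in% names(table)) {
    pass <- pass & table$call_rate >= call_rate_min
  }
  pass
}

#' Score enrichment of one population against another
#'
#' Builds one record per variant carrying the log2 AF ratio of `num_pop` over
#' `den_pop`, the observed flag (numerator AF > 0), and nothing else.
#' Variants with denominator AF of zero are dropped with a diagnostic
#' message, and optional QC columns (`filter_pass`, `call_rate` >= 0.97)
#' gate the input when present.
#'
#' @param table Allele-frequency tibble: `chrom`, `pos`, `ref`, `alt` (or a
#'   `variant_id`) plus one AF column per population (named either by the
#'   population label or `AF_<label>`).
#' @param num_pop,den_pop Population labels.
#' @param sentinel Sentinel for numerator AF = 0.
#' @return Tibble with `variant_id`, `af_num`, `af_den`, `log2_ratio`,
#'   `observed`.
#' @export
enrichment_records <- function(table, num_pop, den_pop, sentinel = -5) {
  table <- dplyr::distinct(tibble::as_tibble(table))
  if (!"variant_id" %in% names(table)) {
    table$variant_id <- variant_key(table$chrom, table$pos, table$ref, table$alt)
  }
  table <- table[qc_pass(table), ]
  num <- table[[af_column(table, num_pop)]]
  den <- table[[af_column(table, den_pop)]]
  excluded <- den == 0 | is.na(den) | is.na(num)
  if (any(excluded)) {
    message(sum(excluded), " variant(s) excluded: AF missing or zero in ", den_pop)
  }
  table <- table[!excluded, ]
  num <- num[!excluded]
  den <- den[!excluded]
  tibble::tibble(
    variant_id = table$variant_id,
    af_num = num,
    af_den = den,
    log2_ratio = log2_af_ratio(num, den, sentinel),
    observed = num > 0
  )
}

#' Classify Finnish-enriched-style variants
#'
#' A variant is called enriched when its log2 AF ratio between the numerator
#' and denominator populations strictly exceeds `ratio_min` AND its numerator
#' AF lies inside the closed band `af_band`. The band captures
#' bottleneck-elevated variants that are rare elsewhere but common enough to
#' test; both rules are configurable.
#'
#' @inheritParams enrichment_records
#' @param ratio_min Strict lower bound on the log2 ratio.
#' @param af_band Closed interval for the numerator AF; `NULL` disables the
#'   band (see [classify_population_enriched()]).
#' @return Character vector of enriched `variant_id`s.
#' @export
classify_finnish_enriched <- function(table, num_pop = "FIN", den_pop = "NFE",
                                      ratio_min = 2, af_band = c(0.01, 0.1),
                                      sentinel = -5) {
  rec <- enrichment_records(table, num_pop, den_pop, sentinel)
  keep <- rec$log2_ratio > ratio_min
  if (!is.null(af_band)) {
    keep <- keep & rec$af_num >= af_band[1] & rec$af_num <= af_band[2]
  }
  rec$variant_id[keep]
}

#' Classify population-enriched variants (no AF band)
#'
#' Same strict log2-ratio rule as [classify_finnish_enriched()] but without
#' the numerator AF band; the form used to call variants enriched in the
#' study cohort relative to a reference population.
#'
#' @inheritParams classify_finnish_enriched
#' @return Character vector of enriched `variant_id`s.
#' @export
classify_population_enriched <- function(table, num_pop = "RUS",
                                         den_pop = "NFE", ratio_min = 2,
                                         sentinel = -5) {
  classify_finnish_enriched(table, num_pop, den_pop,
    ratio_min = ratio_min,
    af_band = NULL, sentinel = sentinel
  )
}

#' Summarize an enrichment distribution
#'
#' @param records Tibble from [enrichment_records()] (needs `log2_ratio` and
#'   `observed`).
#' @param ratio_min Threshold for the "above" fraction.
#' @return One-row tibble: `median_log2_ratio` (over observed records only;
#'   `NA` with a warning when none are observed), `fraction_observed` and
#'   `fraction_above` (both over all records), `n_records`, `n_observed`.
#' @export
enrichment_summary <- function(records, ratio_min = 2) {
  if (nrow(records) == 0) stop("no enrichment records supplied", call. = FALSE)
  obs <- records$log2_ratio[records$observed]
  med <- if (length(obs) == 0) {
    warning("no observed records: median undefined", call. = FALSE)
    NA_real_
  } else {
    median(obs)
  }
  tibble::tibble(
    median_log2_ratio = med,
    fraction_observed = mean(records$observed),
    fraction_above = mean(records$log2_ratio > ratio_min),
    n_records = nrow(records),
    n_observed = length(obs)
  )
}

#' Logistic regression of population membership on log2 allele frequency
#'
#' Tests whether a variant set is systematically more frequent in population
#' A than population B: each variant contributes two rows, (label 1,
#' log2 AF_A) and (label 0, log2 AF_B); rows with AF = 0 are dropped; the
#' label is regressed on log2(AF) by maximum likelihood. A positive slope
#' means the set is enriched in A.
#'
#' @param table Allele-frequency tibble (see [enrichment_records()]).
#' @param pop_a,pop_b Population labels (A is coded 1).
#' @param variant_set Optional character vector restricting to these
#'   `variant_id`s.
#' @return Object of class `enrichment_fit`; see [tidy.enrichment_fit()].
#' @export
enrichment_regression <- function(table, pop_a = "RUS", pop_b = "NFE",
                                  variant_set = NULL) {
  table <- tibble::as_tibble(table)
  if (!"variant_id" %in% names(table)) {
    table$variant_id <- variant_key(table$chrom, table$pos, table$ref, table$alt)
  }
  if (!is.null(variant_set)) {
    table <- table[table$variant_id %in% variant_set, ]
  }
  af_a <- table[[af_column(table, pop_a)]]
  af_b <- table[[af_column(table, pop_b)]]
  rows <- tibble::tibble(
    label = c(rep(1L, nrow(table)), rep(0L, nrow(table))),
    af = c(af_a, af_b)
  )
  rows <- rows[!is.na(rows$af) & rows$af > 0, ]
  if (nrow(rows) < 10) {
    stop("fewer than 10 usable rows for the enrichment regression",
      call. = FALSE
    )
  }
  rows$log2_af <- log2(rows$af)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(label ~ log2_af, data = rows, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    warning("possible complete separation in the enrichment regression",
      call. = FALSE
    )
  }
  structure(
    list(
      fit = fit, n_rows = nrow(rows), separation = separation,
      pop_a = pop_a, pop_b = pop_b
    ),
    class = "enrichment_fit"
  )
}

#' @export
print.enrichment_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  cat(sprintf(
    "<enrichment_fit> %s(1)/%s(0) ~ log2(AF): beta = %.4g, se = %.3g, p = %.3g (n = %d%s)\n",
    x$pop_a, x$pop_b, s["log2_af", 1], s["log2_af", 2], s["log2_af", 4],
    x$n_rows, if (x$separation) ", separation!" else ""
  ))
  invisible(x)
}

#' @rdname enrichment_regression
#' @param x,object An `enrichment_fit`.
#' @param ... Unused.
#' @export
tidy.enrichment_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' @rdname enrichment_regression
#' @export
glance.enrichment_fit <- function(object, ...) {
  tibble::tibble(
    n_rows = object$n_rows,
    separation = object$separation,
    converged = object$fit$converged,
    deviance = object$fit$deviance,
    null.deviance = object$fit$null.deviance
  )
}
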