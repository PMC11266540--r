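#' Inverse rank-normal transform
#'
#' Ranks (ties averaged) mapped to standard-normal quantiles via
#' `qnorm((rank - 0.5) / n)`; missing values are preserved. A constant
#' vector collapses to all-zero scores with a warning.
#'
#' @param values Numeric vector.
#' @return Numeric vector of normal scores, same length and missingness.
#' @export
#' @examples
#' irnt(c(3, 1, 2))
irnt <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stop("need at least two non-missing values", call. = FALSE)
  x <- values[ok]
  if (length(unique(x)) == 1) {
    warning("constant input: all normal scores are 0", call. = FALSE)
  }
  r <- rank(x, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - 0.5) / length(x))
  out
}

#' Phenotype quality control
#'
#' Drops phenotypes observed in `min_n` or fewer individuals (strict "more
#' than" rule). For quantitative phenotypes flagged for trimming, values
#' strictly below the lower or strictly above the upper empirical quantile
#' (type-7) are set to missing — a guard against lab-measurement artifacts.
#' Every quantitative phenotype also gains an untrimmed inverse rank-normal
#' version named `<name>_irnt`, computed from the original (pre-trim)
#' values: the rank transform already neutralizes outliers, so trimming it
#' would discard information twice.
#'
#' @param table Phenotype tibble: `sample_id`, covariates, one column per
#'   phenotype.
#' @param pheno_specs Tibble with columns `name`, `type` ("quantitative" or
#'   "binary") and optional logical `trim`.
#' @param min_n Strict minimum number of non-missing observations.
#' @param trim_quantiles Lower/upper trim quantiles.
#' @return The QC'd tibble; attribute `pheno_log` records per-phenotype
#'   decisions.
#' @export
phenotype_qc <- function(table, pheno_specs, min_n = 200,
                         trim_quantiles = c(0.05, 0.95)) {
  table <- tibble::as_tibble(table)
  log <- list()
  for (i in seq_len(nrow(pheno_specs))) {
    nm <- pheno_specs$name[i]
    type <- pheno_specs$type[i]
    trim <- isTRUE(pheno_specs$trim[i])
    vals <- table[[nm]]
    n_obs <- sum(!is.na(vals))
    if (n_obs <= min_n) {
      table[[nm]] <- NULL
      log[[nm]] <- tibble::tibble(
        name = nm, kept = FALSE, n_obs = n_obs,
        reason = "n <= min_n"
      )
      next
    }
    if (type == "quantitative") {
      table[[paste0(nm, "_irnt")]] <- irnt(vals)
      if (trim) {
        q <- quantile(vals, trim_quantiles, na.rm = TRUE, type = 7)
        drop <- !is.na(vals) & (vals < q[1] | vals > q[2])
        vals[drop] <- NA_real_
        table[[nm]] <- vals
      }
    }
    log[[nm]] <- tibble::tibble(
      name = nm, kept = TRUE, n_obs = n_obs, reason = ""
    )
  }
  attr(table, "pheno_log") <- dplyr::bind_rows(log)
  table
}

check_design <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; offending column(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(qrX)
}

#' Linear association of a phenotype with one variant
#'
#' Ordinary least squares of the phenotype on dosage plus covariates and an
#' intercept, listwise-deleting samples with any missing value. The reported
#' effect is the dosage coefficient with its Wald t-test p-value.
#'
#' @param dosage Numeric dosage vector.
#' @param phenotype Numeric phenotype vector.
#' @param covariates Data frame / tibble of covariates (may be NULL).
#' @return One-row tibble: `beta`, `se`, `p`, `n_used`, `af`.
#' @export
linear_assoc <- function(dosage, phenotype, covariates = NULL) {
  cov_m <- if (is.null(covariates)) {
    matrix(nrow = length(dosage), ncol = 0)
  } else {
    as.matrix(covariates)
  }
  ok <- !is.na(dosage) & !is.na(phenotype) & complete.cases(cov_m)
  X <- cbind(intercept = 1, dosage = dosage, cov_m)[ok, , drop = FALSE]
  y <- phenotype[ok]
  if (nrow(X) < ncol(X) + 2) {
    stop("too few complete observations for the model", call. = FALSE)
  }
  if (sd(X[, "dosage"]) == 0) {
    stop("rank-deficient design; offending column(s): dosage", call. = FALSE)
  }
  check_design(X)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- nrow(X) - ncol(X)
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- fit$coefficients[["dosage"]]
  tibble::tibble(
    beta = beta, se = se,
    p = 2 * pt(abs(beta / se), df, lower.tail = FALSE),
    n_used = nrow(X), af = mean(X[, "dosage"]) / 2
  )
}

#' Logistic association of a binary phenotype with one variant
#'
#' Maximum-likelihood logistic regression (IRLS as implemented by
#' [stats::glm()], tolerance 1e-8, up to 50 iterations) of case status on
#' dosage plus covariates. Non-convergence or separation yields a flagged
#' row with missing `se`/`p` rather than an error.
#'
#' @param dosage Numeric dosage vector.
#' @param phenotype01 Binary 0/1 phenotype vector.
#' @param covariates Data frame / tibble of covariates (may be NULL).
#' @return One-row tibble: `beta`, `se`, `p`, `n_used`, `af`, `af_cases`,
#'   `af_controls`, `converged`.
#' @export
logistic_assoc <- function(dosage, phenotype01, covariates = NULL) {
  cov_m <- if (is.null(covariates)) {
    matrix(nrow = length(dosage), ncol = 0)
  } else {
    as.matrix(covariates)
  }
  ok <- !is.na(dosage) & !is.na(phenotype01) & complete.cases(cov_m)
  y <- phenotype01[ok]
  if (length(unique(y)) < 2) {
    stop("both classes must be present after listwise deletion", call. = FALSE)
  }
  dat <- data.frame(y = y, dosage = dosage[ok])
  if (ncol(cov_m)) dat <- cbind(dat, as.data.frame(cov_m[ok, , drop = FALSE]))
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial(),
      control = list(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
        conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  converged <- fit$converged && !separation
  s <- summary(fit)$coefficients
  tibble::tibble(
    beta = s["dosage", 1],
    se = if (converged) s["dosage", 2] else NA_real_,
    p = if (converged) s["dosage", 4] else NA_real_,
    n_used = length(y),
    af = mean(dat$dosage) / 2,
    af_cases = mean(dat$dosage[y == 1]) / 2,
    af_controls = mean(dat$dosage[y == 0]) / 2,
    converged = converged
  )
}

#' Covariate-adjusted genome-wide association scan
#'
#' For each phenotype: restrict to its analysis subsample (non-missing
#' phenotype and covariates), re-apply variant QC (MAF and HWE, strict) on
#' that subsample, then test every surviving variant — linear models for
#' quantitative/categorical phenotypes, logistic for binary — adjusted for
#' the phenotype's covariate set. Per-variant failures are recorded and the
#' scan continues.
#'
#' @param genotypes A [geno_matrix()].
#' @param phenotypes Phenotype tibble (`sample_id`, covariates, phenotype
#'   columns), e.g. from [phenotype_qc()] joined with PC scores.
#' @param pheno_specs Tibble `name`, `type`; only listed phenotypes present
#'   in `phenotypes` are scanned.
#' @param covariates Default covariate column names (e.g.
#'   `c("sex", "age", "PC1", "PC2", "PC3", "PC4")`).
#' @param covariate_overrides Named list phenotype -> covariate columns, for
#'   phenotypes needing extra adjustment (e.g. treatment history).
#' @param maf_min,hwe_min Per-phenotype variant QC thresholds (strict).
#' @return Tibble of class `gwas_result`: `phenotype`, `variant_id`,
#'   `chrom`, `pos`, `beta`, `se`, `p`, `n_used`, `af` (+ case/control AFs
#'   for binary phenotypes).
#' @export
run_gwas <- function(genotypes, phenotypes, pheno_specs,
                     covariates = c("sex", "age"),
                     covariate_overrides = list(),
                     maf_min = 0.01, hwe_min = 1e-4) {
  phenotypes <- tibble::as_tibble(phenotypes)
  res <- list()
  for (i in seq_len(nrow(pheno_specs))) {
    nm <- pheno_specs$name[i]
    if (!nm %in% names(phenotypes)) next
    type <- pheno_specs$type[i]
    covs <- covariate_overrides[[nm]] %||% covariates
    missing_covs <- setdiff(covs, names(phenotypes))
    if (length(missing_covs)) {
      stop("covariate column(s) not found: ",
        paste(missing_covs, collapse = ", "),
        call. = FALSE
      )
    }
    idx <- match(rownames(genotypes$dosage), phenotypes$sample_id)
    ph <- phenotypes[idx, , drop = FALSE]
    usable <- !is.na(ph[[nm]]) & complete.cases(ph[, covs, drop = FALSE])
    if (!any(usable)) next
    sub <- subset_geno(genotypes, samples = which(usable))
    sub_qc <- variant_qc(sub, maf_min = maf_min, hwe_min = hwe_min)
    cov_df <- ph[usable, covs, drop = FALSE]
    y <- ph[[nm]][usable]
    vres <- purrr::map(colnames(sub_qc$dosage), function(vid) {
      g <- sub_qc$dosage[, vid]
      out <- tryCatch(
        if (type == "binary") {
          logistic_assoc(g, y, cov_df)
        } else {
          linear_assoc(g, y, cov_df)
        },
        error = function(e) NULL
      )
      if (!is.null(out)) out$variant_id <- vid
      out
    })
    tab <- dplyr::bind_rows(vres)
    if (nrow(tab)) {
      tab$phenotype <- nm
      tab <- dplyr::left_join(
        tab,
        genotypes$variants[, intersect(
          c("variant_id", "chrom", "pos", "ref", "alt"),
          names(genotypes$variants)
        )],
        by = "variant_id"
      )
      res[[nm]] <- tab
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out)) {
    out <- dplyr::relocate(out, "phenotype", "variant_id")
  }
  class(out) <- c("gwas_result", class(out))
  out
}

#' @rdname run_gwas
#' @param object A `gwas_result`.
#' @param ... Unused.
#' @export
glance.gwas_result <- function(object, ...) {
  object |>
    dplyr::group_by(.data$phenotype) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      min_p = min(.data$p, na.rm = TRUE),
      lambda_gc = median(qnorm(.data$p / 2)^2, na.rm = TRUE) / 0.4549364,
      .groups = "drop"
    )
}
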