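#' Filter IBD segments by LOD score
#'
#' Keeps segments whose LOD score strictly exceeds `lod_min` (the usual
#' quality filter LOD > 3); a segment at exactly the threshold is dropped.
#'
#' @param segments Tibble of IBD segments: `sample_a`, `sample_b`, `chrom`,
#'   `start_bp`, `end_bp`, `start_cm`, `end_cm`, `lod`.
#' @param lod_min Strict lower bound.
#' @return The filtered tibble, pairs canonicalized so `sample_a < sample_b`.
#' @export
filter_segments <- function(segments, lod_min = 3) {
  segments <- tibble::as_tibble(segments)
  if (nrow(segments) == 0) {
    return(segments)
  }
  p <- canonical_pair(segments$sample_a, segments$sample_b)
  segments$sample_a <- p$a
  segments$sample_b <- p$b
  segments[segments$lod > lod_min, ]
}

#' Count discordant homozygotes between two samples in an interval
#'
#' A discordant homozygote is a variant where one sample carries dosage 0 and
#' the other dosage 2 — impossible on a truly shared haplotype, so these
#' veto merging of adjacent IBD segments. Missing genotypes are ignored, and
#' when the variant metadata has a `genotyped` flag only directly genotyped
#' variants are counted (imputed calls would inflate discordance).
#'
#' @param genotypes A [geno_matrix()].
#' @param pair Character vector of two sample ids.
#' @param chromosome Chromosome label.
#' @param bp_interval Numeric length-2 open interval; variants with
#'   `bp_interval[1] < pos < bp_interval[2]` are examined.
#' @return Integer count.
#' @export
count_discordant_homozygotes <- function(genotypes, pair, chromosome,
                                         bp_interval) {
  stopifnot(inherits(genotypes, "geno_matrix"), length(pair) == 2)
  idx <- match(pair, rownames(genotypes$dosage))
  if (anyNA(idx)) {
    stop("sample(s) not present in the genotype matrix: ",
      paste(pair[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  v <- genotypes$variants
  in_gap <- v$chrom == chromosome &
    v$pos > bp_interval[1] & v$pos < bp_interval[2]
  if ("genotyped" %in% names(v)) in_gap <- in_gap & v$genotyped
  g1 <- genotypes$dosage[idx[1], in_gap]
  g2 <- genotypes$dosage[idx[2], in_gap]
  sum((g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0), na.rm = TRUE)
}

merge_pair_chrom <- function(seg, genotypes, gap_max_cm, max_discordant) {
  seg <- seg[order(seg$start_cm, seg$end_cm), ]
  if (nrow(seg) <= 1) {
    return(seg)
  }
  out <- seg[1, ]
  for (i in 2:nrow(seg)) {
    cur <- out[nrow(out), ]
    nxt <- seg[i, ]
    gap_cm <- nxt$start_cm - cur$end_cm
    if (gap_cm < 0) {
      warning("overlapping segments for pair ", cur$sample_a, "/",
        cur$sample_b, " on chromosome ", cur$chrom,
        "; merged unconditionally",
        call. = FALSE
      )
      mergeable <- TRUE
    } else if (gap_cm <= gap_max_cm) {
      n_disc <- if (is.null(genotypes)) {
        0L
      } else {
        count_discordant_homozygotes(
          genotypes, c(cur$sample_a, cur$sample_b), cur$chrom,
          c(cur$end_bp, nxt$start_bp)
        )
      }
      mergeable <- n_disc <= max_discordant
    } else {
      mergeable <- FALSE
    }
    if (mergeable) {
      out$start_bp[nrow(out)] <- min(cur$start_bp, nxt$start_bp)
      out$end_bp[nrow(out)] <- max(cur$end_bp, nxt$end_bp)
      out$start_cm[nrow(out)] <- min(cur$start_cm, nxt$start_cm)
      out$end_cm[nrow(out)] <- max(cur$end_cm, nxt$end_cm)
      out$lod[nrow(out)] <- max(cur$lod, nxt$lod)
    } else {
      out <- dplyr::bind_rows(out, nxt)
    }
  }
  out
}

#' Merge adjacent IBD segments across small gaps
#'
#' Within each (sample pair, chromosome), segments are sorted by start and
#' merged greedily left-to-right when the genetic gap is at most
#' `gap_max_cm` (inclusive) AND the gap's physical interval contains at most
#' `max_discordant` discordant homozygous variants. A merged segment keeps
#' absorbing subsequent segments while the rule holds; its interval spans the
#' union in both bp and cM, and its LOD is the maximum of the parts.
#' Merging is idempotent and independent of input row order.
#'
#' @param segments LOD-filtered segment tibble (see [filter_segments()]).
#' @param genotypes A [geno_matrix()] used for the discordance veto, or
#'   `NULL` to skip the genotype check (gaps then merge on distance alone).
#' @param gap_max_cm Inclusive maximum genetic gap (cM) bridged by a merge.
#' @param max_discordant Inclusive maximum discordant homozygotes tolerated
#'   in the gap.
#' @return Tibble of merged segments.
#' @export
merge_segments <- function(segments, genotypes = NULL, gap_max_cm = 0.6,
                           max_discordant = 1) {
  segments <- tibble::as_tibble(segments)
  if (nrow(segments) == 0) {
    return(segments)
  }
  p <- canonical_pair(segments$sample_a, segments$sample_b)
  segments$sample_a <- p$a
  segments$sample_b <- p$b
  segments |>
    dplyr::group_by(.data$sample_a, .data$sample_b, .data$chrom) |>
    dplyr::group_modify(~ merge_pair_chrom(
      .x |>
        dplyr::mutate(
          sample_a = .y$sample_a, sample_b = .y$sample_b, chrom = .y$chrom
        ),
      genotypes, gap_max_cm, max_discordant
    ) |> dplyr::select(-"sample_a", -"sample_b", -"chrom")) |>
    dplyr::ungroup()
}

#' Total IBD sharing per sample pair
#'
#' Sums merged segment lengths (cM) per pair; pairs listed in `all_pairs`
#' that have no segments get total 0, so zero-sharing pairs stay visible to
#' the population medians.
#'
#' @param merged_segments Tibble from [merge_segments()].
#' @param all_pairs Optional tibble (`sample_a`, `sample_b`) enumerating
#'   every pair that should appear in the output.
#' @return Tibble: `sample_a`, `sample_b`, `total_cm`.
#' @export
pair_totals <- function(merged_segments, all_pairs = NULL) {
  merged_segments <- tibble::as_tibble(merged_segments)
  totals <- merged_segments |>
    dplyr::group_by(.data$sample_a, .data$sample_b) |>
    dplyr::summarise(
      total_cm = sum(.data$end_cm - .data$start_cm),
      .groups = "drop"
    )
  if (!is.null(all_pairs)) {
    p <- canonical_pair(all_pairs$sample_a, all_pairs$sample_b)
    all_pairs <- tibble::tibble(sample_a = p$a, sample_b = p$b)
    totals <- all_pairs |>
      dplyr::distinct() |>
      dplyr::left_join(totals, by = c("sample_a", "sample_b")) |>
      dplyr::mutate(total_cm = dplyr::coalesce(.data$total_cm, 0))
  }
  totals
}

all_sample_pairs <- function(samples) {
  n <- length(samples)
  if (n < 2) {
    return(tibble::tibble(sample_a = character(0), sample_b = character(0)))
  }
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  tibble::tibble(sample_a = samples[i], sample_b = samples[j])
}

#' Median pairwise IBD sharing between populations
#'
#' Entry (P, Q) is the median total sharing over all pairs with one member in
#' P and one in Q; the diagonal uses within-population pairs (self-pairs
#' excluded). Zero-sharing pairs count toward the median when present in the
#' input.
#'
#' @param totals Pair-total tibble from [pair_totals()].
#' @param pop_labels Tibble `sample_id`, `population` covering every sample
#'   appearing in `totals`.
#' @return Object of class `pop_sharing`: list with `labels`, `median_cm`
#'   and `n_pairs` matrices.
#' @export
population_median_matrix <- function(totals, pop_labels) {
  lab <- setNames(pop_labels$population, pop_labels$sample_id)
  if (anyNA(lab[totals$sample_a]) || anyNA(lab[totals$sample_b])) {
    stop("every sample in the totals must have a population label",
      call. = FALSE
    )
  }
  pops <- sort(unique(pop_labels$population))
  k <- length(pops)
  med <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  npair <- matrix(0L, k, k, dimnames = list(pops, pops))
  pa <- lab[totals$sample_a]
  pb <- lab[totals$sample_b]
  for (i in seq_len(k)) {
    for (j in i:k) {
      sel <- (pa == pops[i] & pb == pops[j]) | (pa == pops[j] & pb == pops[i])
      vals <- totals$total_cm[sel]
      npair[i, j] <- npair[j, i] <- length(vals)
      if (length(vals)) med[i, j] <- med[j, i] <- median(vals)
    }
  }
  structure(
    list(labels = pops, median_cm = med, n_pairs = npair),
    class = "pop_sharing"
  )
}

#' @export
print.pop_sharing <- function(x, ...) {
  cat("<pop_sharing> median pairwise IBD sharing (cM)\n")
  print(round(x$median_cm, 2))
  invisible(x)
}

#' @rdname population_median_matrix
#' @param x A `pop_sharing` object.
#' @param ... Unused.
#' @export
tidy.pop_sharing <- function(x, ...) {
  expand.grid(pop_a = x$labels, pop_b = x$labels,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::mutate(
      median_cm = as.vector(x$median_cm),
      n_pairs = as.vector(x$n_pairs)
    )
}

#' Hierarchical clustering of populations by IBD sharing
#'
#' Converts the sharing similarity into a distance
#' `d(P, Q) = max(median_cm) - median_cm(P, Q)` and runs agglomerative
#' clustering. Labels are processed in sorted order so ties resolve
#' deterministically.
#'
#' @param sharing A `pop_sharing` from [population_median_matrix()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List of class `pop_dendrogram`: `hclust`, `phylo` (an
#'   [ape::as.phylo()] tree) and `newick` string with branch lengths.
#' @export
cluster_populations <- function(sharing, linkage = "average") {
  m <- sharing$median_cm
  if (nrow(m) < 2) stop("need at least two populations", call. = FALSE)
  if (anyNA(m)) stop("sharing matrix has missing entries", call. = FALSE)
  ord <- order(rownames(m))
  m <- m[ord, ord]
  d <- max(m) - m
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = linkage)
  phy <- ape::as.phylo(hc)
  structure(
    list(
      hclust = hc, phylo = phy,
      newick = ape::write.tree(phy),
      linkage = linkage, transform = "max_entry - median_cm"
    ),
    class = "pop_dendrogram"
  )
}

#' @export
print.pop_dendrogram <- function(x, ...) {
  cat("<pop_dendrogram>", x$newick, "\n")
  invisible(x)
}
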