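test_that("LOD filtering is strictly greater-than", {
  seg <- dplyr::bind_rows(
    seg_row(10, 20, lod = 3.1),
    seg_row(30, 40, lod = 2.9),
    seg_row(50, 60, lod = 3.0)
  )
  kept <- filter_segments(seg, lod_min = 3)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$lod, 3.1)
  empty <- filter_segments(seg[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("discordant homozygotes are counted over the gap interval", {
  d <- rbind(
    A = c(0, 1, 2, 0, 2, 0),
    B = c(2, 1, 2, 2, 0, 2)
  )
  g <- toy_geno(d, pos = c(1000, 2000, 3000, 4000, 5000, 6000))
  # sites (0,2), (1,1), (2,2) -> 1 discordance
  expect_equal(
    count_discordant_homozygotes(g, c("A", "B"), "1", c(500, 3500)), 1
  )
  # identical vectors -> 0
  g2 <- toy_geno(rbind(A = c(0, 1, 2), B = c(0, 1, 2)))
  expect_equal(
    count_discordant_homozygotes(g2, c("A", "B"), "1", c(0, 1e6)), 0
  )
  # sites (0,2), (2,0), (0,2) -> 3
  expect_equal(
    count_discordant_homozygotes(g, c("A", "B"), "1", c(3500, 6500)), 3
  )
  # interval is open: endpoints excluded
  expect_equal(
    count_discordant_homozygotes(g, c("A", "B"), "1", c(1000, 4000)), 0
  )
  # missing genotypes ignored
  d3 <- rbind(A = c(0, NA), B = c(2, 2))
  expect_equal(
    count_discordant_homozygotes(toy_geno(d3), c("A", "B"), "1", c(0, 1e6)), 1
  )
  expect_error(
    count_discordant_homozygotes(g, c("A", "Z"), "1", c(0, 1)),
    "not present"
  )
})

test_that("segments merge across small clean gaps only", {
  clean <- toy_geno(
    rbind(A = rep(0, 5), B = rep(0, 5)),
    pos = seq(20.1e6, 20.4e6, length.out = 5)
  )
  # gap 0.5 cM <= 0.6, no discordance -> one merged segment of 20 cM
  seg <- dplyr::bind_rows(seg_row(10, 20), seg_row(20.5, 30))
  merged <- merge_segments(seg, clean)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start_cm, 10)
  expect_equal(merged$end_cm, 30)
  expect_equal(merged$end_cm - merged$start_cm, 20)

  # gap 0.7 cM > 0.6 -> unmerged, total 19.3 cM
  seg2 <- dplyr::bind_rows(seg_row(10, 20), seg_row(20.7, 30))
  merged2 <- merge_segments(seg2, clean)
  expect_equal(nrow(merged2), 2)
  expect_equal(sum(merged2$end_cm - merged2$start_cm), 19.3)

  # gap 0.5 cM but 2 discordant homozygotes in the gap -> unmerged
  dirty <- toy_geno(
    rbind(A = c(0, 0), B = c(2, 2)),
    pos = c(20.2e6, 20.3e6)
  )
  merged3 <- merge_segments(seg, dirty)
  expect_equal(nrow(merged3), 2)

  # exactly 1 discordant homozygote is tolerated
  one_bad <- toy_geno(
    rbind(A = c(0, 1), B = c(2, 1)),
    pos = c(20.2e6, 20.3e6)
  )
  expect_equal(nrow(merge_segments(seg, one_bad)), 1)
})

test_that("merging chains, is idempotent, and ignores input order", {
  clean <- toy_geno(
    rbind(A = rep(0, 3), B = rep(0, 3)),
    pos = c(1e6, 50e6, 90e6)
  )
  seg <- dplyr::bind_rows(
    seg_row(10, 20, lod = 4),
    seg_row(20.5, 30, lod = 6),
    seg_row(30.4, 41, lod = 5),
    seg_row(60, 70, lod = 7)
  )
  merged <- merge_segments(seg, clean)
  expect_equal(nrow(merged), 2)
  expect_equal(sort(merged$end_cm - merged$start_cm), c(10, 31))
  expect_equal(max(merged$lod), 7)
  expect_equal(merged$lod[merged$end_cm == 41], 6) # max of chained parts

  # idempotent
  expect_equal(
    merge_segments(merged, clean) |> dplyr::arrange(start_cm),
    merged |> dplyr::arrange(start_cm)
  )
  # order-invariant
  shuffled <- seg[c(3, 1, 4, 2), ]
  expect_equal(
    merge_segments(shuffled, clean) |> dplyr::arrange(start_cm),
    merged |> dplyr::arrange(start_cm)
  )
  # merging never decreases a pair's total length
  expect_gte(
    sum(merged$end_cm - merged$start_cm),
    sum(seg$end_cm - seg$start_cm)
  )
  # overlapping segments merge unconditionally, with a warning
  over <- dplyr::bind_rows(seg_row(10, 22), seg_row(20, 30))
  expect_warning(m_over <- merge_segments(over, clean), "overlap")
  expect_equal(nrow(m_over), 1)
})

test_that("pair totals include zero-sharing pairs", {
  seg <- dplyr::bind_rows(
    seg_row(0, 4, pair = c("A", "B")),
    seg_row(10, 16, pair = c("A", "B")),
    seg_row(0, 5, pair = c("A", "C")),
    seg_row(20, 27, pair = c("B", "C"))
  )
  pairs <- all_pairs <- tibble::tibble(
    sample_a = c("A", "A", "B", "A"),
    sample_b = c("B", "C", "C", "D")
  )
  totals <- pair_totals(seg, all_pairs)
  got <- setNames(
    totals$total_cm,
    paste(totals$sample_a, totals$sample_b)
  )
  expect_equal(got[["A B"]], 10)
  expect_equal(got[["A C"]], 5)
  expect_equal(got[["B C"]], 7)
  expect_equal(got[["A D"]], 0)
})

test_that("population medians match pair-level enumeration", {
  # 2 populations x 3 samples: hand-built totals over all 15 pairs
  samples <- c("P1", "P2", "P3", "Q1", "Q2", "Q3")
  labels <- tibble::tibble(
    sample_id = samples,
    population = rep(c("P", "Q"), each = 3)
  )
  pairs <- all_sample_pairs(samples)
  # within-P: 10, 12, 14; within-Q: 0, 0, 6; cross: 1..9
  totals <- pairs
  key <- paste(pairs$sample_a, pairs$sample_b)
  val <- setNames(rep(0, nrow(pairs)), key)
  val[c("P1 P2", "P1 P3", "P2 P3")] <- c(10, 12, 14)
  val[c("Q1 Q2", "Q1 Q3", "Q2 Q3")] <- c(0, 0, 6)
  cross <- setdiff(key, c("P1 P2", "P1 P3", "P2 P3", "Q1 Q2", "Q1 Q3", "Q2 Q3"))
  val[cross] <- 1:9
  totals$total_cm <- unname(val[key])
  m <- population_median_matrix(totals, labels)
  expect_equal(m$median_cm["P", "P"], 12)
  expect_equal(m$median_cm["Q", "Q"], 0) # zeros included
  expect_equal(m$median_cm["P", "Q"], 5)
  expect_equal(m$n_pairs["P", "Q"], 9)
  expect_true(isSymmetric(m$median_cm))

  # cross-population medians: {4, 6} -> 5
  t2 <- tibble::tibble(
    sample_a = c("P1", "P2"), sample_b = c("Q1", "Q1"),
    total_cm = c(4, 6)
  )
  l2 <- tibble::tibble(
    sample_id = c("P1", "P2", "Q1"),
    population = c("P", "P", "Q")
  )
  m2 <- population_median_matrix(t2, l2)
  expect_equal(m2$median_cm["P", "Q"], 5)
  expect_true(is.na(m2$median_cm["Q", "Q"])) # < 2 samples
})

test_that("population dendrograms join the most-sharing pair first", {
  med <- matrix(
    c(
      40, 30, 5,
      30, 40, 5,
      5, 5, 40
    ),
    3, 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  sh <- structure(
    list(labels = c("A", "B", "C"), median_cm = med,
      n_pairs = matrix(3, 3, 3)),
    class = "pop_sharing"
  )
  dend <- cluster_populations(sh)
  first_merge <- dend$hclust$merge[1, ]
  expect_setequal(dend$hclust$labels[-first_merge], c("A", "B"))
  expect_match(dend$newick, "\\(A:.*B:|\\(B:.*A:")

  # identical rows -> all merge heights equal
  flat <- matrix(10, 3, 3, dimnames = dimnames(med))
  sh2 <- sh
  sh2$median_cm <- flat
  expect_equal(length(unique(cluster_populations(sh2)$hclust$height)), 1)

  # 4-population hand trace of average linkage on d = max - median
  med4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  med4["A", "B"] <- med4["B", "A"] <- 38
  med4["A", "C"] <- med4["C", "A"] <- 20
  med4["B", "C"] <- med4["C", "B"] <- 22
  med4["A", "D"] <- med4["D", "A"] <- 5
  med4["B", "D"] <- med4["D", "B"] <- 6
  med4["C", "D"] <- med4["D", "C"] <- 4
  diag(med4) <- 40
  sh4 <- structure(
    list(labels = LETTERS[1:4], median_cm = med4,
      n_pairs = matrix(3, 4, 4)),
    class = "pop_sharing"
  )
  # hand trace: d(A,B)=2 joins first; d(AB,C)=mean(20,18)=19 joins next;
  # D joins last at mean(35,34,36)=35
  phy <- cluster_populations(sh4)
  expect_equal(phy$hclust$height, c(2, 19, 35))
  expect_error(
    cluster_populations(structure(
      list(labels = "A", median_cm = matrix(1, 1, 1, dimnames = list("A", "A"))),
      class = "pop_sharing"
    )),
    "at least two"
  )
})

test_that("synthetic cohorts show elevated within-population sharing", {
  cfg <- sim_config(
    ibd_rate_within = 3, ibd_rate_between = 0.3,
    ibd_mean_length_cM = 4, seed = 44
  )
  samples <- sprintf("S%03d", 1:30)
  labels <- rep(c("p1", "p2", "p3"), each = 10)
  out <- simulate_ibd_segments(samples, labels, cfg)
  kept <- filter_segments(out$segments)
  merged <- suppressWarnings(merge_segments(kept, NULL))
  totals <- pair_totals(merged, all_sample_pairs(samples))
  m <- population_median_matrix(
    totals,
    tibble::tibble(sample_id = samples, population = labels)
  )
  expect_gt(min(diag(m$median_cm)), max(m$median_cm[upper.tri(m$median_cm)]))
  dend <- cluster_populations(m)
  expect_equal(length(dend$hclust$height), 2)
})
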