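test_that("stitching merges chained gaps and respects contigs", {
  peaks <- tibble::tibble(
    contig = "chr1", start = c(0L, 10000L), end = c(100L, 10100L),
    name = c("p1", "p2"), mark = "H3K27ac"
  )
  # gap 9900 <= 12500: one region spanning both
  r <- stitch_peaks(peaks, 12500)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(0L, 10100L))
  expect_equal(r$constituents[[1]], c("p1", "p2"))

  r2 <- stitch_peaks(peaks[1, ], 12500)
  expect_equal(c(r2$start, r2$end), c(0L, 100L))

  peaks$contig <- c("chr1", "chr2")
  expect_equal(nrow(stitch_peaks(peaks, 1e6)), 2L)
})

test_that("stitching matches the interval-merge oracle on random peak sets", {
  skip_if_not_installed("GenomicRanges")
  for (seed in 1:20) {
    set.seed(seed)
    peaks <- random_peaks(1000)
    d <- sample(c(0L, 500L, 12500L), 1L)
    got <- stitch_peaks(peaks, d)[, c("contig", "start", "end")]
    expect_equal(as.data.frame(got), as.data.frame(oracle_stitch(peaks, d)))
  }
})

test_that("TSS-excluded peaks break stitching chains", {
  peaks <- tibble::tibble(
    contig = "chr1", start = c(0L, 200L, 400L), end = c(100L, 300L, 500L),
    name = c("a", "b", "c"), mark = "H3K27ac"
  )
  excl <- tibble::tibble(contig = "chr1", start = 250L, end = 260L)
  r <- stitch_peaks(peaks, 1000, tss_exclusion = excl)
  expect_equal(nrow(r), 3L)  # b overlaps the exclusion: nothing bridges
  expect_equal(nrow(stitch_peaks(peaks, 1000)), 1L)
})

test_that("region scoring integrates value x covered bp with control floor", {
  regions <- tibble::tibble(contig = "chr1", start = 0L, end = 100L,
                            region_id = "r1")
  sig <- tibble::tibble(contig = "chr1", start = 0L, end = 100L, value = 2)
  expect_equal(score_regions(regions, sig)$signal, 200)

  ctrl <- tibble::tibble(contig = "chr1", start = 0L, end = 100L, value = 5)
  expect_equal(score_regions(regions, sig, ctrl)$signal, 0)

  two <- tibble::tibble(contig = "chr1", start = c(0L, 50L), end = c(50L, 100L),
                        value = c(1, 3))
  expect_equal(score_regions(regions, two)$signal, 200)  # 1*50 + 3*50

  # partial overlap only counts covered base pairs
  part <- tibble::tibble(contig = "chr1", start = 80L, end = 150L, value = 10)
  expect_equal(score_regions(regions, part)$signal, 200)  # 10 * 20
})

test_that("tangent cutoff isolates the high-signal tail and handles degeneracy", {
  cut <- find_se_cutoff(c(1, 1, 1, 1, 100))
  expect_equal(cut$se_idx, 5L)
  expect_equal(cut$cutoff, 1)

  expect_equal(find_se_cutoff(rep(7, 10))$se_idx, integer(0))
  expect_equal(find_se_cutoff(5)$se_idx, integer(0))
})

test_that("enhancer calls partition regions into SE and TE by signal", {
  set.seed(3)
  peaks <- tibble::tibble(
    contig = "chr1",
    start = seq(0L, by = 20000L, length.out = 20L),
    end = seq(1000L, by = 20000L, length.out = 20L),
    name = sprintf("p%d", 1:20), mark = "H3K27ac"
  )
  sig <- tibble::tibble(contig = "chr1", start = peaks$start, end = peaks$end,
                        value = c(rep(10, 18), 200, 220))
  calls <- call_enhancers(peaks, sig, stitch_distance = 1000)
  expect_setequal(calls$class, c("SE", "TE"))
  expect_equal(sum(calls$class == "SE"), 2L)
  expect_equal(sort(calls$rank), 1:20)
  expect_true(min(calls$signal[calls$class == "SE"]) >
                max(calls$signal[calls$class == "TE"]))
})

test_that("raising one region's signal never demotes it from SE", {
  set.seed(9)
  for (i in 1:30) {
    signals <- c(stats::rnorm(40, 10, 1), stats::runif(5, 50, 400))
    cut <- find_se_cutoff(signals)
    if (!length(cut$se_idx)) next
    idx <- sample(cut$se_idx, 1L)
    for (c_mult in c(1.5, 3, 10)) {
      boosted <- signals
      boosted[idx] <- boosted[idx] * c_mult
      expect_true(idx %in% find_se_cutoff(boosted)$se_idx)
    }
  }
})

test_that("gene assignment windows are half-open with edge distances", {
  calls <- tibble::tibble(
    contig = "chr1", start = 1000L, end = 2000L, region_id = "r1",
    signal = 100, class = "SE"
  )
  gene <- function(tss) tibble::tibble(gene_id = "g", symbol = "g",
                                       contig = "chr1", tss = tss,
                                       strand = "+", is_tf = FALSE)
  inside <- assign_genes_to_ses(calls, gene(1500L))
  expect_equal(inside$distance, 0L)
  # exactly window bp past the end boundary: excluded (half-open)
  expect_equal(nrow(assign_genes_to_ses(calls, gene(3000L), window = 1000)), 0L)
  expect_equal(assign_genes_to_ses(calls, gene(2999L), window = 1000)$distance,
               1000L)
  expect_equal(assign_genes_to_ses(calls, gene(0L), window = 1000)$distance,
               1000L)
})

test_that("gene assignment equals the all-pairs distance oracle", {
  set.seed(21)
  calls <- tibble::tibble(
    contig = sample(c("chr1", "chr2"), 30, replace = TRUE),
    start = sample.int(50000L, 30),
    region_id = sprintf("r%02d", 1:30),
    signal = stats::runif(30, 10, 100),
    class = sample(c("SE", "TE"), 30, replace = TRUE)
  )
  calls$end <- calls$start + sample.int(5000L, 30)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:40), symbol = sprintf("g%02d", 1:40),
    contig = sample(c("chr1", "chr2"), 40, replace = TRUE),
    tss = sample.int(60000L, 40), strand = "+", is_tf = FALSE
  )
  got <- assign_genes_to_ses(calls, genes, window = 1000)
  expected <- list()
  for (i in seq_len(nrow(calls))) {
    if (calls$class[i] != "SE") next
    for (j in seq_len(nrow(genes))) {
      if (calls$contig[i] != genes$contig[j]) next
      tss <- genes$tss[j]
      if (tss >= calls$start[i] - 1000L && tss < calls$end[i] + 1000L) {
        d <- max(0L, calls$start[i] - tss, tss - (calls$end[i] - 1L))
        expected[[length(expected) + 1L]] <-
          data.frame(region_id = calls$region_id[i],
                     gene_id = genes$gene_id[j], distance = d)
      }
    }
  }
  expected <- do.call(rbind, expected)
  expected <- expected[order(expected$region_id, expected$gene_id), ]
  expect_equal(got$region_id, expected$region_id)
  expect_equal(got$gene_id, expected$gene_id)
  expect_equal(got$distance, expected$distance)
})

test_that("SE/TE overlap statistics count per class with span densities", {
  calls <- tibble::tibble(
    contig = "chr1", start = c(0L, 10000L), end = c(1000L, 12000L),
    region_id = c("r1", "r2"), signal = c(500, 10), class = c("SE", "TE")
  )
  inside_se <- tibble::tibble(contig = "chr1", start = c(10L, 500L),
                              end = c(20L, 510L),
                              name = c("t1", "t2"), mark = "TF")
  st <- se_te_overlap_stats(inside_se, calls)
  expect_equal(st$frac_se, 1)
  expect_equal(st$frac_te, 0)
  expect_equal(st$n_hits_se, 2L)
  expect_equal(st$density_se, 2 / (1000 / 1e6))

  nowhere <- tibble::tibble(contig = "chr1", start = 50000L, end = 50100L,
                            name = "t", mark = "TF")
  st0 <- se_te_overlap_stats(nowhere, calls)
  expect_equal(st0$n_hits_se + st0$n_hits_te, 0L)

  no_te <- dplyr::mutate(calls, class = "SE")
  expect_equal(se_te_overlap_stats(inside_se, no_te)$ratio, Inf)
})

test_that("SE/TE overlap counts match the findOverlaps oracle", {
  skip_if_not_installed("GenomicRanges")
  set.seed(5)
  for (i in 1:10) {
    calls <- random_peaks(40)
    calls$region_id <- sprintf("r%d", 1:40)
    calls$signal <- stats::runif(40)
    calls$class <- sample(c("SE", "TE"), 40, replace = TRUE)
    tf <- random_peaks(60)
    st <- se_te_overlap_stats(tf, calls)
    expect_equal(st$n_hits_se,
                 sum(oracle_overlaps_any(tf, dplyr::filter(calls, class == "SE"))))
    expect_equal(st$n_hits_te,
                 sum(oracle_overlaps_any(tf, dplyr::filter(calls, class == "TE"))))
  }
})

test_that("broad-domain ranking flags the widest ceiling(f * N) peaks", {
  peaks <- tibble::tibble(
    contig = "chr1", start = c(0L, 100L, 1000L),
    end = c(10L, 600L, 1020L),
    name = c("a", "b", "c"), mark = "H3K4me3"
  )
  # widths 10, 500, 20; ceiling(0.34 * 3) = 2 broad
  r <- rank_broad_domains(peaks, broad_fraction = 0.34)
  expect_equal(r$name[r$is_broad], c("b", "c"))
  expect_true(all(rank_broad_domains(peaks, 1.0)$is_broad))
  expect_true(rank_broad_domains(peaks[1, ], 0.01)$is_broad)
  expect_error(rank_broad_domains(peaks, 0), "broad_fraction")
  expect_error(rank_broad_domains(peaks, 1.5), "broad_fraction")
})
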