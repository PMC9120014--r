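test_that("region extension is symmetric and clamped", {
  lens <- c(chr1 = 10000L)
  r <- tibble::tibble(contig = "chr1", start = 1000L, end = 2000L)
  expect_equal(unlist(extend_regions(r, 500, lens)[, c("start", "end")]),
               c(start = 500L, end = 2500L))
  r2 <- tibble::tibble(contig = "chr1", start = 100L, end = 300L)
  expect_equal(unlist(extend_regions(r2, 500, lens)[, c("start", "end")]),
               c(start = 0L, end = 800L))
  expect_equal(extend_regions(r, 0, lens), r)
})

test_that("exact null distribution of a 1-position motif enumerates 4 outcomes", {
  m <- new_pwm_motif("one", matrix(c(1, 0, 0, 0), nrow = 1,
                                   dimnames = list(NULL, c("A", "C", "G", "T"))),
                     pseudocount = 1e-3)
  dist <- motif_score_distribution(m)
  # hand enumeration: score(A) = log(1.001/1.004/0.25), score(C/G/T) equal
  c <- 1e-3
  sA <- log(((1 + c) / (1 + 4 * c)) / 0.25)
  sO <- log(((0 + c) / (1 + 4 * c)) / 0.25)
  expect_equal(dist$support, sort(unique(round(c(sO, sA) / dist$step))))
  expect_equal(dist$prob, c(0.75, 0.25))
  expect_equal(sum(dist$prob), 1)
})

test_that("thresholding follows exact tail probabilities with degenerate rules", {
  set.seed(1)
  m <- random_motif(6)
  # p = 1 admits every score: threshold is the minimum attainable
  thr <- score_threshold(m, p_threshold = 1)
  expect_equal(round(thr$threshold / thr$distribution$step),
               min(thr$distribution$support))

  # uniform rows: all log-odds are 0, nothing can reach p <= 1e-4
  u <- new_pwm_motif("unif", matrix(0.25, nrow = 3, ncol = 4,
                                    dimnames = list(NULL, c("A", "C", "G", "T"))),
                     pseudocount = 0)
  dist_u <- motif_score_distribution(u)
  expect_equal(dist_u$support, 0L)
  expect_warning(thr_u <- score_threshold(u, 1e-4), "no score attains")
  expect_true(thr_u$unattainable)
  expect_equal(nrow(scan_sequence(u, "ACGTACGT", thr_u)), 0L)
})

test_that("consensus scores maximally and strand symmetry holds", {
  set.seed(2)
  m <- random_motif(8)
  thr <- score_threshold(m, 1e-3)
  cons <- motif_consensus(m)
  hits <- scan_sequence(m, cons, thr)
  expect_true(any(hits$strand == "+" & hits$start == 0L))
  c <- m$pseudocount
  lod <- log(((m$mat + c) / (1 + 4 * c)) / rep(m$background, each = nrow(m$mat)))
  expect_equal(max(hits$score), sum(apply(lod, 1L, max)), tolerance = 1e-9)

  seq <- random_seq(500)
  fwd <- scan_sequence(m, seq, thr)
  rc <- scan_sequence(m, reverse_complement(seq), thr)
  # mirrored coordinates and flipped strands
  n <- nchar(seq); L <- nrow(m$mat)
  mirrored <- tibble::tibble(start = n - rc$end, strand = ifelse(rc$strand == "+", "-", "+"))
  expect_setequal(paste(fwd$start, fwd$strand),
                  paste(mirrored$start, mirrored$strand))
})

test_that("sequences shorter than the motif yield no hits", {
  set.seed(4)
  m <- random_motif(10)
  expect_equal(nrow(scan_sequence(m, "ACGT", 0)), 0L)
})

test_that("lowering the p-value threshold never adds hits", {
  set.seed(6)
  m <- random_motif(7)
  seq <- random_seq(2000)
  pvals <- c(1e-2, 1e-3, 1e-4)
  hits <- lapply(pvals, function(p) {
    h <- scan_sequence(m, seq, score_threshold(m, p))
    paste(h$start, h$strand)
  })
  expect_true(all(hits[[2]] %in% hits[[1]]))
  expect_true(all(hits[[3]] %in% hits[[2]]))
})

test_that("N bases score as background and do not block scanning", {
  m <- new_pwm_motif("two", matrix(c(1, 0, 0, 0, 1, 0, 0, 0), nrow = 2,
                                   byrow = TRUE,
                                   dimnames = list(NULL, c("A", "C", "G", "T"))))
  hits <- scan_sequence(m, "ANAA", threshold = 0, both_strands = FALSE)
  # windows: AN (A + 0), NA (0 + A), AA (A + A): all non-negative scores
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$score[3], 2 * hits$score[1] - 0, tolerance = 1e-9)
})

test_that("hit sets equal exhaustive per-window scoring on random instances", {
  set.seed(8)
  for (i in 1:25) {
    L <- sample(4:9, 1)
    m <- random_motif(L, sprintf("m%d", i))
    seq <- random_seq(300)
    thr <- score_threshold(m, 1e-2)
    got <- scan_sequence(m, seq, thr)
    thr_bin <- round(thr$threshold / thr$distribution$step)
    exp <- oracle_scan_hits(m, seq, thr_bin)
    expect_equal(paste(got$start, got$strand), paste(exp$start, exp$strand))
  }
})

test_that("hit counting over regions matches summed per-window hits", {
  set.seed(10)
  genome <- c(chr1 = random_seq(5000))
  motifs <- list(m1 = random_motif(6, "m1"), m2 = random_motif(8, "m2"))
  calls <- tibble::tibble(
    contig = "chr1", start = c(500L, 3000L), end = c(900L, 3600L),
    region_id = c("r1", "r2"), signal = c(10, 20), class = "SE"
  )
  counts <- hits_in_regions(motifs, calls, genome, extension = 100,
                            p_threshold = 1e-2)
  expect_equal(nrow(counts), 4L)  # dense mapping
  for (id in names(motifs)) {
    thr <- score_threshold(motifs[[id]], 1e-2)
    thr_bin <- round(thr$threshold / thr$distribution$step)
    for (k in 1:2) {
      win <- extract_sequences(genome,
                               tibble::tibble(contig = "chr1",
                                              start = calls$start[k] - 100L,
                                              end = calls$end[k] + 100L))
      exp_n <- nrow(oracle_scan_hits(motifs[[id]], win, thr_bin))
      got_n <- counts$n_hits[counts$tf_id == id &
                               counts$region_id == calls$region_id[k]]
      expect_equal(got_n, exp_n)
    }
  }
})

test_that("Monte-Carlo tail probabilities match the exact convolution", {
  set.seed(12)
  n_mc <- 100000L
  for (L in c(5L, 7L, 10L)) {
    m <- random_motif(L)
    dist <- motif_score_distribution(m)
    thr <- score_threshold(m, 1e-3)
    thr_bin <- round(thr$threshold / dist$step)
    p_exact <- thr$p_actual
    # independent binned scoring of background draws
    c <- m$pseudocount
    lod_bins <- round(log(((t(m$mat) + c) / (1 + 4 * c)) / m$background) /
                        dist$step)  # 4 x L
    codes <- matrix(sample.int(4L, n_mc * L, replace = TRUE), n_mc, L)
    scores <- rowSums(vapply(seq_len(L), function(j) {
      lod_bins[codes[, j], j]
    }, numeric(n_mc)))
    p_mc <- mean(scores >= thr_bin)
    se <- sqrt(p_exact * (1 - p_exact) / n_mc)
    expect_lt(abs(p_mc - p_exact), 3 * se + 1e-12)
  }
})
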