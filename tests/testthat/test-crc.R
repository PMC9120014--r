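test_that("TF assignment picks the highest-signal SE with deterministic ties", {
  calls <- tibble::tibble(
    contig = "chr1", start = c(1000L, 5000L), end = c(2000L, 6000L),
    region_id = c("r1", "r2"), signal = c(50, 80), class = "SE"
  )
  genes <- tibble::tibble(
    gene_id = c("TF1", "G1"), symbol = c("TF1", "G1"), contig = "chr1",
    tss = c(1500L, 1600L), strand = "+", is_tf = c(TRUE, FALSE)
  )
  a <- assign_tf_to_se(calls, genes)
  expect_equal(a$tf_id, "TF1")
  expect_equal(a$region_id, "r1")

  # TSS within the window of both SEs: higher signal wins
  genes2 <- dplyr::mutate(genes, tss = c(4800L, 100L))
  calls2 <- dplyr::mutate(calls, start = c(3500L, 5000L), end = c(4500L, 6000L))
  expect_equal(assign_tf_to_se(calls2, genes2)$region_id, "r2")

  # equal signal: lower (contig, start) wins
  calls3 <- dplyr::mutate(calls2, signal = c(80, 80))
  expect_equal(assign_tf_to_se(calls3, genes2)$region_id, "r1")

  # non-TF genes are never assigned
  genes3 <- dplyr::mutate(genes, is_tf = FALSE)
  expect_equal(nrow(assign_tf_to_se(calls, genes3)), 0L)
})

test_that("auto-regulation requires a self-hit in the TF's own SE window", {
  assignments <- tibble::tibble(
    tf_id = c("A", "B"), region_id = c("r1", "r2"),
    distance = 0L, signal = c(10, 20)
  )
  hits <- tidyr::expand_grid(tf_id = c("A", "B"), region_id = c("r1", "r2")) |>
    dplyr::mutate(n_hits = c(1L, 0L, 0L, 0L))  # A in r1 only
  expect_equal(detect_autoregulated_tfs(assignments, hits), "A")
})

test_that("regulatory graph edges follow the hit-count threshold", {
  assignments <- tibble::tibble(
    tf_id = c("A", "B", "C"), region_id = c("r1", "r2", "r3"),
    distance = 0L, signal = 1
  )
  hits <- tidyr::expand_grid(tf_id = c("A", "B", "C"),
                             region_id = c("r1", "r2", "r3")) |>
    dplyr::mutate(n_hits = 2L)
  g <- build_regulatory_graph(c("A", "B", "C"), assignments, hits)
  expect_equal(nrow(g$edges), 6L)  # all ordered pairs, no self-loops

  g2 <- build_regulatory_graph(c("A", "B", "C"), assignments, hits,
                               min_hits = 3)
  expect_equal(nrow(g2$edges), 0L)

  # thresholding equals a direct filter of the count table
  set.seed(14)
  hits$n_hits <- sample(0:3, 9, replace = TRUE)
  g3 <- build_regulatory_graph(c("A", "B", "C"), assignments, hits,
                               min_hits = 2)
  manual <- merge(hits, assignments[, c("tf_id", "region_id")],
                  by = "region_id", suffixes = c("", ".t"))
  manual <- manual[manual$tf_id != manual$tf_id.t & manual$n_hits >= 2, ]
  expect_equal(nrow(g3$edges), nrow(manual))
})

test_that("clique enumeration requires mutual edges and reports fractions", {
  tri <- toy_graph(c("A", "B", "C"),
                   list(c("A", "B"), c("B", "A"), c("A", "C"), c("C", "A"),
                        c("B", "C"), c("C", "B")))
  res <- enumerate_crc_cliques(tri)
  expect_equal(res$cliques, list(c("A", "B", "C")))
  expect_equal(res$clique_fraction$fraction, rep(1, 3))

  # one-way edge never forms a clique
  oneway <- toy_graph(c("A", "B"), list(c("A", "B")))
  expect_equal(length(enumerate_crc_cliques(oneway)$cliques), 0L)

  empty <- toy_graph(character(0), list())
  expect_equal(enumerate_crc_cliques(empty)$crc_tfs, character(0))
})

test_that("maximal cliques equal exhaustive subset enumeration", {
  set.seed(16)
  for (i in 1:12) {
    n <- sample(4:8, 1)
    nodes <- sprintf("T%02d", seq_len(n))
    adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    # random mutual and one-way directed edges
    edges <- list()
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a != b && stats::runif(1) < 0.4) {
        edges[[length(edges) + 1L]] <- c(nodes[a], nodes[b])
      }
    }
    g <- toy_graph(nodes, edges)
    res <- enumerate_crc_cliques(g)
    for (e in edges) {
      if (any(vapply(edges, function(x) identical(x, c(e[2], e[1])), logical(1)))) {
        adj[e[1], e[2]] <- TRUE
      }
    }
    expect_identical(res$cliques, oracle_max_cliques(adj))
  }
})

test_that("adding hits never removes a clique; raising min_hits never adds one", {
  set.seed(18)
  assignments <- tibble::tibble(tf_id = sprintf("T%d", 1:6),
                                region_id = sprintf("r%d", 1:6),
                                distance = 0L, signal = 1)
  hits <- tidyr::expand_grid(tf_id = sprintf("T%d", 1:6),
                             region_id = sprintf("r%d", 1:6)) |>
    dplyr::mutate(n_hits = sample(0:2, 36, replace = TRUE))
  auto <- sprintf("T%d", 1:6)
  base <- enumerate_crc_cliques(build_regulatory_graph(auto, assignments, hits))
  more <- dplyr::mutate(hits, n_hits = n_hits + 1L)
  grown <- enumerate_crc_cliques(build_regulatory_graph(auto, assignments, more))
  for (cl in base$cliques) {
    expect_true(any(vapply(grown$cliques, function(g) all(cl %in% g), logical(1))))
  }
  stricter <- enumerate_crc_cliques(
    build_regulatory_graph(auto, assignments, hits, min_hits = 2))
  for (cl in stricter$cliques) {
    expect_true(any(vapply(base$cliques, function(g) all(cl %in% g), logical(1))))
  }
})

test_that("expression filtering keeps TFs at or above the threshold", {
  tri <- toy_graph(c("A", "B", "C"),
                   list(c("A", "B"), c("B", "A"), c("A", "C"), c("C", "A"),
                        c("B", "C"), c("C", "B")))
  crc <- enumerate_crc_cliques(tri)
  expr <- tibble::tibble(gene_id = c("A", "B"), s1 = c(50, 2))
  expect_warning(out <- filter_expressed_crc_tfs(crc, expr, "s1", 10),
                 "absent")
  expect_equal(out$expressed_crc_tfs, "A")
  expect_equal(suppressWarnings(
    filter_expressed_crc_tfs(crc, expr, "s1", 0)$expressed_crc_tfs
  ), c("A", "B", "C"))
  expect_error(filter_expressed_crc_tfs(crc, expr, "nope"), "no column")
})

test_that("CRC target genes need hits from enough distinct TFs", {
  links <- tibble::tibble(region_id = c("r1", "r1", "r2"),
                          gene_id = c("g1", "g2", "g3"),
                          symbol = c("g1", "g2", "g3"),
                          distance = 0L, signal = 1)
  hits <- tidyr::expand_grid(tf_id = c("A", "B", "C"),
                             region_id = c("r1", "r2")) |>
    dplyr::mutate(n_hits = c(1L, 0L, 2L, 1L, 1L, 0L))
  # r1 has hits from A, B, C? A:1 (r1), B:2 (r1), C:1 (r1) -> 3 distinct
  hits$n_hits <- c(1L, 0L, 2L, 0L, 1L, 0L)
  got <- infer_crc_targets(links, hits, c("A", "B", "C"), min_distinct_tfs = 3)
  expect_equal(got, c("g1", "g2"))
  # with only two distinct TFs required, r2 still has just one
  expect_equal(infer_crc_targets(links, hits, c("A", "B", "C"), 2),
               c("g1", "g2"))
  # total-occurrence mode counts multiplicity
  expect_equal(infer_crc_targets(links, hits, c("A", "B"), 3,
                                 count_total = TRUE), c("g1", "g2"))
})
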