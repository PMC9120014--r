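# Independent oracles: straight-line scalar implementations sharing no code
# with the package, used to cross-check each algorithmic stage.

# ---- interval stitching oracle (GenomicRanges::reduce) ----

oracle_stitch <- function(peaks, stitch_distance) {
  gr <- GenomicRanges::GRanges(
    peaks$contig,
    IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1L)
  tibble::tibble(
    contig = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  ) |> dplyr::arrange(contig, start)
}

# ---- overlap oracle (IRanges::findOverlaps) ----

oracle_overlaps_any <- function(x, y) {
  if (nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  gx <- GenomicRanges::GRanges(x$contig,
                               IRanges::IRanges(x$start + 1L, x$end))
  gy <- GenomicRanges::GRanges(y$contig,
                               IRanges::IRanges(y$start + 1L, y$end))
  GenomicRanges::countOverlaps(gx, gy) > 0L
}

# ---- per-window motif scan oracle ----

# Per-window integer-bin scores computed with explicit loops and an
# independently derived log-odds table.
oracle_window_bins <- function(seq, mat, background, pseudocount, step) {
  bases <- c("A", "C", "G", "T")
  p <- (mat + pseudocount) / (1 + 4 * pseudocount)
  chars <- strsplit(seq, NULL)[[1L]]
  L <- nrow(mat)
  n_win <- length(chars) - L + 1L
  if (n_win < 1L) return(integer(0))
  out <- integer(n_win)
  for (i in seq_len(n_win)) {
    s <- 0L
    for (j in seq_len(L)) {
      b <- match(chars[i + j - 1L], bases)
      if (!is.na(b)) {
        s <- s + as.integer(round(log(p[j, b] / background[b]) / step))
      }
    }
    out[i] <- s
  }
  out
}

oracle_scan_hits <- function(motif, seq, thr_bin, step = 1e-3) {
  fwd <- oracle_window_bins(seq, motif$mat, motif$background,
                            motif$pseudocount, step)
  comp <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, NULL)[[1L]]),
                                         collapse = ""))
  rev <- oracle_window_bins(comp, motif$mat, motif$background,
                            motif$pseudocount, step)
  n <- nchar(seq); L <- nrow(motif$mat)
  hits <- list()
  for (i in seq_along(fwd)) {
    if (fwd[i] >= thr_bin) hits[[length(hits) + 1L]] <- c(i - 1L, 1L)
  }
  for (i in seq_along(rev)) {
    if (rev[i] >= thr_bin) {
      hits[[length(hits) + 1L]] <- c(n - i - L + 1L, -1L)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), strand = character(0)))
  }
  m <- do.call(rbind, hits)
  df <- data.frame(start = m[, 1L],
                   strand = ifelse(m[, 2L] > 0, "+", "-"))
  df[order(df$start, df$strand), ]
}

# ---- maximal clique oracle (2^n subset enumeration) ----

oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  complete <- function(members) {
    if (length(members) < 2L) return(TRUE)
    for (a in members) for (b in members) {
      if (a != b && !adj[a, b]) return(FALSE)
    }
    TRUE
  }
  subsets <- list()
  for (mask in seq_len(2^n - 1L)) {
    members <- nodes[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    if (length(members) >= 2L && complete(members)) {
      subsets[[length(subsets) + 1L]] <- members
    }
  }
  is_maximal <- vapply(subsets, function(s) {
    !any(vapply(subsets, function(t) {
      length(t) > length(s) && all(s %in% t)
    }, logical(1)))
  }, logical(1))
  cl <- lapply(subsets[is_maximal], sort)
  cl[order(-lengths(cl), vapply(cl, paste, "", collapse = "\r"))]
}

# ---- D-measure oracle: scalar evaluation of the three-term formula ----

oracle_entropy <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log(v)
  s
}

# same round-off floor convention as the package: JSD below 1e-13 is zero
oracle_jsd2 <- function(p, q) {
  m <- (p + q) / 2
  j <- oracle_entropy(m) - (oracle_entropy(p) + oracle_entropy(q)) / 2
  if (j < 1e-13) 0 else j
}

oracle_shortest_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_profiles <- function(A) {
  n <- nrow(A)
  if (n <= 1L) {
    return(list(P = NULL, mu = numeric(0), diam = 0L,
                unreach = FALSE, n = n))
  }
  D <- oracle_shortest_paths(A)
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off)]
  diam <- if (length(fin)) max(fin) else 0
  unreach <- any(!is.finite(off))
  nbins <- diam + as.integer(unreach)
  P <- matrix(0, n, nbins)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- D[i, j]
      col <- if (is.finite(d)) d else nbins
      P[i, col] <- P[i, col] + 1 / (n - 1)
    }
  }
  list(P = P, mu = colMeans(P), diam = diam, unreach = unreach, n = n)
}

oracle_nnd <- function(prof) {
  if (prof$n < 2L) return(0)
  nbins <- prof$diam + as.integer(prof$unreach)
  if (nbins <= 0) return(0)
  m <- colMeans(prof$P)
  j <- oracle_entropy(m) -
    mean(apply(prof$P, 1L, oracle_entropy))
  if (j < 1e-13) return(0)
  j / log(nbins + 1)
}

oracle_alpha <- function(A) {
  n <- nrow(A)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(1)
  lam <- max(abs(eigen(A, only.values = TRUE)$values))
  cv <- solve(diag(n) - A / (1 + lam)) %*% rep(1, n)
  cv <- as.numeric(cv)
  cv <- cv - min(cv, 0)
  sort(cv / sum(cv), decreasing = TRUE)
}

oracle_complement <- function(A) {
  C <- 1 - A
  diag(C) <- 0
  C
}

oracle_pad <- function(x, len) c(x, rep(0, len - length(x)))

oracle_dmeasure <- function(A1, A2, w = c(0.45, 0.45, 0.1)) {
  p1 <- oracle_profiles(A1)
  p2 <- oracle_profiles(A2)
  d <- max(p1$diam, p2$diam)
  mu_of <- function(p) {
    fin <- rep(0, d)
    if (p$diam > 0) fin[seq_len(p$diam)] <- p$mu[seq_len(p$diam)]
    c(fin, if (p$unreach) p$mu[length(p$mu)] else 0)
  }
  term1 <- sqrt(oracle_jsd2(mu_of(p1), mu_of(p2)) / log(2))
  term2 <- abs(sqrt(oracle_nnd(p1)) - sqrt(oracle_nnd(p2)))
  a1 <- oracle_alpha(A1); a2 <- oracle_alpha(A2)
  c1 <- oracle_alpha(oracle_complement(A1))
  c2 <- oracle_alpha(oracle_complement(A2))
  la <- max(length(a1), length(a2), 1L)
  lc <- max(length(c1), length(c2), 1L)
  term3 <- sqrt(oracle_jsd2(oracle_pad(a1, la), oracle_pad(a2, la)) / log(2)) +
    sqrt(oracle_jsd2(oracle_pad(c1, lc), oracle_pad(c2, lc)) / log(2))
  if (xor(nrow(A1) == 0L, nrow(A2) == 0L)) {
    return(max(term1, term2, term3))
  }
  w[1] * term1 + w[2] * term2 + w[3] * term3
}

graph_to_adj <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# ---- shared random generators ----

random_peaks <- function(n, contigs = c("chr1", "chr2", "chr3"),
                         max_pos = 100000L, max_width = 2000L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    contig = sample(contigs, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE),
    name = sprintf("p%d", seq_len(n)),
    mark = "H3K27ac"
  )
}

random_motif <- function(len, id = "M1") {
  mat <- matrix(stats::rgamma(len * 4, 1), nrow = len)
  mat <- mat / rowSums(mat)
  colnames(mat) <- c("A", "C", "G", "T")
  new_pwm_motif(id, mat)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Regulatory graph object from a directed edge list over named nodes.
toy_graph <- function(nodes, edges) {
  e <- if (length(edges)) {
    tibble::tibble(
      from = vapply(edges, `[[`, "", 1L),
      to = vapply(edges, `[[`, "", 2L),
      n_hits = 1L
    )
  } else {
    tibble::tibble(from = character(), to = character(), n_hits = integer())
  }
  structure(list(nodes = tibble::tibble(tf_id = nodes, autoregulated = TRUE),
                 edges = e),
            class = "regulatory_graph")
}
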