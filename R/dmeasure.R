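#' Per-node shortest-path distance distributions
#'
#' For each node `i`, `P_i(d)` is the fraction of the other `N - 1` nodes at
#' shortest-path distance `d`, over bins `1..diam` (the diameter over finite
#' distances); pairs with no connecting path accumulate in one extra
#' unreachable bin appended when any exist. The mean profile `mu` is the
#' arithmetic mean of the rows.
#'
#' @param graph An undirected simple `igraph` graph.
#' @return A list with `P` (N x bins matrix), `mu`, `diam` (number of finite
#'   distance bins), `has_unreachable` and `n` (node count). For `n <= 1`
#'   the profile is empty (`0`-column matrix).
#' @export
node_distance_profiles <- function(graph) {
  if (igraph::is_directed(graph)) {
    stop("node_distance_profiles requires an undirected graph", call. = FALSE)
  }
  n <- igraph::vcount(graph)
  if (n <= 1L) {
    return(list(P = matrix(numeric(0), nrow = n, ncol = 0L),
                mu = numeric(0), diam = 0L, has_unreachable = FALSE, n = n))
  }
  d <- igraph::distances(graph)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  diam <- if (length(finite)) as.integer(max(finite)) else 0L
  has_unreachable <- any(!is.finite(off))
  nbins <- diam + as.integer(has_unreachable)
  P <- matrix(0, nrow = n, ncol = nbins)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    if (diam > 0L) {
      tab <- tabulate(di[is.finite(di)], nbins = diam)
      P[i, seq_len(diam)] <- tab / (n - 1L)
    }
    if (has_unreachable) {
      P[i, nbins] <- sum(!is.finite(di)) / (n - 1L)
    }
  }
  list(P = P, mu = colMeans(P), diam = diam,
       has_unreachable = has_unreachable, n = n)
}

#' Generalized Jensen-Shannon divergence
#'
#' `J = H(mean of the distributions) - mean of H(distribution)`, with
#' Shannon entropy `H` in natural-log units; `0 <= J <= log(N)` for `N`
#' distributions. Zero-padded vectors are handled with the `0 log 0 = 0`
#' convention.
#'
#' @param distributions A matrix (one distribution per row) or list of
#'   equal-length probability vectors.
#' @return The divergence in nats.
#' @export
generalized_jsd <- function(distributions) {
  P <- if (is.matrix(distributions)) distributions else {
    lens <- lengths(distributions)
    if (length(unique(lens)) > 1L) {
      stop("distributions must have a common support length", call. = FALSE)
    }
    do.call(rbind, distributions)
  }
  if (nrow(P) < 2L) stop("need at least two distributions", call. = FALSE)
  shannon_entropy(colMeans(P)) - mean(apply(P, 1L, shannon_entropy))
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Network node dispersion
#'
#' The generalized Jensen-Shannon divergence of the per-node distance
#' distributions, normalized by `log(diam + 1)` where `diam` counts the
#' finite distance bins plus the unreachable bin when present. Zero for
#' graphs whose nodes all have identical profiles (complete or edgeless
#' graphs) and for graphs with fewer than two nodes.
#'
#' @param graph An undirected simple `igraph` graph.
#' @param profiles Optional precomputed [node_distance_profiles()] result.
#' @return The dispersion value in `[0, 1]`.
#' @export
nnd <- function(graph = NULL, profiles = NULL) {
  if (is.null(profiles)) profiles <- node_distance_profiles(graph)
  if (profiles$n < 2L) return(0)
  nbins <- profiles$diam + as.integer(profiles$has_unreachable)
  if (nbins <= 0L) return(0)
  j <- generalized_jsd(profiles$P)
  if (j < 1e-13) return(0)  # round-off floor (see jsd_pair)
  j / log(nbins + 1)
}

#' Alpha-centrality probability distribution
#'
#' Solves the alpha-centrality system `c = alpha * A %*% c + e` with
#' exogenous vector `e = 1` and damping `alpha = 1 / (1 + lambda_max(A))`
#' (guaranteeing a convergent, positive solution), then normalizes `c` to a
#' probability vector sorted in descending order. Comparisons between
#' graphs of different size zero-pad the shorter vector.
#'
#' @param graph An undirected simple `igraph` graph.
#' @return Probability vector sorted descending (length = node count);
#'   `numeric(0)` for the empty graph.
#' @export
alpha_centrality_distribution <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(numeric(0))
  if (n == 1L) return(1)
  A <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = FALSE))
  lam <- max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  alpha <- 1 / (1 + lam)
  cvec <- solve(diag(n) - alpha * A, rep(1, n))
  cvec <- cvec - min(cvec, 0)  # shift to non-negative (already positive here)
  sort(cvec / sum(cvec), decreasing = TRUE)
}

#' Default D-measure weights
#'
#' @param w1 Weight of the global distance-distribution term.
#' @param w2 Weight of the node-dispersion term.
#' @param w3 Weight of the alpha-centrality term.
#' @return Named numeric vector of validated weights.
#' @export
d_weights <- function(w1 = 0.45, w2 = 0.45, w3 = 0.1) {
  w <- c(w1 = w1, w2 = w2, w3 = w3)
  if (any(!is.finite(w)) || any(w < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  w
}

# Align two mean distance profiles on a common support: finite bins padded
# to the longer diameter, then one shared unreachable bin appended last.
pad_mu <- function(p1, p2) {
  d <- max(p1$diam, p2$diam)
  pad <- function(p) {
    fin <- numeric(d)
    if (p$diam > 0L) fin[seq_len(p$diam)] <- p$mu[seq_len(p$diam)]
    unr <- if (p$has_unreachable) p$mu[length(p$mu)] else 0
    c(fin, unr)
  }
  rbind(pad(p1), pad(p2))
}

pad_right <- function(x, len) c(x, numeric(len - length(x)))

#' Structural dissimilarity between two networks
#'
#' The three-term D-measure:
#' `D = w1 * sqrt(J(mu_G, mu_G') / log 2)`
#' `  + w2 * |sqrt(NND(G)) - sqrt(NND(G'))|`
#' `  + w3 * (sqrt(J(P_aG, P_aG') / log 2) + sqrt(J(P_aGc, P_aG'c) / log 2))`
#' where `J` is the Jensen-Shannon divergence, `mu` the mean shortest-path
#' distance distribution, `NND` the network node dispersion, `P_a` the
#' alpha-centrality distribution and `Gc` the graph complement. The
#' similarity score is `S = 1 - D`. `D` ignores node identity: it compares
#' structure only.
#'
#' Degenerate inputs follow fixed rules: one-node graphs contribute an empty
#' (zero-padded) distance profile and a point-mass centrality; a zero-node
#' graph against a non-empty one yields `D = max(term1, term2, term3)`
#' computed with all-zero profiles, with a warning.
#'
#' @param g1,g2 Undirected simple `igraph` graphs.
#' @param weights Weights from [d_weights()].
#' @return A one-row tibble with `term1`, `term2`, `term3` (unweighted),
#'   `D` and `S`.
#' @examples
#' g <- igraph::make_full_graph(4)
#' d_measure(g, g)
#' @export
d_measure <- function(g1, g2, weights = d_weights()) {
  weights <- d_weights(weights[["w1"]], weights[["w2"]], weights[["w3"]])
  if (igraph::is_directed(g1) || igraph::is_directed(g2)) {
    stop("d_measure requires undirected graphs", call. = FALSE)
  }
  p1 <- node_distance_profiles(g1)
  p2 <- node_distance_profiles(g2)

  mus <- pad_mu(p1, p2)
  term1 <- sqrt(jsd_pair(mus[1L, ], mus[2L, ]) / log(2))

  term2 <- abs(sqrt(nnd(profiles = p1)) - sqrt(nnd(profiles = p2)))

  a1 <- alpha_centrality_distribution(g1)
  a2 <- alpha_centrality_distribution(g2)
  c1 <- alpha_centrality_distribution(igraph::complementer(g1))
  c2 <- alpha_centrality_distribution(igraph::complementer(g2))
  len_a <- max(length(a1), length(a2), 1L)
  len_c <- max(length(c1), length(c2), 1L)
  term3 <- sqrt(jsd_pair(pad_right(a1, len_a), pad_right(a2, len_a)) / log(2)) +
    sqrt(jsd_pair(pad_right(c1, len_c), pad_right(c2, len_c)) / log(2))

  if (xor(p1$n == 0L, p2$n == 0L)) {
    warning("comparing an empty graph: D is the maximum of the raw terms",
            call. = FALSE)
    D <- max(term1, term2, term3)
  } else {
    D <- weights[["w1"]] * term1 + weights[["w2"]] * term2 +
      weights[["w3"]] * term3
  }
  tibble::tibble(term1 = term1, term2 = term2, term3 = term3,
                 D = D, S = 1 - D)
}

# Two-distribution JSD tolerating zero-padded (or all-zero) vectors.
# Values below the round-off floor collapse to an exact zero so that
# sqrt(J) does not amplify 1e-16-scale noise into 1e-8-scale terms.
jsd_pair <- function(p, q) {
  m <- (p + q) / 2
  j <- shannon_entropy(m) - (shannon_entropy(p) + shannon_entropy(q)) / 2
  if (j < 1e-13) 0 else j
}

#' Pairwise dissimilarity matrix of CRC networks
#'
#' Computes the D-measure for every pair of sample graphs, plus the
#' companion similarity matrix `S = 1 - D`.
#'
#' @param graphs Named list of undirected `igraph` graphs (or `crc_result`
#'   objects, which are projected with [crc_graph()]).
#' @param weights Weights from [d_weights()].
#' @return A `crc_dissimilarity` object: list with symmetric matrices `D`
#'   and `S` (zero / unit diagonal) and `weights`.
#' @export
pairwise_dissimilarity <- function(graphs, weights = d_weights()) {
  if (length(graphs) < 2L) stop("need at least two samples", call. = FALSE)
  graphs <- lapply(graphs, function(g) {
    if (inherits(g, "crc_result")) crc_graph(g) else g
  })
  empties <- vapply(graphs, function(g) igraph::vcount(g) == 0L, logical(1))
  if (any(empties)) {
    warning("sample(s) with empty CRC graph: ",
            paste(names(graphs)[empties], collapse = ", "), call. = FALSE)
  }
  ids <- names(graphs)
  if (is.null(ids)) ids <- paste0("sample_", seq_along(graphs))
  n <- length(graphs)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- suppressWarnings(d_measure(graphs[[i]], graphs[[j]], weights))$D
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(list(D = D, S = 1 - D, weights = weights),
            class = "crc_dissimilarity")
}

#' @export
print.crc_dissimilarity <- function(x, ...) {
  cat("<crc_dissimilarity> ", nrow(x$D), " samples\n", sep = "")
  print(round(x$D, 4))
  invisible(x)
}

#' Cluster samples from a dissimilarity matrix
#'
#' Agglomerative clustering (default average linkage) on the D matrix, cut
#' into `k` groups. Group labels are deterministic: group 1 is the group
#' containing the first sample in input order, then groups are numbered by
#' first appearance.
#'
#' @param dissimilarity A `crc_dissimilarity` object or symmetric numeric
#'   matrix of D values.
#' @param k Number of groups.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return A `sample_clustering` object: list with `labels` (tibble
#'   `sample`, `group`), `hclust`, `k` and the input matrix `D`.
#' @export
cluster_samples <- function(dissimilarity, k = 2, linkage = "average") {
  D <- if (inherits(dissimilarity, "crc_dissimilarity")) dissimilarity$D
       else dissimilarity
  n <- nrow(D)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")",
                  call. = FALSE)
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  raw <- stats::cutree(hc, k = k)
  relabel <- match(raw, unique(raw))  # group of first sample becomes 1
  labels <- tibble::tibble(sample = rownames(D), group = as.integer(relabel))
  structure(list(labels = labels, hclust = hc, k = k, D = D),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering> k = ", x$k, "\n", sep = "")
  print(x$labels, n = nrow(x$labels))
  invisible(x)
}

#' Random Erdos-Renyi graph helper
#'
#' Seeded G(n, p) generator used by the property checks on the D-measure
#' bounds (each graph drawn with its own seed for reproducibility).
#'
#' @param n Number of nodes.
#' @param p Edge probability.
#' @param seed Integer seed.
#' @return An undirected simple `igraph` graph.
#' @export
random_gnp <- function(n, p, seed) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed(igraph::sample_gnp(n, p))
}
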