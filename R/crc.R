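#' Assign transcription factors to their primary super-enhancer
#'
#' A TF gene is super-enhancer assigned when at least one SE's window (the
#' same TSS rule as [assign_genes_to_ses()]) contains its TSS. Among
#' candidate SEs the highest-signal one is the primary SE; ties break by
#' `(contig, start)` ascending. TFs without a qualifying SE are absent from
#' the result.
#'
#' @inheritParams assign_genes_to_ses
#' @return A tibble with one row per assigned TF: `tf_id`, `region_id`,
#'   `distance`, `signal`.
#' @export
assign_tf_to_se <- function(calls, genes, window = 1000) {
  tfs <- dplyr::filter(genes, .data$is_tf)
  links <- assign_genes_to_ses(calls, tfs, window)
  if (nrow(links) == 0L) {
    return(tibble::tibble(tf_id = character(), region_id = character(),
                          distance = integer(), signal = double()))
  }
  ses <- tibble::as_tibble(calls)[, c("region_id", "contig", "start")]
  links |>
    dplyr::left_join(ses, by = "region_id") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(dplyr::desc(.data$signal), .data$contig, .data$start,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(tf_id = .data$gene_id, region_id = .data$region_id,
                     distance = .data$distance, signal = .data$signal) |>
    dplyr::arrange(.data$tf_id)
}

#' Detect auto-regulated transcription factors
#'
#' A TF is auto-regulated when its own binding motif occurs at least once in
#' the extended window of its primary super-enhancer.
#'
#' @param assignments Output of [assign_tf_to_se()].
#' @param hit_counts Dense hit-count tibble from [hits_in_regions()] over
#'   the same SE universe.
#' @return Character vector of auto-regulated TF ids (sorted).
#' @export
detect_autoregulated_tfs <- function(assignments, hit_counts) {
  self <- dplyr::inner_join(
    assignments,
    hit_counts,
    by = c(tf_id = "tf_id", region_id = "region_id")
  )
  sort(self$tf_id[self$n_hits >= 1L])
}

#' Build the directed TF-to-TF motif-evidence graph
#'
#' Nodes are the auto-regulated TFs. A directed edge `i -> j` is stored when
#' the motif of `i` has at least `min_hits` occurrences in the extended
#' primary-SE window of `j`. Self-loops are carried by the auto-regulated
#' flag, not as edges.
#'
#' @param autoregulated Character vector from [detect_autoregulated_tfs()].
#' @param assignments Output of [assign_tf_to_se()].
#' @param hit_counts Dense hit counts from [hits_in_regions()].
#' @param min_hits Minimum motif occurrences supporting an edge.
#' @return A `regulatory_graph` object: list with `nodes` (tibble `tf_id`,
#'   `autoregulated`) and `edges` (tibble `from`, `to`, `n_hits`).
#' @export
build_regulatory_graph <- function(autoregulated, assignments, hit_counts,
                                   min_hits = 1) {
  nodes <- tibble::tibble(tf_id = sort(unique(autoregulated)),
                          autoregulated = TRUE)
  node_se <- assignments[assignments$tf_id %in% nodes$tf_id,
                         c("tf_id", "region_id")]
  edges <- hit_counts |>
    dplyr::filter(.data$tf_id %in% nodes$tf_id) |>
    dplyr::inner_join(node_se, by = "region_id", suffix = c("", ".target"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$tf_id != .data$tf_id.target,
                  .data$n_hits >= min_hits) |>
    dplyr::transmute(from = .data$tf_id, to = .data$tf_id.target,
                     n_hits = .data$n_hits) |>
    dplyr::arrange(.data$from, .data$to)
  structure(list(nodes = nodes, edges = edges), class = "regulatory_graph")
}

#' @export
print.regulatory_graph <- function(x, ...) {
  cat("<regulatory_graph> ", nrow(x$nodes), " auto-regulated TFs, ",
      nrow(x$edges), " directed edges\n", sep = "")
  invisible(x)
}

# Undirected igraph keeping only mutual edge pairs (i->j and j->i).
mutual_projection <- function(graph) {
  nodes <- graph$nodes$tf_id
  e <- graph$edges
  if (nrow(e)) {
    key <- paste(e$from, e$to, sep = "\r")
    rev_key <- paste(e$to, e$from, sep = "\r")
    mutual <- e[key %in% rev_key & e$from < e$to, c("from", "to")]
  } else {
    mutual <- e[integer(0), c("from", "to")]
  }
  igraph::graph_from_data_frame(mutual, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Enumerate core-regulatory-circuitry cliques
#'
#' Projects the directed graph onto its mutual (bidirectional) edges and
#' enumerates all maximal fully interconnected TF sets (maximal cliques) of
#' size two or more. CRC TFs are the union of clique members; each TF's
#' `clique_fraction` is the fraction of maximal cliques containing it.
#' Cliques are ordered by size descending, then lexicographically by member
#' list; members within a clique are sorted.
#'
#' @param graph A `regulatory_graph` from [build_regulatory_graph()].
#' @return A `crc_result` object: list with `cliques` (list of character
#'   vectors), `crc_tfs`, `clique_fraction` (tibble `tf_id`, `fraction`),
#'   `graph` (the input graph) and `expressed_crc_tfs` (`NULL` until
#'   [filter_expressed_crc_tfs()] is applied).
#' @export
enumerate_crc_cliques <- function(graph) {
  g <- mutual_projection(graph)
  cl <- igraph::max_cliques(g, min = 2L)
  cliques <- lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
  if (length(cliques)) {
    ord <- order(-lengths(cliques),
                 vapply(cliques, paste, "", collapse = "\r"))
    cliques <- cliques[ord]
  }
  crc_tfs <- sort(unique(as.character(unlist(cliques))))
  fraction <- if (length(cliques)) {
    tab <- table(unlist(cliques)) / length(cliques)
    tibble::tibble(tf_id = names(tab), fraction = as.numeric(tab)) |>
      dplyr::arrange(.data$tf_id)
  } else {
    tibble::tibble(tf_id = character(), fraction = double())
  }
  structure(
    list(cliques = cliques, crc_tfs = crc_tfs, clique_fraction = fraction,
         graph = graph, expressed_crc_tfs = NULL),
    class = "crc_result"
  )
}

#' @export
print.crc_result <- function(x, ...) {
  cat("<crc_result> ", length(x$cliques), " maximal clique(s), ",
      length(x$crc_tfs), " CRC TF(s)\n", sep = "")
  for (cl in x$cliques) cat("  {", paste(cl, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Filter CRC transcription factors by expression
#'
#' Keeps the CRC TFs with expression at or above `threshold` in the given
#' sample (master TF candidates must be highly expressed). TFs missing from
#' the table are treated as expression 0 with a warning.
#'
#' @param crc A `crc_result`.
#' @param expression Expression tibble from [read_expression()].
#' @param sample_id Column of `expression` to use.
#' @param threshold Minimum expression (TPM-like).
#' @return `crc` with `expressed_crc_tfs` filled in.
#' @export
filter_expressed_crc_tfs <- function(crc, expression, sample_id,
                                     threshold = 10) {
  if (!sample_id %in% names(expression)) {
    stop("expression table has no column '", sample_id, "'", call. = FALSE)
  }
  vals <- expression[[sample_id]][match(crc$crc_tfs, expression$gene_id)]
  missing <- is.na(vals)
  if (any(missing)) {
    warning("TF(s) absent from expression table treated as 0: ",
            paste(crc$crc_tfs[missing], collapse = ", "), call. = FALSE)
    vals[missing] <- 0
  }
  crc$expressed_crc_tfs <- crc$crc_tfs[vals >= threshold]
  crc
}

#' Infer target genes of the core regulatory circuitry
#'
#' A gene is a CRC target when at least one super-enhancer linked to it has
#' motif evidence from `min_distinct_tfs` or more distinct CRC TFs in its
#' extended window (or that many total occurrences when
#' `count_total = TRUE`).
#'
#' @param se_gene_links Links from [assign_genes_to_ses()].
#' @param hit_counts Dense hit counts from [hits_in_regions()] over the same
#'   SE universe.
#' @param crc_tfs Character vector of CRC TF ids.
#' @param min_distinct_tfs Minimum number of distinct CRC TFs with at least
#'   one hit (default 3).
#' @param count_total Count total motif occurrences instead of distinct TFs.
#' @return Sorted character vector of target gene ids.
#' @export
infer_crc_targets <- function(se_gene_links, hit_counts, crc_tfs,
                              min_distinct_tfs = 3, count_total = FALSE) {
  per_se <- hit_counts |>
    dplyr::filter(.data$tf_id %in% crc_tfs, .data$n_hits >= 1L) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(score = if (count_total) sum(.data$n_hits) else dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$score >= min_distinct_tfs)
  sort(unique(se_gene_links$gene_id[se_gene_links$region_id %in% per_se$region_id]))
}

#' Build the core regulatory circuitry for one sample
#'
#' Convenience wrapper running TF-to-SE assignment, motif-hit counting,
#' auto-regulation detection, graph construction and clique enumeration, and
#' (when an expression table is given) the expression filter.
#'
#' @param calls `enhancer_calls` tibble for the sample.
#' @param genes Gene tibble.
#' @param motifs Named list of `pwm_motif`; names must match TF `gene_id`s.
#' @param genome Named character vector of contig sequences.
#' @param expression,sample_id Optional expression table and sample column
#'   for [filter_expressed_crc_tfs()].
#' @param window TSS assignment window (bp).
#' @param extension Scanning extension (bp).
#' @param p_threshold Exact motif p-value threshold.
#' @param min_hits Minimum occurrences supporting a graph edge.
#' @param expression_threshold Minimum expression for a master TF candidate.
#' @param thresholds Optional precomputed [score_threshold()] results.
#' @return A `crc_result` with additional fields `assignments`, `hit_counts`
#'   and `links` attached.
#' @export
build_crc <- function(calls, genes, motifs, genome,
                      expression = NULL, sample_id = NULL,
                      window = 1000, extension = 500, p_threshold = 1e-4,
                      min_hits = 1, expression_threshold = 10,
                      thresholds = NULL) {
  assignments <- assign_tf_to_se(calls, genes, window)
  hit_counts <- hits_in_regions(motifs, calls, genome, extension,
                                p_threshold, thresholds)
  auto <- detect_autoregulated_tfs(assignments, hit_counts)
  graph <- build_regulatory_graph(auto, assignments, hit_counts, min_hits)
  crc <- enumerate_crc_cliques(graph)
  if (!is.null(expression) && !is.null(sample_id)) {
    crc <- filter_expressed_crc_tfs(crc, expression, sample_id,
                                    expression_threshold)
  }
  crc$assignments <- assignments
  crc$hit_counts <- hit_counts
  crc$links <- assign_genes_to_ses(calls, genes, window)
  crc
}

#' Undirected mutual-edge CRC graph for network comparison
#'
#' The CRC identity used for structural comparison: the undirected
#' mutual-edge subgraph induced on the CRC TFs (self-loops dropped).
#'
#' @param crc A `crc_result`.
#' @return An undirected simple `igraph` graph.
#' @export
crc_graph <- function(crc) {
  g <- mutual_projection(crc$graph)
  igraph::induced_subgraph(g, which(igraph::V(g)$name %in% crc$crc_tfs))
}
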