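#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a CRC result into a clique-membership table
#'
#' @param x A `crc_result`.
#' @param ... Ignored.
#' @return A tibble with one row per (clique, TF): `clique`, `size`,
#'   `tf_id`, `clique_fraction`, `expressed` (NA until the expression filter
#'   has run).
#' @export
tidy.crc_result <- function(x, ...) {
  if (!length(x$cliques)) {
    return(tibble::tibble(clique = integer(), size = integer(),
                          tf_id = character(), clique_fraction = double(),
                          expressed = logical()))
  }
  purrr::imap(x$cliques, function(members, i) {
    tibble::tibble(clique = i, size = length(members), tf_id = members)
  }) |>
    dplyr::bind_rows() |>
    dplyr::left_join(x$clique_fraction, by = "tf_id") |>
    dplyr::rename(clique_fraction = "fraction") |>
    dplyr::mutate(expressed = if (is.null(x$expressed_crc_tfs)) NA else
      .data$tf_id %in% x$expressed_crc_tfs)
}

#' One-row summary of a CRC result
#'
#' @param x A `crc_result`.
#' @param ... Ignored.
#' @return A one-row tibble: `n_tfs` (graph nodes), `n_edges`, `n_cliques`,
#'   `n_crc_tfs`, `n_expressed`, `max_clique_size`.
#' @export
glance.crc_result <- function(x, ...) {
  tibble::tibble(
    n_tfs = nrow(x$graph$nodes),
    n_edges = nrow(x$graph$edges),
    n_cliques = length(x$cliques),
    n_crc_tfs = length(x$crc_tfs),
    n_expressed = if (is.null(x$expressed_crc_tfs)) NA_integer_
                  else length(x$expressed_crc_tfs),
    max_clique_size = if (length(x$cliques)) max(lengths(x$cliques)) else 0L
  )
}

#' Tidy a pairwise dissimilarity object into long form
#'
#' @param x A `crc_dissimilarity`.
#' @param ... Ignored.
#' @return A tibble with `sample1`, `sample2`, `D`, `S` (all ordered pairs).
#' @export
tidy.crc_dissimilarity <- function(x, ...) {
  ids <- rownames(x$D)
  tidyr::expand_grid(sample1 = ids, sample2 = ids) |>
    dplyr::mutate(D = as.vector(t(x$D)), S = 1 - .data$D)
}

#' One-row summary of a pairwise dissimilarity object
#'
#' @param x A `crc_dissimilarity`.
#' @param ... Ignored.
#' @return A one-row tibble: `n_samples`, `min_d`, `max_d`, `mean_d` over
#'   off-diagonal pairs.
#' @export
glance.crc_dissimilarity <- function(x, ...) {
  off <- x$D[row(x$D) != col(x$D)]
  tibble::tibble(n_samples = nrow(x$D), min_d = min(off), max_d = max(off),
                 mean_d = mean(off))
}

#' Tidy sample clustering labels
#'
#' @param x A `sample_clustering`.
#' @param ... Ignored.
#' @return The `labels` tibble (`sample`, `group`).
#' @export
tidy.sample_clustering <- function(x, ...) x$labels

#' One-row summary of a sample clustering
#'
#' @param x A `sample_clustering`.
#' @param ... Ignored.
#' @return A one-row tibble: `n_samples`, `k`, `merge_height` (height of the
#'   final retained merge).
#' @export
glance.sample_clustering <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$labels), k = x$k,
                 merge_height = max(x$hclust$height))
}

#' @importFrom rlang .data
NULL
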