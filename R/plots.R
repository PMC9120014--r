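#' Hockey-stick plot of ranked enhancer signal
#'
#' The classic rank-ordering diagnostic: regions ordered by increasing
#' signal, super-enhancers highlighted above the tangent cutoff.
#'
#' @param calls `enhancer_calls` tibble from [call_enhancers()].
#' @return A ggplot object.
#' @export
plot_enhancer_ranks <- function(calls) {
  df <- tibble::as_tibble(calls)
  df$asc_rank <- nrow(df) - df$rank + 1L
  cutoff <- attr(calls, "cutoff")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$asc_rank, y = .data$signal,
                                        colour = .data$class)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(SE = "#d62728", TE = "#7f7f7f")) +
    ggplot2::labs(x = "enhancer rank (increasing signal)",
                  y = "background-corrected signal", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' @rdname plot_enhancer_ranks
#' @param object,... `enhancer_calls` object and ignored extra arguments.
#' @export
autoplot.enhancer_calls <- function(object, ...) plot_enhancer_ranks(object)

#' Heatmap of the pairwise D matrix
#'
#' @param object A `crc_dissimilarity`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.crc_dissimilarity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample1, y = .data$sample2,
                                   fill = .data$D)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#d62728") +
    ggplot2::labs(x = NULL, y = NULL, fill = "D") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dendrogram of the sample clustering
#'
#' @param object A `sample_clustering`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sample_clustering <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$order)
  leaf_x <- stats::setNames(seq_len(n), hc$order)
  # x position and height of each merge node
  node_x <- numeric(nrow(hc$merge))
  segs <- list()
  pos <- function(id) {
    if (id < 0) c(leaf_x[[as.character(-id)]], 0) else c(node_x[id], hc$height[id])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2])
    h <- hc$height[i]
    node_x[i] <- (a[1] + b[1]) / 2
    segs[[length(segs) + 1L]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], h, h), yend = c(h, h, b[2])
    )
  }
  segs <- dplyr::bind_rows(segs)
  labels <- tibble::tibble(x = seq_len(n), label = hc$labels[hc$order]) |>
    dplyr::left_join(object$labels, by = c(label = "sample"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = labels,
                       ggplot2::aes(x = .data$x, y = 0, label = .data$label,
                                    colour = factor(.data$group)),
                       angle = 90, hjust = 1.1, show.legend = FALSE) +
    ggplot2::scale_y_continuous("dissimilarity (D)",
                                expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}
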