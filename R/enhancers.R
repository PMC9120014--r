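#' Stitch peaks into candidate enhancer regions
#'
#' Merges peaks on the same contig that are connected by a chain of gaps no
#' larger than `stitch_distance` (the rank-ordering convention; gap between
#' half-open intervals `[a,b)` and `[c,d)` is `c - b`, so abutting or
#' overlapping peaks always merge). Peaks overlapping a TSS-exclusion
#' interval never bridge regions: they form their own single-peak region and
#' break the chain on both sides.
#'
#' @param peaks Peak tibble (see [read_peaks()]).
#' @param stitch_distance Maximum gap in bp bridged by stitching.
#' @param tss_exclusion Optional tibble of intervals (`contig`, `start`,
#'   `end`); peaks overlapping any of them do not bridge.
#' @return A tibble of stitched regions with columns `contig`, `start`,
#'   `end`, `region_id`, `n_constituents` and a list-column `constituents`
#'   of the member peak names, sorted by `(contig, start)`.
#' @examples
#' peaks <- tibble::tibble(contig = "chr1", start = c(0L, 10000L),
#'                         end = c(100L, 10100L),
#'                         name = c("p1", "p2"), mark = "H3K27ac")
#' stitch_peaks(peaks, stitch_distance = 12500)
#' @export
stitch_peaks <- function(peaks, stitch_distance = 12500, tss_exclusion = NULL) {
  stopifnot(stitch_distance >= 0)
  if (nrow(peaks) == 0L) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), region_id = character(),
                          n_constituents = integer(),
                          constituents = list()))
  }
  p <- dplyr::arrange(peaks, .data$contig, .data$start, .data$end)
  excluded <- rep(FALSE, nrow(p))
  if (!is.null(tss_exclusion) && nrow(tss_exclusion) > 0L) {
    excluded <- overlaps_any(p, tss_exclusion)
  }
  p$.excluded <- excluded
  regions <- p |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(
      .gap_break = .data$start - cummax_lag_end(.data$end) > stitch_distance,
      .break = .data$.gap_break | .data$.excluded | dplyr::lag(.data$.excluded, default = FALSE),
      .grp = cumsum(.data$.break)
    ) |>
    dplyr::group_by(.data$contig, .data$.grp) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_constituents = dplyr::n(),
      constituents = list(.data$name),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$contig, .data$start) |>
    dplyr::select(-".grp")
  regions$region_id <- sprintf("region_%04d", seq_len(nrow(regions)))
  dplyr::relocate(regions, "region_id", .after = "end")
}

# Running maximum of previous ends; -Inf for the first peak so it always
# starts a region.
cummax_lag_end <- function(end) {
  if (length(end) == 1L) return(-Inf)
  c(-Inf, cummax(end)[-length(end)])
}

# For each row of x, TRUE if it overlaps (>= 1 bp) any interval of y on the
# same contig. Desk-scale all-pairs join per contig.
overlaps_any <- function(x, y) {
  if (nrow(x) == 0L || nrow(y) == 0L) return(rep(FALSE, nrow(x)))
  xi <- dplyr::mutate(x[, c("contig", "start", "end")], .row = dplyr::row_number())
  hits <- dplyr::inner_join(xi, y[, c("contig", "start", "end")],
                            by = "contig", relationship = "many-to-many",
                            suffix = c("", ".y")) |>
    dplyr::filter(.data$start < .data$end.y, .data$start.y < .data$end)
  out <- rep(FALSE, nrow(x))
  out[unique(hits$.row)] <- TRUE
  out
}

#' Score stitched regions against a signal track
#'
#' Region signal is the sum over intersecting runs of
#' `value * overlapping_bp`; base pairs not covered by the track contribute
#' zero. With a control track, the control signal over the region is
#' subtracted and the result floored at zero.
#'
#' @param regions Stitched-region tibble from [stitch_peaks()] (any tibble
#'   with `contig`, `start`, `end` works).
#' @param signal Signal tibble from [read_bedgraph()].
#' @param control Optional control signal tibble (same format).
#' @return `regions` with an added `signal` column.
#' @export
score_regions <- function(regions, signal, control = NULL) {
  s <- region_track_sum(regions, signal)
  if (!is.null(control)) {
    s <- pmax(0, s - region_track_sum(regions, control))
  }
  dplyr::mutate(regions, signal = s)
}

region_track_sum <- function(regions, track) {
  if (nrow(regions) == 0L) return(numeric(0))
  if (nrow(track) == 0L) return(rep(0, nrow(regions)))
  ri <- dplyr::mutate(regions[, c("contig", "start", "end")],
                      .row = dplyr::row_number())
  joined <- dplyr::inner_join(ri, track, by = "contig",
                              relationship = "many-to-many",
                              suffix = c("", ".t")) |>
    dplyr::filter(.data$start < .data$end.t, .data$start.t < .data$end) |>
    dplyr::mutate(.bp = pmin(.data$end, .data$end.t) - pmax(.data$start, .data$start.t)) |>
    dplyr::group_by(.data$.row) |>
    dplyr::summarise(.sum = sum(.data$value * .data$.bp), .groups = "drop")
  out <- rep(0, nrow(regions))
  out[joined$.row] <- joined$.sum
  out
}

#' Find the super-enhancer signal cutoff
#'
#' Implements the rank-ordering tangent rule: sort signals ascending, scale
#' rank and signal each to `[0, 1]`, and scan from low to high rank for the
#' first point whose forward finite-difference slope exceeds 1. The cutoff
#' is the (unscaled) signal at that point; super-enhancers are the regions
#' with signal strictly greater than the cutoff. Degenerate inputs (a single
#' region, or all signals equal) yield zero super-enhancers.
#'
#' @param signals Numeric vector of region signals.
#' @return A list with `cutoff` (signal value) and `se_idx` (indices into
#'   `signals` classified as super-enhancers).
#' @examples
#' find_se_cutoff(c(1, 1, 1, 1, 100))
#' @export
find_se_cutoff <- function(signals) {
  stopifnot(length(signals) >= 1L)
  n <- length(signals)
  if (n == 1L || diff(range(signals)) == 0) {
    return(list(cutoff = max(signals), se_idx = integer(0)))
  }
  y <- sort(signals)
  ys <- (y - y[1L]) / (y[n] - y[1L])
  # scaled x spacing is 1/(n-1), so slope_i = (ys[i+1] - ys[i]) * (n - 1)
  slope <- diff(ys) * (n - 1L)
  i <- which(slope > 1)[1L]
  if (is.na(i)) {
    return(list(cutoff = max(signals), se_idx = integer(0)))
  }
  cutoff <- y[i]
  list(cutoff = cutoff, se_idx = which(signals > cutoff))
}

#' Call super-enhancers and typical enhancers
#'
#' Runs the full rank-ordering procedure: stitch peaks, score the stitched
#' regions against the (optionally control-corrected) signal track, find the
#' tangent cutoff, and classify each region as super-enhancer (`"SE"`) or
#' typical enhancer (`"TE"`). Rank 1 is the highest-signal region.
#'
#' @inheritParams stitch_peaks
#' @inheritParams score_regions
#' @return An `enhancer_calls` tibble: the stitched regions plus `signal`,
#'   `rank` and `class` columns, ordered by rank. The cutoff signal is
#'   attached as attribute `"cutoff"`.
#' @export
call_enhancers <- function(peaks, signal, control = NULL,
                           stitch_distance = 12500, tss_exclusion = NULL) {
  regions <- stitch_peaks(peaks, stitch_distance, tss_exclusion)
  scored <- score_regions(regions, signal, control)
  cut <- find_se_cutoff(scored$signal)
  scored$class <- ifelse(seq_len(nrow(scored)) %in% cut$se_idx, "SE", "TE")
  # rank 1 = highest signal; ties broken by (contig, start) for determinism
  ord <- order(-scored$signal, scored$contig, scored$start)
  scored$rank <- integer(nrow(scored))
  scored$rank[ord] <- seq_len(nrow(scored))
  out <- dplyr::arrange(scored, .data$rank)
  attr(out, "cutoff") <- cut$cutoff
  class(out) <- c("enhancer_calls", class(out))
  out
}

#' Assign genes to super-enhancers by TSS proximity
#'
#' A gene links to a super-enhancer when its TSS lies in
#' `[start - window, end + window)` (half-open on the right). The distance is
#' 0 for a TSS inside the region and otherwise the base-pair offset to the
#' nearest covered base.
#'
#' @param calls `enhancer_calls` tibble from [call_enhancers()] (only the SE
#'   class is used).
#' @param genes Gene tibble from [read_gene_table()].
#' @param window Assignment window in bp on each side of the region.
#' @return A tibble with columns `region_id`, `gene_id`, `symbol`,
#'   `distance` (bp), `signal`; one row per (SE, gene) link.
#' @export
assign_genes_to_ses <- function(calls, genes, window = 1000) {
  ses <- dplyr::filter(tibble::as_tibble(calls), .data$class == "SE")
  if (nrow(ses) == 0L || nrow(genes) == 0L) {
    return(tibble::tibble(region_id = character(), gene_id = character(),
                          symbol = character(), distance = integer(),
                          signal = double()))
  }
  dplyr::inner_join(
    ses[, c("region_id", "contig", "start", "end", "signal")],
    genes[, c("gene_id", "symbol", "contig", "tss")],
    by = "contig", relationship = "many-to-many"
  ) |>
    dplyr::mutate(distance = pmax(0L, .data$start - .data$tss,
                                  .data$tss - (.data$end - 1L))) |>
    dplyr::filter(.data$distance <= window) |>
    dplyr::arrange(.data$region_id, .data$gene_id) |>
    dplyr::select("region_id", "gene_id", "symbol", "distance", "signal")
}

#' Super-enhancer versus typical-enhancer binding statistics
#'
#' Counts how many of a transcription factor's binding peaks overlap (by at
#' least 1 bp) each enhancer class. A peak overlapping both classes counts
#' for both. Densities are hits per megabase of total class span, and
#' `ratio` is `density_se / density_te` (infinite when the TE span is zero).
#'
#' @param tf_peaks Peak tibble of TF binding sites.
#' @param calls `enhancer_calls` tibble.
#' @return A one-row tibble with `n_hits_se`, `n_hits_te`, `frac_se`,
#'   `frac_te`, `density_se`, `density_te`, `ratio`.
#' @export
se_te_overlap_stats <- function(tf_peaks, calls) {
  calls <- tibble::as_tibble(calls)
  se <- dplyr::filter(calls, .data$class == "SE")
  te <- dplyr::filter(calls, .data$class == "TE")
  n_total <- nrow(tf_peaks)
  n_se <- sum(overlaps_any(tf_peaks, se))
  n_te <- sum(overlaps_any(tf_peaks, te))
  span_mb <- function(x) sum(as.numeric(x$end - x$start)) / 1e6
  se_mb <- span_mb(se)
  te_mb <- span_mb(te)
  density_se <- if (se_mb > 0) n_se / se_mb else 0
  density_te <- if (te_mb > 0) n_te / te_mb else 0
  ratio <- if (te_mb == 0 || density_te == 0) Inf else density_se / density_te
  tibble::tibble(
    n_hits_se = n_se, n_hits_te = n_te,
    frac_se = if (n_total) n_se / n_total else 0,
    frac_te = if (n_total) n_te / n_total else 0,
    density_se = density_se, density_te = density_te,
    ratio = ratio
  )
}

#' Rank broad histone domains by width
#'
#' Ranks peaks by width descending (ties broken by `(contig, start)`) and
#' flags the widest `ceiling(broad_fraction * N)` as broad domains. Broad
#' H3K4me3 domains are used as markers of cell-identity genes.
#'
#' @param peaks Peak tibble (typically H3K4me3).
#' @param broad_fraction Fraction of peaks to flag, in `(0, 1]`.
#' @return `peaks` with added `width`, `width_rank` and `is_broad` columns,
#'   ordered by `width_rank`.
#' @export
rank_broad_domains <- function(peaks, broad_fraction = 0.05) {
  if (!is.numeric(broad_fraction) || broad_fraction <= 0 || broad_fraction > 1) {
    stop("broad_fraction must be in (0, 1]", call. = FALSE)
  }
  stopifnot(nrow(peaks) >= 1L)
  out <- peaks |>
    dplyr::mutate(width = .data$end - .data$start)
  ord <- order(-out$width, out$contig, out$start)
  out$width_rank <- integer(nrow(out))
  out$width_rank[ord] <- seq_len(nrow(out))
  n_broad <- ceiling(broad_fraction * nrow(out))
  out$is_broad <- out$width_rank <= n_broad
  dplyr::arrange(out, .data$width_rank)
}
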