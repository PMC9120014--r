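#' Extend regions symmetrically, clamped to contig bounds
#'
#' Motif scanning operates on super-enhancer regions extended 500 bp both
#' upstream and downstream; the extension is clamped to `[0, contig_length)`.
#'
#' @param regions Tibble with `contig`, `start`, `end`.
#' @param extension Extension in bp on each side.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return `regions` with `start`/`end` replaced by the extended, clamped
#'   coordinates.
#' @export
extend_regions <- function(regions, extension = 500, contig_lengths) {
  stopifnot(extension >= 0)
  dplyr::mutate(
    regions,
    start = pmax(0L, as.integer(.data$start - extension)),
    end = pmin(as.integer(unname(contig_lengths[.data$contig])),
               as.integer(.data$end + extension))
  )
}

# Per-position log-odds matrix in natural-log units, 5 rows (N, A, C, G, T)
# by motif length; N scores 0 (background). Pseudocount smoothing:
# p' = (p + c) / (1 + 4c).
motif_lod <- function(motif) {
  c <- motif$pseudocount
  p <- (motif$mat + c) / (1 + 4 * c)
  lod <- log(sweep(p, 2L, motif$background, "/"))
  rbind(N = 0, t(lod))  # 5 x L; row 1 = N
}

#' Exact null score distribution of a motif
#'
#' Computes the exact distribution of the log-odds score of a random
#' background sequence of motif length, by position-wise convolution over
#' scores discretized to a fixed step. This reproduces the exact p-value
#' semantics of standard PWM scanners.
#'
#' @param motif A `pwm_motif`.
#' @param step Discretization step in natural-log-odds units.
#' @return A list with `step`, `support` (integer score bins) and `prob`
#'   (probabilities summing to 1).
#' @export
motif_score_distribution <- function(motif, step = 1e-3) {
  lod <- motif_lod(motif)[-1L, , drop = FALSE]  # 4 x L, A/C/G/T
  L <- ncol(lod)
  bins <- round(lod / step)
  bg <- motif$background
  # the null distribution depends only on the per-position multiset of
  # (score bin, background probability) pairs, so structurally identical
  # motifs share one convolution
  pos_keys <- lapply(seq_len(L), function(j) {
    m <- cbind(bins[, j], signif(unname(bg), 12))
    m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  })
  key <- rlang::hash(list(pos_keys, step))
  cached <- .dist_cache[[key]]
  if (!is.null(cached)) return(cached)
  # dist: named-by-offset probability vector, held as a dense array over
  # [min_sum, max_sum] integer bins
  lo <- 0L; hi <- 0L
  prob <- 1
  offset <- 0L  # prob[k] is probability of bin (lo + k - 1)
  for (j in seq_len(L)) {
    b <- bins[, j]
    new_lo <- lo + min(b)
    new_hi <- hi + max(b)
    new_prob <- numeric(new_hi - new_lo + 1L)
    for (a in 1:4) {
      idx <- (lo + b[a] - new_lo + 1L):(hi + b[a] - new_lo + 1L)
      new_prob[idx] <- new_prob[idx] + prob * bg[a]
    }
    prob <- new_prob; lo <- new_lo; hi <- new_hi
  }
  keep <- prob > 0
  support <- (lo:hi)[keep]
  out <- list(step = step, support = support, prob = unname(prob[keep]))
  .dist_cache[[key]] <- out
  out
}

# Session-level memo of null-score convolutions.
.dist_cache <- new.env(parent = emptyenv())

#' Score threshold for a motif at an exact p-value
#'
#' The threshold is the smallest discretized score `s` with
#' `P(score >= s) <= p_threshold` under the background model. When no
#' attainable score is that improbable (very short or uninformative motifs),
#' the threshold is set just above the maximum attainable score and
#' `unattainable` is flagged, so scanning returns no hits.
#'
#' @param motif A `pwm_motif`.
#' @param p_threshold Exact p-value threshold in `(0, 1]`.
#' @param step Discretization step passed to [motif_score_distribution()].
#' @return A list with `threshold` (natural-log-odds units), `p_actual`
#'   (exact p-value at the threshold), `distribution` and `unattainable`.
#' @export
score_threshold <- function(motif, p_threshold = 1e-4, step = 1e-3) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  dist <- motif_score_distribution(motif, step)
  tail_p <- rev(cumsum(rev(dist$prob)))  # P(score >= support[i])
  ok <- which(tail_p <= p_threshold)
  if (length(ok) == 0L) {
    max_score <- max(dist$support) * step
    warning("motif ", motif$tf_id, ": no score attains p <= ", p_threshold,
            "; threshold set above the maximum score", call. = FALSE)
    return(list(threshold = max_score + step, p_actual = NA_real_,
                distribution = dist, unattainable = TRUE))
  }
  i <- ok[1L]
  list(threshold = dist$support[i] * step, p_actual = tail_p[i],
       distribution = dist, unattainable = FALSE)
}

# Exact p-value P(score >= bin) of integer score bins under a
# motif_score_distribution.
bin_pvalue <- function(bins, dist) {
  tail_p <- rev(cumsum(rev(dist$prob)))
  out <- numeric(length(bins))
  below <- bins <= dist$support[1L]
  out[below] <- 1
  above <- bins > dist$support[length(dist$support)]
  out[above] <- 0
  mid <- !below & !above
  if (any(mid)) {
    # smallest support index with support >= bin
    j <- findInterval(bins[mid] - 1L, dist$support) + 1L
    out[mid] <- tail_p[j]
  }
  out
}

# Encode DNA as integers: N/other = 1, A = 2, C = 3, G = 4, T = 5
# (matching motif_lod row order).
encode_dna <- function(seq) {
  codes <- match(strsplit(seq, NULL)[[1L]], c("A", "C", "G", "T")) + 1L
  codes[is.na(codes)] <- 1L
  codes
}

#' Scan a sequence for motif occurrences
#'
#' Scores every window of motif length with the natural-log-odds sum
#' `sum(log(p'_base / background_base))`; `N` bases contribute 0. With
#' `both_strands`, the reverse complement is scanned too and hits are
#' reported in forward-strand coordinates with `strand = "-"`. Hits are the
#' windows scoring at or above `threshold`.
#'
#' @param motif A `pwm_motif`.
#' @param seq Sequence string over A, C, G, T, N.
#' @param threshold Score threshold (see [score_threshold()]); a list as
#'   returned by that function is also accepted.
#' @param both_strands Scan the reverse strand as well.
#' @param contig,offset Genomic context of `seq`: hits are reported on
#'   `contig` with `start = offset + window_position`.
#' @return A tibble with `tf_id`, `contig`, `start`, `end`, `strand`,
#'   `score`, `p_value`, sorted by `(start, strand)`.
#' @export
scan_sequence <- function(motif, seq, threshold, both_strands = TRUE,
                          contig = "seq", offset = 0L) {
  dist <- NULL
  if (is.list(threshold)) {
    dist <- threshold$distribution
    threshold <- threshold$threshold
  }
  L <- nrow(motif$mat)
  n <- nchar(seq)
  empty <- tibble::tibble(tf_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          strand = character(), score = double(),
                          p_value = double())
  if (n < L) return(empty)
  lod <- motif_lod(motif)
  # Thresholding and p-values use the same per-position discretization as
  # the null distribution, so the reported hit set is exactly consistent
  # with the exact p-value machinery; the real-valued score is reported.
  bin_lod <- if (!is.null(dist)) round(lod / dist$step) else NULL
  one_strand <- function(codes, strand_pos) {
    sc <- window_scores(codes, lod)
    bn <- if (is.null(bin_lod)) rep(NA_integer_, length(sc)) else
      window_scores(codes, bin_lod)
    tibble::tibble(pos = strand_pos(seq_along(sc)), score = sc, bin = bn)
  }
  fwd <- one_strand(encode_dna(seq), function(i) i)
  fwd$strand <- if (nrow(fwd)) "+" else character(0)
  res <- list(fwd)
  if (both_strands) {
    # window starting at position i (1-based) of the reverse complement
    # covers forward positions (n - i - L + 2) .. (n - i + 1)
    rev_tab <- one_strand(encode_dna(reverse_complement(seq)),
                          function(i) n - i - L + 2L)
    rev_tab$strand <- if (nrow(rev_tab)) "-" else character(0)
    res[[2L]] <- rev_tab
  }
  hits <- dplyr::bind_rows(res)
  if (is.null(dist)) {
    hits <- dplyr::filter(hits, .data$score >= threshold - 1e-9)
  } else {
    thr_bin <- round(threshold / dist$step)
    hits <- dplyr::filter(hits, .data$bin >= thr_bin)
  }
  if (nrow(hits) == 0L) return(empty)
  hits |>
    dplyr::transmute(
      tf_id = motif$tf_id,
      contig = contig,
      start = as.integer(offset + .data$pos - 1L),
      end = as.integer(offset + .data$pos - 1L + L),
      strand = .data$strand,
      score = .data$score,
      p_value = if (is.null(dist)) NA_real_ else bin_pvalue(.data$bin, dist)
    ) |>
    dplyr::arrange(.data$start, .data$strand)
}

# Scores of all length-L windows of an encoded sequence under a 5 x L
# log-odds matrix (row 1 = N = 0).
window_scores <- function(codes, lod) {
  L <- ncol(lod)
  n <- length(codes)
  n_win <- n - L + 1L
  if (n_win < 1L) return(numeric(0))
  out <- numeric(n_win)
  for (j in seq_len(L)) {
    out <- out + lod[codes[j:(j + n_win - 1L)], j]
  }
  out
}

#' Count motif hits in extended super-enhancer windows
#'
#' Extends each super-enhancer region by `extension` bp on both sides
#' (clamped to the contig), extracts its sequence, and scans every motif at
#' its exact p-value threshold. The mapping is dense: (motif, region) pairs
#' with zero hits are retained.
#'
#' @param motifs Named list of `pwm_motif` objects.
#' @param calls `enhancer_calls` tibble; only `class == "SE"` rows are
#'   scanned.
#' @param genome Named character vector of contig sequences.
#' @param extension Extension in bp (scanning window = region +/- extension).
#' @param p_threshold Exact p-value threshold per motif.
#' @param thresholds Optional precomputed list of [score_threshold()] results
#'   named by motif id (avoids recomputing distributions across samples).
#' @return A tibble with `tf_id`, `region_id`, `n_hits`.
#' @export
hits_in_regions <- function(motifs, calls, genome, extension = 500,
                            p_threshold = 1e-4, thresholds = NULL) {
  ses <- dplyr::filter(tibble::as_tibble(calls), .data$class == "SE")
  if (is.null(thresholds)) {
    thresholds <- lapply(motifs, score_threshold, p_threshold = p_threshold)
  }
  if (nrow(ses) == 0L || length(motifs) == 0L) {
    return(tibble::tibble(tf_id = character(), region_id = character(),
                          n_hits = integer()))
  }
  windows <- extend_regions(ses, extension, contig_lengths = nchar(genome))
  seqs <- extract_sequences(genome, windows)
  # encode each window (and its reverse complement) once, then count hits
  # per motif with integer-bin window scores only
  fwd_codes <- lapply(seqs, encode_dna)
  rev_codes <- lapply(reverse_complement(seqs), encode_dna)
  counts <- purrr::map(names(motifs), function(id) {
    thr <- thresholds[[id]]
    dist <- thr$distribution
    bin_lod <- round(motif_lod(motifs[[id]]) / dist$step)
    thr_bin <- round(thr$threshold / dist$step)
    n_hits <- vapply(seq_along(seqs), function(i) {
      as.integer(sum(window_scores(fwd_codes[[i]], bin_lod) >= thr_bin) +
                   sum(window_scores(rev_codes[[i]], bin_lod) >= thr_bin))
    }, integer(1))
    tibble::tibble(tf_id = id, region_id = windows$region_id, n_hits = n_hits)
  })
  dplyr::bind_rows(counts)
}
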