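#' Specification for a synthetic enhancer-landscape cohort
#'
#' Defines the study conditions of a desk-scale cohort with planted ground
#' truth: a small multi-contig genome, genes with TSSs, TFs with informative
#' motifs, background enhancer peaks, and for each sample group a planted
#' fully interconnected auto-regulatory clique whose member TFs carry
#' high-signal "super" peak clusters near their TSSs. Group identity is
#' carried by which regions are super-enhancers in a sample: all planted
#' motif occurrences live in one shared cohort genome, in group-disjoint
#' regions, so scanning is sample-agnostic while SE landscapes differ.
#'
#' @param seed Integer master seed; all cohort randomness derives from it.
#' @param n_contigs,contig_length Genome shape (contigs of `contig_length` bp).
#' @param n_genes,n_tfs Number of genes, of which the first `n_tfs` are TFs.
#' @param motif_length Motif width in bp.
#' @param n_background_peaks Background peaks per sample, laid out as
#'   clusters of up to 4 peaks separated by more than `stitch_distance` so
#'   background regions have comparable signal and never chain into the
#'   planted regions.
#' @param background_signal_mean,background_signal_sd Per-peak signal level
#'   (signal units per bp), normal truncated at zero.
#' @param super_signal_multiplier Signal multiplier of planted super peaks
#'   (must be > 1).
#' @param planted_cliques Named list (one element per group) of TF-id sets;
#'   each set is planted as a fully interconnected auto-regulatory clique.
#'   The default cliques have different sizes because the structural
#'   D-measure ignores node identity: equal-size cliques would be
#'   indistinguishable.
#' @param n_samples_per_group Samples per group.
#' @param motif_planting_rate Planted occurrences per SE per clique edge.
#' @param expression_high,expression_low TPM-like expression of clique TFs
#'   in their own group / in other groups.
#' @param peak_width Width of each generated peak in bp.
#' @param stitch_distance Stitch distance the layout guards against (the
#'   rank-ordering default).
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_contigs = 2L,
                           contig_length = 300000L,
                           n_genes = 60L,
                           n_tfs = 12L,
                           motif_length = 8L,
                           n_background_peaks = 80L,
                           background_signal_mean = 10,
                           background_signal_sd = 2,
                           super_signal_multiplier = 20,
                           planted_cliques = list(
                             A = c("TF01", "TF02", "TF03"),
                             B = c("TF04", "TF05", "TF06", "TF07")
                           ),
                           n_samples_per_group = 3L,
                           motif_planting_rate = 2L,
                           expression_high = 50,
                           expression_low = 1,
                           peak_width = 1000L,
                           stitch_distance = 12500L) {
  spec <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length), n_genes = as.integer(n_genes),
    n_tfs = as.integer(n_tfs), motif_length = as.integer(motif_length),
    n_background_peaks = as.integer(n_background_peaks),
    background_signal_mean = background_signal_mean,
    background_signal_sd = background_signal_sd,
    super_signal_multiplier = super_signal_multiplier,
    planted_cliques = planted_cliques,
    n_samples_per_group = as.integer(n_samples_per_group),
    motif_planting_rate = as.integer(motif_planting_rate),
    expression_high = expression_high, expression_low = expression_low,
    peak_width = as.integer(peak_width),
    stitch_distance = as.integer(stitch_distance)
  )
  if (spec$n_genes < spec$n_tfs) {
    stop("n_genes must be at least n_tfs", call. = FALSE)
  }
  if (spec$super_signal_multiplier <= 1) {
    stop("super_signal_multiplier must exceed 1", call. = FALSE)
  }
  if (is.null(names(planted_cliques)) || any(names(planted_cliques) == "")) {
    stop("planted_cliques must be a named list (one element per group)",
         call. = FALSE)
  }
  tf_ids <- synthetic_tf_ids(spec)
  extra <- setdiff(unlist(planted_cliques), tf_ids)
  if (length(extra)) {
    stop("planted clique TF(s) outside the TF set: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  spec$n_super_regions <- length(unique(unlist(planted_cliques)))
  class(spec) <- "synthetic_spec"
  spec
}

synthetic_tf_ids <- function(spec) sprintf("TF%02d", seq_len(spec$n_tfs))

synthetic_gene_ids <- function(spec) {
  c(synthetic_tf_ids(spec),
    sprintf("G%03d", seq(spec$n_tfs + 1L, length.out = spec$n_genes - spec$n_tfs)))
}

# Deterministic genome layout: background peak clusters and one SE peak
# cluster per clique TF, all separated by more than the stitch distance;
# plain TSSs nested inside the large inter-cluster gaps.
synthetic_layout <- function(spec) {
  tf_ids <- synthetic_tf_ids(spec)
  gene_ids <- synthetic_gene_ids(spec)
  clique_tfs <- unique(unlist(spec$planted_cliques))
  gap_intra <- 600L
  sep <- spec$stitch_distance + 1600L  # > stitch, with room for margins

  n_bg_clusters <- ceiling(spec$n_background_peaks / 4L)
  bg_sizes <- rep(4L, n_bg_clusters)
  if (n_bg_clusters > 0L && spec$n_background_peaks %% 4L) {
    bg_sizes[n_bg_clusters] <- spec$n_background_peaks %% 4L
  }
  entities <- tibble::tibble(
    kind = c(rep("bg", n_bg_clusters), rep("se", length(clique_tfs))),
    tf = c(rep(NA_character_, n_bg_clusters), clique_tfs),
    n_peaks = c(bg_sizes, rep(3L, length(clique_tfs)))
  )
  # interleave SE blocks evenly among background clusters
  n_ent <- nrow(entities)
  rank <- numeric(n_ent)
  rank[entities$kind == "bg"] <- seq_len(n_bg_clusters)
  if (length(clique_tfs)) {
    rank[entities$kind == "se"] <-
      seq(0.5, n_bg_clusters + 0.5, length.out = length(clique_tfs) + 2L)[-c(1L, length(clique_tfs) + 2L)]
  }
  entities <- entities[order(rank), ]
  entities$contig <- sprintf("chr%d", ((seq_len(n_ent) - 1L) %% spec$n_contigs) + 1L)

  cursor <- stats::setNames(rep(1000L, spec$n_contigs),
                            sprintf("chr%d", seq_len(spec$n_contigs)))
  blocks <- vector("list", n_ent)
  gaps <- list()
  for (i in seq_len(n_ent)) {
    ctg <- entities$contig[i]
    npk <- entities$n_peaks[i]
    span <- npk * spec$peak_width + (npk - 1L) * gap_intra
    start <- cursor[[ctg]]
    end <- start + span
    if (end + 1600L > spec$contig_length) {
      stop("synthetic layout does not fit: increase contig_length or reduce ",
           "peaks/genes", call. = FALSE)
    }
    peak_starts <- start + (seq_len(npk) - 1L) * (spec$peak_width + gap_intra)
    blocks[[i]] <- tibble::tibble(
      kind = entities$kind[i], tf = entities$tf[i], contig = ctg,
      start = start, end = end, block = i,
      peak_start = list(peak_starts)
    )
    gap_lo <- end + 1600L
    gap_hi <- end + sep - 1600L  # next block begins at end + sep
    gaps[[length(gaps) + 1L]] <- tibble::tibble(
      contig = ctg, start = gap_lo, end = gap_hi
    )
    cursor[[ctg]] <- start + sep + span
  }
  blocks <- dplyr::bind_rows(blocks)

  # unused contig tails (and whole contigs without blocks) also host TSSs
  for (ctg in names(cursor)) {
    tail_lo <- if (any(blocks$contig == ctg)) cursor[[ctg]] - 1600L else 1000L
    gaps[[length(gaps) + 1L]] <- tibble::tibble(
      contig = ctg, start = tail_lo, end = spec$contig_length - 1000L
    )
  }

  # plain TSS slots inside the inter-cluster gaps (2.5 kb apart, >= 1.6 kb
  # from any peak block so no stray gene falls in an SE assignment window)
  gaps <- dplyr::bind_rows(gaps)
  slots <- purrr::pmap(gaps, function(contig, start, end) {
    if (end - start < 0L) return(NULL)
    tibble::tibble(contig = contig, pos = seq(start, end, by = 2500L))
  }) |> dplyr::bind_rows()
  slots <- slots[slots$pos < spec$contig_length - 1000L, ]
  slots <- dplyr::distinct(slots, .data$contig, .data$pos)

  n_plain <- spec$n_genes - length(clique_tfs)
  if (nrow(slots) < n_plain) {
    stop("synthetic layout does not fit: not enough TSS slots for ",
         n_plain, " genes", call. = FALSE)
  }

  se_blocks <- blocks[blocks$kind == "se", ]
  genes <- tibble::tibble(
    gene_id = gene_ids, symbol = gene_ids,
    is_tf = gene_ids %in% tf_ids,
    contig = NA_character_, tss = NA_integer_
  )
  # clique TFs sit mid-block, inside their SE region
  idx <- match(se_blocks$tf, genes$gene_id)
  genes$contig[idx] <- se_blocks$contig
  genes$tss[idx] <- as.integer((se_blocks$start + se_blocks$end) %/% 2L)
  plain <- which(is.na(genes$tss))
  genes$contig[plain] <- slots$contig[seq_len(n_plain)]
  genes$tss[plain] <- as.integer(slots$pos[seq_len(n_plain)])
  genes$strand <- rep(c("+", "-"), length.out = spec$n_genes)
  genes <- genes[, c("gene_id", "symbol", "contig", "tss", "strand", "is_tf")]

  list(blocks = blocks, genes = genes, clique_tfs = clique_tfs)
}

#' Generate the shared cohort reference
#'
#' Builds the genome (i.i.d. uniform background sequence with planted
#' consensus motif occurrences inside every clique SE window), the gene
#' table, and one informative position weight matrix per TF (0.85 on the
#' consensus base, pairwise-distinct consensi). Deterministic: the same spec
#' yields byte-identical outputs.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `genome` (named character vector), `genes` (tibble),
#'   `motifs` (named `pwm_motif` list), `layout` (internal placement record)
#'   and `spec`.
#' @export
generate_reference <- function(spec) {
  layout <- synthetic_layout(spec)
  old_seed <- preserve_rng()
  on.exit(restore_rng(old_seed))
  set.seed(spec$seed)

  bases <- c("A", "C", "G", "T")
  genome <- stats::setNames(
    vapply(seq_len(spec$n_contigs), function(i) {
      paste(sample(bases, spec$contig_length, replace = TRUE), collapse = "")
    }, ""),
    sprintf("chr%d", seq_len(spec$n_contigs))
  )

  # distinct consensus words, then consensus-dominated PWMs
  tf_ids <- synthetic_tf_ids(spec)
  repeat {
    consensi <- vapply(tf_ids, function(id) {
      paste(sample(bases, spec$motif_length, replace = TRUE), collapse = "")
    }, "")
    if (!anyDuplicated(consensi)) break
  }
  motifs <- lapply(seq_along(tf_ids), function(i) {
    cons <- strsplit(consensi[i], NULL)[[1L]]
    mat <- matrix(0.05, nrow = spec$motif_length, ncol = 4L,
                  dimnames = list(NULL, bases))
    mat[cbind(seq_len(spec$motif_length), match(cons, bases))] <- 0.85
    new_pwm_motif(tf_ids[i], mat)
  })
  names(motifs) <- tf_ids

  # plant consensus occurrences of every clique member (including self)
  # inside each clique TF's SE region, shared across all samples
  se_blocks <- layout$blocks[layout$blocks$kind == "se", ]
  for (g in names(spec$planted_cliques)) {
    members <- spec$planted_cliques[[g]]
    for (tf in members) {
      blk <- se_blocks[se_blocks$tf == tf, ]
      offset <- blk$start + 100L
      for (m in members) {
        for (k in seq_len(spec$motif_planting_rate)) {
          word <- consensi[[m]]
          substr(genome[[blk$contig]], offset + 1L,
                 offset + spec$motif_length) <- word
          offset <- offset + spec$motif_length + 5L
        }
      }
      if (offset > blk$end) {
        stop("synthetic layout does not fit: planted motifs exceed the SE ",
             "region; reduce motif_planting_rate or clique size", call. = FALSE)
      }
    }
  }

  list(genome = genome, genes = layout$genes, motifs = motifs,
       layout = layout, spec = spec)
}

preserve_rng <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Generate one synthetic sample
#'
#' Emits the sample's peak set and bedGraph-style signal track: background
#' peaks at truncated-normal signal, and for every TF of the sample group's
#' planted clique a high-signal peak cluster (signal multiplied by
#' `super_signal_multiplier`) at that TF's SE block. Peak positions are
#' jittered by up to 200 bp per sample.
#'
#' @param spec A `synthetic_spec`.
#' @param reference Output of [generate_reference()].
#' @param group Group label (a name of `spec$planted_cliques`).
#' @param sample_seed Integer seed for this sample's randomness.
#' @return A list with `peaks` (tibble), `signal` (tibble) and `truth`
#'   (list: `group`, `clique`, `se_regions` tibble).
#' @export
generate_sample <- function(spec, reference, group, sample_seed) {
  if (!group %in% names(spec$planted_cliques)) {
    stop("no planted clique for group '", group, "'", call. = FALSE)
  }
  old_seed <- preserve_rng()
  on.exit(restore_rng(old_seed))
  set.seed(sample_seed)

  clique <- spec$planted_cliques[[group]]
  blocks <- reference$layout$blocks
  active <- blocks[blocks$kind == "bg" | blocks$tf %in% clique, ]

  rows <- purrr::pmap(active, function(kind, tf, contig, start, end, block,
                                       peak_start) {
    n <- length(peak_start)
    jitter <- sample.int(401L, n, replace = TRUE) - 201L
    s <- as.integer(peak_start + jitter)
    value <- pmax(0, stats::rnorm(n, spec$background_signal_mean,
                                  spec$background_signal_sd))
    if (kind == "se") value <- value * spec$super_signal_multiplier
    tibble::tibble(
      contig = contig, start = s, end = s + spec$peak_width,
      name = sprintf("%s_%02d_p%d",
                     ifelse(kind == "se", paste0("se_", tf), "bg"), block,
                     seq_len(n)),
      mark = "H3K27ac", value = value
    )
  }) |> dplyr::bind_rows() |>
    dplyr::arrange(.data$contig, .data$start)

  se_blocks <- blocks[blocks$kind == "se" & blocks$tf %in% clique, ]
  truth <- list(
    group = group,
    clique = sort(clique),
    se_regions = tibble::tibble(tf = se_blocks$tf, contig = se_blocks$contig,
                                start = se_blocks$start, end = se_blocks$end)
  )
  list(
    peaks = rows[, c("contig", "start", "end", "name", "mark")],
    signal = dplyr::transmute(rows, contig = .data$contig,
                              start = .data$start, end = .data$end,
                              value = .data$value),
    truth = truth
  )
}

#' Generate a full synthetic cohort
#'
#' Produces the shared reference plus `n_samples_per_group` samples per
#' group, a gene-by-sample expression table (clique TFs at
#' `expression_high` in their own group, `expression_low` elsewhere; all
#' other genes at a baseline drawn once per gene), and a machine-readable
#' ground-truth record. With `dir` set, all standard files are written
#' (FASTA, TSV, MEME, per-sample BED + bedGraph, truth JSON, and a
#' `samples.tsv` manifest).
#'
#' @param spec A `synthetic_spec`.
#' @param dir Optional output directory (created if needed).
#' @return A `synthetic_cohort` list: `reference`, `samples` (named list
#'   with `peaks`, `signal`, `group`, `truth`), `expression`, `truth`, and
#'   `paths` when `dir` was given.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  groups <- names(spec$planted_cliques)
  if (length(groups) < 2L || spec$n_samples_per_group < 2L) {
    stop("cohort needs >= 2 groups and >= 2 samples per group", call. = FALSE)
  }
  reference <- generate_reference(spec)

  sample_ids <- as.vector(t(outer(groups, seq_len(spec$n_samples_per_group),
                                  function(g, i) sprintf("%s_s%d", g, i))))
  sample_groups <- rep(groups, each = spec$n_samples_per_group)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample names", call. = FALSE)
  }
  samples <- purrr::map2(sample_ids, seq_along(sample_ids), function(id, idx) {
    g <- sample_groups[idx]
    res <- generate_sample(spec, reference, g,
                           sample_seed = derive_seed(spec$seed, idx))
    c(res, list(group = g))
  })
  names(samples) <- sample_ids

  old_seed <- preserve_rng()
  on.exit(restore_rng(old_seed))
  set.seed(derive_seed(spec$seed, 0L))
  genes <- reference$genes
  baseline <- stats::runif(nrow(genes), 15, 25)
  expr <- matrix(rep(baseline, length(sample_ids)), ncol = length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (g in groups) {
    members <- match(spec$planted_cliques[[g]], genes$gene_id)
    expr[members, ] <- spec$expression_low
    expr[members, sample_groups == g] <- spec$expression_high
  }
  expression <- dplyr::bind_cols(
    tibble::tibble(gene_id = genes$gene_id),
    tibble::as_tibble(round(expr, 3))
  )

  clique_tfs <- unique(unlist(spec$planted_cliques))
  expr_class <- ifelse(genes$gene_id %in% clique_tfs, "planted", "baseline")
  truth <- list(
    seed = spec$seed,
    groups = lapply(stats::setNames(nm = groups), function(g) list(
      clique = sort(spec$planted_cliques[[g]]),
      samples = sample_ids[sample_groups == g]
    )),
    samples = lapply(stats::setNames(nm = sample_ids), function(id) list(
      group = samples[[id]]$group,
      clique = samples[[id]]$truth$clique,
      se_regions = samples[[id]]$truth$se_regions
    )),
    expression_class = stats::setNames(as.list(expr_class), genes$gene_id)
  )

  cohort <- structure(
    list(reference = reference, samples = samples, expression = expression,
         truth = truth, spec = spec),
    class = "synthetic_cohort"
  )
  if (!is.null(dir)) {
    cohort$paths <- write_cohort(cohort, dir)
  }
  cohort
}

derive_seed <- function(seed, idx) {
  as.integer((as.double(seed) * 7919 + (idx + 1) * 104729) %% 2147483647)
}

#' Write a synthetic cohort to disk
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.tsv"),
    motifs = file.path(dir, "motifs.meme"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json"),
    manifest = file.path(dir, "samples.tsv")
  )
  write_genome(cohort$reference$genome, paths$genome)
  write_gene_table(cohort$reference$genes, paths$genes)
  write_meme(cohort$reference$motifs, paths$motifs)
  write_expression(cohort$expression, paths$expression)
  jsonlite::write_json(cohort$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- tibble::tibble(
    sample = names(cohort$samples),
    group = vapply(cohort$samples, `[[`, "", "group"),
    peaks = sprintf("%s.peaks.bed", names(cohort$samples)),
    signal = sprintf("%s.signal.bedGraph", names(cohort$samples))
  )
  readr::write_tsv(manifest, paths$manifest, progress = FALSE)
  for (id in names(cohort$samples)) {
    write_peaks(cohort$samples[[id]]$peaks,
                file.path(dir, sprintf("%s.peaks.bed", id)))
    write_bedgraph(cohort$samples[[id]]$signal,
                   file.path(dir, sprintf("%s.signal.bedGraph", id)))
  }
  paths$samples <- manifest
  invisible(paths)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$samples), " samples, ",
      length(unique(vapply(x$samples, `[[`, "", "group"))), " groups, seed ",
      x$spec$seed, "\n", sep = "")
  invisible(x)
}
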