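#' Pipeline configuration
#'
#' Validated parameter set for [run_pipeline()] and [analyze_cohort()].
#' Unknown parameter names are rejected.
#'
#' @param peaks Named character vector of per-sample peak BED paths.
#' @param signal Named character vector of per-sample bedGraph paths (names
#'   matching `peaks`).
#' @param control Optional named character vector of control bedGraph paths.
#' @param fasta Genome FASTA path.
#' @param genes Gene table TSV path.
#' @param motifs MEME motif file path.
#' @param expression Optional expression TSV path.
#' @param outdir Output directory.
#' @param stitch_distance Peak stitching distance (bp).
#' @param gene_window SE-to-gene TSS assignment window (bp).
#' @param extension Motif-scan extension of SE regions (bp).
#' @param p_threshold Exact motif p-value threshold.
#' @param min_hits Minimum motif occurrences per regulatory edge.
#' @param expression_threshold Minimum TPM-like expression of a master TF
#'   candidate.
#' @param min_distinct_tfs Distinct CRC TFs required to call a target gene.
#' @param w1,w2,w3 D-measure weights.
#' @param k Number of sample groups for clustering.
#' @param broad_fraction Fraction of widest peaks flagged as broad domains.
#' @param seed Integer seed for any stochastic steps.
#' @param ... Rejected; catches unknown parameters.
#' @return A `crc_config` list.
#' @export
crc_config <- function(peaks = NULL, signal = NULL, control = NULL,
                       fasta = NULL, genes = NULL, motifs = NULL,
                       expression = NULL, outdir = NULL,
                       stitch_distance = 12500, gene_window = 1000,
                       extension = 500, p_threshold = 1e-4, min_hits = 1,
                       expression_threshold = 10, min_distinct_tfs = 3,
                       w1 = 0.45, w2 = 0.45, w3 = 0.1, k = 2,
                       broad_fraction = 0.05, seed = 1L, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration parameter(s): ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  cfg <- list(
    peaks = peaks, signal = signal, control = control, fasta = fasta,
    genes = genes, motifs = motifs, expression = expression, outdir = outdir,
    stitch_distance = stitch_distance, gene_window = gene_window,
    extension = extension, p_threshold = p_threshold, min_hits = min_hits,
    expression_threshold = expression_threshold,
    min_distinct_tfs = min_distinct_tfs,
    weights = d_weights(w1, w2, w3), k = k,
    broad_fraction = broad_fraction, seed = as.integer(seed)
  )
  class(cfg) <- "crc_config"
  cfg
}

#' Write a configuration template
#'
#' Emits a YAML file holding every pipeline parameter at its default, ready
#' to edit.
#'
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
init_config <- function(path = "crcscape.yaml") {
  cfg <- crc_config()
  flat <- cfg[!vapply(cfg, is.null, logical(1))]
  flat$weights <- as.list(flat$weights)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Read a YAML configuration file
#'
#' @param path YAML path written by [init_config()] (or hand-edited).
#' @return A `crc_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$weights)) {
    raw$w1 <- raw$weights$w1; raw$w2 <- raw$weights$w2; raw$w3 <- raw$weights$w3
    raw$weights <- NULL
  }
  for (f in c("peaks", "signal", "control")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(crc_config, raw)
}

#' Analyse one sample: enhancer landscape and CRC
#'
#' Runs stitch, score, cutoff, gene assignment, motif scanning and CRC
#' construction on in-memory inputs.
#'
#' @param peaks,signal,control Sample peak and signal tibbles.
#' @param genes,motifs,genome Shared cohort reference objects.
#' @param expression,sample_id Optional expression table and sample column.
#' @param config A `crc_config` (parameters only; paths are ignored).
#' @param thresholds Optional precomputed [score_threshold()] results.
#' @return A list with `calls`, `links` and `crc`.
#' @export
analyze_sample <- function(peaks, signal, genes, motifs, genome,
                           control = NULL, expression = NULL,
                           sample_id = NULL, config = crc_config(),
                           thresholds = NULL) {
  calls <- call_enhancers(peaks, signal, control,
                          stitch_distance = config$stitch_distance)
  crc <- build_crc(calls, genes, motifs, genome,
                   expression = expression, sample_id = sample_id,
                   window = config$gene_window, extension = config$extension,
                   p_threshold = config$p_threshold,
                   min_hits = config$min_hits,
                   expression_threshold = config$expression_threshold,
                   thresholds = thresholds)
  list(calls = calls, links = crc$links, crc = crc)
}

#' Analyse a cohort: per-sample CRCs, network comparison, clustering
#'
#' The in-memory core of the pipeline: runs [analyze_sample()] on every
#' sample, compares the CRC graphs pairwise with the D-measure, clusters
#' samples into `k` groups, and derives CRC target genes plus the common
#' master-TF intersection per clustered group.
#'
#' @param cohort A `synthetic_cohort`, or any list with the same shape
#'   (`reference$genome`, `reference$genes`, `reference$motifs`, `samples`
#'   as named lists with `peaks` and `signal`, optional `expression`).
#' @param config A `crc_config`.
#' @return A `cohort_analysis` list: `samples` (per-sample results),
#'   `dissimilarity` (`crc_dissimilarity`), `clustering`
#'   (`sample_clustering`), `targets` (per-sample CRC target genes),
#'   `common_mtfs` (per clustered group and overall).
#' @export
analyze_cohort <- function(cohort, config = crc_config()) {
  ref <- cohort$reference
  thresholds <- lapply(ref$motifs, score_threshold,
                       p_threshold = config$p_threshold)
  results <- purrr::imap(cohort$samples, function(s, id) {
    analyze_sample(s$peaks, s$signal, ref$genes, ref$motifs, ref$genome,
                   control = s$control, expression = cohort$expression,
                   sample_id = id, config = config, thresholds = thresholds)
  })
  graphs <- lapply(results, function(r) crc_graph(r$crc))
  dis <- pairwise_dissimilarity(graphs, config$weights)
  clustering <- cluster_samples(dis, k = config$k)
  targets <- lapply(results, function(r) {
    infer_crc_targets(r$links, r$crc$hit_counts, r$crc$crc_tfs,
                      min_distinct_tfs = config$min_distinct_tfs)
  })
  mtfs <- lapply(results, function(r) {
    if (is.null(r$crc$expressed_crc_tfs)) r$crc$crc_tfs
    else r$crc$expressed_crc_tfs
  })
  by_group <- split(names(results), clustering$labels$group)
  common_mtfs <- c(
    lapply(by_group, function(ids) sort(Reduce(intersect, mtfs[ids]))),
    list(all = sort(Reduce(intersect, mtfs)))
  )
  structure(
    list(samples = results, dissimilarity = dis, clustering = clustering,
         targets = targets, common_mtfs = common_mtfs, config = config),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis> ", length(x$samples), " samples, k = ",
      x$config$k, "\n", sep = "")
  print(x$clustering$labels, n = nrow(x$clustering$labels))
  invisible(x)
}

#' Run the full pipeline from files
#'
#' Reads every input named in the configuration, runs [analyze_cohort()],
#' and writes per-sample enhancer tables (TSV), SE/TE BED files, CRC
#' reports (JSON), the cohort D and S matrices (TSV), group labels (TSV)
#' and a machine-readable `report.json` with a provenance block (config
#' hash; identical config and inputs reproduce identical report content).
#' A stage failure aborts with the failing sample and stage named; outputs
#' written up to that point are retained next to a `FAILED` marker file.
#'
#' @param config A `crc_config` with all input paths set.
#' @return The `cohort_analysis`, invisibly; side effect: files under
#'   `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "crc_config"))
  for (f in c("peaks", "signal", "fasta", "genes", "motifs", "outdir")) {
    if (is.null(config[[f]])) {
      stop("config field '", f, "' is required", call. = FALSE)
    }
  }
  if (is.null(names(config$peaks)) || is.null(names(config$signal))) {
    stop("config peaks/signal must be named by sample", call. = FALSE)
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(what, sample, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage=", what, " sample=", sample, " : ",
                        conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop("pipeline stage '", what, "' failed for sample '", sample, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  genome <- stage("read-genome", "-", read_genome(config$fasta))
  genes <- stage("read-genes", "-", read_gene_table(config$genes))
  motifs <- stage("read-motifs", "-", read_meme(config$motifs))
  expression <- if (!is.null(config$expression)) {
    stage("read-expression", "-", read_expression(config$expression))
  }
  samples <- lapply(stats::setNames(nm = names(config$peaks)), function(id) {
    list(
      peaks = stage("read-peaks", id, read_peaks(config$peaks[[id]])),
      signal = stage("read-signal", id, read_bedgraph(config$signal[[id]])),
      control = if (!is.null(config$control) && id %in% names(config$control)) {
        stage("read-control", id, read_bedgraph(config$control[[id]]))
      }
    )
  })
  cohort <- list(
    reference = list(genome = genome, genes = genes, motifs = motifs),
    samples = samples, expression = expression
  )
  analysis <- stage("analyze", "-", analyze_cohort(cohort, config))

  for (id in names(analysis$samples)) {
    res <- analysis$samples[[id]]
    tab <- tibble::as_tibble(res$calls)[
      , c("region_id", "contig", "start", "end", "n_constituents",
          "signal", "rank", "class")]
    readr::write_tsv(tab, file.path(outdir, sprintf("%s.enhancers.tsv", id)),
                     progress = FALSE)
    for (cls in c("SE", "TE")) {
      sub <- dplyr::filter(tab, .data$class == cls)
      writeLines(sprintf("%s\t%d\t%d\t%s", sub$contig, sub$start, sub$end,
                         sub$region_id),
                 file.path(outdir, sprintf("%s.%s.bed", id, tolower(cls))))
    }
    readr::write_tsv(res$links,
                     file.path(outdir, sprintf("%s.se_genes.tsv", id)),
                     progress = FALSE)
    jsonlite::write_json(crc_report(res$crc, id),
                         file.path(outdir, sprintf("%s.crc.json", id)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_matrix_tsv <- function(m, path) {
    df <- tibble::as_tibble(m, rownames = "sample")
    readr::write_tsv(df, path, progress = FALSE)
  }
  write_matrix_tsv(analysis$dissimilarity$D, file.path(outdir, "D_matrix.tsv"))
  write_matrix_tsv(analysis$dissimilarity$S, file.path(outdir, "S_matrix.tsv"))
  readr::write_tsv(analysis$clustering$labels,
                   file.path(outdir, "groups.tsv"), progress = FALSE)
  report <- list(
    samples = lapply(analysis$samples, function(r) list(
      n_regions = nrow(r$calls),
      n_se = sum(r$calls$class == "SE"),
      crc_tfs = r$crc$crc_tfs,
      expressed_crc_tfs = r$crc$expressed_crc_tfs,
      cliques = r$crc$cliques
    )),
    groups = stats::setNames(as.list(analysis$clustering$labels$group),
                             analysis$clustering$labels$sample),
    common_mtfs = analysis$common_mtfs,
    targets = analysis$targets,
    provenance = list(
      package = "crcscape",
      version = as.character(utils::packageVersion("crcscape")),
      # hash over the analysis-relevant configuration: the output location
      # does not change what is computed
      config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(analysis)
}

# JSON-ready CRC report for one sample.
crc_report <- function(crc, sample_id) {
  list(
    sample = sample_id,
    tfs = crc$graph$nodes$tf_id,
    autoregulated = crc$graph$nodes$tf_id,
    edges = unname(purrr::pmap(crc$graph$edges, function(from, to, n_hits) {
      list(from, to, n_hits)
    })),
    cliques = crc$cliques,
    clique_fraction = stats::setNames(as.list(crc$clique_fraction$fraction),
                                      crc$clique_fraction$tf_id),
    expressed_crc_tfs = crc$expressed_crc_tfs
  )
}
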