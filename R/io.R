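#' Read called peaks from a BED file
#'
#' Parses BED3/BED4 into a peak tibble. Coordinates are kept 0-based
#' half-open, exactly as stored in BED. Peaks are sorted by
#' `(contig, start, end)` and peaks lacking a name column get deterministic
#' auto-generated names of the form `<mark>_<ordinal>` (ordinal assigned
#' after sorting).
#'
#' @param path Path to a BED3+ file (no header).
#' @param mark Source mark label attached to every peak, one of
#'   `"H3K27ac"`, `"H3K4me3"` or `"TF"`.
#' @return A tibble with columns `contig`, `start`, `end`, `name`, `mark`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100", bed)
#' read_peaks(bed)
#' @export
read_peaks <- function(path, mark = c("H3K27ac", "H3K4me3", "TF")) {
  mark <- match.arg(mark)
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    return(tibble::tibble(
      contig = character(), start = integer(), end = integer(),
      name = character(), mark = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3L)
  if (length(bad)) {
    stop("BED parse error at line ", bad[1L], ": fewer than 3 fields", call. = FALSE)
  }
  contig <- vapply(fields, `[[`, "", 1L)
  start <- parse_coord(vapply(fields, `[[`, "", 2L), path_label = "BED")
  end <- parse_coord(vapply(fields, `[[`, "", 3L), path_label = "BED")
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end | contig == "")
  if (length(bad)) {
    stop("BED parse error at line ", bad[1L],
         ": invalid interval (need 0 <= start < end, non-empty contig)",
         call. = FALSE)
  }
  name <- ifelse(n_fields >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  out <- tibble::tibble(contig = contig, start = start, end = end, name = name, mark = mark) |>
    dplyr::arrange(.data$contig, .data$start, .data$end)
  missing_name <- is.na(out$name) | out$name == ""
  if (any(missing_name)) {
    out$name[missing_name] <- paste0(mark, "_", which(missing_name))
  }
  out
}

#' Write peaks to BED
#'
#' Emits BED4 (`contig`, `start`, `end`, `name`), the dialect [read_peaks()]
#' parses back identically.
#'
#' @param peaks Peak tibble as returned by [read_peaks()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", peaks$contig, peaks$start, peaks$end, peaks$name)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' The value of a run is interpreted as signal per base pair; the signal of a
#' region is the sum of `value * covered_bp` over runs it intersects (see
#' [score_regions()]). Runs are sorted by `(contig, start)`; abutting runs
#' with unequal values are retained as-is, never merged. Overlapping runs or
#' negative values are rejected.
#'
#' @param path Path to a 4-column bedGraph file.
#' @return A tibble with columns `contig`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    return(tibble::tibble(contig = character(), start = integer(),
                          end = integer(), value = double()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) {
    stop("bedGraph parse error at line ", bad[1L], ": fewer than 4 fields", call. = FALSE)
  }
  contig <- vapply(fields, `[[`, "", 1L)
  start <- parse_coord(vapply(fields, `[[`, "", 2L), "bedGraph")
  end <- parse_coord(vapply(fields, `[[`, "", 3L), "bedGraph")
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(value) | start < 0L | start >= end)
  if (length(bad)) {
    stop("bedGraph parse error at line ", bad[1L], ": invalid run", call. = FALSE)
  }
  if (any(value < 0)) {
    stop("bedGraph parse error: negative signal value at line ",
         which(value < 0)[1L], call. = FALSE)
  }
  out <- tibble::tibble(contig = contig, start = start, end = end, value = value) |>
    dplyr::arrange(.data$contig, .data$start)
  overlap <- out |>
    dplyr::group_by(.data$contig) |>
    dplyr::mutate(.bad = .data$start < dplyr::lag(.data$end, default = -1L)) |>
    dplyr::ungroup()
  if (any(overlap$.bad)) {
    stop("bedGraph parse error: overlapping runs on contig ",
         overlap$contig[overlap$.bad][1L], call. = FALSE)
  }
  out
}

#' Write a signal track to bedGraph
#'
#' @param track Signal tibble as returned by [read_bedgraph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", track$contig, track$start, track$end,
                   format_signal(track$value))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with header columns `gene_id`, `symbol`, `contig`, `tss`, `strand`,
#' `is_tf`. The `is_tf` column accepts `1`/`0`, `true`/`false`, `TRUE`/`FALSE`.
#' Transcription start sites (`tss`) are 0-based positions.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per gene; `is_tf` is logical.
#' @export
read_gene_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    symbol = readr::col_character(),
    contig = readr::col_character(),
    tss = readr::col_integer(),
    strand = readr::col_character(),
    is_tf = readr::col_character()
  ), progress = FALSE)
  required <- c("gene_id", "symbol", "contig", "tss", "strand", "is_tf")
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup)) {
    stop("gene table has duplicate gene_id: ", dup[1L], call. = FALSE)
  }
  if (any(out$tss < 0L)) {
    stop("gene table has negative tss for gene ",
         out$gene_id[out$tss < 0L][1L], call. = FALSE)
  }
  flag <- tolower(out$is_tf)
  if (!all(flag %in% c("0", "1", "true", "false"))) {
    stop("gene table is_tf values must be 0/1/true/false", call. = FALSE)
  }
  out$is_tf <- flag %in% c("1", "true")
  tibble::as_tibble(out)
}

#' Write a gene annotation table
#'
#' @param genes Gene tibble as returned by [read_gene_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  out <- genes
  out$is_tf <- ifelse(out$is_tf, "1", "0")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read transcription factor motifs in MEME minimal format
#'
#' Supports the minimal dialect: a `MEME version` line, optional `ALPHABET`
#' and `Background letter frequencies` sections, then `MOTIF` blocks each
#' followed by a `letter-probability matrix` and one row of A/C/G/T
#' probabilities per motif position. A missing background defaults to
#' uniform 0.25.
#'
#' @param path Path to the MEME file.
#' @param pseudocount Probability mass added to every matrix cell before
#'   log-odds scoring (see [score_threshold()]).
#' @return A named list of `pwm_motif` objects (named by motif id), each with
#'   fields `tf_id`, `mat` (positions x 4 probability matrix, columns
#'   A,C,G,T), `background` (length-4 named numeric) and `pseudocount`.
#' @export
read_meme <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME minimal file (no 'MEME version' line): ", path, call. = FALSE)
  }
  alpha_idx <- grep("^ALPHABET", lines)
  if (length(alpha_idx)) {
    alpha <- gsub("^ALPHABET\\s*=\\s*", "", lines[alpha_idx[1L]])
    if (gsub("\\s", "", alpha) != "ACGT") {
      stop("unsupported MEME alphabet: ", alpha, call. = FALSE)
    }
  }
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_idx <- grep("^Background letter frequencies", lines)
  if (length(bg_idx) && bg_idx[1L] < length(lines)) {
    toks <- strsplit(trimws(lines[bg_idx[1L] + 1L]), "\\s+")[[1L]]
    if (length(toks) >= 8L) {
      vals <- as.numeric(toks[seq(2L, 8L, by = 2L)])
      names(vals) <- toks[seq(1L, 7L, by = 2L)]
      background <- vals[c("A", "C", "G", "T")]
      if (abs(sum(background) - 1) > 1e-3) {
        stop("MEME background does not sum to 1", call. = FALSE)
      }
    }
  }
  motif_idx <- grep("^MOTIF\\b", lines)
  motifs <- list()
  for (k in seq_along(motif_idx)) {
    header <- strsplit(trimws(lines[motif_idx[k]]), "\\s+")[[1L]]
    tf_id <- header[2L]
    block_end <- if (k < length(motif_idx)) motif_idx[k + 1L] - 1L else length(lines)
    block <- lines[motif_idx[k]:block_end]
    row_lines <- grep("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", block, value = TRUE)
    if (!length(row_lines)) {
      stop("MEME motif ", tf_id, " has no letter-probability rows", call. = FALSE)
    }
    mat <- do.call(rbind, lapply(row_lines, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    }))
    colnames(mat) <- c("A", "C", "G", "T")
    bad <- which(abs(rowSums(mat) - 1) > 1e-3)
    if (length(bad)) {
      stop("MEME motif ", tf_id, " row ", bad[1L], " does not sum to 1",
           call. = FALSE)
    }
    motifs[[tf_id]] <- new_pwm_motif(tf_id, mat, background, pseudocount)
  }
  motifs
}

#' Write motifs in MEME minimal format
#'
#' @param motifs Named list of `pwm_motif` objects (see [read_meme()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  bg <- if (length(motifs)) motifs[[1L]]$background else c(A = .25, C = .25, G = .25, T = .25)
  out <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.5f C %.5f G %.5f T %.5f", bg[["A"]], bg[["C"]], bg[["G"]], bg[["T"]]),
    ""
  )
  for (m in motifs) {
    out <- c(out,
      paste("MOTIF", m$tf_id),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
              nrow(m$mat)),
      apply(m$mat, 1L, function(r) sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])),
      ""
    )
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a position probability matrix motif
#'
#' @param tf_id Motif / transcription factor identifier.
#' @param mat Positions x 4 probability matrix with columns A, C, G, T; each
#'   row must sum to 1 within 1e-9 of tolerance after construction checks.
#' @param background Length-4 background probabilities (named A, C, G, T).
#' @param pseudocount Smoothing mass `c`; log-odds use
#'   `p' = (p + c) / (1 + 4c)`.
#' @return A `pwm_motif` object.
#' @export
new_pwm_motif <- function(tf_id, mat,
                          background = c(A = .25, C = .25, G = .25, T = .25),
                          pseudocount = 1e-3) {
  stopifnot(is.matrix(mat), ncol(mat) == 4L, nrow(mat) >= 1L)
  colnames(mat) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(mat) - 1) > 1e-3)) {
    stop("motif matrix rows must sum to 1", call. = FALSE)
  }
  if (abs(sum(background) - 1) > 1e-6) {
    stop("background must sum to 1", call. = FALSE)
  }
  structure(
    list(tf_id = tf_id, mat = mat,
         background = stats::setNames(as.numeric(background), c("A", "C", "G", "T")),
         pseudocount = pseudocount),
    class = "pwm_motif"
  )
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat("<pwm_motif> ", x$tf_id, ": ", nrow(x$mat), " bp, consensus ",
      motif_consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a motif
#'
#' @param motif A `pwm_motif`.
#' @return The string of per-position most probable bases.
#' @export
motif_consensus <- function(motif) {
  paste(colnames(motif$mat)[max.col(motif$mat, ties.method = "first")], collapse = "")
}

#' Read a genome from FASTA
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A named character vector, one upper-case sequence per contig.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path, width = 70L)
  invisible(path)
}

#' Extract region sequences from a genome
#'
#' Regions are 0-based half-open. When `regions` has a `strand` column,
#' minus-strand regions are returned reverse-complemented. Coordinates
#' outside the contig raise an error unless `clamp = TRUE`, which truncates
#' to contig bounds.
#'
#' @param genome Named character vector of contig sequences.
#' @param regions Tibble with columns `contig`, `start`, `end` and optionally
#'   `strand`.
#' @param clamp Clamp out-of-bounds coordinates instead of erroring.
#' @return Character vector of sequences, one per region row.
#' @export
extract_sequences <- function(genome, regions, clamp = FALSE) {
  missing <- setdiff(unique(regions$contig), names(genome))
  if (length(missing)) {
    stop("contig(s) absent from genome: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lens <- nchar(genome)[regions$contig]
  start <- regions$start
  end <- regions$end
  if (clamp) {
    start <- pmax(start, 0L)
    end <- pmin(end, lens)
  } else if (any(start < 0L | end > lens)) {
    stop("region outside contig bounds (use clamp = TRUE to truncate)",
         call. = FALSE)
  }
  seqs <- substr(genome[regions$contig], start + 1L, end)
  if ("strand" %in% names(regions)) {
    minus <- !is.na(regions$strand) & regions$strand == "-"
    seqs[minus] <- reverse_complement(seqs[minus])
  }
  unname(seqs)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over the alphabet A, C, G, T, N.
#' @return The reverse complements.
#' @export
reverse_complement <- function(x) {
  if (!length(x)) return(x)
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(s) {
    paste(rev(s), collapse = "")
  }, ""))
}

#' Read a gene-by-sample expression table
#'
#' TSV with a `gene_id` column followed by one numeric column per sample
#' (TPM-like values).
#'
#' @param path Path to the TSV file.
#' @return A tibble with `gene_id` and one column per sample.
#' @export
read_expression <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (!"gene_id" %in% names(out)) {
    stop("expression table must have a gene_id column", call. = FALSE)
  }
  out
}

#' Write a gene-by-sample expression table
#'
#' @param expr Expression tibble as returned by [read_expression()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

# Non-comment, non-track data lines of a UCSC-style text file.
read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)]
}

parse_coord <- function(x, path_label) {
  out <- suppressWarnings(as.integer(x))
  out[!grepl("^-?[0-9]+$", x)] <- NA_integer_
  out
}

# bedGraph values: integers rendered without decimal point, otherwise
# shortest round-tripping decimal representation.
format_signal <- function(v) {
  ifelse(v == round(v), format(as.integer(round(v))),
         vapply(v, function(x) format(x, digits = 15L, scientific = FALSE), ""))
}
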