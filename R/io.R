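#' Expression table with condition design
#'
#' Container for a gene x sample matrix of nonnegative abundance values
#' (BPKM-like units) plus the sample-to-condition assignment.
#'
#' @param values Numeric matrix, rows = genes, columns = samples; finite and
#'   nonnegative.
#' @param design Named character vector mapping sample name -> condition
#'   label; names must equal `colnames(values)`.
#' @return Object of class `expression_table` with elements `values` and
#'   `design`.
#' @export
expression_table <- function(values, design) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)),
            is.character(design), !is.null(names(design)))
  if (!setequal(names(design), colnames(values)) ||
      anyDuplicated(names(design)))
    stop("design must assign every sample (column) to exactly one condition")
  design <- design[colnames(values)]
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite or negative expression value at gene ",
         sQuote(rownames(values)[bad[1, 1]]), ", sample ",
         sQuote(colnames(values)[bad[1, 2]]))
  structure(list(values = values, design = design), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%d conditions)\n",
              nrow(x$values), ncol(x$values), length(unique(x$design))))
  invisible(x)
}

#' Replicate columns of one condition
#' @param expr An [expression_table()].
#' @param condition Condition label.
#' @return Numeric matrix of the samples assigned to `condition`.
#' @export
condition_values <- function(expr, condition) {
  stopifnot(inherits(expr, "expression_table"))
  samples <- names(expr$design)[expr$design == condition]
  if (length(samples) == 0L)
    stop("condition ", sQuote(condition), " has no samples in the design")
  expr$values[, samples, drop = FALSE]
}

#' Read / write an expression table
#'
#' Tab-separated text: first column gene identifiers, remaining columns
#' samples. Every sample column must be named in `design`; values must be
#' finite and nonnegative. `read_expression_table(write_expression_table())`
#' round-trips exactly at the serialized precision.
#'
#' @param path File path.
#' @param design Named character vector sample -> condition (or a
#'   `pipeline_config` is *not* enough: the design carries sample names).
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, design) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column plus samples")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  unknown <- setdiff(colnames(m), names(design))
  if (length(unknown) > 0L)
    stop("samples not present in the design: ", paste(unknown, collapse = ", "))
  expression_table(m, design[colnames(m)])
}

#' @rdname read_expression_table
#' @param expr An [expression_table()].
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(inherits(expr, "expression_table"))
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scored edge table into a PPI network
#'
#' Three tab-separated columns: node, node, combined confidence score in
#' (0, 1]. The graph is undirected and simple: duplicate pairs (in either
#' orientation) are collapsed keeping the maximum score, and self-pairs are
#' dropped with a warning.
#'
#' @param path File path (header optional; detected by a non-numeric third
#'   field in the first line).
#' @return A [ppi_network()].
#' @export
read_edge_table <- function(path) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  header <- ncol(first) >= 3 && is.na(suppressWarnings(as.numeric(first[[3]])))
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("edge table needs columns: node, node, score")
  df <- df[, 1:3]
  names(df) <- c("node_a", "node_b", "score")
  ppi_network(df)
}

#' Read a Ct measurement table
#'
#' Tab-separated columns `gene`, `condition`, `bio_rep`, `tech_rep`, `ct`.
#' Keys (gene, condition, bio_rep, tech_rep) must be unique and Ct values
#' finite.
#'
#' @param path File path.
#' @return `data.frame` of Ct records.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "bio_rep", "tech_rep", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (!all(is.finite(df$ct))) stop("non-finite Ct value in ", path)
  key <- do.call(paste, c(df[, 1:4], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (gene, condition, bio_rep, tech_rep) key in ", path)
  df
}

#' Read a relative-expression table
#'
#' Tab-separated columns `gene`, `condition`, `bio_rep`, `value` (positive
#' fold-values relative to a calibrator), as produced by [delta_delta_ct()]
#' or transcribed from a published validation table.
#'
#' @param path File path.
#' @return `data.frame`.
#' @export
read_relative_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "condition", "bio_rep", "value")
  if (!all(need %in% names(df)))
    stop("relative-expression table must have columns: ",
         paste(need, collapse = ", "))
  df <- df[, need]
  if (!all(is.finite(df$value) & df$value > 0))
    stop("relative expression values must be positive and finite")
  df
}

#' Read a one-symbol-per-line gene list
#' @param path File path; blank lines and `#` comments ignored.
#' @return Character vector (identifiers are opaque, case-sensitive).
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a dN/dS table
#'
#' Tab-separated columns `gene`, `dnds_pair_a`, `dnds_pair_b`; the two value
#' columns hold the substitution-rate ratio for the two species pairings.
#' @param path File path.
#' @return `data.frame` with nonnegative values.
#' @export
read_dnds_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "dnds_pair_a", "dnds_pair_b")
  if (!all(need %in% names(df)))
    stop("dN/dS table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  if (any(df$dnds_pair_a < 0 | df$dnds_pair_b < 0, na.rm = TRUE))
    stop("dN/dS values must be nonnegative")
  df
}

#' Read GO annotations
#' @param path Tab-separated columns `gene`, `term`.
#' @return `data.frame`.
#' @export
read_go_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(df)))
    stop("annotation table must have columns: gene, term")
  df[, c("gene", "term")]
}

#' Read a motif file
#'
#' Either FASTA (id in the header) or plain two-column text
#' (`id<TAB>sequence`). Motifs use the IUPAC nucleotide alphabet.
#'
#' @param path File path.
#' @return Named character vector motif_id -> IUPAC string (uppercase).
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty motif file: ", path)
  if (startsWith(lines[[1]], ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    motifs <- stats::setNames(toupper(as.character(ss)), names(ss))
  } else {
    parts <- strsplit(lines, "\t")
    if (any(lengths(parts) < 2L))
      stop("plain motif file needs two tab-separated columns: id, sequence")
    motifs <- stats::setNames(toupper(vapply(parts, `[[`, "", 2L)),
                              vapply(parts, `[[`, "", 1L))
  }
  bad <- grepl("[^ACGTRYSWKMBDHVN]", motifs)
  if (any(bad))
    stop("motif ", sQuote(names(motifs)[bad][1]), " contains non-IUPAC letters")
  if (any(!nzchar(motifs))) stop("empty motif sequence")
  motifs
}

#' Read TSS records from BED
#'
#' 6-column BED (0-based half-open). The TSS is the 5' end of the feature:
#' `start` on the + strand, `end - 1` on the - strand.
#'
#' @param path BED file path.
#' @return `data.frame` with `gene`, `chrom`, `tss`, `strand`.
#' @export
read_tss_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("TSS records must be stranded (+/-)")
  data.frame(
    gene = if (!is.null(gr$name)) gr$name else paste0("feature", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    tss = ifelse(strand == "+", GenomicRanges::start(gr) - 1L,
                 GenomicRanges::end(gr) - 1L),
    strand = strand, stringsAsFactors = FALSE)
}

#' Read aligned-read intervals from BED
#' @param path BED file path.
#' @return A `GRanges` of read intervals.
#' @export
read_reads_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write a result table
#'
#' Tab-separated, fixed column order as given, floating point serialized with
#' 6 significant digits (printed validation tables carry 3 decimals; 6
#' significant digits avoid round-trip loss).
#'
#' @param df `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) signif(v, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' @param chrom Chromosome name.
#' @param start 0-based start of the covered window.
#' @param values Per-base numeric values for
#'   `[start, start + length(values))`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(chrom, start, values, path) {
  stopifnot(length(values) >= 1L)
  r <- rle(values)
  ends <- start + cumsum(r$lengths)
  starts <- ends - r$lengths
  df <- data.frame(chrom = chrom, start = starts, end = ends,
                   value = signif(r$values, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
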