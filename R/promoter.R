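#' Extract putative promoter regions
#'
#' The putative promoter is the window of `promoter_length` bp immediately
#' upstream of the transcription start site. Coordinates are 0-based
#' half-open throughout: a + strand gene with TSS `t` yields the genomic
#' interval `[t - L, t)`; a - strand gene yields `[t + 1, t + 1 + L)` and its
#' sequence is reverse-complemented, so returned sequences always read
#' promoter-5' to 3'. Windows hitting a chromosome edge are truncated and
#' flagged with a warning.
#'
#' @param tss_records `data.frame` with `gene`, `chrom`, `tss` (0-based
#'   position), `strand` (see [read_tss_bed()]).
#' @param genome A `DNAStringSet` (or path to a FASTA read with
#'   `Biostrings::readDNAStringSet`); names must contain every `chrom`.
#' @param promoter_length Window length L in bp.
#' @return `data.frame` with `gene`, `chrom`, `start`, `end`, `strand`,
#'   `truncated`, `sequence` (uppercase).
#' @export
extract_promoters <- function(tss_records, genome, promoter_length = 5000L) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"),
            all(c("gene", "chrom", "tss", "strand") %in% names(tss_records)))
  # FASTA headers may carry descriptions after the first word
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(tss_records$chrom), names(genome))
  if (length(missing) > 0L)
    stop("chromosome(s) absent from genome: ", paste(missing, collapse = ", "))
  L <- as.integer(promoter_length)
  rows <- lapply(seq_len(nrow(tss_records)), function(i) {
    chrom <- tss_records$chrom[i]
    t0 <- as.integer(tss_records$tss[i])
    strand <- tss_records$strand[i]
    clen <- length(genome[[chrom]])
    if (strand == "+") {
      start <- t0 - L; end <- t0
    } else if (strand == "-") {
      start <- t0 + 1L; end <- t0 + 1L + L
    } else stop("strand must be '+' or '-'")
    truncated <- start < 0L || end > clen
    if (truncated) {
      warning("promoter of ", sQuote(tss_records$gene[i]),
              " truncated at the ", chrom, " edge")
      start <- max(0L, start); end <- min(clen, end)
    }
    seq <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
    if (strand == "-") seq <- Biostrings::reverseComplement(seq)
    data.frame(gene = tss_records$gene[i], chrom = chrom,
               start = start, end = end, strand = strand,
               truncated = truncated,
               sequence = toupper(as.character(seq)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Exact IUPAC motif scan of a promoter sequence
#'
#' All exact occurrences of each motif in the promoter sequence, with IUPAC
#' degeneracy honoured in the motif (e.g. `W` matches A or T) but never in
#' the sequence: an `N` in the promoter matches nothing. Overlapping
#' occurrences are each reported. With `both_strands = TRUE` (default; the
#' factor binds double-stranded DNA) the reverse complement of each motif is
#' scanned too and hits labeled with `strand_of_match = "-"`; offsets always
#' refer to the promoter (plus) orientation of the stored sequence.
#'
#' @param region One row of [extract_promoters()] output (or any list with
#'   `gene` and `sequence`).
#' @param motifs Named character vector of IUPAC motifs (see
#'   [read_motifs()]).
#' @param both_strands Scan the reverse complements as well (default TRUE).
#' @return `data.frame`: `gene`, `motif_id`, `offset` (0-based),
#'   `strand_of_match`, `width`.
#' @export
#' @examples
#' region <- list(gene = "g1", sequence = "AAAAA")
#' scan_motifs(region, c(m = "AAAA"), both_strands = FALSE)  # offsets 0 and 1
scan_motifs <- function(region, motifs, both_strands = TRUE) {
  stopifnot(!is.null(region$sequence), !is.null(region$gene),
            is.character(motifs), length(motifs) >= 1L,
            !is.null(names(motifs)))
  if (any(!nzchar(motifs))) stop("empty motif")
  subject <- Biostrings::DNAString(region$sequence)
  hit_rows <- function(motif_id, pattern, strand) {
    # fixed = "subject": IUPAC codes interpreted in the pattern only, so a
    # motif W matches A/T in the sequence while a sequence N matches nothing.
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                  fixed = "subject")
    if (length(m) > 0L) {
      # fixed = "subject" still lets a motif N match a sequence N; the
      # contract is that an ambiguous sequence base never matches anything
      clean <- !grepl("[^ACGT]", as.character(m))
      m <- m[clean]
    }
    if (length(m) == 0L) return(NULL)
    data.frame(gene = region$gene, motif_id = motif_id,
               offset = Biostrings::start(m) - 1L,
               strand_of_match = strand, width = nchar(pattern),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (id in names(motifs)) {
    out[[length(out) + 1L]] <- hit_rows(id, motifs[[id]], "+")
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motifs[[id]])))
      out[[length(out) + 1L]] <- hit_rows(id, rc, "-")
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(gene = character(), motif_id = character(),
                      offset = integer(), strand_of_match = character(),
                      width = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$offset, res$motif_id), , drop = FALSE]
}

#' Background-normalized read coverage over a promoter
#'
#' Per-base raw depth from interval overlap of aligned reads with the
#' promoter window, normalized by the expected depth under uniform
#' genome-wide read placement, `total_mapped * read_length / genome_length`.
#' A normalized value of 1 therefore means background-level coverage;
#' values above 1 indicate enrichment over the genome-wide background.
#'
#' @param reads `GRanges` of aligned-read intervals (see
#'   [read_reads_bed()]).
#' @param region One row of [extract_promoters()] output.
#' @param total_mapped Total number of mapped reads genome-wide.
#' @param genome_length Genome length in bp.
#' @param read_length Read length in bp.
#' @return List of class `coverage_track`: `gene`, `chrom`, `start`,
#'   `raw` (integer per-base counts, length `end - start`), `normalized`,
#'   `expected_depth`.
#' @export
promoter_coverage <- function(reads, region, total_mapped, genome_length,
                              read_length) {
  stopifnot(methods::is(reads, "GRanges"),
            total_mapped > 0, genome_length > 0, read_length > 0)
  width <- region$end - region$start
  on_chrom <- reads[as.character(GenomicRanges::seqnames(reads)) == region$chrom]
  if (length(on_chrom) == 0L) {
    raw <- integer(width)
  } else {
    # GRanges are 1-based closed; region is 0-based half-open
    ir <- IRanges::restrict(IRanges::ranges(on_chrom),
                            start = region$start + 1L, end = region$end)
    ir <- ir[IRanges::width(ir) > 0L]
    cov <- IRanges::coverage(IRanges::shift(ir, -region$start), width = width)
    raw <- as.integer(cov)
  }
  expected <- total_mapped * read_length / genome_length
  structure(list(gene = region$gene, chrom = region$chrom,
                 start = region$start, raw = raw,
                 normalized = raw / expected, expected_depth = expected),
            class = "coverage_track")
}

#' Motif / coverage co-occurrence summary
#'
#' Per-gene summary of how motif hits sit relative to read-coverage peaks: a
#' hit counts as overlapping when at least one base of its interval has
#' normalized coverage above `enrichment_threshold`.
#'
#' @param hits [scan_motifs()] output for one gene.
#' @param track [promoter_coverage()] output for the same gene.
#' @param enrichment_threshold Normalized-coverage cutoff defining "covered"
#'   bases (default 1, i.e. above genome-wide background).
#' @return List: `gene`, `n_hits`, `n_overlapping`, `hits` (the input with
#'   an `overlaps_peak` column), `covered_fraction`.
#' @export
cooccurrence_report <- function(hits, track, enrichment_threshold = 1) {
  stopifnot(inherits(track, "coverage_track"))
  if (nrow(hits) > 0L && any(hits$gene != track$gene))
    stop("hits and track refer to different genes")
  covered <- track$normalized > enrichment_threshold
  overlaps <- vapply(seq_len(nrow(hits)), function(i) {
    span <- seq.int(hits$offset[i] + 1L,
                    min(length(covered), hits$offset[i] + hits$width[i]))
    any(covered[span])
  }, logical(1))
  hits$overlaps_peak <- overlaps
  list(gene = track$gene, n_hits = nrow(hits),
       n_overlapping = sum(overlaps), hits = hits,
       covered_fraction = mean(covered))
}
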