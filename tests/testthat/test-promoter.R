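toy_genome <- function() {
  Biostrings::DNAStringSet(c(chrA = "ACGTACGTACGT", chrB = paste(
    rep("ACGT", 2000), collapse = "")))
}

test_that("extract_promoters: strand handling, boundary, truncation", {
  genome <- toy_genome()
  # + strand, TSS exactly L downstream of the chromosome start
  tss <- data.frame(gene = "gp", chrom = "chrB", tss = 5000, strand = "+")
  pr <- extract_promoters(tss, genome, 5000)
  expect_equal(pr$start, 0); expect_equal(pr$end, 5000)
  expect_equal(nchar(pr$sequence), 5000)
  expect_false(pr$truncated)

  # - strand on a 12-bp toy chromosome: hand-written reverse complement.
  # chrA = ACGTACGTACGT; TSS at position 3, promoter interval [4, 10) holds
  # ACGTAC; read 5'->3' on the minus strand that is GTACGT
  tssm <- data.frame(gene = "gm", chrom = "chrA", tss = 3, strand = "-")
  prm <- extract_promoters(tssm, genome, 6)
  expect_equal(prm$start, 4); expect_equal(prm$end, 10)
  expect_equal(prm$sequence, "GTACGT")

  # determinism
  expect_identical(extract_promoters(tssm, genome, 6), prm)

  # truncation at the chromosome edge is flagged
  tsst <- data.frame(gene = "gt", chrom = "chrA", tss = 5, strand = "+")
  expect_warning(prt <- extract_promoters(tsst, genome, 10), "truncated")
  expect_true(prt$truncated)
  expect_equal(prt$start, 0); expect_equal(prt$end, 5)

  expect_error(extract_promoters(
    data.frame(gene = "x", chrom = "nope", tss = 1, strand = "+"), genome, 2),
    "absent from genome")
})

test_that("scan_motifs: overlaps, IUPAC degeneracy, N semantics", {
  region <- list(gene = "g", sequence = "AAAAA")
  hits <- scan_motifs(region, c(m = "AAAA"), both_strands = FALSE)
  expect_equal(hits$offset, c(0, 1))
  # absent motif
  expect_equal(nrow(scan_motifs(region, c(m = "CCC"), both_strands = FALSE)), 0)
  # IUPAC degeneracy in the motif: W = A|T
  hits <- scan_motifs(list(gene = "g", sequence = "CATAC"), c(m = "AWA"),
                      both_strands = FALSE)
  expect_equal(hits$offset, 1)
  # N in the sequence never matches, even against motif N
  expect_equal(nrow(scan_motifs(list(gene = "g", sequence = "ANA"),
                                c(m = "ANA"), both_strands = FALSE)), 0)
  expect_equal(nrow(scan_motifs(list(gene = "g", sequence = "ANA"),
                                c(m = "AAA"), both_strands = FALSE)), 0)
  # both-strand scanning labels reverse-complement matches
  hits <- scan_motifs(list(gene = "g", sequence = "TTTTGCA"), c(m = "TGCA"))
  expect_true(any(hits$strand_of_match == "+"))
  hits2 <- scan_motifs(list(gene = "g", sequence = "AATTCC"), c(m = "GGAA"))
  expect_equal(hits2$strand_of_match, "-")
  expect_equal(hits2$offset, 2)
  expect_error(scan_motifs(region, c(m = "")), "empty motif")
})

test_that("scan_motifs equals the naive matcher on random short inputs", {
  set.seed(13)
  alphabet <- c("A", "C", "G", "T", "N")
  for (i in 1:30) {
    seq <- paste(sample(alphabet, sample(20:200, 1), replace = TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
    motif <- paste(sample(c("A", "C", "G", "T", "W", "R", "N"),
                          sample(3:6, 1), replace = TRUE), collapse = "")
    hits <- scan_motifs(list(gene = "g", sequence = seq), c(m = motif),
                        both_strands = FALSE)
    expect_equal(hits$offset, scan_naive(seq, motif))
  }
})

test_that("hit sets are strand-symmetric under sequence reverse-complement", {
  set.seed(14)
  seq <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
               collapse = "")
  motif <- c(m = "GWCAT")
  fwd <- scan_motifs(list(gene = "g", sequence = seq), motif)
  rev <- scan_motifs(list(gene = "g", sequence = revcomp_chr(seq)), motif)
  # every + hit becomes a - hit at the mirrored offset, and vice versa
  mirror <- function(off) nchar(seq) - off - nchar(motif[[1]])
  expect_setequal(mirror(fwd$offset[fwd$strand_of_match == "+"]),
                  rev$offset[rev$strand_of_match == "-"])
  expect_setequal(mirror(fwd$offset[fwd$strand_of_match == "-"]),
                  rev$offset[rev$strand_of_match == "+"])
})

test_that("promoter_coverage: interval arithmetic and normalization", {
  region <- list(gene = "g", chrom = "chr1", start = 100, end = 200)
  # one 10-bp read fully inside -> raw depth 1 over exactly 10 bases
  reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(121, width = 10))
  track <- promoter_coverage(reads, region, total_mapped = 1000,
                             genome_length = 1e5, read_length = 10)
  expect_equal(sum(track$raw), 10)
  expect_equal(track$raw[21:30], rep(1L, 10))
  expect_s3_class(track, "coverage_track")
  # zero reads in the promoter -> all zeros (valid)
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, width = 10))
  expect_equal(sum(promoter_coverage(far, region, 1000, 1e5, 10)$raw), 0)
  # total raw mass equals the sum of read-region overlap lengths
  set.seed(15)
  starts <- sample(1:300, 50, replace = TRUE)
  reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 25))
  track <- promoter_coverage(reads, region, 50, 1e4, 25)
  overlap <- pmax(0, pmin(starts + 24, 200) - pmax(starts, 101) + 1)
  expect_equal(sum(track$raw), sum(overlap))
  # uniform 1x tiling -> normalized ~ 1 everywhere
  tile <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    seq(1, 991, by = 10), width = 10))
  track <- promoter_coverage(tile, list(gene = "g", chrom = "chr1",
                                        start = 100, end = 200),
                             total_mapped = 100, genome_length = 1000,
                             read_length = 10)
  expect_equal(track$normalized, rep(1, 100))
})

test_that("cooccurrence_report counts hits overlapping covered bases", {
  region <- list(gene = "g", chrom = "c", start = 0, end = 50)
  reads <- GenomicRanges::GRanges("c", IRanges::IRanges(11, width = 10))
  # expected depth 0.1 -> the covered stretch is 10x background
  track <- promoter_coverage(reads, region, total_mapped = 10,
                             genome_length = 1000, read_length = 10)
  hits <- data.frame(gene = "g", motif_id = "m", offset = c(12, 40),
                     strand_of_match = "+", width = 4)
  rep <- cooccurrence_report(hits, track, enrichment_threshold = 1)
  expect_equal(rep$n_hits, 2)
  expect_equal(rep$n_overlapping, 1)
  expect_true(rep$hits$overlaps_peak[1])
  # no coverage anywhere -> zero overlaps regardless of motif count
  empty <- promoter_coverage(GenomicRanges::GRanges(), region, 10, 1000, 10)
  expect_equal(cooccurrence_report(hits, empty)$n_overlapping, 0)
})

test_that("simulated promoters recover planted motifs and peak enrichment", {
  motifs <- c(mA = "GACGTCAT", mB = "TTGACGGA")
  sim <- simulate_promoters_and_reads(4, motifs, n_planted = 2,
                                      promoter_length = 800,
                                      background_depth = 2,
                                      peak_enrichment = 5, seed = 19)
  proms <- extract_promoters(sim$tss, sim$genome, 800)
  for (i in seq_len(nrow(proms))) {
    hits <- scan_motifs(proms[i, ], motifs)
    planted <- sim$truth[sim$truth$gene == proms$gene[i], ]
    expect_equal(nrow(hits), nrow(planted))
    expect_setequal(paste(hits$motif_id, hits$offset),
                    paste(planted$motif_id, planted$offset))
  }
  # coverage enrichment inside the planted peak ~ peak_enrichment (+/- 25%)
  peaks <- attr(sim$truth, "peaks")
  ratios <- sapply(seq_len(nrow(proms)), function(i) {
    track <- promoter_coverage(sim$reads, proms[i, ], sim$total_mapped,
                               sim$genome_length, sim$read_length)
    pk <- peaks[peaks$gene == proms$gene[i], ]
    inside <- seq.int(pk$start + 1, pk$end)
    mean(track$normalized[inside]) / mean(track$normalized[-inside])
  })
  expect_lt(abs(mean(ratios) / 5 - 1), 0.25)
  # alphabet-disjoint motif, zero planted -> zero hits
  sim0 <- simulate_promoters_and_reads(1, c(only = "AAAAAAAAAA"),
                                       n_planted = 1, promoter_length = 300,
                                       seed = 20)
  pr0 <- extract_promoters(sim0$tss, sim0$genome, 300)
  h <- scan_motifs(pr0[1, ], c(absent = "TTTTTTTTTT"), both_strands = FALSE)
  expect_equal(nrow(h), 0)
  # seed reproducibility
  sim2 <- simulate_promoters_and_reads(4, motifs, n_planted = 2,
                                       promoter_length = 800,
                                       background_depth = 2,
                                       peak_enrichment = 5, seed = 19)
  expect_identical(as.character(sim2$genome), as.character(sim$genome))
  expect_identical(sim2$truth, sim$truth)
})
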