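#' Default simulated design
#'
#' The default synthetic design mirrors the screening setup this package
#' emulates: one focal condition, three comparison conditions, one
#' empty-vector control, two biological replicates each (extendable to
#' three).
#'
#' @param n_replicates Biological replicates per condition (default 2).
#' @return A [pipeline_config()] with conditions `hsa` (focal), `ptr`,
#'   `mmu`, `cja` (comparisons) and `vec` (control).
#' @export
default_sim_config <- function(n_replicates = 2L) {
  pipeline_config("hsa", c("ptr", "mmu", "cja"), control_condition = "vec",
                  reference_genes = c("REF1", "REF2"), calibrator = "vec")
}

#' Simulate an expression table with planted focal effects
#'
#' Baseline gene abundances are drawn log-normal (BPKM-like scale);
#' replicate values carry multiplicative log-normal noise at the stated
#' coefficient of variation. A planted fraction of genes shifts the focal
#' condition by the planted log2 effect uniformly against *all* comparison
#' conditions (direction drawn per gene), so planted genes satisfy the
#' unidirectional entry criterion up to noise. Identical seed gives an
#' identical table.
#'
#' @param n_genes Number of genes.
#' @param config A [pipeline_config()] naming the conditions (default
#'   [default_sim_config()]).
#' @param frac_affected Fraction of genes with a planted effect (default
#'   0.05).
#' @param log2_effect Planted log2 fold difference of the focal condition
#'   (default 1.5).
#' @param cv Replicate coefficient of variation (default 0.15, matching the
#'   visible replicate spread of small-sample overexpression screens).
#' @param n_replicates Biological replicates per condition (default 2).
#' @param seed Integer seed.
#' @return List: `expr` (an [expression_table()]) and `truth`
#'   (`data.frame`: `gene`, `planted_effect` in log2, `planted_direction`).
#' @export
simulate_expression <- function(n_genes, config = default_sim_config(),
                                frac_affected = 0.05, log2_effect = 1.5,
                                cv = 0.15, n_replicates = 2L, seed = 1L) {
  stopifnot(n_genes >= 1L, n_replicates >= 2L,
            frac_affected >= 0, frac_affected <= 1, cv >= 0)
  withr_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    conditions <- config_conditions(config)
    samples <- as.vector(t(outer(conditions, seq_len(n_replicates),
                                 function(c, r) paste0(c, "_", r))))
    design <- stats::setNames(rep(conditions, each = n_replicates), samples)
    # log-normal baseline on a BPKM-like scale (median ~ e, long right tail)
    baseline <- stats::rlnorm(n_genes, meanlog = 1, sdlog = 1.5)
    n_affected <- round(frac_affected * n_genes)
    affected <- if (n_affected > 0) sample(genes, n_affected) else character()
    dir_up <- stats::setNames(sample(c(TRUE, FALSE), n_affected, replace = TRUE),
                              affected)
    sdlog <- sqrt(log(1 + cv^2))
    values <- matrix(0, n_genes, length(samples),
                     dimnames = list(genes, samples))
    for (s in samples) {
      mu <- baseline
      if (design[[s]] == config$focal_condition && n_affected > 0) {
        idx <- match(affected, genes)
        mu[idx] <- mu[idx] * 2^(ifelse(dir_up, log2_effect, -log2_effect))
      }
      noise <- if (cv > 0)
        stats::rlnorm(n_genes, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, n_genes)
      values[, s] <- mu * noise
    }
    truth <- data.frame(gene = genes,
                        planted_effect = 0, planted_direction = "none",
                        stringsAsFactors = FALSE)
    if (n_affected > 0) {
      idx <- match(affected, genes)
      truth$planted_effect[idx] <- ifelse(dir_up, log2_effect, -log2_effect)
      truth$planted_direction[idx] <- ifelse(dir_up, "up", "down")
    }
    list(expr = expression_table(values, design), truth = truth)
  })
}

#' Simulate Ct measurements from planted relative abundances
#'
#' Ct values follow the perfect-doubling model
#' `Ct = base - log2(abundance) + N(0, noise_sd)`, with the given number of
#' technical replicates per biological replicate; reference genes are
#' constant across conditions up to the same noise. Input abundances are
#' normalized per gene so the calibrator condition has geometric mean 1 —
#' with zero noise [delta_delta_ct()] then recovers the (normalized)
#' abundances exactly.
#'
#' @param abundances Long `data.frame`: `gene`, `condition`, `bio_rep`,
#'   `abundance` (> 0). Must include the calibrator condition for every
#'   gene.
#' @param config A [pipeline_config()] providing `reference_genes` and
#'   `calibrator`.
#' @param noise_sd Gaussian Ct noise in cycles (default 0.1).
#' @param n_tech Technical replicates (default 3).
#' @param base_ct Baseline cycle number (default 25).
#' @param seed Integer seed.
#' @return List: `ct` (`data.frame` of Ct records incl. reference genes) and
#'   `truth` (`data.frame`: `gene`, `condition`, `bio_rep`, `value` — the
#'   calibrator-normalized planted abundances).
#' @export
simulate_ct <- function(abundances, config = default_sim_config(),
                        noise_sd = 0.1, n_tech = 3L, base_ct = 25,
                        seed = 1L) {
  stopifnot(is.data.frame(abundances),
            all(c("gene", "condition", "bio_rep", "abundance") %in%
                  names(abundances)),
            all(abundances$abundance > 0),
            length(config$reference_genes) >= 1L,
            !is.null(config$calibrator))
  withr_seed(seed, {
    # normalize per gene so the calibrator geometric mean is exactly 1
    norm <- do.call(rbind, lapply(split(abundances, abundances$gene),
                                  function(g) {
      cal <- g$abundance[g$condition == config$calibrator]
      if (length(cal) == 0L)
        stop("gene ", sQuote(g$gene[1]), " lacks calibrator condition ",
             sQuote(config$calibrator))
      g$value <- g$abundance / exp(mean(log(cal)))
      g
    }))
    rownames(norm) <- NULL
    keys <- unique(norm[, c("condition", "bio_rep")])
    ref_rows <- do.call(rbind, lapply(config$reference_genes, function(rg)
      data.frame(gene = rg, condition = keys$condition,
                 bio_rep = keys$bio_rep, value = 1,
                 stringsAsFactors = FALSE)))
    all_rows <- rbind(norm[, c("gene", "condition", "bio_rep", "value")],
                      ref_rows)
    ct <- do.call(rbind, lapply(seq_len(nrow(all_rows)), function(i) {
      mu <- base_ct - log2(all_rows$value[i])
      data.frame(gene = all_rows$gene[i], condition = all_rows$condition[i],
                 bio_rep = all_rows$bio_rep[i], tech_rep = seq_len(n_tech),
                 ct = mu + stats::rnorm(n_tech, 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
    rownames(ct) <- NULL
    list(ct = ct, truth = norm[, c("gene", "condition", "bio_rep", "value")])
  })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate promoters with planted motifs and enriched read coverage
#'
#' Each gene receives its own chromosome: `promoter_length` bp of iid
#' uniform background (the promoter, upstream of a TSS placed at position
#' `promoter_length`) plus a 3' flank. Motif instances are planted at
#' recorded non-overlapping offsets; the background is redrawn (up to 50
#' times) until it contains no spontaneous matches of any motif outside the
#' planted offsets, so scanned hits equal planted hits. Reads of fixed
#' length are placed uniformly over the whole genome at the stated mean
#' background depth, plus extra reads inside the planted peak interval at
#' `peak_enrichment` times the background density.
#'
#' @param n_genes Number of genes/chromosomes.
#' @param motifs Named character vector of IUPAC motifs.
#' @param n_planted Planted instances per motif per promoter (default 2).
#' @param promoter_length Promoter window length (default 1000 for
#'   simulation speed; the analysis default is 5000).
#' @param flank 3' flank length beyond the TSS (default 500).
#' @param background_depth Mean per-base background read depth (default 1).
#' @param peak_enrichment Coverage enrichment factor inside the planted peak
#'   (default 5).
#' @param peak_width Width of the planted peak interval (default 200).
#' @param read_length Read length in bp (default 50).
#' @param seed Integer seed.
#' @return List: `genome` (`DNAStringSet`), `tss` (`data.frame` for
#'   [extract_promoters()]), `reads` (`GRanges`), `read_length`,
#'   `total_mapped`, `genome_length`, and `truth` (`data.frame`: `gene`,
#'   `motif_id`, `offset`; plus attribute `peaks` with the planted peak
#'   intervals in promoter coordinates).
#' @export
simulate_promoters_and_reads <- function(n_genes, motifs, n_planted = 2L,
                                         promoter_length = 1000L,
                                         flank = 500L,
                                         background_depth = 1,
                                         peak_enrichment = 5,
                                         peak_width = 200L,
                                         read_length = 50L, seed = 1L) {
  stopifnot(n_genes >= 1L, length(motifs) >= 1L,
            all(nchar(motifs) < promoter_length))
  withr_seed(seed, {
    genes <- sprintf("gene%03d", seq_len(n_genes))
    chrom_len <- promoter_length + flank
    seqs <- character(n_genes)
    truth <- list(); peaks <- list()
    widths <- nchar(motifs)
    for (gi in seq_len(n_genes)) {
      # plant non-overlapping motif instances in the promoter
      for (attempt in seq_len(50L)) {
        seq <- random_dna(chrom_len)
        placed <- data.frame(motif_id = character(), offset = integer(),
                             stringsAsFactors = FALSE)
        occupied <- integer()
        ok <- TRUE
        for (id in names(motifs)) {
          w <- widths[[id]]
          for (k in seq_len(n_planted)) {
            slot <- NULL
            for (try in seq_len(200L)) {
              cand <- sample.int(promoter_length - w + 1L, 1L) - 1L
              if (!any(seq.int(cand, cand + w - 1L) %in% occupied)) {
                slot <- cand; break
              }
            }
            if (is.null(slot)) { ok <- FALSE; break }
            # instantiate the IUPAC motif as a concrete sequence
            inst <- vapply(strsplit(motifs[[id]], "")[[1]], function(ch) {
              opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
              opts[sample.int(length(opts), 1L)]
            }, character(1))
            substr(seq, slot + 1L, slot + w) <- paste(inst, collapse = "")
            occupied <- c(occupied, seq.int(slot, slot + w - 1L))
            placed <- rbind(placed, data.frame(motif_id = id, offset = slot,
                                               stringsAsFactors = FALSE))
          }
          if (!ok) break
        }
        if (!ok) next
        # collision check: no hits beyond the planted ones (either strand)
        hits <- scan_motifs(list(gene = genes[gi],
                                 sequence = substr(seq, 1, promoter_length)),
                            motifs, both_strands = TRUE)
        planted_keys <- paste(placed$motif_id, placed$offset, "+")
        if (nrow(hits) == nrow(placed) &&
            setequal(paste(hits$motif_id, hits$offset, hits$strand_of_match),
                     planted_keys)) break
        if (attempt == 50L)
          stop("could not generate a collision-free background; ",
               "use longer or fewer motifs")
      }
      seqs[gi] <- seq
      placed$gene <- genes[gi]
      truth[[gi]] <- placed[, c("gene", "motif_id", "offset")]
      peak_start <- sample.int(promoter_length - peak_width + 1L, 1L) - 1L
      peaks[[gi]] <- data.frame(gene = genes[gi], start = peak_start,
                                end = peak_start + peak_width,
                                stringsAsFactors = FALSE)
    }
    genome <- Biostrings::DNAStringSet(stats::setNames(seqs, genes))
    tss <- data.frame(gene = genes, chrom = genes,
                      tss = promoter_length, strand = "+",
                      stringsAsFactors = FALSE)
    # background reads: uniform over every chromosome
    n_bg_per_chrom <- round(background_depth * chrom_len / read_length)
    read_rows <- list()
    for (gi in seq_len(n_genes)) {
      starts <- sample.int(chrom_len - read_length + 1L, n_bg_per_chrom,
                           replace = TRUE) - 1L
      pk <- peaks[[gi]]
      n_peak <- round((peak_enrichment - 1) * background_depth *
                        (pk$end - pk$start) / read_length)
      if (n_peak > 0) {
        # peak reads lie fully inside the peak so the planted coverage mass
        # (n_peak * read_length) lands entirely in the interval
        starts <- c(starts, sample(seq.int(pk$start, pk$end - read_length),
                                   n_peak, replace = TRUE))
      }
      read_rows[[gi]] <- data.frame(chrom = genes[gi], start = starts,
                                    stringsAsFactors = FALSE)
    }
    rr <- do.call(rbind, read_rows)
    reads <- GenomicRanges::GRanges(rr$chrom,
                                    IRanges::IRanges(rr$start + 1L,
                                                     width = read_length))
    truth_df <- do.call(rbind, truth)
    attr(truth_df, "peaks") <- do.call(rbind, peaks)
    list(genome = genome, tss = tss, reads = reads,
         read_length = read_length, total_mapped = length(reads),
         genome_length = n_genes * chrom_len, truth = truth_df)
  })
}

#' Simulate a scored network and GO annotations with a planted module
#'
#' A two-block random graph: a dense planted module (edge probability
#' `edge_prob_within`) embedded in a sparse background
#' (`edge_prob_between`), with combined scores drawn uniform(0.15, 1). One
#' planted GO term annotates the module genes plus background genes at the
#' base annotation rate; the remaining terms annotate genes at the base
#' rate only.
#'
#' @param n_nodes Total nodes.
#' @param module_size Planted module size (<= `n_nodes`).
#' @param edge_prob_within Edge probability inside the module (default 0.6).
#' @param edge_prob_between Edge probability elsewhere (default 0.05).
#' @param n_terms Number of GO terms (default 20); term 1 is the planted
#'   one.
#' @param base_rate Background annotation probability per gene/term
#'   (default 0.08).
#' @param seed Integer seed.
#' @return List: `network` ([ppi_network()]), `annotations` (`data.frame`
#'   `gene`, `term`), `sample` (module genes), `universe` (all genes),
#'   `truth` (list with `module`, `planted_term`).
#' @export
simulate_network_and_go <- function(n_nodes, module_size,
                                    edge_prob_within = 0.6,
                                    edge_prob_between = 0.05,
                                    n_terms = 20L, base_rate = 0.08,
                                    seed = 1L) {
  stopifnot(module_size <= n_nodes, module_size >= 2L,
            edge_prob_within > 0, edge_prob_within < 1,
            edge_prob_between > 0, edge_prob_between < 1)
  withr_seed(seed, {
    nodes <- sprintf("prot%03d", seq_len(n_nodes))
    module <- nodes[seq_len(module_size)]
    pairs <- utils::combn(nodes, 2)
    in_module <- pairs[1, ] %in% module & pairs[2, ] %in% module
    prob <- ifelse(in_module, edge_prob_within, edge_prob_between)
    present <- stats::runif(ncol(pairs)) < prob
    edges <- data.frame(node_a = pairs[1, present], node_b = pairs[2, present],
                        score = stats::runif(sum(present), 0.15, 1),
                        stringsAsFactors = FALSE)
    net <- ppi_network(edges, nodes = nodes)
    terms <- sprintf("GO:%07d", seq_len(n_terms))
    ann <- list()
    for (tm in terms) {
      carriers <- nodes[stats::runif(n_nodes) < base_rate]
      if (tm == terms[1]) carriers <- union(carriers, module)
      if (length(carriers) > 0L)
        ann[[tm]] <- data.frame(gene = carriers, term = tm,
                                stringsAsFactors = FALSE)
    }
    annotations <- do.call(rbind, ann)
    rownames(annotations) <- NULL
    list(network = net, annotations = annotations, sample = module,
         universe = nodes,
         truth = list(module = module, planted_term = terms[1]))
  })
}

# Evaluate `expr` with a locally-set RNG seed, restoring the caller's RNG
# state afterwards (generators must not disturb the session RNG).
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
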