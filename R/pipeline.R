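#' Run the full screening pipeline
#'
#' Chains the analysis stages over a set of input files and writes one
#' tab-separated result table per stage (plus bedGraph coverage tracks and a
#' plain-text run log recording the configuration, seed, package version and
#' input checksums). Identical config + inputs + seed give byte-identical
#' result tables.
#'
#' Stage-to-input mapping (paths in `inputs`, all optional except those of
#' the requested stages):
#' * `screen`: `expression` (TSV) + `design` (TSV `sample`, `condition`),
#'   optional `reference_lists` (named in config) and `annotations`;
#' * `qpcr`: `ct` (TSV of Ct records);
#' * `validate`: `relative_expression` (TSV);
#' * `promoters`: `genome` (FASTA), `tss` (BED), `motifs`, optional `reads`
#'   (BED) with `total_mapped`, `genome_length`, `read_length` entries;
#' * `network`: `edges` (TSV);
#' * `go`: `go_annotations` (TSV), `go_sample`, `go_universe` (gene lists);
#' * `dnds`: `dnds` (TSV).
#'
#' @param config A [pipeline_config()].
#' @param inputs Named list of file paths / values as above.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run, or `"all"`.
#' @return Invisibly, a named list of the output file paths.
#' @export
run_pipeline <- function(config, inputs, out_dir,
                         stages = c("screen", "qpcr", "validate", "promoters",
                                    "network", "go", "dnds")) {
  stopifnot(inherits(config, "pipeline_config"), is.list(inputs))
  if (identical(stages, "all"))
    stages <- c("screen", "qpcr", "validate", "promoters", "network", "go",
                "dnds")
  known <- c("screen", "qpcr", "validate", "promoters", "network", "go",
             "dnds")
  if (length(bad <- setdiff(stages, known)) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))

  required <- list(
    screen = c("expression", "design"), qpcr = "ct",
    validate = "relative_expression",
    promoters = c("genome", "tss", "motifs"),
    network = "edges", go = c("go_annotations", "go_sample", "go_universe"),
    dnds = "dnds")
  for (st in stages) {
    missing <- setdiff(required[[st]], names(inputs))
    if (length(missing) > 0L)
      stop("stage ", sQuote(st), " requires input(s): ",
           paste(missing, collapse = ", "))
    paths <- unlist(inputs[required[[st]]])
    unreadable <- paths[!file.exists(paths)]
    if (length(unreadable) > 0L)
      stop("input file(s) not found for stage ", sQuote(st), ": ",
           paste(unreadable, collapse = ", "))
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  outputs <- list()
  log_lines <- c(
    "phylocontrast run log",
    paste0("package_version: ", as.character(utils::packageVersion("phylocontrast"))),
    paste0("seed: ", config$seed),
    paste0("config: ", jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                        digits = NA)),
    paste0("stages: ", paste(stages, collapse = ",")),
    vapply(names(inputs)[vapply(inputs, function(x)
      is.character(x) && length(x) == 1 && file.exists(x), logical(1))],
      function(nm) paste0("input ", nm, " md5=",
                          unname(tools::md5sum(inputs[[nm]]))), character(1)))

  if ("screen" %in% stages) {
    design_df <- utils::read.delim(inputs$design, stringsAsFactors = FALSE)
    design <- stats::setNames(design_df$condition, design_df$sample)
    expr <- read_expression_table(inputs$expression, design)
    candidates <- entry_screen(expr, config)
    st <- screen_stats(expr, config, genes = rownames(expr$values))
    ref_lists <- if (!is.null(inputs$reference_lists))
      lapply(inputs$reference_lists, read_gene_list) else list()
    ann <- if (!is.null(inputs$annotations))
      utils::read.delim(inputs$annotations, stringsAsFactors = FALSE)
    else data.frame(gene = character(), protein_coding = logical(),
                    brain_expressed = logical())
    screen_res <- classify(candidates, st, ref_lists, ann, config)
    outputs$screen <- file.path(out_dir, "screen_results.tsv")
    write_result_table(screen_res, outputs$screen)
    outputs$screen_stats <- file.path(out_dir, "screen_stats.tsv")
    write_result_table(comparison_table(st), outputs$screen_stats)
  }

  if ("qpcr" %in% stages) {
    ct <- read_ct_table(inputs$ct)
    collapsed <- collapse_technical(ct)
    if (length(config$reference_genes) == 0L || is.null(config$calibrator))
      stop("qpcr stage requires reference_genes and calibrator in the config")
    rel <- delta_delta_ct(collapsed, config$reference_genes,
                          config$calibrator)
    outputs$qpcr <- file.path(out_dir, "qpcr_relative_expression.tsv")
    write_result_table(rel, outputs$qpcr)
  }

  if ("validate" %in% stages) {
    rel <- read_relative_expression(inputs$relative_expression)
    v <- validate(rel, config)
    tab <- comparison_table(v$stats)
    tab$verdict <- v$verdicts$verdict[match(tab$gene, v$verdicts$gene)]
    outputs$validate <- file.path(out_dir, "validation_stats.tsv")
    write_result_table(tab, outputs$validate)
  }

  if ("promoters" %in% stages) {
    tss <- read_tss_bed(inputs$tss)
    proms <- extract_promoters(tss, inputs$genome, config$promoter_length)
    motifs <- read_motifs(inputs$motifs)
    hits <- do.call(rbind, lapply(seq_len(nrow(proms)), function(i)
      scan_motifs(proms[i, ], motifs)))
    outputs$promoter_hits <- file.path(out_dir, "motif_hits.tsv")
    write_result_table(hits, outputs$promoter_hits)
    outputs$promoter_fasta <- file.path(out_dir, "promoters.fasta")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(stats::setNames(proms$sequence, proms$gene)),
      outputs$promoter_fasta)
    if (!is.null(inputs$reads)) {
      reads <- read_reads_bed(inputs$reads)
      summaries <- list()
      for (i in seq_len(nrow(proms))) {
        track <- promoter_coverage(reads, proms[i, ],
                                   total_mapped = inputs$total_mapped,
                                   genome_length = inputs$genome_length,
                                   read_length = inputs$read_length)
        bg <- file.path(out_dir, paste0("coverage_", proms$gene[i],
                                        ".bedGraph"))
        write_bedgraph(proms$chrom[i], proms$start[i], track$normalized, bg)
        outputs[[paste0("coverage_", proms$gene[i])]] <- bg
        rep_i <- cooccurrence_report(hits[hits$gene == proms$gene[i], ,
                                          drop = FALSE], track)
        summaries[[i]] <- data.frame(gene = rep_i$gene, n_hits = rep_i$n_hits,
                                     n_overlapping = rep_i$n_overlapping,
                                     covered_fraction = rep_i$covered_fraction)
      }
      outputs$promoter_summary <- file.path(out_dir, "promoter_summary.tsv")
      write_result_table(do.call(rbind, summaries), outputs$promoter_summary)
    }
  }

  if ("network" %in% stages) {
    net <- read_edge_table(inputs$edges)
    rows <- lapply(config$network_thresholds, function(th) {
      v <- threshold_view(net, th)
      ls <- lcc_stats(v)
      data.frame(threshold = th, n_nodes = length(v$nodes),
                 n_edges = nrow(v$edges), lcc_size = length(ls$lcc_nodes),
                 mean_degree_lcc = ls$mean_degree_lcc,
                 n_isolated = ls$n_isolated,
                 clustering = clustering_coefficient(v))
    })
    outputs$network <- file.path(out_dir, "network_stats.tsv")
    write_result_table(do.call(rbind, rows), outputs$network)
    deg <- lcc_stats(net)$degree
    outputs$degrees <- file.path(out_dir, "node_degrees.tsv")
    write_result_table(data.frame(node = names(deg),
                                  degree = as.integer(deg)),
                       outputs$degrees)
  }

  if ("go" %in% stages) {
    ann <- read_go_annotations(inputs$go_annotations)
    smp <- read_gene_list(inputs$go_sample)
    uni <- read_gene_list(inputs$go_universe)
    res <- go_enrichment(smp, ann, uni, config$go_alpha)
    outputs$go <- file.path(out_dir, "go_enrichment.tsv")
    write_result_table(res, outputs$go)
  }

  if ("dnds" %in% stages) {
    rec <- read_dnds_table(inputs$dnds)
    cmp <- compare_dnds(rec)
    outputs$dnds <- file.path(out_dir, "dnds_comparison.tsv")
    write_result_table(data.frame(
      n = cmp$n, mean_a = cmp$mean_a, mean_b = cmp$mean_b,
      median_a = cmp$median_a, median_b = cmp$median_b,
      U = cmp$mwu$U, p_two_sided = cmp$mwu$p_two_sided,
      method = cmp$mwu$method, note = cmp$note), outputs$dnds)
  }

  log_lines <- c(log_lines,
                 vapply(names(outputs), function(nm)
                   paste0("output ", nm, ": ", outputs[[nm]]), character(1)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  outputs$log <- file.path(out_dir, "run_log.txt")
  invisible(outputs)
}

#' Command-line entry point
#'
#' Subcommand interface mirroring [run_pipeline()]:
#' `phylocontrast_cli(c("screen", "--config", "cfg.json", ...))`.
#' Subcommands: `screen`, `qpcr`, `validate`, `promoters`, `network`, `go`,
#' `dnds`, `simulate`, `all`. Global flags: `--config FILE` (required except
#' for `simulate`), `--seed INT` (overrides the config seed), `--out-dir
#' DIR`, `--log-level quiet|info`, plus `--input.<name> PATH` pairs naming
#' the stage inputs (e.g. `--input.expression expr.tsv`).
#'
#' `simulate` writes a synthetic expression bundle (expression, design and
#' truth tables) usable as `screen` inputs; flags `--n-genes`,
#' `--frac-affected`, `--log2-effect`, `--cv`.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 on success, 1 on any handled
#'   error (so a wrapper script can `quit(status = ...)`).
#' @export
phylocontrast_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      stop("usage: phylocontrast <subcommand> [--config FILE] [--seed INT] ",
           "[--out-dir DIR] [--input.NAME PATH ...]")
    subcommand <- args[[1]]
    opts <- parse_cli_flags(args[-1])
    out_dir <- opts$flags[["out-dir"]] %||% "."
    quiet <- identical(opts$flags[["log-level"]], "quiet")

    if (subcommand == "simulate") {
      n_genes <- as.integer(opts$flags[["n-genes"]] %||% "1000")
      seed <- as.integer(opts$flags[["seed"]] %||% "1")
      sim <- simulate_expression(
        n_genes,
        frac_affected = as.numeric(opts$flags[["frac-affected"]] %||% "0.05"),
        log2_effect = as.numeric(opts$flags[["log2-effect"]] %||% "1.5"),
        cv = as.numeric(opts$flags[["cv"]] %||% "0.15"), seed = seed)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_expression_table(sim$expr, file.path(out_dir, "expression.tsv"))
      utils::write.table(data.frame(sample = names(sim$expr$design),
                                    condition = unname(sim$expr$design)),
                         file.path(out_dir, "design.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_result_table(sim$truth, file.path(out_dir, "truth.tsv"))
      if (!quiet) message("simulated ", n_genes, " genes into ", out_dir)
      return(invisible(0L))
    }

    if (is.null(opts$flags[["config"]]))
      stop("--config FILE is required")
    config <- read_config(opts$flags[["config"]])
    if (!is.null(opts$flags[["seed"]])) {
      config$seed <- as.integer(opts$flags[["seed"]])
    }
    stages <- if (subcommand == "all") "all" else
      strsplit(subcommand, ",", fixed = TRUE)[[1]]
    out <- run_pipeline(config, opts$inputs, out_dir, stages = stages)
    if (!quiet) message("wrote ", length(out), " output file(s) to ", out_dir)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  flags <- list(); inputs <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(args)) stop("flag ", a, " needs a value")
    val <- args[[i + 1L]]
    if (startsWith(key, "input.")) {
      inputs[[substring(key, 7)]] <- val
    } else {
      flags[[key]] <- val
    }
    i <- i + 2L
  }
  # numeric input parameters arrive as strings
  for (nm in c("total_mapped", "genome_length", "read_length"))
    if (!is.null(inputs[[nm]])) inputs[[nm]] <- as.numeric(inputs[[nm]])
  list(flags = flags, inputs = inputs)
}
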