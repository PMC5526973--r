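#' Unidirectional entry screen
#'
#' The entry criterion of the phylogenetic contrast: a gene passes when its
#' focal-condition mean is strictly above (direction "up") or strictly below
#' ("down") the mean of *every* comparison condition — including the
#' empty-vector control when the design has one. Mixed genes are excluded.
#'
#' @param expr An [expression_table()].
#' @param config A [pipeline_config()]; conditions are taken from it and the
#'   control condition (when set and present in the design) is screened
#'   against as well.
#' @return `data.frame` with `gene` and `direction` for passing genes.
#' @export
entry_screen <- function(expr, config) {
  stopifnot(inherits(expr, "expression_table"),
            inherits(config, "pipeline_config"))
  comps <- screen_comparison_conditions(expr, config)
  focal <- condition_values(expr, config$focal_condition)
  if (ncol(focal) < 2L)
    stop("focal condition needs >= 2 replicates")
  comp_means <- sapply(comps, function(cc) {
    v <- condition_values(expr, cc)
    if (ncol(v) < 2L) stop("condition ", sQuote(cc), " needs >= 2 replicates")
    rowMeans(v)
  })
  fm <- rowMeans(focal)
  up <- rowSums(fm > comp_means) == length(comps)
  down <- rowSums(fm < comp_means) == length(comps)
  data.frame(gene = rownames(expr$values)[up | down],
             direction = ifelse(up[up | down], "up", "down"),
             stringsAsFactors = FALSE)
}

# Comparison conditions used at the RNA screening stage: the configured
# comparisons plus the control when expression data exist for it.
screen_comparison_conditions <- function(expr, config) {
  comps <- config$comparison_conditions
  if (!is.null(config$control_condition) &&
      config$control_condition %in% expr$design)
    comps <- union(comps, config$control_condition)
  missing <- setdiff(comps, unique(expr$design))
  if (length(missing) > 0L)
    stop("conditions absent from the expression design: ",
         paste(missing, collapse = ", "))
  comps
}

#' Per-gene screening statistics
#'
#' Computes the full [group_comparison()] (focal vs pooled comparison
#' replicates) for a set of genes and assigns Benjamini-Hochberg FDRs across
#' that family (all genes tested in one stage form one family).
#'
#' @param expr An [expression_table()].
#' @param genes Genes to test; default all rows.
#' @param config A [pipeline_config()].
#' @param variant t-test variant (default Welch).
#' @return Named list of `group_comparison` records with `fdr` filled in.
#' @export
screen_stats <- function(expr, config, genes = rownames(expr$values),
                         variant = c("welch", "student")) {
  variant <- match.arg(variant)
  comps <- screen_comparison_conditions(expr, config)
  res <- lapply(genes, function(g) {
    reps <- lapply(comps, function(cc) condition_values(expr, cc)[g, ])
    names(reps) <- comps
    group_comparison(g, condition_values(expr, config$focal_condition)[g, ],
                     reps, variant = variant, alpha = config$alpha)
  })
  names(res) <- genes
  assign_fdr(res)
}

# BH across one testing family; fdr slot of each record is filled.
assign_fdr <- function(comparisons) {
  p <- vapply(comparisons, function(gc) gc$p_two_sided, numeric(1))
  fdr <- bh_fdr(p)
  for (i in seq_along(comparisons)) comparisons[[i]]$fdr <- fdr[[i]]
  comparisons
}

#' Twofold mean-versus-mean filter
#'
#' Retains candidates whose min fold-change satisfies
#' `|log2(fold)| >= log2(fold_threshold)`, i.e. every per-condition fold is
#' at least `fold_threshold` or at most `1/fold_threshold`. The boundary is
#' inclusive ("at least twofold"). Genes whose fold map is undefined
#' (nonpositive means) are dropped here.
#'
#' @param candidates Character vector of genes that passed [entry_screen()].
#' @param stats Named list of [group_comparison()] records (e.g. from
#'   [screen_stats()]).
#' @param config A [pipeline_config()].
#' @return Character vector of retained genes.
#' @export
twofold_filter <- function(candidates, stats, config) {
  keep <- vapply(candidates, function(g) {
    mfc <- stats[[g]]$min_fold_change
    !is.na(mfc) && abs(log2(mfc)) >= log2(config$fold_threshold)
  }, logical(1))
  candidates[keep]
}

#' Classify screened genes
#'
#' Three-way classification of entry-screen candidates:
#' * `reproduced` — present in at least one reference study's gene list with
#'   FDR below `alpha`;
#' * `new_candidate` — absent from all reference lists, passing entry and
#'   twofold filters, flagged protein-coding and brain-expressed;
#' * `rejected` — everything else. Genes that fail only the twofold
#'   threshold but are significant keep an explicit `below_fold_threshold`
#'   flag rather than disappearing.
#'
#' @param candidates `data.frame` from [entry_screen()] (`gene`,
#'   `direction`).
#' @param stats Named list of [group_comparison()] records with FDRs
#'   assigned.
#' @param reference_lists Named list of character vectors (one per reference
#'   study).
#' @param annotations `data.frame` with columns `gene`, `protein_coding`,
#'   `brain_expressed` (logical); genes absent from it default both flags to
#'   `FALSE`.
#' @param config A [pipeline_config()].
#' @return `data.frame` (one row per candidate): `gene`, `direction`,
#'   `passes_entry`, `passes_twofold`, `protein_coding`, `brain_expressed`,
#'   `in_reference_lists` (comma-joined labels), `fdr`, `min_fold_change`,
#'   `r_effect`, `power`, `below_fold_threshold`, `category`.
#' @export
classify <- function(candidates, stats, reference_lists, annotations, config) {
  stopifnot(is.data.frame(candidates), is.list(reference_lists))
  twofold <- twofold_filter(candidates$gene, stats, config)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    g <- candidates$gene[i]
    gc <- stats[[g]]
    in_refs <- names(reference_lists)[vapply(reference_lists,
                                             function(s) g %in% s, logical(1))]
    a <- annotations[match(g, annotations$gene), , drop = FALSE]
    pc <- isTRUE(a$protein_coding)
    be <- isTRUE(a$brain_expressed)
    passes_twofold <- g %in% twofold
    significant <- !is.na(gc$fdr) && gc$fdr < config$alpha
    category <- if (length(in_refs) > 0L && significant) "reproduced"
      else if (length(in_refs) == 0L && passes_twofold && pc && be) "new_candidate"
      else "rejected"
    data.frame(gene = g, direction = candidates$direction[i],
               passes_entry = TRUE, passes_twofold = passes_twofold,
               protein_coding = pc, brain_expressed = be,
               in_reference_lists = paste(in_refs, collapse = ","),
               fdr = gc$fdr, min_fold_change = gc$min_fold_change,
               r_effect = gc$r_effect, power = gc$power,
               below_fold_threshold = significant && !passes_twofold,
               category = category, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Reshape a long relative-expression table (gene, condition, bio_rep, value)
# into per-gene replicate lists: focal vector + named list per comparison.
split_relative <- function(values, config, comparison_conditions) {
  stopifnot(is.data.frame(values),
            all(c("gene", "condition", "bio_rep", "value") %in% names(values)))
  lapply(split(values, values$gene), function(g) {
    focal <- g$value[g$condition == config$focal_condition]
    comps <- lapply(comparison_conditions, function(cc)
      g$value[g$condition == cc])
    names(comps) <- comparison_conditions
    comps <- comps[lengths(comps) > 0L]
    list(focal = focal, comparisons = comps)
  })
}

#' Validation statistics on relative-expression values
#'
#' Runs the full per-gene statistics on a validation panel (qPCR relative
#' expression or densitometric values): Welch/Student t, BH FDR within this
#' panel's family, effect-size r, post-hoc power, per-condition folds and
#' min fold-change. The verdict per gene is `"significant"` (FDR < alpha),
#' `"large_effect_ns"` (not significant but r above the large-effect
#' benchmark — reported as a flagged, non-significant observation, never
#' merged with significance), or `"ns"`.
#'
#' Only the configured comparison conditions present in the table are used;
#' validation panels typically omit the empty-vector control.
#'
#' @param values Long `data.frame`: `gene`, `condition`, `bio_rep`, `value`.
#' @param config A [pipeline_config()].
#' @param variant t-test variant (default Welch).
#' @return List with `stats` (named list of [group_comparison()] with FDR)
#'   and `verdicts` (`data.frame`: `gene`, `verdict`).
#' @export
validate <- function(values, config, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  comps <- intersect(config$comparison_conditions, unique(values$condition))
  if (length(comps) == 0L)
    stop("no configured comparison condition present in the values")
  per_gene <- split_relative(values, config, comps)
  stats <- lapply(names(per_gene), function(g) {
    pg <- per_gene[[g]]
    group_comparison(g, pg$focal, pg$comparisons, variant = variant,
                     alpha = config$alpha)
  })
  names(stats) <- names(per_gene)
  stats <- assign_fdr(stats)
  verdicts <- do.call(rbind, lapply(names(stats), function(g) {
    gc <- stats[[g]]
    verdict <- if (!is.na(gc$fdr) && gc$fdr < config$alpha) "significant"
      else if (!is.na(gc$r_effect) && gc$r_effect > config$effect_r_threshold)
        "large_effect_ns"
      else "ns"
    data.frame(gene = g, verdict = verdict, stringsAsFactors = FALSE)
  }))
  list(stats = stats, verdicts = verdicts)
}

#' Reduced-sample re-analysis
#'
#' Recomputes the full per-gene statistics after excluding one or more
#' comparison conditions (e.g. a condition whose conspicuous values inflate
#' the pooled variance). N is unchanged, M shrinks, and the `1/(pq)` term of
#' the effect-size r uses the reduced sizes. With an empty drop set the
#' result is identical to [validate()].
#'
#' @param values Long `data.frame` as in [validate()].
#' @param drop_conditions Character vector of comparison conditions to
#'   exclude.
#' @param config A [pipeline_config()].
#' @param variant t-test variant.
#' @return As [validate()].
#' @export
reduced_sample_reanalysis <- function(values, drop_conditions, config,
                                      variant = c("welch", "student")) {
  variant <- match.arg(variant)
  comps <- intersect(config$comparison_conditions, unique(values$condition))
  remaining <- setdiff(comps, drop_conditions)
  if (length(remaining) == 0L)
    stop("cannot drop every comparison condition")
  reduced <- values[!values$condition %in% drop_conditions, , drop = FALSE]
  validate(reduced, config, variant = variant)
}

#' Compare two dN/dS samples
#'
#' Two-tailed Mann-Whitney U test between the two pairing columns of a dN/dS
#' table, with means and medians of both. When every value is below 1 the
#' summary carries a purifying-selection note (dN/dS < 1 indicates selection
#' against amino-acid exchanges).
#'
#' @param records `data.frame` with columns `gene`, `dnds_pair_a`,
#'   `dnds_pair_b` (see [read_dnds_table()]); rows with missing values are
#'   dropped.
#' @return List: `mwu` ([mwu_test()] result), `mean_a`, `mean_b`,
#'   `median_a`, `median_b`, `n`, `note` (`"purifying selection"` or `NA`).
#' @export
compare_dnds <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("dnds_pair_a", "dnds_pair_b") %in% names(records)))
  ok <- stats::complete.cases(records[, c("dnds_pair_a", "dnds_pair_b")])
  a <- records$dnds_pair_a[ok]
  b <- records$dnds_pair_b[ok]
  if (length(a) < 2L) stop("need >= 2 complete dN/dS records")
  mwu <- mwu_test(a, b)
  list(mwu = mwu, mean_a = mean(a), mean_b = mean(b),
       median_a = stats::median(a), median_b = stats::median(b),
       n = length(a),
       note = if (all(c(a, b) < 1)) "purifying selection" else NA_character_)
}
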