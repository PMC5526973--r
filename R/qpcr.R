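#' Collapse technical qPCR replicates
#'
#' Arithmetic mean Ct per (gene, condition, biological replicate); the number
#' of technical replicates entering each mean is retained for audit.
#'
#' @param records `data.frame` of Ct records with columns `gene`,
#'   `condition`, `bio_rep`, `tech_rep`, `ct` (see [read_ct_table()]).
#' @return `data.frame` with columns `gene`, `condition`, `bio_rep`, `ct`
#'   (the mean) and `n_tech`.
#' @export
collapse_technical <- function(records) {
  need <- c("gene", "condition", "bio_rep", "ct")
  stopifnot(is.data.frame(records), all(need %in% names(records)))
  agg <- stats::aggregate(ct ~ gene + condition + bio_rep, data = records,
                          FUN = mean)
  n <- stats::aggregate(ct ~ gene + condition + bio_rep, data = records,
                        FUN = length)
  agg$n_tech <- n$ct[match(
    paste(agg$gene, agg$condition, agg$bio_rep, sep = "\r"),
    paste(n$gene, n$condition, n$bio_rep, sep = "\r"))]
  agg[order(agg$gene, agg$condition, agg$bio_rep), , drop = FALSE]
}

#' Comparative-Ct relative quantification (2^-dCt-dCt[calibrator])
#'
#' The comparative-Ct (Livak-Schmittgen) method with multi-reference-gene
#' normalization. Per (target gene, condition, biological replicate):
#' \deqn{\Delta Ct = Ct_{target} - \mathrm{mean}(Ct_{references})}
#' \deqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{calibrator}}
#' \deqn{value = 2^{-\Delta\Delta Ct}}
#' where the calibrator baseline is the mean \eqn{\Delta Ct} over the
#' calibrator condition's biological replicates of the same gene. Averaging
#' reference Cts is equivalent to the geometric mean of the linear reference
#' quantities. PCR efficiency is fixed at 2 (perfect doubling).
#'
#' By construction the *mean ΔΔCt* of the calibrator condition is 0 per
#' gene, hence the geometric mean of calibrator values is exactly 1, and a
#' constant plate shift added to all Cts of a run cancels.
#'
#' @param ct_means Output of [collapse_technical()] (columns `gene`,
#'   `condition`, `bio_rep`, `ct`), containing target *and* reference genes.
#' @param reference_genes Character vector of reference gene identifiers
#'   (length >= 1); each must be measured for every (condition, bio_rep)
#'   combination in which a target is measured.
#' @param calibrator Condition label serving as calibrator.
#' @return `data.frame` with columns `gene`, `condition`, `bio_rep`,
#'   `delta_ct`, `delta_delta_ct`, `value` for all non-reference genes.
#' @export
#' @examples
#' ct <- data.frame(gene = rep(c("T", "REF"), each = 4),
#'                  condition = rep(c("ctl", "ctl", "trt", "trt"), 2),
#'                  bio_rep = rep(c("I", "II"), 4),
#'                  ct = c(20, 20, 18, 18, 15, 15, 15, 15))
#' delta_delta_ct(ct, "REF", "ctl")  # treatment at 4-fold
delta_delta_ct <- function(ct_means, reference_genes, calibrator) {
  stopifnot(is.data.frame(ct_means),
            all(c("gene", "condition", "bio_rep", "ct") %in% names(ct_means)),
            length(reference_genes) >= 1L)
  if (!calibrator %in% ct_means$condition)
    stop("calibrator condition ", sQuote(calibrator), " not present in Ct data")
  missing_refs <- setdiff(reference_genes, ct_means$gene)
  if (length(missing_refs) > 0L)
    stop("reference gene(s) not measured: ", paste(missing_refs, collapse = ", "))

  refs <- ct_means[ct_means$gene %in% reference_genes, , drop = FALSE]
  ref_mean <- stats::aggregate(ct ~ condition + bio_rep, data = refs, FUN = mean)
  ref_n <- stats::aggregate(ct ~ condition + bio_rep, data = refs, FUN = length)
  incomplete <- ref_n$ct < length(reference_genes)
  if (any(incomplete))
    stop("missing reference measurement for (condition, bio_rep) = (",
         ref_n$condition[incomplete][1], ", ", ref_n$bio_rep[incomplete][1], ")")

  targets <- ct_means[!ct_means$gene %in% reference_genes, , drop = FALSE]
  key <- paste(targets$condition, targets$bio_rep, sep = "\r")
  ref_key <- paste(ref_mean$condition, ref_mean$bio_rep, sep = "\r")
  idx <- match(key, ref_key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("missing reference measurement for (condition, bio_rep) = (",
         targets$condition[miss], ", ", targets$bio_rep[miss], ")")
  }
  targets$delta_ct <- targets$ct - ref_mean$ct[idx]

  out <- do.call(rbind, lapply(split(targets, targets$gene), function(g) {
    cal <- g$delta_ct[g$condition == calibrator]
    if (length(cal) == 0L)
      stop("gene ", sQuote(g$gene[1]), " has no measurement in calibrator ",
           sQuote(calibrator))
    g$delta_delta_ct <- g$delta_ct - mean(cal)
    g$value <- 2^(-g$delta_delta_ct)
    g
  }))
  rownames(out) <- NULL
  out[order(out$gene, out$condition, out$bio_rep),
      c("gene", "condition", "bio_rep", "delta_ct", "delta_delta_ct", "value")]
}
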