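#' Pipeline configuration
#'
#' Central parameter object for a phylogenetic-contrast screen. The focal
#' condition (e.g. cells overexpressing the human cDNA) is contrasted against
#' an ordered set of comparison conditions (non-human cDNAs) and, optionally,
#' an empty-vector control.
#'
#' @param focal_condition Label of the condition of interest.
#' @param comparison_conditions Character vector of comparison condition
#'   labels, in display order. Must not contain `focal_condition`.
#' @param control_condition Optional control label (e.g. empty vector). When
#'   present it is included among the comparisons at the RNA screening stage.
#' @param fold_threshold Minimum mean-versus-mean fold change (default 2):
#'   candidate genes must show at least this fold difference against every
#'   comparison condition.
#' @param alpha Significance threshold for all tests except GO enrichment
#'   (default 0.05).
#' @param go_alpha Significance threshold for GO enrichment (default 0.01).
#' @param effect_r_threshold Benchmark for a "large" effect-size correlation r
#'   (default 0.5).
#' @param power_threshold Benchmark of acceptable post-hoc test power
#'   (default 0.8).
#' @param promoter_length Length in bp of the putative promoter window
#'   upstream of the TSS (default 5000).
#' @param network_thresholds Combined-confidence score cutoffs defining the
#'   low/medium/high/maximum network views (default 0.15, 0.4, 0.7, 0.9).
#' @param reference_genes Identifiers of qPCR reference (housekeeping) genes.
#' @param calibrator Calibrator condition for comparative-Ct quantification;
#'   defaults to `control_condition` when unset.
#' @param seed Integer seed recorded with every run.
#'
#' @return An object of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config("hsa", c("ptr", "mmu", "cja"), control_condition = "vec")
#' cfg$fold_threshold
pipeline_config <- function(focal_condition,
                            comparison_conditions,
                            control_condition = NULL,
                            fold_threshold = 2,
                            alpha = 0.05,
                            go_alpha = 0.01,
                            effect_r_threshold = 0.5,
                            power_threshold = 0.8,
                            promoter_length = 5000L,
                            network_thresholds = c(0.15, 0.4, 0.7, 0.9),
                            reference_genes = character(),
                            calibrator = NULL,
                            seed = 1L) {
  stopifnot(is.character(focal_condition), length(focal_condition) == 1L,
            is.character(comparison_conditions), length(comparison_conditions) >= 1L)
  if (focal_condition %in% comparison_conditions)
    stop("focal_condition ", sQuote(focal_condition),
         " must not appear among comparison_conditions")
  if (anyDuplicated(comparison_conditions))
    stop("comparison_conditions contains duplicates")
  if (!is.null(control_condition)) {
    stopifnot(is.character(control_condition), length(control_condition) == 1L)
    if (control_condition == focal_condition)
      stop("control_condition equals focal_condition")
  }
  check_range <- function(x, name, lo, hi, lo_open = TRUE, hi_open = TRUE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
      (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
    if (!ok) stop(name, " must lie in the ", if (lo_open) "(" else "[", lo,
                  ", ", hi, if (hi_open) ")" else "]", " range")
  }
  check_range(fold_threshold, "fold_threshold", 0, Inf)
  check_range(alpha, "alpha", 0, 1)
  check_range(go_alpha, "go_alpha", 0, 1)
  check_range(effect_r_threshold, "effect_r_threshold", 0, 1, lo_open = FALSE)
  check_range(power_threshold, "power_threshold", 0, 1, lo_open = FALSE)
  if (!is.numeric(promoter_length) || length(promoter_length) != 1L ||
      promoter_length < 1 || promoter_length != round(promoter_length))
    stop("promoter_length must be a positive integer number of bp")
  if (!is.numeric(network_thresholds) || length(network_thresholds) < 1L ||
      any(network_thresholds <= 0 | network_thresholds > 1))
    stop("network_thresholds must lie in (0, 1]")
  if (is.null(calibrator)) calibrator <- control_condition

  structure(list(
    focal_condition = focal_condition,
    comparison_conditions = comparison_conditions,
    control_condition = control_condition,
    fold_threshold = as.numeric(fold_threshold),
    alpha = as.numeric(alpha),
    go_alpha = as.numeric(go_alpha),
    effect_r_threshold = as.numeric(effect_r_threshold),
    power_threshold = as.numeric(power_threshold),
    promoter_length = as.integer(promoter_length),
    network_thresholds = as.numeric(network_thresholds),
    reference_genes = as.character(reference_genes),
    calibrator = calibrator,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' All condition labels of a design
#'
#' Focal condition first, then comparisons, then the control if present.
#' @param config A [pipeline_config()].
#' @return Character vector of condition labels.
#' @export
config_conditions <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  c(config$focal_condition, config$comparison_conditions,
    setdiff(config$control_condition %||% character(), config$comparison_conditions))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config\n")
  cat("  focal:      ", x$focal_condition, "\n")
  cat("  comparisons:", paste(x$comparison_conditions, collapse = ", "), "\n")
  cat("  control:    ", x$control_condition %||% "<none>", "\n")
  cat("  fold >=", x$fold_threshold, " alpha", x$alpha, " go_alpha", x$go_alpha, "\n")
  cat("  promoter", x$promoter_length, "bp; network thresholds",
      paste(x$network_thresholds, collapse = "/"), "\n")
  invisible(x)
}

#' Write / read a pipeline configuration
#'
#' Serialized as JSON; `read_config(write_config(cfg, f))` reproduces `cfg`
#' exactly.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    focal_condition = raw$focal_condition,
    comparison_conditions = raw$comparison_conditions,
    control_condition = raw$control_condition,
    fold_threshold = raw$fold_threshold,
    alpha = raw$alpha,
    go_alpha = raw$go_alpha,
    effect_r_threshold = raw$effect_r_threshold,
    power_threshold = raw$power_threshold,
    promoter_length = raw$promoter_length,
    network_thresholds = raw$network_thresholds,
    reference_genes = raw$reference_genes %||% character(),
    calibrator = raw$calibrator,
    seed = raw$seed
  )
}
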