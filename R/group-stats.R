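#' Two-sample t-test (Student or Welch)
#'
#' Thin, contract-checked two-sample t-test. The Welch variant is the package
#' default throughout, consistent with the heteroscedastic effect-size measure
#' ([effect_size_r()]); Student's pooled-variance test is available for strict
#' replication of equal-variance software defaults.
#'
#' Degenerate inputs are resolved explicitly rather than propagating NaN:
#' both samples constant with equal means gives `t = 0, p = 1`; both constant
#' with unequal means gives `p = 0` and `degenerate = TRUE`.
#'
#' @param x,y Numeric samples, each of length >= 2, all values finite.
#' @param variant `"welch"` (default) or `"student"`.
#' @return List with `t`, `df`, `p`, and logical `degenerate`.
#' @export
#' @examples
#' t_test_two_sample(c(0.177, 0.211), c(1.875, 1.973, 1.598, 1.999), "student")
t_test_two_sample <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = if (variant == "student") n1 + n2 - 2 else NA_real_,
                  p = 1, degenerate = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = if (variant == "student") n1 + n2 - 2 else NA_real_,
                p = 0, degenerate = TRUE))
  }
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tval <- (mean(x) - mean(y)) / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df), degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values, capped at 1 and monotone in rank.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of the same length (empty in, empty out).
#' @export
bh_fdr <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  if (length(p) == 0L) return(numeric())
  stats::p.adjust(p, method = "BH")
}

#' Effect-size correlation r for heteroscedastic, unequal-n contrasts
#'
#' Standardized mean difference using the variance-averaged SD,
#' \deqn{d_{av} = (\bar y - \bar x) / \sqrt{(s_x^2 + s_y^2)/2},}
#' converted to a correlation-scale effect with the group-size proportion
#' term, \deqn{r = |d_{av}| / \sqrt{d_{av}^2 + 1/(pq)},} where
#' `p = n_x/(n_x+n_y)` and `q = n_y/(n_x+n_y)`. With equal group sizes the
#' term `1/(pq)` reduces to the familiar 4 of the d-to-r conversion; unequal
#' sizes shrink r toward 0. r lies in `[0, 1)`, is invariant under common
#' positive rescaling of both samples and under swapping the two groups.
#'
#' @param x Focal sample (length >= 2).
#' @param y Pooled comparison sample (length >= 2).
#' @return List with `d_av`, `r`, and logical `degenerate` (both variances
#'   zero: d and r undefined, returned as `NA`, unless the means are also
#'   equal, in which case `d_av = r = 0`).
#' @export
#' @examples
#' # focal n=2 vs pooled n=6, strongly separated groups
#' effect_size_r(c(4.423, 4.172), c(0.105, 0.143, 0.143, 0.169, 0.153, 0.182))$r
effect_size_r <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L,
            all(is.finite(x)), all(is.finite(y)))
  vx <- stats::var(x); vy <- stats::var(y)
  if (mean(x) == mean(y) && vx == 0 && vy == 0)
    return(list(d_av = 0, r = 0, degenerate = FALSE))
  if (vx == 0 && vy == 0)
    return(list(d_av = NA_real_, r = NA_real_, degenerate = TRUE))
  d <- (mean(y) - mean(x)) / sqrt((vx + vy) / 2)
  n1 <- length(x); n2 <- length(y)
  p <- n1 / (n1 + n2); q <- n2 / (n1 + n2)
  r <- abs(d) / sqrt(d^2 + 1 / (p * q))
  list(d_av = d, r = r, degenerate = FALSE)
}

#' Post-hoc power of the two-tailed two-sample t-test
#'
#' Exact noncentral-t power at the observed standardized difference and the
#' realized group sizes: noncentrality `ncp = |d_av| * sqrt(n1*n2/(n1+n2))`,
#' `df = n1 + n2 - 2`, rejection at the two-sided critical value
#' `qt(1 - alpha/2, df)`. At `d_av = 0` the power equals `alpha`; power is
#' nondecreasing in `|d_av|`, `n1`, `n2` and `alpha`.
#'
#' @param d_av Standardized mean difference (see [effect_size_r()]).
#' @param n1,n2 Group sizes, each >= 2.
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in `[alpha, 1]`.
#' @export
#' @examples
#' posthoc_power(0, 2, 6)             # = alpha
#' posthoc_power(3.9, 2, 6, 0.05)     # strong observed effect, small n
posthoc_power <- function(d_av, n1, n2, alpha = 0.05) {
  stopifnot(is.finite(d_av), n1 >= 2L, n2 >= 2L, alpha > 0, alpha < 1)
  ncp <- abs(d_av) * sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp = ncp) + stats::pt(tcrit, df, ncp = ncp,
                                               lower.tail = FALSE)
}

#' Min fold-change (mean versus mean) across comparison conditions
#'
#' For each comparison condition the fold is `mean_focal / mean_condition`;
#' the min fold-change is the fold closest to 1 in log space, i.e. the
#' element with minimal `|log2(fold)|` — the least extreme mean/mean ratio.
#' Direction is `"up"` when every fold exceeds 1, `"down"` when every fold is
#' below 1, and `"mixed"` otherwise (a fold of exactly 1 counts as mixed).
#'
#' Conditions with nonpositive means are excluded from the fold map and
#' reported in `excluded`; if the focal mean is nonpositive no folds can be
#' formed.
#'
#' @param mean_focal Focal-condition mean.
#' @param means_by_condition Named numeric vector of comparison-condition
#'   means.
#' @return List with `fold_by_condition` (named), `min_fold_change`,
#'   `direction`, and `excluded` (names of dropped conditions).
#' @export
#' @examples
#' min_fold_change(4.2975, c(ptr = 0.124, mmu = 0.156, cja = 0.1675))
min_fold_change <- function(mean_focal, means_by_condition) {
  stopifnot(is.numeric(mean_focal), length(mean_focal) == 1L,
            is.numeric(means_by_condition), length(means_by_condition) >= 1L,
            !is.null(names(means_by_condition)))
  excluded <- names(means_by_condition)[means_by_condition <= 0 |
                                          !is.finite(means_by_condition)]
  if (mean_focal <= 0 || !is.finite(mean_focal))
    return(list(fold_by_condition = stats::setNames(numeric(), character()),
                min_fold_change = NA_real_, direction = NA_character_,
                excluded = union(excluded, names(means_by_condition))))
  keep <- setdiff(names(means_by_condition), excluded)
  if (length(keep) == 0L)
    return(list(fold_by_condition = stats::setNames(numeric(), character()),
                min_fold_change = NA_real_, direction = NA_character_,
                excluded = excluded))
  folds <- mean_focal / means_by_condition[keep]
  mfc <- unname(folds[which.min(abs(log2(folds)))])
  direction <- if (all(folds > 1)) "up" else if (all(folds < 1)) "down" else "mixed"
  list(fold_by_condition = folds, min_fold_change = mfc,
       direction = direction, excluded = excluded)
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact null distribution (via the Wilcoxon rank-sum distribution) when
#' `length(a) * length(b) <= 400` and the data contain no ties; otherwise the
#' normal approximation with tie and continuity corrections. The reported U
#' is the statistic of sample `a` (`U <= n_a * n_b` always holds).
#'
#' @param a,b Numeric samples, each of length >= 1.
#' @return Object of class `mwu_result`: list with `U`, `p_two_sided`,
#'   `median_a`, `median_b`, `mean_a`, `mean_b`, `method`.
#' @export
#' @examples
#' mwu_test(c(1, 2), c(3, 4))  # U = 0, exact p = 2/6
mwu_test <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L,
            all(is.finite(a)), all(is.finite(b)))
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  U <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && n1 * n2 <= 400) {
    # exact: two-sided p as twice the smaller tail of the discrete U law
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(c(a, b))
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    mu <- n1 * n2 / 2
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- if (sigma2 == 0) 1 else min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(U = U, p_two_sided = p,
                 median_a = stats::median(a), median_b = stats::median(b),
                 mean_a = mean(a), mean_b = mean(b), method = method),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (%s), two-sided p = %.4g\n",
              x$U, x$method, x$p_two_sided))
  cat(sprintf("  medians %.4g vs %.4g; means %.4g vs %.4g\n",
              x$median_a, x$median_b, x$mean_a, x$mean_b))
  invisible(x)
}

#' Full statistical record for one focal-versus-pooled contrast
#'
#' Bundles everything the screen reports per gene: group summaries, the
#' t-test (p-value only; the FDR is assigned afterwards across the testing
#' family with [bh_fdr()]), the effect-size correlation r, noncentral-t
#' post-hoc power, per-condition folds and the min fold-change.
#'
#' @param gene Gene/protein identifier.
#' @param x Focal replicate values (length N >= 2).
#' @param replicates_by_condition Named list of comparison replicate vectors;
#'   their concatenation is the pooled sample (length M).
#' @param variant t-test variant, see [t_test_two_sample()].
#' @param alpha Significance level used for the power computation.
#' @return Object of class `group_comparison` (a one-row-per-gene record as a
#'   named list); `fdr` is `NA` until assigned by the caller.
#' @export
group_comparison <- function(gene, x, replicates_by_condition,
                             variant = c("welch", "student"), alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(is.list(replicates_by_condition),
            !is.null(names(replicates_by_condition)),
            length(replicates_by_condition) >= 1L)
  y <- unlist(replicates_by_condition, use.names = FALSE)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  tt <- t_test_two_sample(x, y, variant)
  es <- effect_size_r(x, y)
  pw <- if (is.na(es$d_av)) NA_real_ else
    posthoc_power(es$d_av, length(x), length(y), alpha)
  cond_means <- vapply(replicates_by_condition, mean, numeric(1))
  mfc <- min_fold_change(mean(x), cond_means)
  structure(list(
    gene = gene,
    N = length(x), M = length(y),
    mean_focal = mean(x), mean_other = mean(y),
    sd_focal = stats::sd(x), sd_other = stats::sd(y),
    t_stat = tt$t, df = tt$df, p_two_sided = tt$p, degenerate = tt$degenerate,
    fdr = NA_real_,
    d_av = es$d_av, r_effect = es$r, power = pw,
    fold_by_condition = mfc$fold_by_condition,
    min_fold_change = mfc$min_fold_change,
    direction = mfc$direction
  ), class = "group_comparison")
}

#' Flatten group comparisons to a result table
#'
#' One row per gene, mirroring the layout of a validation table: sample
#' sizes, means/SDs, t, df, p, FDR, d_av, r, power, min fold-change and
#' direction.
#'
#' @param comparisons List of [group_comparison()] records.
#' @return A `data.frame`.
#' @export
comparison_table <- function(comparisons) {
  stopifnot(all(vapply(comparisons, inherits, logical(1), "group_comparison")))
  do.call(rbind, lapply(comparisons, function(gc) {
    data.frame(gene = gc$gene, N = gc$N, M = gc$M,
               mean_focal = gc$mean_focal, mean_other = gc$mean_other,
               sd_focal = gc$sd_focal, sd_other = gc$sd_other,
               t_stat = gc$t_stat, df = gc$df, p_two_sided = gc$p_two_sided,
               fdr = gc$fdr, d_av = gc$d_av, r_effect = gc$r_effect,
               power = gc$power, min_fold_change = gc$min_fold_change,
               direction = gc$direction, stringsAsFactors = FALSE)
  }))
}
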