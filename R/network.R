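#' Scored protein-protein interaction network
#'
#' An undirected simple graph whose edges carry a combined confidence score
#' in (0, 1]. Duplicate pairs (in either orientation) are collapsed keeping
#' the maximum score; self-pairs are dropped with a warning. Nodes without
#' edges are retained when listed explicitly.
#'
#' @param edges `data.frame` with columns `node_a`, `node_b`, `score`.
#' @param nodes Optional character vector of node identifiers; defaults to
#'   the nodes appearing in `edges`. Extra isolated nodes may be added here.
#' @return Object of class `ppi_network`: list with `nodes` and `edges`
#'   (canonicalized `data.frame`).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b", "score") %in% names(edges)))
  if (nrow(edges) > 0L) {
    if (any(!is.finite(edges$score) | edges$score <= 0 | edges$score > 1))
      stop("combined scores must lie in (0, 1]")
    self <- edges$node_a == edges$node_b
    if (any(self)) {
      warning(sum(self), " self-interaction(s) dropped")
      edges <- edges[!self, , drop = FALSE]
    }
    a <- pmin(edges$node_a, edges$node_b)
    b <- pmax(edges$node_a, edges$node_b)
    key <- paste(a, b, sep = "\r")
    score <- tapply(edges$score, key, max)
    pairs <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
    edges <- data.frame(node_a = pairs[, 1], node_b = pairs[, 2],
                        score = as.numeric(score), stringsAsFactors = FALSE)
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_a = character(), node_b = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  }
  nodes <- sort(union(nodes %||% character(),
                      union(edges$node_a, edges$node_b)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Confidence-threshold view of a network
#'
#' Same node set, only edges with combined score at or above the threshold —
#' the low/medium/high/maximum confidence views correspond to thresholds
#' 0.15, 0.4, 0.7, 0.9.
#'
#' @param net A [ppi_network()].
#' @param threshold Score cutoff in (0, 1].
#' @return A [ppi_network()].
#' @export
threshold_view <- function(net, threshold) {
  stopifnot(inherits(net, "ppi_network"), threshold > 0, threshold <= 1)
  ppi_network(net$edges[net$edges$score >= threshold, , drop = FALSE],
              nodes = net$nodes)
}

#' Largest connected component and degree statistics
#'
#' Connected components by traversal; the LCC is the largest by node count,
#' with ties broken in favour of the component containing the
#' lexicographically smallest member. Degrees are counted within the full
#' (thresholded) graph by default; `degrees_within_lcc = TRUE` restricts the
#' counting to LCC-internal edges before averaging.
#'
#' @param net A [ppi_network()].
#' @param degrees_within_lcc Average LCC-internal degrees instead of
#'   full-graph degrees (default FALSE).
#' @return List: `lcc_nodes`, `degree` (named, all nodes, full graph),
#'   `mean_degree_lcc`, `n_isolated` (degree-0 nodes).
#' @export
lcc_stats <- function(net, degrees_within_lcc = FALSE) {
  stopifnot(inherits(net, "ppi_network"))
  if (length(net$nodes) == 0L)
    return(list(lcc_nodes = character(), degree = stats::setNames(integer(), character()),
                mean_degree_lcc = NaN, n_isolated = 0L))
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(ci)
      min(names(comp$membership)[comp$membership == ci]), character(1))
    best <- best[order(firsts)][1]
  }
  lcc <- sort(names(comp$membership)[comp$membership == best])
  mean_deg <- if (degrees_within_lcc) {
    sub <- igraph::induced_subgraph(g, lcc)
    mean(igraph::degree(sub))
  } else mean(deg[lcc])
  list(lcc_nodes = lcc, degree = deg, mean_degree_lcc = mean_deg,
       n_isolated = sum(deg == 0))
}

#' Mean local clustering coefficient
#'
#' Unweighted Watts-Strogatz local clustering coefficient averaged over all
#' nodes; nodes with degree below 2 contribute 0 and are included in the
#' mean (documented convention — some tools exclude them).
#'
#' @param net A [ppi_network()].
#' @return Mean local clustering coefficient in `[0, 1]` (`NaN` for an empty
#'   node set).
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  if (length(net$nodes) == 0L) return(NaN)
  local <- igraph::transitivity(as_igraph(net), type = "local",
                                isolates = "zero")
  mean(local)
}

#' PPI enrichment against a binomial background
#'
#' The observed edge count is compared with the expectation under an
#' Erdos-Renyi background in which each of the `choose(n, 2)` node pairs is
#' an edge independently with probability `background_edge_prob`. The
#' p-value is the one-sided upper binomial tail of observing at least the
#' observed number of edges. (Degree-corrected nulls as used by interaction
#' databases are deliberately not reproduced; the background probability is
#' user-supplied.)
#'
#' @param net A [ppi_network()].
#' @param background_edge_prob Background edge probability in (0, 1).
#' @return List: `observed`, `expected`, `p` (upper tail, >= observed).
#' @export
ppi_enrichment <- function(net, background_edge_prob) {
  stopifnot(inherits(net, "ppi_network"),
            background_edge_prob > 0, background_edge_prob < 1)
  n_pairs <- choose(length(net$nodes), 2)
  observed <- nrow(net$edges)
  expected <- n_pairs * background_edge_prob
  p <- stats::pbinom(observed - 1, n_pairs, background_edge_prob,
                     lower.tail = FALSE)
  list(observed = observed, expected = expected, p = p)
}

#' GO term enrichment (hypergeometric) with doubled-FDR adjustment
#'
#' Per term with K annotated universe genes and k annotated sample genes,
#' the p-value is the hypergeometric upper tail of drawing at least k
#' annotated genes in n draws from a universe of N. BH FDRs are computed
#' across terms and then doubled (capped at 1) as a conservative adjustment
#' for running the enrichment on two parallel datasets; a term is enriched
#' when the doubled FDR is below `go_alpha`.
#'
#' @param sample Character vector of sample genes (must all be in
#'   `universe`).
#' @param annotations `data.frame` with columns `gene`, `term`; genes
#'   outside the universe are ignored.
#' @param universe Character vector of universe genes.
#' @param go_alpha Significance threshold on the doubled FDR (default 0.01).
#' @return `data.frame` ordered by p: `term`, `k`, `K`, `n`, `N_universe`,
#'   `p`, `fdr`, `fdr_adjusted`, `enriched`.
#' @export
go_enrichment <- function(sample, annotations, universe, go_alpha = 0.01) {
  stopifnot(is.character(sample), is.character(universe),
            is.data.frame(annotations),
            all(c("gene", "term") %in% names(annotations)))
  sample <- unique(sample); universe <- unique(universe)
  offenders <- setdiff(sample, universe)
  if (length(offenders) > 0L)
    stop("sample gene(s) missing from universe: ",
         paste(offenders, collapse = ", "))
  ann <- unique(annotations[annotations$gene %in% universe, c("gene", "term")])
  if (nrow(ann) == 0L)
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N_universe = integer(), p = numeric(),
                      fdr = numeric(), fdr_adjusted = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE))
  N <- length(universe); n <- length(sample)
  K <- table(ann$term)
  k_tab <- table(ann$term[ann$gene %in% sample])
  terms <- names(K)
  k <- as.integer(k_tab[terms]); k[is.na(k)] <- 0L
  Kv <- as.integer(K)
  p <- stats::phyper(k - 1, Kv, N - Kv, n, lower.tail = FALSE)
  fdr <- bh_fdr(p)
  res <- data.frame(term = terms, k = k, K = Kv, n = n, N_universe = N,
                    p = p, fdr = fdr, fdr_adjusted = pmin(1, 2 * fdr),
                    enriched = pmin(1, 2 * fdr) < go_alpha,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
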