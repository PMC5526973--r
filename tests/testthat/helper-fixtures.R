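# Shared fixtures and independent oracles used across test files.

# The printed validation-table replicate values (shipped fixture).
qpcr_fixture <- function() {
  read_relative_expression(system.file("extdata",
                                       "qpcr_validation_replicates.tsv",
                                       package = "phylocontrast"))
}

densitometry_fixture <- function() {
  read_relative_expression(system.file("extdata",
                                       "densitometry_replicates.tsv",
                                       package = "phylocontrast"))
}

screen_config <- function() {
  pipeline_config("hsa", c("ptr", "mmu", "cja"), control_condition = "vec",
                  reference_genes = c("REF1", "REF2"), calibrator = "vec")
}

# --- independent oracles (kept deliberately naive) -----------------------

# BH step-up straight from the definition.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  # step-up: running minimum from the largest rank down
  for (i in seq_len(n)) adj[i] <- min(sorted[i:n], 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact two-sided MWU p by full enumeration of group assignments.
mwu_enumerate <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_stat <- function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- u_stat(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_stat)
  mu <- n1 * n2 / 2
  # two-sided: twice the smaller tail (matching the implementation's rule)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# Naive position-by-position IUPAC matcher.
iupac_sets <- local({
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
           W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
           V = "ACG", N = "ACGT")
  lapply(map, function(s) strsplit(s, "")[[1]])
})

scan_naive <- function(sequence, motif) {
  seq_chars <- strsplit(sequence, "")[[1]]
  motif_chars <- strsplit(motif, "")[[1]]
  L <- length(seq_chars); w <- length(motif_chars)
  if (w > L) return(integer())
  hits <- integer()
  for (off in 0:(L - w)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      s <- seq_chars[off + j]
      # N (or any ambiguity) in the sequence never matches
      if (!s %in% c("A", "C", "G", "T") ||
          !s %in% iupac_sets[[motif_chars[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Brute-force connected-component labeling by label propagation.
components_bruteforce <- function(nodes, edges) {
  label <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges$node_a[i]; b <- edges$node_b[i]
      m <- min(label[[a]], label[[b]])
      if (label[[a]] != m || label[[b]] != m) {
        label[[a]] <- m; label[[b]] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(label), label)
}

# Hypergeometric upper tail by direct enumeration of the mass function.
hyper_tail_enumerate <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
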