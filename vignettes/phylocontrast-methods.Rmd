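---
title: "Methods: phylogenetic-contrast screening with phylocontrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic-contrast screening with phylocontrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocontrast)
```

## The screening model

A phylogenetic-contrast screen compares one focal condition against several
comparison conditions that bracket it phylogenetically (orthologous cDNAs of
related species plus an empty-vector control). The inferential logic is that
a gene whose expression under the focal condition lies *outside the range* of
all comparison conditions — strictly above all of them or strictly below all
of them — is a candidate for lineage-specific regulatory change, whereas a
gene that falls inside the range ("mixed") is not. `phylocontrast` implements
this as a pure rank condition on condition means (`entry_screen()`); no
distributional assumption enters at this stage.

The entry set is then tightened by the **min fold-change** criterion
(`min_fold_change()`): with per-condition folds
$f_c = \bar x_{\mathrm{focal}} / \bar x_c$, the reported statistic is the
fold with minimal $|\log_2 f_c|$ — deliberately the *least* extreme ratio, so
"min fold $\geq$ 2" means the focal condition differs at least twofold from
*every* comparison condition, mean versus mean. The boundary is inclusive.
Ratios are undefined for nonpositive means; such conditions are excluded and
flagged rather than patched with a pseudocount (a configurable choice —
screens of this kind report candidates with clearly positive means, and a
silent pseudocount would bias folds of low-expression genes).

## Small-sample statistics

With $N$ focal and $M$ pooled comparison replicates (typically $2$ and $6$),
p-values alone are weak instruments, so the package reports a full record per
gene (`group_comparison()`):

* **t-test.** Welch by default; Student's pooled-variance test via
  `variant = "student"`. The Welch default is consistent with the
  heteroscedastic effect-size measure below; since small screens rarely
  support a variance-equality assumption across transfectant lines, this was
  the defensible default. Both constant samples with equal means give
  $t = 0, p = 1$; both constant with unequal means give $p = 0$ with a
  `degenerate` flag, so downstream code can see that the test left its
  domain of validity.
* **FDR.** Benjamini–Hochberg across one *stage family*: all genes of the
  RNA screen form one family, the qPCR validation panel another, the protein
  panel a third. This is the most conservative reading when the original
  family is not recorded.
* **Effect-size correlation.** The standardized difference uses the
  variance-averaged SD,
  $d_{av} = (\bar y - \bar x)\big/\sqrt{(s_x^2 + s_y^2)/2}$, which weights
  both group variances equally regardless of group size (appropriate under
  heteroscedasticity), and converts to the correlation scale with the
  group-size proportion term:
  $r = |d_{av}| \big/ \sqrt{d_{av}^2 + 1/(pq)}$, $p = N/(N{+}M)$,
  $q = M/(N{+}M)$. With equal groups $1/(pq) = 4$ (the familiar d-to-r
  conversion); unequal groups shrink $r$. $r \in [0, 1)$, is invariant under
  common rescaling and group exchange, and $r \geq 0.5$ is used as the
  benchmark of a large effect. This reconstruction reproduces published
  panel values to three decimals (see the acceptance tests), which is the
  package's evidence that it is the intended formula.
* **Post-hoc power.** Exact noncentral-t: $ncp = |d_{av}|\sqrt{NM/(N{+}M)}$,
  $df = N{+}M{-}2$, two-sided rejection at $t_{1-\alpha/2}$. Computed with
  R's `pt(ncp=)` (accuracy well below the $10^{-6}$ target). Power $> 0.8$
  is the conventional acceptability benchmark. The variance-averaged
  $d_{av}$ (not a pooled-SD $d$) reproduces published power values, so it is
  the adopted input.
* **Mann–Whitney U.** Exact (via the Wilcoxon distribution) for
  $N M \leq 400$ without ties; otherwise normal approximation with tie and
  continuity corrections. Two-sided p is twice the smaller tail, capped
  at 1.

The **validation verdict** per gene is `significant` (stage-family FDR below
$\alpha$), `large_effect_ns` ($r$ above the large-effect benchmark without
significance — reported as a flagged observation, never merged into
significance), or `ns`. The `reduced_sample_reanalysis()` operation repeats
everything after dropping chosen comparison conditions; $N$ is unchanged, $M$
shrinks, and the $1/(pq)$ term uses the reduced sizes.

## qPCR quantification

`delta_delta_ct()` implements the comparative-Ct method at fixed efficiency
2.0: $\Delta Ct = Ct_{target} - \mathrm{mean}(Ct_{refs})$, then
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{calibrator}$ (mean over
the calibrator condition's biological replicates of the same gene), and
$value = 2^{-\Delta\Delta Ct}$. Averaging reference *Cts* equals the
geometric mean of the linear reference quantities, the standard choice for
multi-reference normalization. Subtracting the *mean* calibrator $\Delta Ct$
makes the calibrator's geometric (not arithmetic) mean exactly 1; with one
calibrator replicate the two coincide. Plate shifts (a constant added to all
Cts of a run) cancel exactly. Efficiency estimation from amplification
curves is out of scope; the calibrator condition is configurable and
defaults to the empty-vector control.

## Promoter scanning and coverage

Putative promoters are the `promoter_length` bp (default 5000) upstream of
the TSS, 0-based half-open, reverse-complemented for minus-strand genes so
sequences always read promoter-5′→3′; windows truncated at chromosome edges
are flagged. Motif matching is *exact* (no mismatches, no PWM scores): IUPAC
degeneracy is honoured in the motif but an ambiguous base in the *sequence*
matches nothing — an `N` is missing data, not a wildcard. Matching is backed
by `Biostrings::matchPattern(fixed = "subject")` plus a post-filter removing
matches over non-ACGT sequence letters (that engine lets motif-`N` pair with
sequence-`N`); the test suite holds an independent naive matcher as oracle.
Both strands are scanned by default (the factor binds double-stranded DNA);
a flag disables this for strict single-strand replication.

Read coverage over a promoter is per-base depth divided by the expected
depth under uniform genome-wide placement,
$\mathrm{total\ mapped} \times \mathrm{read\ length} / \mathrm{genome\
length}$, so 1.0 means background level. The normalization constant is fully
parameterized because mapping parameters of external read sets are usually
unstated. `cooccurrence_report()` counts motif hits overlapping at least one
base above a configurable enrichment threshold (default 1.0).

## Network and GO statistics

Edge tables become simple undirected graphs (max-score deduplication,
self-pairs dropped with a warning, scores in (0,1]); threshold views at
0.15/0.4/0.7/0.9 correspond to low/medium/high/maximum confidence. The LCC
is the largest component (ties broken toward the lexicographically smallest
member, documented); mean degree over the LCC uses full-graph degrees by
default with an LCC-internal option, since published mean degrees do not
always state the convention. The mean local clustering coefficient includes
degree-<2 nodes as zeros (again a convention choice, stated rather than
silent). PPI enrichment uses a binomial Erdős–Rényi null with a
*user-supplied* background edge probability — an explicit simplification of
database-style degree-corrected nulls, which depend on a global interaction
snapshot this package does not ship. GO enrichment is the hypergeometric
upper tail per term against a user-supplied universe, BH-adjusted across
terms, then doubled and capped at 1 as a conservative correction for running
two parallel datasets; a term is enriched when the doubled FDR is below
`go_alpha` (default 0.01). Annotations are taken as already propagated; no
ontology-graph propagation is performed.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `fold_threshold` | 2.0 | fold | "at least twofold, mean vs mean"; boundary inclusive |
| `alpha` | 0.05 | — | all tests except GO enrichment |
| `go_alpha` | 0.01 | — | GO enrichment on the doubled FDR |
| `effect_r_threshold` | 0.5 | — | conventional large-effect benchmark |
| `power_threshold` | 0.8 | — | conventional acceptable-power benchmark |
| `promoter_length` | 5000 | bp | standard upstream-window size for this screen type |
| `network_thresholds` | .15/.4/.7/.9 | score | low/medium/high/maximum confidence views |
| t-variant | welch | — | heteroscedasticity-consistent; student available |

## The synthetic world

The generators emit exactly the formats the readers consume, with planted
truth serialized alongside:

* `simulate_expression()` draws log-normal baselines (meanlog 1, sdlog 1.5 —
  a right-skewed, BPKM-like scale) with multiplicative replicate noise at CV
  15% by default, matching the visible replicate spread of small
  overexpression panels; affected genes shift the focal condition by a
  planted log2 effect against *all* comparisons. The default design is one
  focal + three comparison conditions + one control at two replicates,
  extendable to three.
* `simulate_ct()` inverts the quantification model exactly at zero noise
  (abundances are calibrator-normalized before Ct synthesis, so the
  round-trip identity is exact, not approximate).
* `simulate_promoters_and_reads()` gives each gene its own chromosome,
  plants non-overlapping motif instances and redraws the background until no
  spontaneous match exists, so scanned hits *equal* planted hits.
  Palindromic motifs cannot satisfy this (each instance matches both
  strands) and are rejected after bounded retries. Peak reads are placed
  fully inside the planted interval so the mean enrichment ratio is unbiased.
* `simulate_network_and_go()` embeds a dense module in a sparse two-block
  graph and annotates it with one planted term over a base annotation rate.

What a green test on this world establishes: the pipeline's operations
compute their definitions correctly and recover structure they are designed
to detect, at stated noise levels. What it does not establish: robustness to
real-data pathologies absent from the generators — library-size artifacts,
correlated replicates, mappability bias in coverage, annotation
incompleteness, or degree-dependent edge nulls.

## Numerical and degenerate-input choices

Noncentral-t probabilities come from R's `pt(ncp=)` implementation
(series-based, ≲1e-12 here). Zero-variance t-tests and zero-variance effect
sizes resolve to documented constants or flagged `NA`s rather than NaNs.
Fold maps drop nonpositive means with flags. Result tables serialize
floating point at 6 significant digits (printed panels carry 3 decimals;
6 digits round-trip losslessly through text). Ties: a fold of exactly 1
makes a gene "mixed"; the LCC tie-break and the degree-<2 clustering
convention are described above.

## Known limitations

* The twofold filter applied to two-replicate means is noisy near the
  boundary: planted 2.5-fold effects at 15% replicate CV are recovered at
  only ~80% (≈95% at 10% CV), because one of several comparison folds
  crossing the inclusive 2.0 cutoff suffices for exclusion. Recovery ≥95%
  requires effects of ~2.8-fold (log2 1.5) at 10% CV, the regime exercised
  by the acceptance suite. Users planning screens near the threshold should
  add replicates rather than trust the filter's boundary behaviour.
* Stage-family FDRs depend on the family actually tested; published
  significance categories computed over a larger, unrecorded family will not
  be reproduced from a printed panel alone (the effect sizes, folds and
  powers will be).
* The PPI-enrichment null is binomial, not degree-corrected.
* Identifiers are opaque case-sensitive strings; no symbol normalization is
  attempted.
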