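---
title: "Statistical methods behind the xgrkit analysers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind the xgrkit analysers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xgrkit)
```

xgrkit provides six analysers over plain-text knowledgebases.  Three end in
ontology enrichment — of a gene list (EAG), of genes linked from GWAS SNPs
(EAS), or of genes linked from genomic regions (EAR) — and three end in gene
subnetwork identification from gene- (SAG), SNP- (SAS) or region-level (SAR)
summary statistics.  This vignette explains the statistical model behind
each stage, the tunable parameters and their defaults, the numerical
conventions, and what the synthetic benchmarks do and do not demonstrate.

## Ontology model and annotation propagation

An ontology is a set of terms, each annotating a set of gene symbols, with
an optional directed acyclic hierarchy of `(child, parent)` edges.  Gene
symbols are opaque, case-sensitive strings: no alias or identifier mapping
is attempted, so the caller must use one naming scheme consistently across
inputs and knowledgebase.

By default annotations are propagated up the hierarchy before testing (the
true-path rule): a gene annotated to a term is implicitly annotated to every
ancestor, `propagated[parent] = direct[parent] ∪ ⋃ propagated[children]`.
Propagation is idempotent and can be disabled (`propagate = FALSE`) for
ontologies whose annotation files are already propagated — whether a
pre-built annotation resource has been propagated varies between releases,
so the flag is exposed rather than guessed.

## Enrichment statistics

For a term annotating $K$ genes within a universe of $N$ genes, an input
list of $n$ genes overlapping the term in $k$ genes defines the 2×2 table
$a = k$, $b = K-k$, $c = n-k$, $d = N-K-n+k$.  The analysers report, per
term:

* **p-value** — the one-sided Fisher's exact test in the enrichment
  direction, i.e. the upper-tail hypergeometric probability
  $p = \sum_{j\ge k} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}$.
* **Z-score** — the overlap standardized by the exact null moments of the
  hypergeometric distribution, $z = (k-\mu)/\sigma$ with $\mu = nK/N$ and
  $\sigma^2 = nK(N-K)(N-n)/(N^2(N-1))$.  Degenerate tables with
  $\sigma = 0$ (e.g. a term equal to the universe) report $z = 0$.
* **Odds ratio and 95% CI** — the sample odds ratio $ad/bc$; when any cell
  is zero the Haldane–Anscombe correction adds 0.5 to all four cells, and
  the Woolf logit interval
  $\exp(\ln \mathrm{OR} \pm z_{0.975}\sqrt{1/a+1/b+1/c+1/d})$ is computed
  on the same (possibly corrected) cells, so strong enrichments with empty
  cells still yield finite estimates and intervals.
* **FDR** — Benjamini–Hochberg step-up across the *tested* terms.  Terms
  are tested when their propagated size within the universe lies in
  `[min_term, max_term]` (defaults 10 and 2000) and the overlap reaches
  `min_overlap` (default 3).  Restricting BH to tested terms treats the
  size/overlap filter as part of the study design; `fdr_scope = "filtered"`
  instead adjusts across all size-filtered terms (untested terms counting
  p = 1), which is never smaller.  Hierarchy-aware corrections are out of
  scope: the DAG dependence between terms is deliberately ignored, as is
  conventional for FDR-reporting enrichment servers.

The default universe is the set of genes with at least one propagated
annotation; a custom background can be substituted.  Input genes outside
the universe are dropped with a logged count.  Results are ordered by
`(fdr, pvalue, -zscore, term_id)` so equal-significance ties resolve
reproducibly.

## SNP and region linking

**Thresholding and LD expansion (SNPs).**  Input SNPs are kept when
$p < 5\times10^{-8}$ (the conventional genome-wide significance level;
adjustable), then expanded with linkage-disequilibrium proxies at
$r^2 \ge 0.8$ from a precomputed panel.  A proxy inherits its seed's
p-value and provenance; a SNP reachable from several seeds keeps the most
significant seed.  LD is consumed, never computed: the panel arrives as a
`seed, proxy, r2, proxy_chrom, proxy_pos` table for one population.

**Evidence.**  Three kinds of evidence link entities (SNPs or regions) to
genes, each producing rows `(entity, seed, gene, dataset, raw_weight)` with
weights in $[0,1]$:

* *Proximity*: a gene is linked when its TSS lies strictly within `window`
  (default 50 kb, chosen as a conventional cis-regulatory neighbourhood)
  of the entity; the weight decays linearly, $1 - d/W$.  The strict
  inequality means a SNP exactly at the window boundary produces no
  zero-weight evidence row.
* *Interval maps* (promoter-capture Hi-C, activity-by-contact enhancer
  maps): any half-open overlap between the entity and a dataset interval
  links the interval's gene, weighted by the interaction strength divided
  by the dataset-wide maximum.  Normalizing per dataset keeps
  heterogeneous assays comparable.  Multiple intervals linking the same
  entity–gene pair keep the maximum weight.
* *e/pQTL*: SNP–gene pairs with a precomputed weight in $(0,1]$.

Coordinates follow the field's two conventions at once: SNP positions are
1-based, intervals and regions are 0-based half-open (BED).  A SNP at
position $p$ is treated as the interval $[p-1, p)$.  One genome build per
run is assumed; no liftover is attempted.

**Scores.**  Published linked-gene scores "range 1 to 10" without a printed
formula, so xgrkit fixes a concrete, monotone, testable scheme: each
evidence row contributes $w \cdot s$ where $s = \min(-\log_{10} p_{seed},
10)/10$ for SNP-derived evidence and $s = 1$ for regions; per-gene raw
scores sum the contributions (additive pooling; `pool = "max"` takes the
per-dataset-kind maximum first, for callers who regard same-kind cell-type
datasets as redundant rather than cumulative); display scores rescale raw
scores linearly onto $[1, 10]$.  When all raw scores are equal — including
a single linked gene — every gene reports 10: a sole linked gene is the top
evidence, not the bottom.

## Subnetwork identification

Gene-level inputs become node scores $x = \min(-\log_{10} p, 16)$ (the cap
keeps prizes finite when p-values underflow to 0); SNP/region inputs use
the linked genes' display scores.  Network nodes without a score get
$x = 0$ and act as pure connectors — Steiner nodes are the point of the
formulation, so unscored genes are retained, not excluded.

**Prize-collecting Steiner tree heuristic.**  Given a penalty $\lambda$,
every node's prize is $x - \lambda$ and the goal is a connected subgraph
maximizing the prize sum.  The solver is deterministic and two-staged:

1. *Merging*: within each connected component, seeds (prize > 0) are
   merged in the Takahashi–Matsuyama style — starting from the
   highest-prize seed, the seed with the cheapest shortest-path connection
   to the growing tree is attached, with edge costs
   $((-p_u)_+ + (-p_v)_+)/2 + \varepsilon$ ($\varepsilon = 10^{-6}$) so
   paths prefer high-prize connectors and ties are broken by node order.
2. *Strong pruning*: the optimal connected subtree of the merged tree is
   extracted by dynamic programming ($f(v) = \text{prize}_v + \sum_c
   \max(f(c), 0)$, keeping the best-rooted positive subtree).  Pruning
   only leaves would keep negative bridges whose seeds were not worth
   reaching; the subtree DP is exact on trees, which also makes the
   heuristic exactly optimal whenever the input graph is itself a tree
   (paths, stars), a property the test suite checks by brute-force
   enumeration of connected subsets on graphs of up to 8 nodes.

All tie-breaks (root choice, attachment order, Dijkstra pops, DP root) use
lexicographic gene order, so results are bit-reproducible.

**Size targeting.**  The desired subnetwork size is reached by bisection on
$\lambda \in [0, \max x]$: larger penalties shrink the tree.  The search
stops when the size is within `tol` (default $\max(1, \lceil 0.1\,
\text{target}\rceil)$) of the target or after `max_iter` (50) steps, and
returns the iterate closest in size (ties: larger objective, then smaller
$\lambda$).  Size is not guaranteed to be strictly monotone in $\lambda$
for a heuristic, but the bisection trace is recorded and checked for
monotonicity in the test battery.

**Permutation significance.**  The degree-preserving null shuffles node
scores only within degree-quantile bins (10 deciles by default, fewer when
the network has fewer distinct degrees), preserving any score–hubness
relationship.  Each of the `B` permutations (default 100, a latency-minded
default; raise it for finer p-values) re-runs the *full* size-targeted
search, so the null distribution reflects the same selection procedure as
the observed statistic, and
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + B) \in
[1/(B+1), 1]$.  Re-running the search under the null (rather than re-using
the observed $\lambda$) was a deliberate choice: fixing $\lambda$ would
anti-conservatively ignore the adaptivity of the size search.

## Synthetic data: what it emulates, what it does not

`synth_knowledgebase()` / `generate_fixtures()` build a coherent toy world:
2,000 genes with TSS on a 200 kb grid over two chromosomes; 50 ontology
terms with sizes drawn from 20–200 and a shallow random hierarchy; one
designated planted term (40 genes, never an internal node of the DAG); a
100-node scale-free (preferential-attachment) network containing a planted
10-node high-confidence module drawn from the planted term; LD blocks of 3
proxies per significant seed with $r^2 \sim U(0.5, 1)$; promoter-anchored
interval evidence covering the planted genes plus ~30% of the genome; and
analyser inputs carrying the planted signal (an EAG list of 30 planted + 30
background genes; 15 genome-wide-significant SNPs within 20 kb of planted
TSS among 200; 12 planted regions among 50; module gene p-values of
$10^{-6}$–$10^{-10}$ against a uniform background).  These dimensions are
the package's benchmark conditions and are deliberately modest so the whole
battery runs on a laptop; the grid TSS layout makes proximity linking
unambiguous (at most one gene per 50 kb window).

What passing these benchmarks shows: the statistics match their closed
forms and independent oracles; planted signal of realistic strength is
recovered through the full pipelines; the permutation p-value is calibrated
under an exchangeable null.  What it does not show: behaviour on real
knowledgebases (correlated term memberships, annotation bias, LD structure
beyond block proxies, assay-specific strength distributions), robustness to
identifier mismatches, or the statistical subtleties of overlapping real
GWAS loci.  The planted-module recovery in particular benefits from the
module's elevated edge density; sparse real disease modules will be harder.

## Numerical conventions and edge cases

* Fisher p-values come from the hypergeometric upper tail; the test suite
  checks agreement with direct summation to relative error $10^{-10}$ over
  random tables with $N \le 200$.
* $\sigma = 0 \Rightarrow z = 0$; empty evidence yields an empty linked
  table (not an error); an empty pathway list merges to an empty network;
  all-negative prizes yield an empty subnetwork with objective 0.
* Duplicate network edges keep the maximum weight, making tier filtering
  monotone: the medium-confidence (≥0.4) network contains the
  high-confidence (≥0.7) network contains the highest-confidence (≥0.9)
  network, for any input.
* Duplicate input SNPs keep the smallest p-value.
* All RNG flows through explicit seeds; fixed-seed runs (including CLI
  runs) are byte-identical.

## Known limitations

* The linked-gene scoring scheme is this package's own concrete choice for
  a published 1–10 range without a printed formula; rankings are stable
  under monotone rescalings, absolute scores are not comparable to other
  tools.
* The PCST solver is a heuristic: near-optimality is validated empirically
  (≥ 0.9 × the enumerated optimum on random 8-node graphs, exact on trees)
  but not guaranteed on arbitrary graphs.
* Permutation p-values are bounded below by $1/(B+1)$; multiple-testing
  across several subnetwork runs is the caller's responsibility.
* One genome build, one gene naming scheme, one LD population per run.
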