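---
title: "Network fingerprints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network fingerprints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netfingerprint)
```

## The problem

Experimentalists routinely derive context-specific gene networks — a
differential-expression subnetwork, a curated disease module — and then
need to know *which biological processes the network resembles*.
Node-list enrichment answers part of that question but discards the
edges.  The network-fingerprint approach keeps them: a query network is
compared, pairwise, against an ordered set of expert-curated reference
pathway networks, and the vector of normalized similarity scores — one
coordinate per reference — is the query's *fingerprint*.  High
coordinates point at the pathways whose interaction structure and gene
content the query resembles; two queries fingerprinted against the same
reference set can be compared coordinate by coordinate.

Each coordinate is produced in two steps:

1. **Node–node mapping.**  The query and one reference are merged into
   a single graph and their nodes are clustered, so that genes playing
   similar roles in the two networks land in shared clusters.
2. **Similarity scoring.**  Every cluster gets a local similarity
   score; the raw network similarity is the mean over clusters; and the
   raw score is normalized to a Z-score against a permutation null.

## Attribute similarity

Edge weights between the two networks come from gene–gene attribute
similarity.  The default backend derives it from an ontology and a
gene→term annotation table:

* **Information content.**  For a term $t$,
  $IC(t) = -\ln\big(n(t)/N\big)$, where $n(t)$ counts universe genes
  annotated to $t$ or any descendant and $N$ is the annotated-gene
  universe.  The corpus is the supplied annotation table itself — no
  external frequency tables — with annotations propagated to ancestors
  before counting.  Only `is_a` edges are followed.
* **Term similarity** is Lin's measure,
  $\mathrm{sim}(t_1,t_2) = 2\,IC(\mathrm{MICA})/(IC(t_1)+IC(t_2))$,
  with the MICA (most informative common ancestor) allowed to be one of
  the terms themselves; it is 0 when the only shared ancestry has zero
  IC.
* **Gene similarity** is the best-match average (BMA) over the two
  genes' direct term sets: the mean of the average row maxima and
  average column maxima of the pairwise Lin matrix.

The measure itself is a declared design choice: Lin + BMA is bounded in
$[0,1]$ and is the standard gene-level aggregation for ontology-based
similarity.  The scorer is pluggable — `make_matrix_scorer()` accepts
any precomputed gene×gene matrix in $[0,1]$ (for example
sequence-derived similarities), and unannotated genes score 0 against
everything rather than being dropped, so network topology is preserved.

## Node mapping

`merge_networks()` forms the disjoint union of query and reference
(nodes tagged `Q:`/`R:`) plus cross edges wherever attribute similarity
reaches `tau` (default 0.5).  `build_affinity()` blends topology and
attributes,

$$s(i,j) = w_{topo}\,J\big(N(i), N(j)\big) + (1 - w_{topo})\,\mathrm{attr}(i,j),$$

with $J$ the Jaccard overlap of merged-graph neighborhoods and
`w_topo` defaulting to 0.5.  The published description of the method
names the clustering algorithm but not the merged-graph construction;
the blend above, and `tau`, are this package's explicit reconstruction
and are surfaced as ordinary parameters.  Same-origin pairs use the
same gene-level scorer, so densely annotated within-network groups can
share clusters (clusters are not limited to size 2).

Clustering uses **affinity propagation** with the standard
responsibility/availability message passing, damping 0.9, up to 1000
sweeps, and convergence declared when the exemplar set is stable for 50
consecutive sweeps.  Two numerical details matter:

* Exactly tied similarities can lock the messages into a period-2
  oscillation of the exemplar set.  A fixed, non-random asymmetric
  perturbation of about $10^{-9}\max|s|$ is added to break ties; it is
  orders of magnitude below any meaningful similarity difference and
  keeps every run fully deterministic.
* If message passing ends with an empty exemplar set (all evidence
  negative), the single strongest candidate is promoted so that the
  output still partitions the node set; non-convergence within the
  sweep budget degrades to a warning, never an error.

On small instances ($n \le 8$) the solutions are tested against an
exhaustive search over all exemplar subsets: the AP net similarity must
reach at least 95% of the optimum on block-structured matrices.

Two alternatives share the same output contract (`node_mapping`, a
partition into exemplar-led clusters): a greedy best-pair-first aligner
with lexicographic tie-breaking, and a subprocess adapter for external
alignment tools (edge lists out, one whitespace-separated cluster per
line back in, `Q:`/`R:` prefixes preserved; nodes missing from the
output become singletons).

## Scoring and the permutation null

A mixed cluster (nodes from both networks) is scored by the BMA of the
cross-network gene similarities among its members; a single-origin
cluster scores 0.  The raw network similarity is the unweighted mean
over *all* clusters — counting unmixed clusters as zeros penalizes
non-overlap, whereas dropping them would let one lucky cluster dominate.

The null model randomizes the *labels* of the query while preserving
its topology exactly: node names are resampled without replacement
from the annotated-gene pool.  The score depends on node attributes and
cross-network structure, so label permutation isolates exactly the
attribute signal; edge rewiring would instead destroy the query's
topology, which both networks' scores condition on.  This is the
single largest reconstruction of the under-specified "randomized
networks" in the original description, and it is the package's declared
choice.  With $n_{perm}$ permuted copies scored through the identical
pipeline,

$$z = \frac{raw - \overline{null}}{\max(sd_{null}, 10^{-8})},$$

clipped to $[-1000, 1000]$; the sample (n−1) standard deviation is
used.  `fast` mode runs $n_{perm} = 10$, `normal` mode 100 (the modes
are named in the original tool's interface; their definitions here are
declared).  Null scores come from randomizing the query side only.

Reference $i$ of a scan uses the derived seed
$\mathrm{seed} + 1000\,i$, so the per-reference permutation streams
never collide and a scan gives byte-identical results regardless of
the order in which references are evaluated.

## Reference sets and enrichment

Reference pathways are ingested only through a manifest (id, category,
source, edge-list path) — no live database retrieval — and pathways
with fewer than 10 edges are excluded, since they carry too little
interaction structure to act as fingerprint coordinates.  Manifest
order defines coordinate order and is never sorted implicitly.

Enrichment is classical over-representation: upper-tail hypergeometric
p-values with Benjamini–Hochberg adjustment, universe defaulting to
all annotated genes (the choice is surfaced because p-values are
universe-sensitive).  GO-term sets are built with ancestor
propagation.  A reference is labeled *positive* for a query when the
BH-adjusted p-value of the overlap between the query's genes and the
reference's gene set falls below `alpha` (default 0.05).

## The validation harness

The accuracy design treats fingerprinting as a classifier of
enrichment labels: for each query, references are labeled by
enrichment, the fingerprint's Z-scores are used as prediction scores,
and agreement is summarized by ROC/AUC computed via the Mann–Whitney
identity (ties credited 0.5), with the unweighted mean AUC across
queries as the headline number.  Z rather than raw score is the
predictor; a flag switches to raw for ablation.

## The synthetic universe

Real pathway resources are snapshots of curated databases and cannot
be regenerated; the package instead ships a generator that produces a
complete, self-consistent test world with known ground truth:

* a layered single-root `is_a` ontology (one root, a mid tier, and a
  leaf tier sized to the reference count);
* a pool of 300 genes, each carrying 2 uniformly drawn background
  leaf terms;
* 20 connected reference pathways of 10–15 nodes (Erdős–Rényi at mean
  degree 3, repaired to one component and topped up to ≥ 10 edges);
* 3 leaf "theme" terms owned by each pathway and assigned to its genes
  with probability 0.8 (the *annotation coherence* — the single knob
  controlling how separable pathways are; 0.8 makes planted-module
  recovery hard but achievable).

`plant_query()` then builds a query with known truth: an induced
subgraph on 90% of one reference's nodes, plus 3 background genes and
5 noise edges (defaults chosen as a realistic dilution for a module of
this size), repaired to one component.  Everything is deterministic
given parameters and a seed.

What the generator does *not* emulate: scale-free degree structure,
inter-pathway gene sharing beyond chance, annotation bias toward
well-studied genes, and the 50–100-node queries typical of real use
(reference modules here are 10–15 nodes so that the full benchmark —
20 recovery seeds plus a 10-query ROC benchmark at $n_{perm} = 10$ —
runs in minutes on one CPU; these problem sizes are stated in the
tests and the acceptance script).  Passing the synthetic benchmark
therefore demonstrates that the pipeline recovers planted attribute +
topology signal under realistic noise, not that any particular
biological result is reproduced.

## Numerical and degenerate-input choices

* Networks are undirected and unweighted; direction in GraphML input
  is discarded.  Self-loops are dropped with a warning, duplicate
  edges collapsed, and canonical (sorted) edge order is used so equal
  networks serialize identically.
* Gene IDs are opaque case-sensitive strings; an optional two-column
  mapping table can be applied at load time, but no ID-namespace
  guessing is done.
* Zero null variance yields $z = \pm 1000$ (the clip bound) rather
  than infinity; annotation-free inputs give raw = z = 0.
* Greedy alignment breaks score ties lexicographically by gene id, so
  its output is invariant to input row/column order.
* `validate_network_size()` only warns — out-of-range networks are
  legitimate inputs.
* A fingerprint scan records per-reference failures in its result
  table and continues, so one malformed reference cannot void a scan.

## Known limitations

* Semantic similarity is quadratic in gene count per network pair;
  scans of 100-node queries against large reference sets are minutes,
  not seconds (memoization across the permutation copies of a scan
  removes most repeated work).
* The enrichment labels used for validation depend on declared
  defaults (BH correction, annotated-gene universe); the original
  description names neither.
* External aligners are trusted to emit the documented cluster format;
  their scoring internals are not reproduced.
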