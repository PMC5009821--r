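---
title: "Methods: GO semantic similarity, integrative scoring and association networks"
author: "goSimNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GO semantic similarity, integrative scoring and association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goSimNet)
```

# Scope and data model

`goSimNet` scores the functional similarity of genes from their Gene
Ontology annotations and turns the scores into functional-association
networks. The pipeline is: parse one GO namespace from OBO into an
`OntologyDAG`; parse GAF annotations into an `AnnotationCorpus` (direct
and true-path-propagated gene–term maps plus an information-content
table); score gene pairs with one of seven seed measures or the
integrative measure; threshold into an `AssociationNetwork` and export.
Every stage is exercised end to end on deterministic synthetic fixtures,
so no external download is required anywhere, including in the tests.

Only `is_a` and `part_of` edges are traversed. Other GO relationship
types (`regulates`, `has_part`, ...) are dropped at parse time, matching
how the mainstream GO-similarity tools define ancestry; obsolete terms
and cross-namespace parent links are discarded with a logged count, and
secondary accessions resolve to their canonical id. Queries never cross
namespaces: one `OntologyDAG` holds exactly one namespace and its single
root.

# Information content and the annotation corpus

A gene annotated to a term is implicitly annotated to all of that term's
ancestors (the *true path rule*). After propagation,

$$IC(t) = -\ln\frac{|G_t|}{|G|}$$

where $G$ is the set of genes with at least one annotation in the loaded
namespace and $G_t$ those reaching $t$. Natural log is used throughout:
the log base cancels in the ratio-form measures but not in Resnik scores,
so fixing it makes every worked value reproducible. $|G|$ counts
annotated genes, not the organism's genes — under propagation this equals
the annotation count of the root, whose IC is therefore exactly 0. IC is
undefined (an explicit error, not 0 or NA) for terms no gene reaches;
callers choose the fallback.

The *most informative common ancestor* (MICA) realizes the "lowest
common ancestor" of IC-based measures: in a DAG "lowest" is ambiguous,
max-IC is not. Ties are broken by lexicographically smallest term id so
results are deterministic.

# Seed measures

**Resnik** is $IC(MICA)$ — zero when the terms share only the root,
bounded by $\ln|G|$.

**Schlicker** normalizes it by the terms' own IC and damps frequent
ancestors: $\frac{2\,IC(MICA)}{IC(t_a)+IC(t_b)}\bigl(1 -
|G_{MICA}|/|G|\bigr)$. A root-against-root comparison has zero total IC
and is defined as 0.

**Wang** is topology-only. The S-value of an ancestor $p$ of $t$ is the
maximal product of per-edge contribution factors over paths from $t$ to
$p$ (defaults: `is_a` 0.8, `part_of` 0.6 — the conventional values of
the method; both configurable in (0,1)). Similarity is the shared
contribution over the total contribution. Each term's self-inclusive
ancestor set is used: with $t \in P_t$ (S-value 1, the empty product)
self-similarity is exactly 1 and the denominator is consistent; without
it neither holds. S-values are computed by dynamic programming in
reverse topological order, verified in the tests against exhaustive path
enumeration.

**HRSS** blends both: with $\alpha = IC(MICA)$, $\beta$ the mean gap
between each term's IC and its most informative leaf's IC, and $\gamma$
the IC distance from the MICA to the two terms,
$Sim = \frac{1}{1+\gamma}\cdot\frac{\alpha}{\alpha+\beta}$. Two
conventions required a decision:

* *Orientation.* A published form of the specificity weight writes
  $IC(root) - IC(MICA)$ in the numerator, which is negative under the
  standard convention that the root's IC is minimal (0). We use the
  orientation above — MICA depth in the numerator, leaf-specificity gap
  in the denominator — which is the form consistent with $IC(root)=0$
  and keeps the score in $[0,1]$.
* *Distance.* $dist(x,y)$ is taken on the IC scale,
  $IC(y)-IC(x)$ for an ancestor $x$, so that $\gamma$ and $\beta$ share
  units; a shortest-path edge-count variant is available via
  `dist = "edges"`.
* *Most informative leaf.* Only annotated leaves have IC; if no leaf
  below a term is annotated, the term itself stands in as its most
  informative descendant (zero specificity gap). Root-only information
  ($\alpha+\beta = 0$) scores 0.

**simUI**, **simGIC** and **TO** compare the genes' propagated term sets
directly: Jaccard, IC-weighted Jaccard, and the raw intersection count.
TO is deliberately returned unnormalized, so network thresholds on TO are
in count units. Two genes annotated only to the root share no
information: simGIC defines the resulting 0/0 as 0.

**Gene-level aggregation.** The four term-level measures reach gene
level by best-match averaging (BMA) over the genes' *direct* annotation
sets: each term's best match in the other set, averaged over both
directions (`strategy = "max"` is also available). Direct sets are used
because propagated sets would let shared ancestors dominate the average;
the set-based measures, by contrast, are defined on propagated sets.
BMA is the dominant convention where no rule is otherwise fixed.

# The integrative measure

Three steps, each deliberately the simplest construction matching its
description, each knob configurable:

1. **Rank matrix.** Every candidate measure's scores over the same $N$
   unordered pairs become descending ranks (ties share the mean of their
   positions) and normalized scores $r' = 1 - (rank-1)/(N-1) \in [0,1]$.
   Ranking makes IC units, counts and [0,1] scores commensurable and is
   invariant to any strictly monotone rescaling of a measure.
2. **Seed selection.** Per pair, the median rank across measures defines
   the consensus; measures within $\delta N$ of it are that pair's
   seeds ($\delta = 0.2$ by default). An empty window falls back to the
   single nearest measure, so selection is never empty.
3. **Addition model.** The integrated score is the weighted mean
   $\sum_{m \in S} w_m r'_m / \sum_{m \in S} w_m$ over the selected
   seeds. Normalizing by the selected weights keeps the score in [0,1]
   whatever subset survives selection; with a single surviving measure
   the integrative matrix equals that measure's normalized rank matrix
   exactly, which is how robustness to unavailable candidates is tested
   at the limit.

Ranks are computed over the user's own pair set. A server-side
deployment could rank against a precalculated organism-wide background;
that requires external data and is intentionally out of scope, and it is
the one place where scores here and scores from such a deployment can
differ.

**Weight training.** Weights are learned from EC-grouped genes by
maximizing the separation objective: mean integrated similarity of
within-group pairs minus between-group pairs. The search is simulated
annealing on the weight simplex — start uniform; each iteration rescales
one weight log-normally (sd 0.3) and renormalizes; accept by the
Metropolis rule under temperature $T_0 = 0.1$ cooled geometrically by
0.995 per iteration; 2000 iterations by default. The best-seen state is
returned, so the trained objective can never fall below the
uniform-weight objective on the same data. The seed is a required,
recorded parameter: training is exactly reproducible, and scoring given
a model is fully deterministic. Weights are non-negative and normalized
to sum 1 after training — the weighted mean is scale-invariant, so this
is purely for identifiability.

# Association networks

An edge joins two genes whose similarity is *strictly greater* than the
edge similarity threshold ("greater than" taken literally; ties at the
threshold are excluded, which also gives the clean containment property
that raising the threshold can only shrink the edge set). Isolated genes
remain nodes. A threshold above the maximum score produces a valid empty
network with a warning rather than an error. The score histogram —
counts over all $\binom{n}{2}$ pair scores — supports threshold choice,
and subnetwork selection induces the subgraph on chosen genes,
optionally extended by their direct neighbors first.

Exports are deterministic (sorted nodes and edges) in three formats:
an edge TSV with a commented header carrying nodes/threshold/measure (so
isolated nodes survive the round trip), GraphML via igraph, and the
cytoscape.js `elements` JSON dialect with the score as an edge data
attribute. Node attributes such as display colors are representable in
the exports but not modeled as behavior. All three formats round-trip
through `importNetwork()` with scores preserved to 6 decimals.

# Synthetic fixtures

The generators define the conditions every test and the acceptance
script run under:

* `toyFixture()` is frozen: seven terms (one with two parents), eight
  genes, chosen so every measure's value is checkable by hand — e.g.
  $IC(A) = -\ln(5/8) = 0.4700$, Wang$(A1, A2) = 0.5902$.
* `randomOntology()` draws each term's 1–`maxParents` parents from
  earlier terms only, so acyclicity holds by construction (and is
  re-verified in tests by an independent topological sort); roughly one
  edge in five is `part_of`.
* `ecGroupedCorpus()` emulates an EC-labelled training set: one branch
  term per group, a disjoint pool of leaf terms per branch, genes split
  evenly across groups, and each annotation drawn from the gene's own
  pool with probability `coherence`, else uniformly from all pools. At
  coherence 1, within-group pairs always share their branch while
  between-group pairs share only the root, so labels are perfectly
  recoverable; at coherence 0 they carry no signal. Defaults (20 genes,
  4 groups, 3 annotations each, coherence 0.9) are the corpus used for
  the parameter-recovery experiments; the null-coherence check is read
  as the average objective over 10 seeds, since a single small corpus
  has sampling noise of the same order as the bound being checked.

What the fixtures do *not* emulate — GO-scale ontologies (tens of
thousands of terms), skewed annotation-depth distributions, evidence
codes of varying reliability, inter-branch cross links — bounds what
passing tests show: correctness of the algorithms and their documented
conventions, not biological performance on real corpora.

# Numerical and degenerate-input conventions

* Log base: natural, everywhere.
* MICA, most informative leaf, and empty-window fallback ties: smallest
  id / first index, always deterministic.
* `rank(..., ties.method = "average")` for rank ties; $r'$ of a
  single-pair set is 1.
* Zero-information conventions: Schlicker and HRSS on root-against-root
  and simGIC on root-only genes all return 0.
* Unannotated genes are skipped and reported, never silently scored;
  an all-unannotated input is an error.
* All stochastic components (generators, training) run on a local RNG
  stream and restore the caller's RNG state.

# Problem sizes

The bundled tests and the acceptance script run at deliberately small
scale, chosen as the smallest sizes at which each claim is
distinguishable from noise: oracle equivalence on 50 DAGs of 5–15 terms
(exhaustive path enumeration is exponential, so small DAGs are the
honest comparison point), parameter recovery on 20 corpora of 20 genes
in 4 EC groups, and networks over 20-gene matrices. The algorithms
themselves are polynomial (ancestor closure is precomputed once per
ontology; scoring is quadratic in genes) and have no small-size
assumptions.

# Known limitations

* No organism-wide rank background (see above); ranks are relative to
  the submitted gene set, so adding genes changes $r'$ values.
* Gene ids are matched exactly against GAF column 2; cross-database id
  mapping is limited to an optional user-supplied two-column table.
* The grouping rule and annealing schedule are explicit stand-ins for a
  published backend whose full algorithmic detail is external to this
  package; both are parameterized rather than hard-coded.
* Evidence codes can be excluded but are not weighted.
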