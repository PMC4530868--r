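---
title: "Methods: feed-forward-loop co-regulatory network analysis"
author: "fflNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feed-forward-loop co-regulatory network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflNet)
```

This vignette documents the models, parameter choices and numerical
conventions behind `fflNet`, and states explicitly which design
decisions were genuinely open and how they were resolved.

## The model

The object of study is the set of three-node feed-forward loops (FFLs)
among a disease gene catalog, a disease mature-miRNA catalog and a list
of known TFs. An FFL is anchored on a (TF, miRNA) pair connected by a
regulator–regulator edge and closed by a gene both regulators target:

* **TF-FFL** — edges {TF→miRNA, TF→gene, miRNA→gene}; the TF is the
  main regulator.
* **miRNA-FFL** — edges {miRNA→TF, miRNA→gene, TF→gene}; the miRNA is
  the main regulator.
* **composite FFL** — both TF→miRNA and miRNA→TF present, plus both
  gene edges.

Typing is **exclusive**: a pair with both regulator–regulator
directions yields composite FFLs only, never an additional TF-FFL or
miRNA-FFL for the same triple. This partition interpretation is forced
by per-type percentages that must sum to one; it is also what makes the
per-type permutation test well defined. A triple whose gene slot equals
its TF id would be a two-node loop and is excluded; with self-edges
banned from edge tables this situation cannot arise from valid input,
but the enumerator guards it anyway. A gene that also appears on the TF
list **may** occupy the gene slot at enumeration time; role
reclassification is deliberately deferred to the network merge, where
such dual nodes take the TF role and their incoming edges are relabeled
(TF→gene becomes TF→TF, miRNA→gene becomes miRNA→TF). Deferring keeps
the catalog's slot counts interpretable (the same id can legitimately
occupy a gene slot in one loop and the TF slot of another) while the
merged network has unique roles.

## Curation parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `minSources` | 2 | distinct databases | an edge must be attested by at least two sources; verified and predicted databases are pooled into one name set. A `keepVerified` flag (default off) lets any experimentally verified edge pass unconditionally, since it is ambiguous whether support thresholds should bind verified evidence. |
| `zMin` | 2.33 | conservation Z score | strictly exceeded (`>`), so a hit at exactly 2.33 does not map. |
| `geneFlank` | 1000 | bases | promoter = ±1 kb around the TSS, strand-independent. |
| `mirnaUpstream` | 2000 | bases | pre-miRNA promoter = 2 kb 5' of the precursor; for a − strand precursor this is the 2 kb *after* its reference-coordinate end. Each mapped precursor fans out to one TF→miRNA edge per mature id. |

Coordinates are 0-based half-open (BED convention) at every interface —
the promoter window `[TSS − flank, TSS + flank)` is half-open, and
overlap means at least one shared base. The window is clipped at
coordinate 0. Multiple qualifying binding sites for one (TF, target)
pair collapse to a single edge: edge tables are sets of
(regulator, target, class) triples with provenance, never multisets.

## Permutation tests

**FFL enrichment.** Only the miRNA→gene class is resampled: each
iteration draws, uniformly *without replacement*, as many pairs as were
observed from the universe of all (focal miRNA, target) pairs, and
re-counts FFLs per type with the TF-side classes fixed. Sampling
without replacement is the only option consistent with edge tables
being sets. The p-value is the plain proportion of null counts at least
as large as the observed count — no +1 smoothing, so p = 0 is
reportable and means "never reached in `nIter` draws". Per-iteration
seeds are pre-drawn from the master seed so the result does not depend
on evaluation order.

**Per-miRNA target counts.** Each iteration draws one random gene set
of the focal set's size from the gene universe and counts, per miRNA,
how many of its targets fall inside. Two p-values are reported per
miRNA: the one-sample t-test of the null sample against the observed
count (one-sided by default, two-sided available), and the empirical
proportion-based p. The t-test deserves a caveat it is honest to state:
its null mean is estimated with standard error `sd/√nIter`, so any
observed count a few Monte-Carlo standard errors from the null mean
produces an extreme p. That is the intended behaviour for strongly
enriched data (it is how astronomically small p-values arise), but it
means the *t-test* p is not calibrated under a random focal set — the
*empirical* p is, and the test suite checks calibration on it. Both a
per-miRNA and a pooled (summed counts) report are emitted, since a
single global p can come from either. Zero-variance null samples
(focal set = universe) report t-test p = 1 with a warning.

## Network topology

* **Degree** is in + out on the directed deduplicated graph; parallel
  edges of *different* classes between one ordered pair remain
  distinct.
* **Power-law fit**: ordinary least squares of `log10 f(k)` on
  `log10 k` over the unbinned degree histogram, using only degrees with
  positive frequency; at least three distinct degree values are
  required, otherwise the fit errors (a regular graph has no degree
  distribution to fit). This is the simplest procedure consistent with
  reporting a slope and an R²; no logarithmic binning is applied.
* **Betweenness** is computed on the *directed* graph. This choice is
  forced by a structural fact the analysis relies on: pure target genes
  have out-degree 0, can never be interior to a directed shortest path,
  and therefore score exactly zero — which fails on the undirected
  view. The top 5% flag is over all network nodes (genes included; they
  simply never qualify), with ceiling rounding and ties broken by node
  id.
* **Hubs** are called per role, either by a degree quantile (default
  0.90, rule ≥) or as a per-role top-N, because the literature's exact
  degree cutoff for "hub" is not recoverable; both parameterizations
  are deterministic under id tie-breaking.

## Clique percolation and module impact

Cliques are found on the simple undirected projection (direction and
class ignored, parallel classes collapsed) — cliques are undefined on
directed multigraphs and clique-percolation tooling conventionally
works on undirected input. All k-cliques are enumerated; two are
adjacent iff they share exactly k−1 nodes (two distinct k-cliques
cannot share k); modules are node unions of the clique-adjacency
components. Modules may overlap, so the deterministic output order
sorts on the full member-id key rather than the smallest member.

The module-removal test uses **harmonic closeness** (sum of reciprocal
shortest-path distances, unreachable pairs contributing 0) by default:
deleting a module can disconnect the graph, where classic closeness is
undefined. The sums are deliberately *unnormalized*, so that removing a
component that was already disconnected from the rest leaves the
remaining nodes' values exactly unchanged (the no-effect control). A
classic variant (closeness on the largest remaining component) is
available. The comparison is a Welch two-sample t-test, one-sided
(reduced < original); when both samples are constant the test is
degenerate and the report falls back to a mean comparison (equal means
→ p = 0.5) with a warning.

## GO semantic similarity

The term measure is Wang's graph-based measure: a term's S-value
propagates up its ancestor graph multiplying by 0.8 per `is_a` edge and
0.6 per `part_of` edge, taking the maximum over paths; the similarity
of two terms is the S-value mass of their shared ancestors over their
total semantic values. Gene-level aggregation is the best-match average
(BMA): `(Σᵢ maxⱼ S(tᵢ, tⱼ) + Σⱼ maxᵢ S(tᵢ, tⱼ)) / (n₁ + n₂)`.
Genes unannotated in a namespace return a missing-value sentinel and
are excluded from score vectors with a logged count. An
information-content (Resnik-style) alternative was considered and not
shipped: it requires a corpus term-frequency table that is itself a
modelling choice, and the graph measure needs only the ontology.

Module coherence pools all pairwise scores from `nIter` random
same-size draws into one null vector and applies a one-sided two-sample
KS test (module scores stochastically greater). Pooling (rather than a
per-draw statistic) matches the framing "are the module's pair scores
higher than random pairs' scores".

The OBO reader is a minimal go-basic-dialect parser (id, name,
namespace, `is_a`, `relationship: part_of`, obsolete terms skipped) —
sufficient for similarity computation, not a general ontology parser.

## The synthetic-data generator

`generateBundle()` emulates the statistical shape of a disease
regulatory-network study; its defaults are the study-shaped universe
(854 genes, 1,698 TFs, 78 miRNAs, 19 dual-role genes; 236/902/94
planted FFLs; three k = 5 communities of 15, 5 and 6 nodes). Choices
worth recording:

* **Planted FFLs** sit on distinct (TF, miRNA) anchor pairs; genes are
  drawn freely, and a verify-and-repair loop resamples genes until
  enumeration of the planted edges returns *exactly* the planted
  catalog (shared TFs/miRNAs/genes can otherwise create accidental
  extra triples). Planted edges always receive support ≥ 2, so they
  survive the default filter.
* **Background edges** are sampled independently per class, matching
  the four-table structure of the curated data. Per-edge support is
  drawn from a categorical distribution (default P(1) = 0.5,
  P(2) = 0.3, P(3) = 0.2) so the support filter has a real effect; no
  published support distribution exists, so this is a package choice
  made once. Default densities were set so the post-filter class tables
  have pair counts of the same order as a real curated study
  (≈1.4k/3.3k/4.4k/0.2k at the default universe).
* Background never adds the *reverse* regulator–regulator edge of a
  planted one-directional anchor, so a planted FFL's type cannot flip;
  per-type counts are monotone in the background density by
  construction.
* **Degree structure**: background endpoints are drawn with Zipf-like
  per-node propensities (exponent 0.9 over permuted ranks), giving the
  heavy-tailed, scale-free-like degree distribution real regulatory
  data shows, rather than a Poisson one.
* **Communities** are chains of n k-cliques overlapping in k−1 nodes
  (community size k + n − 1), on node ids drawn from the catalogs and
  disjoint across communities, emitted as a separate undirected edge
  list with ground truth.
* **GO**: three namespace trees (branching 3, configurable depth) plus
  a few `part_of` cross edges; the designated coherent genes are
  annotated to sibling leaves of one branch, pool genes to random
  leaves — guaranteeing detectable coherence without sequence-level
  realism.

What the generator does **not** emulate: sequence-level binding-site
or seed-match realism, correlated evidence between databases,
identifier versioning noise, and (in the FFL-derived network) the dense
TF–TF co-regulation real networks show — which is why planted
communities live on their own graph rather than inside the sparse
synthetic FFL network. Passing tests on this generator therefore
demonstrate algorithmic correctness and statistical calibration, not
biological fidelity of any particular real dataset.

## Problem sizes

The test suite runs the enumeration oracle on 50 random instances of up
to ~90 nodes with mixed densities; permutation calibration on 200
replicate null datasets at 200 iterations each (15 TFs, 10 miRNAs, 80
genes, 150 observed pairs from an 800-pair universe); the clique
oracle on graphs of 25–30 nodes for k = 3…5; and BH agreement on 1,000
random p-vectors. The acceptance script uses a 300-gene/150-TF/40-miRNA
universe with 125 planted FFLs and 10,000 permutation iterations. These
sizes were chosen as the smallest at which every statistical check has
comfortable resolution (e.g. null FFL counts with dozens of support
points for the uniformity test).

## Known limitations

* Identifier handling is exact-string; no miRNA name versioning or
  gene-symbol aliasing.
* The permutation null randomizes miRNA targeting only; a
  degree-preserving edge-swap null for the TF side would be a natural
  extension but is not the implemented model.
* Exhaustive k-clique enumeration is exponential in principle; it is
  intended for sparse biological networks, not dense graphs.
* The Wang-measure weights (0.8/0.6) are the conventional defaults and
  are not re-estimated.
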