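---
title: "Methods: family-free DCJ-indel orthology inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-free DCJ-indel orthology inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffdcj)
```

## The model

`ffdcj` treats a genome as a set of linear segments (chromosomes or
contigs) of oriented genes.  Two genomes are compared under the
double-cut-and-join (DCJ) model extended with indels: a DCJ cuts the
genome at two positions and rejoins the four open ends differently
(covering inversions, translocations, fusions, fissions, with circular
intermediates allowed), and an indel inserts or deletes one contiguous
block of genes.  No gene may be deleted and later reinserted, which
prevents trivially deleting one genome and inserting the other.

Orthology candidates come from the *gene similarity graph*: genes are
vertices, and a cross-genome pair (x, y) is an edge scored by the
relative reciprocal score of their bitscores, kept only if it passes an
absolute filter and a best-hit-relative reciprocal filter.  A matching
O of this graph is an *ortholog-set*; matched genes are identified
during the rearrangement comparison, unmatched genes must be inserted
or deleted.  The objective is

wd(O) = d(O) + |O| − σ(O) + w(complement of O),

minimised over all matchings: the DCJ-indel operation count plus a
penalty for matching dissimilar genes (1 − σ per pair) and for leaving
well-conserved genes unmatched (their best incident score w).

### The relational graph and its decompositions

All candidate ortholog-sets are encoded at once in the family-free
relational graph on gene extremities (each gene has a head and a tail):
adjacency edges join consecutive extremities within a segment, each
similarity edge contributes a *sibling pair* of extremity edges
(tail–tail and head–head, equal scores), and each gene contributes an
indel edge between its own extremities, weighted by the gene's w.  A
sibling-set (the extremity edges of a matching) induces a *consistent
decomposition*: together with the indel edges of unmatched genes and
all adjacency edges, every vertex lies on exactly one cycle or path.
Paths end at telomeres, so every decomposition has exactly
kappa(A) + kappa(B) paths.

The cost of a decomposition made of cycles only is computed from its
cycle count and its indel runs: traversing a cycle, maximal blocks of
indel edges from one genome form runs; a cycle with l runs contributes
Lambda(l) = ceil((l+1)/2) extra operations (0 if it has no runs), and

d = |O| + p − (number of cycles) + sum of Lambda over cycles,

where 2p is the number of cap vertices added per genome (below).  This
run accounting follows the published DCJ-indel theory for genomes with
unique genes; the package does not re-derive it but verifies it
exhaustively against an independent breadth-first state-space oracle
(`dcj_indel_distance_bfs`) that searches over all DCJ and indel
operation sequences on tiny instances.

### Capping

Paths are closed into cycles by *capping*: every telomere is attached
to a cap vertex, cap-vertex counts are equalised with dummy adjacencies
(paired deterministically by index), and a *capping-set* — a perfect
matching between the cap vertices of the two genomes along the allowed
cap edges — closes all paths.  Optimal capping allows all
(2p\*)² cap edges, hence (2p\*)! capping-sets, and provably preserves
the uncapped cost.  The heuristic capping restricts cap edges via the
*shared-content graph* on segments: Omega(A, B) sums the similarity
scores between the genes of segments A and B; a rank filter tau keeps
an edge only if it is among the tau best of **both** endpoints (ties at
rank tau kept, ranks computed on the unfiltered graph), then a relative
filter removes edges scoring below eps times their endpoint's best
surviving score.  The graph is completed to one admitting a perfect
matching by iteratively adding dummy segments connected to a Hall
violator (found by alternating-path reachability from an unsaturated
vertex of a maximum matching), then pruned to its matchable edges (an
edge is kept iff it is matched or lies on an alternating cycle, i.e.
its endpoints share a strongly connected component in the standard
orientation).  Each shared-content edge contributes the two crosswise
cap pairings (4 cap edges), except single-edge components with a dummy
endpoint, where one pairing suffices because a dummy's two ends are
equivalent.

On the tau semantics: iterating "keep the tau best edges per vertex"
over all vertices means every vertex's constraint applies, so an edge
survives only when both endpoints rank it; computing ranks on the
unfiltered scores makes the filter order-independent.  Segments
disconnected by the filters simply get a dummy partner during
completion, so no segment loses its capping.

### Solving

The optimisation is a joint minimum over sibling-sets and capping-sets.
`solve_capped_ffr` performs an exact branch-and-bound over ortholog
matchings — genes of one genome are decided in order, with an
admissible bound built from per-gene optimistic costs (min of the
gene's w and the cheapest 1 − σ of its remaining edges) — and, at each
complete matching, minimises over all admissible capping-sets by
exhaustive enumeration in compiled code.  It returns the same optimum
an integer-programming formulation of the problem would, with
reproducible tie-breaking: among equally optimal ortholog-sets the
lexicographically smallest edge list is reported, and among equally
optimal capping-sets the one that links the fewest paths into any
single cycle.  `exhaustive_solve` enumerates every sibling-set
(guarded to tiny instances) and is used as an internal reference; the
independent ground truth for the distance itself is the BFS oracle.
This design targets the package's scope — exact analysis of small to
moderate instances and fully validated machinery — rather than
genome-scale ILP throughput; the capping-set enumeration is guarded
(`max_enum`) and the solver reports `feasible-at-timeout` with its best
incumbent when a node or time budget is hit.

## Families

Pairwise ortholog-sets are integrated into an n-partite graph whose
connected components are the families: *ambiguous* if some genome
contributes two or more genes, otherwise *resolved* (complete with one
gene per genome, incomplete otherwise); singleton genes are reported as
unclassified.  Ambiguous families may be refined by Markov clustering
of their σ-weighted subgraph (in-package implementation: column
normalisation, expansion power 2, inflation 1.4, pruning threshold
1e−5, at most 100 iterations, self-loops set to each gene's maximum
incident weight).  The σ weights are the natural choice since they are
the only edge evidence the pipeline carries; inflation 1.4 is the
conservative setting commonly recommended for orthology graphs.
Refinement can only remove within-family pairs, never create them, so
pair-precision against a reference cannot decrease while recall may.

Family sets are evaluated against a reference by 2-subset metrics:
genes absent from the reference are first removed from the inferred
set, then TP/FP/FN are counted over unordered within-family gene pairs
and precision, recall and F1 derived.  If either side has no pairs at
all the metrics are reported as 0 with an explicit `degenerate` flag
rather than dividing by zero.

## Synthetic data

`generate_synthetic_dataset` evolves an ancestral genome independently
per lineage: seeded inversions and translocations (segment count is
preserved and segments stay linear), block deletions (never emptying a
segment), insertions of novel genes, and per-gene duplications.
Bitscores are emitted so that all extant copies of an ancestral gene
score σ ≈ 0.95 (passing the default filters), and optional noise adds
weak random cross hits (σ ≈ 0.15–0.3) that the reciprocal filter
usually removes.  Planted families are the extant copies of each
ancestral gene present in at least two genomes.

The generator emulates gene-level rearrangement, content change and
similarity structure; it does **not** emulate HSP fragmentation,
alignment-length effects, assembly errors, missing annotations or
similarity decay with divergence.  Passing recovery tests therefore
demonstrates the combinatorial correctness of the pipeline, not
robustness to the noise profile of real alignments.

## Problem sizes, tolerances and degenerate inputs

The validation suite works at the scale where exhaustive ground truth
is computable: the BFS oracle is run on genomes of up to ~4 genes per
side (and drives the cost-preservation checks at up to 3 similarity
edges and 2 segments per genome); capping validity is checked on *all*
bipartite segment graphs with up to 4 segments per side; solver
equivalence on dozens of seeded instances with up to 4 genes and 3
segments per genome; pipeline recovery on 3 genomes with ~8–10 genes.
These sizes are the package's validation design: large enough to
exercise every component type (AA/BB/AB paths, runs, dummy segments,
ties), small enough for exhaustive enumeration.

Numerical choices: σ scores are clipped to 1 (reciprocal bitscores can
exceed self-scores, and scores above 1 would make matched pairs earn
negative cost); wd comparisons in the solver use an absolute tolerance
of 1e−9 (all cost terms are small sums of ratios); empty similarity
graphs, empty ortholog-sets and single-gene segments are all legal
inputs, and a genome must have at least one non-empty linear segment.
Circular input chromosomes are rejected by the parser (capping concerns
linear segments; circular intermediates still arise inside the distance
model).  Whole-segment reversal and gene relabeling leave all reported
quantities unchanged, and the shared-content component structure
guarantees segments in different components never share cap edges.

## Known limitations

* Exact solving is exponential in the worst case; dense similarity
  graphs over many genes or many segments per genome are out of reach.
  The intended regime is curated or simulated gene orders and
  fragmented small genomes.
* The heuristic capping can return a sub-optimal ortholog-set by
  construction (its optimum is an upper bound on the true one; they
  coincide whenever both genomes have a single segment).
* Bitscore input uses the last tab-separated column and collapses
  multiple HSPs by maximum; per-HSP normalisation schemes are not
  modelled.
* Transcript selection (e.g. keeping one isoform per gene) is assumed
  to have happened upstream.
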