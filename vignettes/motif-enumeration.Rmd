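---
title: "Enumerating typed subgraph motifs: model, engines, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating typed subgraph motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(submotif)
```

## The model

The target network is an edge-typed multigraph: nodes are opaque strings,
each edge is a triplet `(start, end, type)`, and every type is declared
directed or undirected up front in a `link_registry()`.  Parallel edges
between the same node pair are legal iff their types differ; self-loops are
rejected at load because no motif can match one.  For a directed type `X`
the lower-case key `x` denotes the reversed orientation, so every edge
contributes exactly two oriented adjacency facts.  Two indexes are
maintained incrementally — start nodes per oriented key, and neighbors per
`(node, key)` — so that the candidate-set queries during the search are
constant-time lookups rather than scans.  This indexing is deliberately
linear in the edge count: each edge adds one entry to two adjacency sets
and (at most) two start sets.

A motif on `k` ordered nodes is a linear string of `k(k-1)/2` pair codes in
the column-wise upper-triangle order (1,2), (1,3), (2,3), (1,4), (2,4),
(3,4), …: an upper-case letter is a forward link of that type, a lower-case
letter a reversed directed link, `0` no link.  Exactly one code per pair —
motifs carry no (anti-)parallel links.  Matching is **non-induced** by
default: a `0` pair imposes no constraint.  This follows the candidate-set
semantics of the search itself, which only ever intersects neighbor sets of
declared types and never complements them.  Because the alternative reading
(a `0` pair *forbids* any edge) is also defensible, an `induced = TRUE`
mode post-filters complete instances instead; both modes are verified
against the brute-force oracle.  Instance counts involving `0` pairs differ
between the modes, so users comparing against external tools should check
which convention those tools use.

## The engines

All engines are depth-first backtracking searches over partial instances
(injective motif-node-to-network-node maps), and all report the same cost
metric: the number of mapping events, i.e. the search-tree size.

**Naive baseline (`find_motifs_rsma`).**  Fixed investigation order
`1..k`; the first level iterates over every network node.  Its tree is
broad near the root, which is exactly what the dynamic engine removes.

**Dynamic ordering (`find_motifs_isma`, `find_motifs_isma_recursive`).**
The first motif node is chosen by counting, for every oriented type key
occurring in the motif, the network-wide start-node count; the rarest key
nominates the motif node it departs from.  On ties the intersection value
(IV) — the cardinality of the intersection of the start sets of all keys
departing a motif node — is computed for *all* motif nodes and the minimum
wins, with a residual tie going to the smallest index.  During the search,
each newly mapped network node files one priority object per still-unmapped
motif node it constrains, carrying its neighbor count via the connecting
key.  The next motif node is the owner of the globally minimal count.  That
count is an upper bound on the true candidate-set cardinality, not the
cardinality itself: ranking on it avoids computing intersections during
selection, at the price of a not-always-minimal tree.  This trade-off is
inherited deliberately; the tree-size tests pin the exact behaviour only on
the worked example, where the spec fixes every tie-break.

The iterative engine replaces the recursion stack with four structures: a
checklist (chosen order + rest set), a motif iterator (one live candidate
iterator per chosen node; draws always come from the deepest non-exhausted
one), the priority-queue map, and the symmetry sets described below.
Backtracking distinguishes the three situations that can follow a draw:
nothing to undo after a fresh iterator; unmapping the previous node of the
same iterator; or popping exhausted deeper levels entirely (uncheck, unmap,
purge their priority objects, forget their symmetry sets).  One deviation
from a literal reading of the pseudocode: the queue poll *selects* without
removing, and priority objects are purged only by the backtracking rules,
keyed on the motif node whose mapping created them.  This is behaviorally
identical and keeps a queue correct when its motif node is unchecked and
becomes selectable again.

## Symmetry

The automorphism group of the motif is computed by brute force over all
`k!` permutations (generated by plain changes / Steinhaus–Johnson–Trotter;
motifs are capped at `k <= 10`).  Two shapes are exploited during the
search:

* **Reflection classes** — maximal sets of mutually swappable motif nodes,
  taken as connected components of the transposition graph (group closure
  makes these components cliques).  Each class member lists all other
  members.
* **Rotation cycles** — automorphisms consisting of a single cycle of
  length ≥ 3.  The smallest index in the cycle is designated "first" (any
  fixed choice is correct; smallest is deterministic); the first node lists
  all other members, the others list only the first.

When both shapes could claim a node, reflections are claimed first and only
disjoint rotations are accepted.  The undirected 4-cycle illustrates the
consequence: its dihedral group of order 8 yields two reflection classes
`{1,3}` and `{2,4}`, no accepted rotation, and four residual automorphisms.
The opposite claiming order (rotation first) would be equally sound; what
makes either safe is the backstop: every complete instance is canonicalised
under the **full** automorphism group (lexicographically smallest image,
byte-wise comparison) and discarded if seen before.  Pruning can therefore
only ever remove duplicates, never a distinct instance, and the randomized
oracle-equivalence suite checks exactly that.

During the search, each symmetric motif node keeps a symmetry set of
candidates not yet consumed there.  A drawn node is removed from its own
set — permanently, for the lifetime of that node's iterator — and the sets
of already-chosen symmetric partners join the candidate intersection of a
newly chosen symmetric node.  On the pure toys this enumeration is exact:
`r` reflection-equivalent positions over `s` shared candidates yield
`choose(s, r)` mapped combinations and a rotation of length `r` yields
`s!/(s-r)!/r`, with zero residual discards; the tests assert both counts
and the zero.

## Numerical and determinism choices

* All candidate sets iterate in a fixed node order: numeric order when all
  identifiers are digit strings, radix (C-locale) string order otherwise.
  Ties in first-node selection and queue polling break to the smallest
  motif index.  Together these make instance lists, output files and tree
  sizes bit-reproducible across runs and platforms.
* Canonical-form keys are compared byte-wise (radix).  Locale collation is
  unsafe here: it can ignore the separator byte between node names and
  conflate distinct tuples (found by the randomized suite during
  development).
* Motifs must be connected through their non-`0` pairs; disconnected motifs
  are rejected, since the selection rule can never constrain an untouched
  component.
* Duplicate input edges are silently de-duplicated (interaction files
  commonly repeat lines) and counted; an anti-parallel pair of the same
  directed type is two distinct edges (legal in the graph, impossible in a
  motif).

## What the synthetic generator does and does not establish

`random_typed_graph()` draws each type's edges independently
(Erdős–Rényi per type: ordered pairs for directed, unordered for
undirected), reproducibly for a fixed seed.  The equivalence suite runs the
naive engine, both dynamic engines (symmetry pruning on and off) and the
brute-force oracle over 200 such graphs (up to 30 nodes, edge probability
0.05–0.30) across an asymmetric motif, a reflection-symmetric one, a
cyclic-rotation one, the fully symmetric triangle and the undirected
4-cycle, comparing canonicalized instance sets and the counting identity
(ordered embeddings = unique instances × group order).  A green run
establishes *correctness of enumeration* on graphs of this scale and motif
family.  It does not emulate degree-heavy-tailed biological networks, does
not measure the (hardware- and tie-break-dependent) wall-clock speedups
reported for large published networks, and does not exercise motifs beyond
five nodes against the oracle (the oracle guard is `n <= 40, k <= 5`; the
engines themselves have no such limit).  The six-node worked-example
fixture is reconstructed from printed constraints; of the two edge
completions consistent with every constraint, both are built and tested,
and all reference quantities are invariant to the choice.

## Known limitations

* Exact matching only; no node attributes, weights, or approximate
  matching.
* Only reflections and rotations prune the tree; richer automorphism
  structure (e.g. products of disjoint swaps beyond the claimed classes)
  falls through to canonical-form elimination, which is correct but does
  not shrink the tree.
* The engines are plain R; they are comfortable at the scale of the test
  suite and of moderate real networks, but a compiled implementation would
  be preferred for multi-million-edge inputs.
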