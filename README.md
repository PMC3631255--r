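# submotif

Exact enumeration of all instances of a small query motif in a large
network whose edges carry **types** (directed or undirected).

## The problem

Biological networks routinely overlay several interaction mechanisms on the
same genes or proteins — physical binding (undirected), genetic interaction
(undirected), signaling or regulation (directed).  Composite network motifs
are small subgraph patterns spanning several of these edge types, and
counting their instances exactly is the workhorse behind motif-significance
analysis and motif-based clustering.  Formally, the target network is an
edge-typed multigraph `G = (V, E)` with edges as triplets `(u, v, t)`;
parallel edges are allowed iff their types differ.  A motif on `k` ordered
nodes assigns each of the `K = k(k-1)/2` node pairs one code: an upper-case
type letter (forward link), the lower-case letter (reversed directed link)
or `0` (no link).  Written in the pair order (1,2), (1,3), (2,3), (1,4), …
this gives a linear specification string: `ABC` is the triangle
`1 -A-> 2`, `1 -B-> 3`, `2 -C- 3`.  An instance is an injective assignment
of network nodes to motif nodes realising every non-`0` code by an edge of
exactly that oriented type.

## The algorithm

The package enumerates instances with a backtracking search whose cost
metric is the **search-tree size**: the number of node-to-motif-node
mapping events.  Three engines share one candidate-set core:

* `find_motifs_rsma()` — the naive baseline: fixed investigation order
  `1..k`, first level iterating over *all* network nodes.
* `find_motifs_isma()` — the main engine (iterative): two type-keyed
  indexes on the network (start nodes per oriented type key; neighbors per
  node and key) make candidate sets cheap intersections, and the motif
  node expanded next is always the one whose cheapest upper bound on its
  candidate-set size — maintained in a priority-queue map — is smallest.
  Reflection and cyclic-rotation symmetries of the motif prune equivalent
  branches outright; any residual automorphism is caught by canonical-form
  duplicate elimination, so each instance is reported exactly once.
* `find_motifs_isma_recursive()` — the same dynamic ordering in recursive
  form; `oracle_enumerate()` is a brute-force ground truth for small inputs.

## Worked example

A six-node network with directed types `A`, `B` and undirected `C`:

```r
library(submotif)
wx <- build_worked_example()
find_motifs(wx$graph, "ABC")
#> motif_matches [ABC, isma]: 2 unique instance(s), search tree 6 node(s), 0 duplicate(s) discarded
#>   [1, 5, 4]
#>   [5, 6, 3]
```

Two instances: network nodes 1, 5, 4 (and 5, 6, 3) mapped on motif nodes
1, 2, 3.  The dynamic engine needs 6 mapping events where the naive order
needs 12 — it starts at motif node 2, whose candidate set (the intersection
of the start nodes of key `a` with the endpoints of `C`) has only two
elements, and at every later step expands the motif node with the fewest
candidate nodes.

The same run from the command line, given per-type edge-list files (one
`start<TAB>end` pair per line):

```sh
Rscript inst/scripts/motif_search.R -folder input/ \
  -linkfiles "A d linksAtype.txt B d linksBtype.txt C u linksCtype.txt" \
  -motif "ABC" -output results.txt --algorithm isma,rsma --stats
#> isma: instances=2 tree_nodes=6 duplicates_discarded=0
#> rsma: instances=2 tree_nodes=12 duplicates_discarded=0
#> STRF=2
```

`results.txt` then contains, bit-exactly:

```
Motif [ABC]: [1, 5, 4]
Motif [ABC]: [5, 6, 3]
```

`STRF` is the search-tree reduction factor (naive tree size / dynamic tree
size).

## Scope

Exact, non-induced matching by default (`induced = TRUE` post-filters `0`
pairs); motifs up to 10 nodes, connected through their links; no
approximate matching, node attributes, or motif-significance null models.
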