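## The two recursive engines: a naive fixed-order matcher and the
## dynamic-order matcher.  Both count every network-node-to-motif-node
## mapping event (the search-tree size) and report unique instances after
## canonical-form duplicate elimination, so their outputs are directly
## comparable with the iterative engine and the brute-force oracle.

check_engine_inputs <- function(m, g) {
  stopifnot(inherits(m, "motif_spec"), inherits(g, "typed_graph"))
  if (!motif_connected(m))
    stop("motif '", motif_string(m), "' is not connected through its links; ",
         "the dynamic selection rule cannot constrain an untouched component")
  invisible(NULL)
}

#' Naive recursive subgraph matching (fixed investigation order)
#'
#' Depth-first enumeration in fixed motif-index order `1..k`.  The first
#' level iterates over *all* network nodes; deeper levels intersect the
#' typed neighbor sets of the already-mapped nodes.  This is the baseline
#' against which the dynamic-order engine's search-tree reduction is
#' measured.
#'
#' @param m a [parse_motif()] result; must be connected.
#' @param g a [typed_graph].
#' @param induced if `TRUE`, instances whose `"0"` motif pairs are joined by
#'   any edge are discarded (induced matching); default is non-induced.
#' @return a `motif_matches` object: unique instances (matrix, one row per
#'   instance, columns in motif order) and search statistics.
#' @export
find_motifs_rsma <- function(m, g, induced = FALSE) {
  check_engine_inputs(m, g)
  k <- m$k
  auts <- automorphisms(m)
  ex <- make_exporter(g, m, auts, induced)
  tree <- 0L
  inst <- rep(NA_character_, k)
  all_nodes <- graph_nodes(g)
  recurse <- function(depth) {
    if (depth > k) { ex$export(inst); return(invisible(NULL)) }
    set <- if (depth == 1L) all_nodes
           else determine_set(inst, depth, g, m)
    for (nn in set) {
      inst[depth] <<- nn
      tree <<- tree + 1L
      recurse(depth + 1L)
      inst[depth] <<- NA_character_
    }
    invisible(NULL)
  }
  if (length(all_nodes) > 0L) recurse(1L)
  res <- ex$result()
  new_search_result(instances_matrix(res$instances, k), m, "rsma",
                    tree, res$duplicates)
}

## dynamic next-node rule for the recursive engine: among unmapped motif
## nodes, minimise over mapped nodes the neighbor count via the connecting
## code (an upper bound on the candidate-set size); tie -> smallest index
next_motif_node_recursive <- function(inst, g, m) {
  best <- NA_integer_; best_count <- Inf
  for (mn in seq_len(m$k)) {
    if (!is.na(inst[mn])) next
    for (ni in which(!is.na(inst))) {
      code <- m$codes[ni, mn]
      if (code == "0") next
      cnt <- length(neighbors_of_type(g, inst[ni], code))
      if (cnt < best_count) { best_count <- cnt; best <- mn }
    }
  }
  best
}

#' Dynamic-order recursive subgraph matching
#'
#' Same depth-first scheme as [find_motifs_rsma()], but the motif node to
#' investigate next is chosen dynamically: initially by
#' [select_first_motif_node()], afterwards as the unmapped motif node whose
#' smallest constraining neighbor set (a cheap upper bound on the true
#' candidate-set size) is minimal.  Candidate sets come from
#' [determine_set()], so the first search level is already restricted to
#' nodes with the right link types departing from them.
#'
#' @inheritParams find_motifs_rsma
#' @return a `motif_matches` object.
#' @export
find_motifs_isma_recursive <- function(m, g, induced = FALSE) {
  check_engine_inputs(m, g)
  k <- m$k
  auts <- automorphisms(m)
  ex <- make_exporter(g, m, auts, induced)
  tree <- 0L
  inst <- rep(NA_character_, k)
  recurse <- function(n_mapped) {
    if (n_mapped == k) { ex$export(inst); return(invisible(NULL)) }
    if (n_mapped == 0L) {
      sel <- select_first_motif_node(g, m)
      mn <- sel$index
      set <- sel$candidates
    } else {
      mn <- next_motif_node_recursive(inst, g, m)
      set <- determine_set(inst, mn, g, m)
    }
    for (nn in set) {
      inst[mn] <<- nn
      tree <<- tree + 1L
      recurse(n_mapped + 1L)
      inst[mn] <<- NA_character_
    }
    invisible(NULL)
  }
  if (length(graph_nodes(g)) > 0L) recurse(0L)
  res <- ex$result()
  new_search_result(instances_matrix(res$instances, k), m, "isma-recursive",
                    tree, res$duplicates)
}
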