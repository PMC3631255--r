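## The iterative engine.  Four cooperating structures replace the recursion
## stack:
##   checklist        -- the order in which motif nodes were chosen, plus the
##                       rest set of nodes not chosen yet
##   motif iterator   -- one live candidate iterator per chosen motif node;
##                       draws always come from the deepest non-exhausted one
##   priorityqueuemap -- per rest-set motif node, priority objects
##                       (network node, motif start, neighbor count); the
##                       globally minimal head picks the next motif node
##   symmetry sets    -- per symmetric motif node, the candidates not yet
##                       consumed there; joined into candidate intersections
##                       so equivalent positions never re-use a node
##
## The neighbor count in a priority object is an upper bound on the true
## candidate-set cardinality; ranking on it avoids computing intersections
## during next-node selection at the cost of a not-always-minimal tree.

#' Pick the next motif node from a priority-queue map
#'
#' Scans the queues of the not-yet-chosen motif nodes and returns the motif
#' node owning the priority object with the globally minimal neighbor
#' count; ties break to the smallest motif index.  The queues are left
#' intact (removal happens on backtracking, keyed by the mapped node that
#' created the objects).
#'
#' @param pqm list of priority-object queues, one per motif node; each
#'   object is `list(nn, mstart, count)`.
#' @param rest integer vector of motif nodes not chosen yet.
#' @return the chosen motif index.
#' @export
next_motif_node <- function(pqm, rest) {
  best <- NA_integer_; best_count <- Inf
  for (i in sort(rest)) {
    for (po in pqm[[i]]) {
      if (po$count < best_count) { best_count <- po$count; best <- i }
    }
  }
  if (is.na(best))
    stop("all rest-set priority queues are empty; motif ordering is disconnected")
  best
}

purge_by_start <- function(pqm, mstart) {
  for (i in seq_along(pqm)) {
    if (length(pqm[[i]]) == 0L) next
    keep <- vapply(pqm[[i]], function(po) po$mstart != mstart, logical(1))
    pqm[[i]] <- pqm[[i]][keep]
  }
  pqm
}

#' Iterative dynamic-order subgraph matching
#'
#' The main engine.  After choosing the first motif node (the one whose
#' link types are rarest in the network, [select_first_motif_node()]), the
#' loop repeatedly draws the next candidate from the deepest live iterator,
#' rolls the data structures back to that level, maps the node, and -- if
#' the instance is incomplete -- files one priority object per constrained
#' rest-set motif node, polls the priority-queue map for the next motif
#' node, and opens an iterator over its candidate set.  Complete instances
#' pass canonical-form duplicate elimination before being reported.
#'
#' With `use_symmetry = TRUE` (default), reflection-symmetric motif node
#' classes and cyclic rotations prune the tree directly: a network node
#' consumed on a symmetric position is withheld from equivalent positions
#' via the symmetry sets, so only residual automorphisms ever produce a
#' duplicate at export.
#'
#' @inheritParams find_motifs_rsma
#' @param use_symmetry enable symmetry-set pruning (the result set is
#'   identical either way; only the tree size and the number of discarded
#'   duplicates differ).
#' @return a `motif_matches` object.
#' @export
find_motifs_isma <- function(m, g, use_symmetry = TRUE, induced = FALSE) {
  check_engine_inputs(m, g)
  k <- m$k
  syminfo <- classify_symmetries(m)
  auts <- syminfo$automorphisms
  sym_lists <- syminfo$sym_lists
  is_symmetric <- lengths(sym_lists) > 0L
  ex <- make_exporter(g, m, auts, induced)
  tree <- 0L

  if (length(graph_nodes(g)) == 0L) {
    res <- ex$result()
    return(new_search_result(instances_matrix(res$instances, k), m, "isma",
                             0L, res$duplicates))
  }

  inst <- rep(NA_character_, k)
  symsets <- rep(list(NULL), k)
  pqm <- rep(list(list()), k)

  sel <- select_first_motif_node(g, m)
  chosen <- sel$index                       # checklist: ordered chosen nodes
  iters <- list(list(nodes = sel$candidates, pos = 0L))
  if (use_symmetry && is_symmetric[sel$index]) symsets[[sel$index]] <- sel$candidates

  sym_ctx <- function() {
    if (!use_symmetry) return(NULL)
    list(sets = symsets, lists = sym_lists, checked = chosen)
  }

  repeat {
    # deepest non-exhausted iterator; none left -> done
    p <- length(chosen)
    while (p >= 1L && iters[[p]]$pos >= length(iters[[p]]$nodes)) p <- p - 1L
    if (p < 1L) break
    iters[[p]]$pos <- iters[[p]]$pos + 1L
    nn <- iters[[p]]$nodes[[iters[[p]]$pos]]

    # backtrack: drop exhausted deeper levels (uncheck, unmap, purge their
    # priority objects, forget their symmetry sets), then clear this level's
    # previous mapping if the draw came from an already-used iterator
    if (length(chosen) > p) {
      for (q in length(chosen):(p + 1L)) {
        qmn <- chosen[q]
        inst[qmn] <- NA_character_
        pqm <- purge_by_start(pqm, qmn)
        symsets[qmn] <- list(NULL)
      }
      chosen <- chosen[seq_len(p)]
      iters <- iters[seq_len(p)]
    }
    pmn <- chosen[p]
    if (!is.na(inst[pmn])) {
      inst[pmn] <- NA_character_
      pqm <- purge_by_start(pqm, pmn)
    }

    # map the drawn node on the current motif node
    inst[pmn] <- nn
    tree <- tree + 1L
    if (use_symmetry && is_symmetric[pmn] && !is.null(symsets[[pmn]]))
      symsets[[pmn]] <- setdiff(symsets[[pmn]], nn)

    if (!anyNA(inst)) { ex$export(inst); next }

    rest <- setdiff(seq_len(k), chosen)
    for (i in rest) {
      code <- m$codes[pmn, i]
      if (code != "0")
        pqm[[i]] <- c(pqm[[i]],
                      list(list(nn = nn, mstart = pmn,
                                count = length(neighbors_of_type(g, nn, code)))))
    }

    mn <- next_motif_node(pqm, rest)
    chosen <- c(chosen, mn)
    set <- determine_set(inst, mn, g, m, sym = sym_ctx())
    if (use_symmetry && is_symmetric[mn]) symsets[[mn]] <- set
    iters <- c(iters, list(list(nodes = set, pos = 0L)))
  }

  res <- ex$result()
  new_search_result(instances_matrix(res$instances, k), m, "isma",
                    tree, res$duplicates)
}

#' Enumerate motif instances in a typed network
#'
#' User-facing wrapper around the enumeration engines.
#'
#' @param g a [typed_graph].
#' @param motif a motif specification string (parsed against the graph's
#'   registry) or a [parse_motif()] result.
#' @param algorithm `"isma"` (iterative dynamic-order engine, the default),
#'   `"isma-recursive"`, `"rsma"` (naive fixed-order baseline) or
#'   `"oracle"` (brute force over all node tuples; small graphs only).
#' @param induced discard instances whose `"0"` motif pairs are joined by
#'   an edge of any type; default `FALSE` (non-induced matching).
#' @param use_symmetry symmetry-set pruning for `algorithm = "isma"`.
#' @return a `motif_matches` object.
#' @examples
#' wx <- build_worked_example()
#' find_motifs(wx$graph, "ABC")
#' @export
find_motifs <- function(g, motif,
                        algorithm = c("isma", "isma-recursive", "rsma", "oracle"),
                        induced = FALSE, use_symmetry = TRUE) {
  algorithm <- match.arg(algorithm)
  m <- if (inherits(motif, "motif_spec")) motif else parse_motif(motif, g$registry)
  switch(algorithm,
         "isma" = find_motifs_isma(m, g, use_symmetry = use_symmetry,
                                   induced = induced),
         "isma-recursive" = find_motifs_isma_recursive(m, g, induced = induced),
         "rsma" = find_motifs_rsma(m, g, induced = induced),
         "oracle" = {
           o <- oracle_enumerate(m, g,
                                 mode = if (induced) "induced" else "non-induced")
           new_search_result(o$unique, m, "oracle", NA_integer_,
                             o$n_ordered - o$n_unique)
         })
}
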