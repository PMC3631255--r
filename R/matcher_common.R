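## Candidate-set machinery shared by all engines.
##
## A partial instance is a length-k character vector: position i holds the
## network node mapped on motif node i, or NA.  Candidate sets are built by
## intersecting type-indexed neighbor sets, so every candidate is feasible
## by construction and no post-hoc edge checking is needed.

as_instance <- function(m, inst) {
  k <- m$k
  if (is.null(inst)) return(rep(NA_character_, k))
  if (!is.null(names(inst)) && all(nzchar(names(inst)))) {
    out <- rep(NA_character_, k)
    idx <- as.integer(names(inst))
    if (anyNA(idx) || any(idx < 1L) || any(idx > k))
      stop("instance names must be motif indexes in 1..", k)
    out[idx] <- as.character(unname(inst))
    return(out)
  }
  inst <- as.character(inst)
  if (length(inst) != k) stop("unnamed instance must have length k = ", k)
  inst
}

#' Candidate network nodes for a motif node
#'
#' For an empty partial instance the candidates are the intersection, over
#' all non-`"0"` codes departing `mn`, of the start-node sets of those codes
#' (nodes that have the right link types departing from them).  Otherwise
#' they are the intersection, over every mapped motif node `ni` whose pair
#' code to `mn` is not `"0"`, of the neighbors of the mapped network node
#' via that oriented code.  Nodes already mapped in the instance are
#' excluded (injectivity).  When symmetry pruning is active, the unconsumed
#' symmetry sets of already-chosen motif nodes symmetric to `mn` join the
#' intersection.
#'
#' @param inst partial instance: length-`k` character vector (`NA` =
#'   unmapped) or a named vector like `c("2" = "5", "3" = "4")`.
#' @param mn the unmapped motif node to find candidates for.
#' @param g a [typed_graph].
#' @param m a [parse_motif()] result.
#' @param sym optional symmetry context used internally by the engine:
#'   `list(sets = <per-node candidate sets>, lists = <per-node symmetry
#'   lists>, checked = <chosen motif nodes>)`.
#' @return character vector of candidate nodes in [node_sort()] order.
#' @export
determine_set <- function(inst, mn, g, m, sym = NULL) {
  stopifnot(inherits(m, "motif_spec"), inherits(g, "typed_graph"))
  inst <- as_instance(m, inst)
  if (!is.na(inst[mn])) stop("motif node ", mn, " is already mapped")
  mapped <- which(!is.na(inst))
  sets <- list()
  if (length(mapped) == 0L) {
    codes <- codes_from(m, mn)
    if (length(codes) == 0L)
      stop("motif node ", mn, " has no links: cannot form a candidate set")
    for (code in codes)
      sets[[length(sets) + 1L]] <- start_nodes_of_type(g, code)
  } else {
    for (ni in mapped) {
      code <- m$codes[ni, mn]
      if (code == "0") next
      sets[[length(sets) + 1L]] <- neighbors_of_type(g, inst[ni], code)
    }
    if (length(sets) == 0L)
      stop("disconnected motif ordering: motif node ", mn,
           " has no link to any mapped motif node")
  }
  if (!is.null(sym)) {
    for (cn in sym$checked) {
      if (mn %in% sym$lists[[cn]] && !is.null(sym$sets[[cn]]))
        sets[[length(sets) + 1L]] <- sym$sets[[cn]]
    }
  }
  out <- Reduce(intersect, sets)
  if (length(mapped) > 0L) out <- setdiff(out, inst[mapped])
  node_sort(out)
}

#' Choose the first motif node to investigate
#'
#' Counts the network start nodes of every oriented type code occurring in
#' the motif (reverse codes of directed types included).  If a unique
#' minimal count points at a unique motif node, that node wins outright.
#' On a tie, the intersection value IV -- the cardinality of the
#' intersection of the start-node sets of all codes departing a motif node
#' -- is computed for *all* motif nodes and the minimum wins; a residual tie
#' goes to the smallest motif index.
#'
#' @param g a [typed_graph].
#' @param m a [parse_motif()] result with at least one link.
#' @return list with `index` (the chosen motif node), `candidates` (its
#'   start set, see [determine_set()]) and `type_counts` (named integer
#'   vector of start-node counts per oriented code).
#' @export
select_first_motif_node <- function(g, m) {
  stopifnot(inherits(m, "motif_spec"), inherits(g, "typed_graph"))
  keys <- motif_type_keys(m)
  if (length(keys) == 0L) stop("motif has no links")
  counts <- vapply(keys, function(k2) length(start_nodes_of_type(g, k2)), integer(1))
  names(counts) <- keys
  min_count <- min(counts)
  hits <- list()   # (key, motif node) pairs attaining the minimum
  for (key in keys[counts == min_count])
    for (i in seq_len(m$k))
      if (key %in% codes_from(m, i)) hits[[length(hits) + 1L]] <- c(key, i)
  empty <- rep(NA_character_, m$k)
  if (length(hits) == 1L) {
    winner <- as.integer(hits[[1L]][2L])
  } else {
    best_iv <- Inf; winner <- NA_integer_
    for (i in seq_len(m$k)) {
      if (length(codes_from(m, i)) == 0L) next
      iv <- length(determine_set(empty, i, g, m))
      if (iv < best_iv) { best_iv <- iv; winner <- i }
    }
  }
  list(index = winner,
       candidates = determine_set(empty, winner, g, m),
       type_counts = counts)
}

## instance post-filter for induced matching: every '0' pair must be
## edge-free across all types and both orientations
induced_ok <- function(g, m, inst) {
  k <- m$k
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (m$codes[i, j] == "0" && adjacent_any(g, inst[i], inst[j]))
      return(FALSE)
  }
  TRUE
}

## shared exporter: canonical-form duplicate elimination over the full
## automorphism group, plus the optional induced post-filter
make_exporter <- function(g, m, auts, induced) {
  seen <- new.env(parent = emptyenv())
  found <- list()
  dup <- 0L
  export <- function(inst) {
    if (induced && !induced_ok(g, m, inst)) return(invisible(NULL))
    key <- canonical_instance_key(inst, auts)
    if (exists(key, envir = seen, inherits = FALSE)) {
      dup <<- dup + 1L
    } else {
      assign(key, TRUE, envir = seen)
      found[[length(found) + 1L]] <<- inst
    }
    invisible(NULL)
  }
  list(export = export,
       result = function() list(instances = found, duplicates = dup))
}

## rows of complete instances as a sorted k-column matrix
instances_matrix <- function(found, k) {
  if (length(found) == 0L)
    return(matrix(character(0), nrow = 0L, ncol = k))
  mat <- do.call(rbind, found)
  dimnames(mat) <- NULL
  lv <- node_sort(unique(as.vector(mat)))
  ord <- do.call(order, c(lapply(seq_len(k), function(j) match(mat[, j], lv)),
                          list(method = "radix")))
  mat[ord, , drop = FALSE]
}

new_search_result <- function(instances, m, algorithm, tree_nodes, duplicates) {
  structure(list(instances = instances,
                 motif = motif_string(m),
                 algorithm = algorithm,
                 stats = list(tree_nodes = tree_nodes,
                              instances_found = nrow(instances),
                              duplicates_discarded = duplicates)),
            class = "motif_matches")
}

#' @export
print.motif_matches <- function(x, ...) {
  cat(sprintf("motif_matches [%s, %s]: %d unique instance(s), search tree %d node(s), %d duplicate(s) discarded\n",
              x$motif, x$algorithm, x$stats$instances_found,
              x$stats$tree_nodes, x$stats$duplicates_discarded))
  n <- nrow(x$instances)
  for (i in seq_len(min(n, 10L)))
    cat("  [", paste(x$instances[i, ], collapse = ", "), "]\n", sep = "")
  if (n > 10L) cat("  ... and ", n - 10L, " more\n", sep = "")
  invisible(x)
}
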