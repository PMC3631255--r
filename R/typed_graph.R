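## Edge-typed multigraph with two derived indexes:
##   index_starts:    type key            -> set of start nodes of that key
##   index_neighbors: (node, type key)    -> set of neighbors reachable via key
## Both are maintained incrementally on insertion so candidate-set queries
## during the search are simple environment lookups.

SEP <- "\x1f"  # field separator inside environment keys; never occurs in names

#' Sort node identifiers deterministically
#'
#' Purely numeric identifier sets are ordered numerically (so the output for
#' integer-labelled fixtures reads naturally); anything else falls back to
#' radix (C-locale) string order.  All candidate-set iteration in the
#' matching engines uses this order, which makes runs and search-tree sizes
#' reproducible.
#'
#' @param x character vector of node identifiers.
#' @return `x`, sorted.
#' @export
node_sort <- function(x) {
  if (length(x) <= 1L) return(x)
  if (all(grepl("^[0-9]+$", x))) x[order(as.numeric(x), method = "radix")]
  else sort(x, method = "radix")
}

#' Create an empty edge-typed graph
#'
#' Nodes are opaque strings; edges are `(start, end, type)` triplets.
#' Parallel edges between the same ordered node pair are allowed if and only
#' if their types differ; self-loops are rejected (a motif never contains
#' one).  The graph is a mutable environment: [add_link()] updates it in
#' place and returns it invisibly.
#'
#' @param registry a [link_registry] declaring the permitted edge types.
#' @return an object of class `typed_graph`.
#' @examples
#' g <- typed_graph(link_registry(c(A = "d")))
#' add_link(g, "1", "5", "A")
#' start_nodes_of_type(g, "A")
#' @export
typed_graph <- function(registry) {
  if (!inherits(registry, "link_registry"))
    stop("'registry' must be a link_registry")
  g <- new.env(parent = emptyenv())
  g$registry <- registry
  g$nodes <- new.env(parent = emptyenv())     # node -> TRUE
  g$edges <- new.env(parent = emptyenv())     # "u SEP v SEP T" -> TRUE (canonical)
  g$oriented <- new.env(parent = emptyenv())  # "u SEP v SEP key" -> TRUE (both views)
  g$adj_any <- new.env(parent = emptyenv())   # "u SEP v" -> TRUE (any type, both ways)
  g$index_starts <- new.env(parent = emptyenv())
  g$index_neighbors <- new.env(parent = emptyenv())
  g$n_edges <- 0L
  g$n_duplicates <- 0L
  class(g) <- "typed_graph"
  g
}

set_insert <- function(env, key, value) {
  cur <- get0(key, envir = env, ifnotfound = character(0))
  if (!(value %in% cur)) assign(key, node_sort(c(cur, value)), envir = env)
  invisible(NULL)
}

add_node <- function(g, n) {
  if (!is.character(n) || length(n) != 1L || !nzchar(n))
    stop("node identifiers must be non-empty strings")
  if (grepl(SEP, n, fixed = TRUE)) stop("node identifier contains a control byte")
  assign(n, TRUE, envir = g$nodes)
  invisible(NULL)
}

#' Add one typed edge to a graph
#'
#' Updates both indexes: for a directed type `X` the forward key `X` gains
#' start node `u` and the reverse key `x` gains `v`, and the adjacency index
#' receives the entries `(u, X) -> v` and `(v, x) -> u`.  For an undirected
#' type both endpoints enter the start index and both oriented adjacency
#' entries use the upper-case key.  Duplicate insertions are silently
#' de-duplicated (and counted).
#'
#' @param g a [typed_graph], modified in place.
#' @param u,v start and end node identifiers (strings).
#' @param type declared type name (upper case).
#' @return `g`, invisibly.
#' @export
add_link <- function(g, u, v, type) {
  stopifnot(inherits(g, "typed_graph"))
  if (!reg_has_type(g$registry, type))
    stop("unknown link type '", type, "'")
  u <- as.character(u); v <- as.character(v)
  if (identical(u, v))
    stop("self-loop ", u, " -> ", v, " rejected: motifs cannot match self-loops")
  add_node(g, u); add_node(g, v)
  directed <- reg_is_directed(g$registry, type)
  ckey <- if (directed) paste(u, v, type, sep = SEP)
          else paste(node_sort(c(u, v))[1], node_sort(c(u, v))[2], type, sep = SEP)
  if (exists(ckey, envir = g$edges, inherits = FALSE)) {
    g$n_duplicates <- g$n_duplicates + 1L
    return(invisible(g))
  }
  assign(ckey, TRUE, envir = g$edges)
  g$n_edges <- g$n_edges + 1L
  rkey <- if (directed) tolower(type) else type
  set_insert(g$index_starts, type, u)
  set_insert(g$index_starts, rkey, v)
  set_insert(g$index_neighbors, paste(u, type, sep = SEP), v)
  set_insert(g$index_neighbors, paste(v, rkey, sep = SEP), u)
  assign(paste(u, v, type, sep = SEP), TRUE, envir = g$oriented)
  assign(paste(v, u, rkey, sep = SEP), TRUE, envir = g$oriented)
  assign(paste(u, v, sep = SEP), TRUE, envir = g$adj_any)
  assign(paste(v, u, sep = SEP), TRUE, envir = g$adj_any)
  invisible(g)
}

#' All start nodes of a type key
#'
#' For directed `X`, key `"X"` yields the start nodes of `X` edges and key
#' `"x"` their end nodes; for an undirected type the key yields every
#' endpoint.  The indexed set is returned directly (no recomputation);
#' callers must treat it as read-only.
#'
#' @param g a [typed_graph].
#' @param key oriented type key (`"X"` or `"x"`).
#' @return character vector of node identifiers, in [node_sort()] order.
#' @export
start_nodes_of_type <- function(g, key) {
  stopifnot(inherits(g, "typed_graph"))
  key <- resolve_key(g$registry, key)
  get0(key, envir = g$index_starts, ifnotfound = character(0))
}

#' Neighbors of a node via a type key
#'
#' For directed `X`, key `"X"` yields the out-neighbors of `n` via `X` and
#' `"x"` its in-neighbors; an undirected key yields all partners.
#'
#' @inheritParams start_nodes_of_type
#' @param n node identifier; must exist in the graph.
#' @return character vector of node identifiers, in [node_sort()] order.
#' @export
neighbors_of_type <- function(g, n, key) {
  stopifnot(inherits(g, "typed_graph"))
  n <- as.character(n)
  if (!exists(n, envir = g$nodes, inherits = FALSE))
    stop("unknown node '", n, "'")
  key <- resolve_key(g$registry, key)
  get0(paste(n, key, sep = SEP), envir = g$index_neighbors,
       ifnotfound = character(0))
}

#' Nodes of a graph
#' @param g a [typed_graph].
#' @return character vector of node identifiers in [node_sort()] order.
#' @export
graph_nodes <- function(g) {
  stopifnot(inherits(g, "typed_graph"))
  node_sort(ls(g$nodes, sorted = FALSE))
}

#' Edge list of a graph
#' @param g a [typed_graph].
#' @return data.frame with columns `from`, `to`, `type` (canonical storage
#'   orientation; undirected edges appear once with sorted endpoints).
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "typed_graph"))
  keys <- ls(g$edges, sorted = FALSE)
  if (length(keys) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      type = character(0), stringsAsFactors = FALSE))
  parts <- strsplit(keys, SEP, fixed = TRUE)
  df <- data.frame(from = vapply(parts, `[[`, "", 1L),
                   to = vapply(parts, `[[`, "", 2L),
                   type = vapply(parts, `[[`, "", 3L),
                   stringsAsFactors = FALSE)
  df <- df[order(df$type, df$from, df$to, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Is there an edge realising an oriented pair code?
#' @keywords internal
has_oriented_edge <- function(g, u, v, key) {
  exists(paste(u, v, key, sep = SEP), envir = g$oriented, inherits = FALSE)
}

#' Are two nodes adjacent by any edge of any type?
#' @keywords internal
adjacent_any <- function(g, u, v) {
  exists(paste(u, v, sep = SEP), envir = g$adj_any, inherits = FALSE)
}

#' All oriented edge keys, for vectorised membership tests
#' @keywords internal
oriented_edge_keys <- function(g) ls(g$oriented, sorted = FALSE)

#' @export
print.typed_graph <- function(x, ...) {
  cat(sprintf("typed_graph: %d nodes, %d edges, types: %s\n",
              length(ls(x$nodes, sorted = FALSE)), x$n_edges,
              paste(x$registry$names, collapse = ", ")))
  invisible(x)
}
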