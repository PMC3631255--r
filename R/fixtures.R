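## Deterministic test assets: the six-node worked-example network, a random
## typed-graph generator for property tests, and a brute-force enumeration
## oracle that defines ground truth on small inputs.

#' The six-node worked-example network and its "ABC" motif
#'
#' A small network over nodes `1..6` with two directed types (`A`, `B`) and
#' one undirected type (`C`), together with the three-node motif `"ABC"`
#' (`1 -A-> 2`, `1 -B-> 3`, `2 -C- 3`).  The edge lists are reconstructed
#' from the printed constraints the fixture must satisfy simultaneously:
#' the five per-key start-node sets (`A = {1,2,5}`, `B = {1,2,4,5}`,
#' `C = {2,3,4,5,6}`, `a = {1,5,6}`, `b = {2,3,4}`) and six narrated
#' neighbor sets (`a(5) = {1,2}`, `C(5) = {4}`, `b(4) = {1}`, `a(6) = {5}`,
#' `C(6) = {2,3}`, `B(5) = {3}`).  Two A-edge completions satisfy every
#' constraint; `2 -> 1` is the canonical choice and `5 -> 1` the
#' alternative, and both give identical instances and tree sizes (the test
#' suite asserts this).
#'
#' @param variant `"canonical"` (A edge `2 -> 1`) or `"alternative"`
#'   (A edge `5 -> 1`).
#' @return list with `graph`, `registry`, `motif` (a `motif_spec`),
#'   `motif_string`, `expected_instances` (matrix in motif order) and
#'   `expected_tree_sizes` (named: `rsma`, `isma`).
#' @export
build_worked_example <- function(variant = c("canonical", "alternative")) {
  variant <- match.arg(variant)
  reg <- link_registry(c(A = "d", B = "d", C = "u"))
  g <- typed_graph(reg)
  a_edges <- rbind(c("1", "5"), c("2", "5"), c("5", "6"),
                   if (variant == "canonical") c("2", "1") else c("5", "1"))
  b_edges <- rbind(c("1", "4"), c("2", "3"), c("4", "2"), c("5", "3"))
  c_edges <- rbind(c("4", "5"), c("2", "6"), c("3", "6"))
  for (r in seq_len(nrow(a_edges))) add_link(g, a_edges[r, 1], a_edges[r, 2], "A")
  for (r in seq_len(nrow(b_edges))) add_link(g, b_edges[r, 1], b_edges[r, 2], "B")
  for (r in seq_len(nrow(c_edges))) add_link(g, c_edges[r, 1], c_edges[r, 2], "C")
  list(graph = g,
       registry = reg,
       motif = parse_motif("ABC", reg),
       motif_string = "ABC",
       expected_instances = rbind(c("1", "5", "4"), c("5", "6", "3")),
       expected_tree_sizes = c(rsma = 12L, isma = 6L))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random edge-typed graph (per-type Erdős–Rényi)
#'
#' Each declared type samples its edges independently: directed types over
#' all ordered node pairs, undirected types over unordered pairs, each pair
#' present with probability `p`.  Reproducible for a fixed seed, and the
#' caller's RNG state is left untouched.
#'
#' @param n node count; nodes are named `"1" .. "n"`.
#' @param types a [link_registry].
#' @param p per-type edge probability in `[0, 1]`; scalar or named per type.
#' @param seed integer seed.
#' @return a [typed_graph] (isolated nodes are kept).
#' @export
random_typed_graph <- function(n, types, p, seed) {
  stopifnot(inherits(types, "link_registry"), n >= 1L)
  if (any(p < 0) || any(p > 1)) stop("'p' must be in [0, 1]")
  probs <- if (length(p) == 1L) stats::setNames(rep(p, length(types$names)), types$names)
           else p[types$names]
  if (anyNA(probs)) stop("'p' must be scalar or named for every type")
  g <- typed_graph(types)
  for (i in seq_len(n)) add_node(g, as.character(i))
  with_seed(seed, {
    for (t in types$names) {
      if (n < 2L) next
      if (reg_is_directed(types, t)) {
        pairs <- expand.grid(u = seq_len(n), v = seq_len(n))
        pairs <- pairs[pairs$u != pairs$v, , drop = FALSE]
      } else {
        cmb <- utils::combn(n, 2L)
        pairs <- data.frame(u = cmb[1L, ], v = cmb[2L, ])
      }
      pick <- stats::runif(nrow(pairs)) < probs[[t]]
      for (r in which(pick))
        add_link(g, as.character(pairs$u[r]), as.character(pairs$v[r]), t)
    }
  })
  g
}

#' Brute-force enumeration oracle
#'
#' Tests every injective assignment of `k` network nodes to the motif nodes
#' against every pair code: a non-`"0"` code must be realised by an edge of
#' exactly that oriented type, and in induced mode a `"0"` pair must be
#' edge-free across all types.  Ordered embeddings collapsed by the motif's
#' automorphism group give the unique instances.  This is the ground truth
#' the search engines are verified against; a size guard keeps it honest
#' (use the engines for anything larger).
#'
#' @param m a [parse_motif()] result, `k <= 5`.
#' @param g a [typed_graph] with at most 40 nodes.
#' @param mode `"non-induced"` (default) or `"induced"`.
#' @return list with `ordered` (matrix of all ordered embeddings), `unique`
#'   (matrix of unique instances, motif order, sorted), `n_ordered`,
#'   `n_unique`.
#' @export
oracle_enumerate <- function(m, g, mode = c("non-induced", "induced")) {
  stopifnot(inherits(m, "motif_spec"), inherits(g, "typed_graph"))
  mode <- match.arg(mode)
  k <- m$k
  nodes <- graph_nodes(g)
  if (length(nodes) > 40L || k > 5L)
    stop("oracle guard exceeded (n <= 40, k <= 5): use the search engines instead")
  empty <- matrix(character(0), nrow = 0L, ncol = k)
  if (length(nodes) < k)
    return(list(ordered = empty, unique = empty, n_ordered = 0L, n_unique = 0L))
  keyset <- oriented_edge_keys(g)
  adjset <- ls(g$adj_any, sorted = FALSE)
  combs <- utils::combn(nodes, k)           # k x C, columns are node sets
  perms <- sjt_permutations(k)
  ordered <- list()
  for (p in perms) {
    tup <- combs[p, , drop = FALSE]         # row i: node mapped on motif node i
    ok <- rep(TRUE, ncol(tup))
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        code <- m$codes[i, j]
        if (code != "0") {
          ok <- ok & (paste(tup[i, ], tup[j, ], code, sep = SEP) %in% keyset)
        } else if (mode == "induced") {
          ok <- ok & !(paste(tup[i, ], tup[j, ], sep = SEP) %in% adjset)
        }
        if (!any(ok)) break
      }
      if (!any(ok)) break
    }
    if (any(ok)) ordered[[length(ordered) + 1L]] <- t(tup[, ok, drop = FALSE])
  }
  if (length(ordered) == 0L)
    return(list(ordered = empty, unique = empty, n_ordered = 0L, n_unique = 0L))
  omat <- do.call(rbind, ordered)
  auts <- automorphisms(m)
  keys <- vapply(seq_len(nrow(omat)),
                 function(r) canonical_instance_key(omat[r, ], auts), "")
  umat <- omat[!duplicated(keys), , drop = FALSE]
  list(ordered = omat,
       unique = instances_matrix(lapply(seq_len(nrow(umat)),
                                        function(r) umat[r, ]), k),
       n_ordered = nrow(omat),
       n_unique = nrow(umat))
}
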