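## Motif symmetry analysis.  The automorphism group is found by checking
## every permutation of the k motif nodes against the pair-code table.
## Automorphisms are then classified into the two shapes the search engine
## prunes directly -- reflection classes (mutually swappable node sets) and
## cyclic rotations -- with everything else handled by canonical-form
## duplicate elimination on export ("residual" symmetries).

#' Permutations by plain changes (Steinhaus-Johnson-Trotter)
#'
#' Generates all `k!` permutations of `1..k` such that consecutive
#' permutations differ by a single swap of two adjacent elements, using the
#' directed-integer formulation (Even's speedup of the classic bell-ringers'
#' scheme).  Work per emitted permutation is O(k) for the mobile-element
#' scan, constant amortised in the output size.
#'
#' @param k number of elements, `1 <= k <= 10` (guard against factorial
#'   blow-up).
#' @return list of `k!` integer vectors, starting with the identity.
#' @export
sjt_permutations <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1L || k > 10L)
    stop("'k' must be an integer in 1..10")
  k <- as.integer(k)
  perm <- seq_len(k)
  dir <- rep(-1L, k)               # all elements initially point left
  out <- vector("list", factorial(k))
  out[[1L]] <- perm
  step <- 1L
  repeat {
    # largest mobile element: points at a smaller adjacent element
    mobile <- 0L; mpos <- 0L
    for (pos in seq_len(k)) {
      tgt <- pos + dir[perm[pos]]
      if (tgt >= 1L && tgt <= k && perm[tgt] < perm[pos] && perm[pos] > mobile) {
        mobile <- perm[pos]; mpos <- pos
      }
    }
    if (mobile == 0L) break
    tgt <- mpos + dir[mobile]
    tmp <- perm[tgt]; perm[tgt] <- perm[mpos]; perm[mpos] <- tmp
    if (mobile < k) dir[(mobile + 1L):k] <- -dir[(mobile + 1L):k]
    step <- step + 1L
    out[[step]] <- perm
  }
  out
}

perm_key <- function(p) paste(p, collapse = ",")

compose_perms <- function(p, q) p[q]   # (p o q)(i) = p[q[i]]

#' Automorphism group of a motif
#'
#' A permutation `p` of the motif nodes is an automorphism iff relabelling
#' the nodes by `p` reproduces the identical pair-code table, i.e.
#' `code(p(i), p(j)) == code(i, j)` for every ordered pair.
#'
#' @param m a [parse_motif()] result (`k <= 10`).
#' @return list of integer permutation vectors; always contains the
#'   identity.
#' @export
automorphisms <- function(m) {
  stopifnot(inherits(m, "motif_spec"))
  k <- m$k
  keep <- list()
  for (p in sjt_permutations(k)) {
    ok <- TRUE
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (m$codes[p[i], p[j]] != m$codes[i, j]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) keep[[length(keep) + 1L]] <- p
  }
  keep
}

perm_cycles <- function(p) {
  k <- length(p)
  seen <- logical(k)
  cycles <- list()
  for (s in seq_len(k)) {
    if (seen[s]) next
    cyc <- s; seen[s] <- TRUE; cur <- p[s]
    while (cur != s) { cyc <- c(cyc, cur); seen[cur] <- TRUE; cur <- p[cur] }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

group_closure <- function(generators, k) {
  elems <- new.env(parent = emptyenv())
  id <- seq_len(k)
  assign(perm_key(id), id, envir = elems)
  frontier <- generators
  for (p in frontier) assign(perm_key(p), p, envir = elems)
  while (length(frontier) > 0L) {
    nxt <- list()
    for (p in frontier) {
      for (gkey in ls(elems, sorted = FALSE)) {
        for (q in list(compose_perms(p, get(gkey, envir = elems)),
                       compose_perms(get(gkey, envir = elems), p))) {
          qk <- perm_key(q)
          if (!exists(qk, envir = elems, inherits = FALSE)) {
            assign(qk, q, envir = elems)
            nxt[[length(nxt) + 1L]] <- q
          }
        }
      }
    }
    frontier <- nxt
  }
  mget(ls(elems), envir = elems)
}

#' Classify motif symmetries for search-tree pruning
#'
#' Transposition automorphisms are grouped into *reflection classes*
#' (connected components of the swap graph; closure of the group makes these
#' mutually swappable sets).  Automorphisms consisting of a single cycle of
#' length >= 3 (all other nodes fixed) give *rotation cycles*; the
#' smallest-index node of a cycle is designated its "first" node.  When a
#' node could belong to both shapes, reflections are claimed first and only
#' rotations disjoint from every claimed node are accepted.  Any
#' automorphism not generated by the claimed shapes lands in `residual` and
#' is handled by canonical-form duplicate elimination, which is always
#' sound.
#'
#' Per-node symmetry lists follow the pruning protocol: a reflection-class
#' node lists all other members of its class; a rotation's first node lists
#' all other cycle members while the other members list only the first
#' node.
#'
#' @param m a [parse_motif()] result.
#' @return object of class `symmetry_info`: list with `automorphisms`,
#'   `reflection_classes` (list of integer vectors), `rotation_cycles`
#'   (list of `list(cycle, first)`), `sym_lists` (per motif node, the nodes
#'   it is symmetric to under the pruning protocol) and `residual`
#'   (automorphisms not generated by the claimed shapes).
#' @export
classify_symmetries <- function(m) {
  stopifnot(inherits(m, "motif_spec"))
  k <- m$k
  auts <- automorphisms(m)

  transpositions <- Filter(function(p) sum(p != seq_len(k)) == 2L, auts)
  swap_adj <- matrix(FALSE, k, k)
  for (p in transpositions) {
    moved <- which(p != seq_len(k))
    swap_adj[moved[1], moved[2]] <- TRUE
    swap_adj[moved[2], moved[1]] <- TRUE
  }
  # connected components of the swap graph; group closure makes them cliques
  refl_classes <- list()
  claimed <- logical(k)
  for (s in seq_len(k)) {
    if (claimed[s] || !any(swap_adj[s, ])) next
    comp <- s; frontier <- s; claimed[s] <- TRUE
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (i in frontier) for (j in which(swap_adj[i, ]))
        if (!claimed[j]) { claimed[j] <- TRUE; comp <- c(comp, j); nxt <- c(nxt, j) }
      frontier <- nxt
    }
    refl_classes[[length(refl_classes) + 1L]] <- sort(comp)
  }

  rot_cycles <- list()
  rot_sets <- character(0)
  for (p in auts) {
    cycles <- perm_cycles(p)
    lens <- lengths(cycles)
    if (sum(lens > 1L) != 1L) next
    cyc <- cycles[[which(lens > 1L)]]
    if (length(cyc) < 3L) next
    if (any(claimed[cyc])) next                  # reflections claimed first
    setkey <- paste(sort(cyc), collapse = ",")
    if (setkey %in% rot_sets) next               # sigma and its powers: one cycle
    rot_sets <- c(rot_sets, setkey)
    first <- min(cyc)
    start <- which(cyc == first)
    cyc <- c(cyc[start:length(cyc)], cyc[seq_len(start - 1L)])
    rot_cycles[[length(rot_cycles) + 1L]] <- list(cycle = cyc, first = first)
    claimed[cyc] <- TRUE
  }

  sym_lists <- rep(list(integer(0)), k)
  for (cls in refl_classes)
    for (i in cls) sym_lists[[i]] <- setdiff(cls, i)
  for (rot in rot_cycles) {
    f <- rot$first
    others <- setdiff(rot$cycle, f)
    sym_lists[[f]] <- others
    for (o in others) sym_lists[[o]] <- f
  }

  generators <- list()
  for (cls in refl_classes)
    for (a in cls) for (b in cls) if (a < b) {
      p <- seq_len(k); p[a] <- b; p[b] <- a
      generators[[length(generators) + 1L]] <- p
    }
  for (rot in rot_cycles) {
    p <- seq_len(k)
    cyc <- rot$cycle
    for (i in seq_along(cyc)) p[cyc[i]] <- cyc[if (i == length(cyc)) 1L else i + 1L]
    generators[[length(generators) + 1L]] <- p
  }
  generated <- group_closure(generators, k)
  gen_keys <- vapply(generated, perm_key, "")
  residual <- Filter(function(p) !(perm_key(p) %in% gen_keys), auts)

  structure(list(automorphisms = auts,
                 reflection_classes = refl_classes,
                 rotation_cycles = rot_cycles,
                 sym_lists = sym_lists,
                 residual = residual),
            class = "symmetry_info")
}

#' @export
print.symmetry_info <- function(x, ...) {
  cat(sprintf("symmetry_info: |Aut| = %d, %d reflection class(es), %d rotation cycle(s), %d residual\n",
              length(x$automorphisms), length(x$reflection_classes),
              length(x$rotation_cycles), length(x$residual)))
  invisible(x)
}

## canonical form of a complete instance tuple under the full automorphism
## group: the lexicographically smallest relabelled tuple, as one key string
canonical_instance_key <- function(tuple, auts) {
  keys <- vapply(auts, function(p) {
    img <- tuple
    img[p] <- tuple          # node on motif i moves to position p[i]
    paste(img, collapse = "\x1f")
  }, "")
  # radix sort = C-locale byte comparison; locale collation may ignore the
  # separator byte and conflate distinct tuples
  sort(keys, method = "radix")[1L]
}
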