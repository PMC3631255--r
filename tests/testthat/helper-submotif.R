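# Shared helpers: canonical-set comparison of instance matrices (engines may
# legitimately report different representatives of the same automorphism
# orbit) and the standard registries for the motifs used throughout.

canon_keys <- function(mat, auts) {
  if (nrow(mat) == 0L) return(character(0))
  sort(vapply(seq_len(nrow(mat)),
              function(r) submotif:::canonical_instance_key(mat[r, ], auts), ""),
       method = "radix")
}

expect_same_instances <- function(got, want, auts) {
  expect_identical(canon_keys(got, auts), canon_keys(want, auts))
}

test_registry <- function(motif_string) {
  switch(motif_string,
         "ABC" = link_registry(c(A = "d", B = "d", C = "u")),
         "AAC" = ,
         "AA0" = link_registry(c(A = "d", C = "u")),
         "AaA" = link_registry(c(A = "d")),
         "XXX" = ,
         "X0XX0X" = link_registry(c(X = "u")),
         stop("no registry for ", motif_string))
}

test_motif <- function(motif_string)
  parse_motif(motif_string, test_registry(motif_string))

# complete digraph on n nodes, one directed type A (both orientations)
complete_digraph_A <- function(n) {
  g <- typed_graph(link_registry(c(A = "d")))
  for (u in seq_len(n)) for (v in seq_len(n))
    if (u != v) add_link(g, as.character(u), as.character(v), "A")
  g
}

# complete undirected graph on n nodes, one type X
complete_graph_X <- function(n) {
  g <- typed_graph(link_registry(c(X = "u")))
  cmb <- utils::combn(n, 2L)
  for (c2 in seq_len(ncol(cmb)))
    add_link(g, as.character(cmb[1L, c2]), as.character(cmb[2L, c2]), "X")
  g
}

# star: center "c" with directed A edges to s leaves
star_graph_A <- function(s, registry = link_registry(c(A = "d"))) {
  g <- typed_graph(registry)
  for (l in seq_len(s)) add_link(g, "c", paste0("l", l), "A")
  g
}

perm_is_identity <- function(p) all(p == seq_along(p))
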