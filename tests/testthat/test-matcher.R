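# The enumeration engines and their candidate-set machinery, traced against
# the worked-example narration and verified against the brute-force oracle.

wx <- build_worked_example()

test_that("determine_set reproduces the worked-example candidate sets", {
  g <- wx$graph; m <- wx$motif
  # empty instance, motif node 2: intersection of start sets of 'a' and 'C'
  expect_identical(determine_set(NULL, 2, g, m), c("5", "6"))
  # after mapping 5 on node 2: candidates for node 3 via C
  expect_identical(determine_set(c("2" = "5"), 3, g, m), "4")
  # {2:5, 3:4} -> node 1 is the singleton {1}
  expect_identical(determine_set(c("2" = "5", "3" = "4"), 1, g, m), "1")
  # second branch: 6 on node 2 -> node 1 candidates {5}
  expect_identical(determine_set(c("2" = "6"), 1, g, m), "5")
  # {2:6, 1:5} -> node 3 is the singleton {3}
  expect_identical(determine_set(c("2" = "6", "1" = "5"), 3, g, m), "3")
})

test_that("candidate sets are subsets of every constituent neighbor set", {
  reg <- link_registry(c(A = "d", B = "d", C = "u"))
  m <- parse_motif("ABC", reg)
  for (seed in 1:5) {
    g <- random_typed_graph(12, reg, p = 0.25, seed = seed)
    nodes <- graph_nodes(g)
    for (n1 in nodes[1:4]) {
      inst <- c("2" = n1)
      for (mn in c(1L, 3L)) {
        set <- determine_set(inst, mn, g, m)
        code <- link_code_between(m, 2L, mn)
        expect_true(all(set %in% neighbors_of_type(g, n1, code)))
        expect_false(n1 %in% set)  # injectivity
      }
    }
  }
})

test_that("determine_set rejects unconstrained motif nodes mid-search", {
  g <- wx$graph
  m4 <- parse_motif("A0000A", wx$registry)  # 1-A->2, 3-A->4, disconnected
  expect_error(determine_set(c("1" = "1"), 3, g, m4), "disconnected motif ordering")
})

test_that("first-node selection counts types and breaks ties by intersection value", {
  sel <- select_first_motif_node(wx$graph, wx$motif)
  expect_identical(sel$type_counts[c("A", "B", "C", "a", "b")],
                   c(A = 3L, B = 4L, C = 5L, a = 3L, b = 3L))
  expect_identical(sel$index, 2L)
  expect_identical(sel$candidates, c("5", "6"))
})

test_that("an empty candidate set short-circuits the search to zero instances", {
  # single S-edge cannot carry a triangle
  g <- typed_graph(link_registry(c(S = "d")))
  add_link(g, "1", "2", "S")
  m <- parse_motif("SSS", link_registry(c(S = "d")))
  expect_identical(find_motifs_isma(m, g)$stats$instances_found, 0L)
  # directed star, motif needing a C link that has no edges
  reg <- link_registry(c(A = "d", C = "u"))
  g2 <- star_graph_A(5, reg)
  m2 <- parse_motif("AAC", reg)
  o <- oracle_enumerate(m2, g2)
  expect_identical(o$n_unique, 0L)
  expect_identical(find_motifs_isma(m2, g2)$stats$instances_found, 0L)
  expect_identical(find_motifs_rsma(m2, g2)$stats$instances_found, 0L)
})

test_that("next_motif_node returns the motif end of the globally minimal head", {
  # the documented 4-node-motif state: network 9 on motif 2, network 5 on
  # motif 4; queues exist for rest nodes 1 and 3, one object per mapped node
  pqm <- list(
    list(list(nn = "9", mstart = 2L, count = 3L),
         list(nn = "5", mstart = 4L, count = 2L)),
    list(),
    list(list(nn = "9", mstart = 2L, count = 4L),
         list(nn = "5", mstart = 4L, count = 1L)),
    list())
  expect_identical(next_motif_node(pqm, rest = c(1L, 3L)), 3L)
  # tie breaks to the smallest motif index
  pqm[[1]][[2]]$count <- 1L
  expect_identical(next_motif_node(pqm, rest = c(1L, 3L)), 1L)
  expect_error(next_motif_node(list(list(), list()), rest = 1:2), "empty")
})

test_that("both engines find exactly the two worked-example instances", {
  for (variant in c("canonical", "alternative")) {
    b <- build_worked_example(variant)
    for (alg in c("isma", "isma-recursive", "rsma")) {
      r <- find_motifs(b$graph, b$motif, algorithm = alg)
      expect_identical(r$instances, b$expected_instances)
    }
  }
})

test_that("worked-example search-tree sizes are 6 (dynamic) vs 12 (naive)", {
  for (variant in c("canonical", "alternative")) {
    b <- build_worked_example(variant)
    expect_identical(find_motifs_isma(b$motif, b$graph)$stats$tree_nodes,
                     unname(b$expected_tree_sizes["isma"]))
    expect_identical(find_motifs_rsma(b$motif, b$graph)$stats$tree_nodes,
                     unname(b$expected_tree_sizes["rsma"]))
  }
})

test_that("empty graph yields zero instances and an empty tree", {
  g <- typed_graph(link_registry(c(A = "d", B = "d", C = "u")))
  m <- parse_motif("ABC", link_registry(c(A = "d", B = "d", C = "u")))
  for (alg in c("isma", "isma-recursive", "rsma")) {
    r <- find_motifs(g, m, algorithm = alg)
    expect_identical(r$stats$instances_found, 0L)
    expect_identical(r$stats$tree_nodes, 0L)
  }
})

test_that("triangle motif on K5 gives the 10 node triples", {
  g <- complete_graph_X(5)
  m <- test_motif("XXX")
  r <- find_motifs_isma(m, g)
  expect_identical(r$stats$instances_found, 10L)
  expect_identical(find_motifs_rsma(m, g)$stats$instances_found, 10L)
})

test_that("reflection pruning explores exactly choose(s, r) combinations", {
  # two reflection-symmetric positions fed from the same s candidates
  m <- test_motif("AA0")
  for (s in c(4L, 6L)) {
    g <- star_graph_A(s)
    r_on <- find_motifs_isma(m, g, use_symmetry = TRUE)
    expect_identical(r_on$stats$instances_found, as.integer(choose(s, 2L)))
    expect_identical(r_on$stats$duplicates_discarded, 0L)  # pruning is exact
    r_off <- find_motifs_isma(m, g, use_symmetry = FALSE)
    expect_identical(r_off$stats$instances_found, as.integer(choose(s, 2L)))
    expect_identical(r_off$stats$duplicates_discarded, as.integer(choose(s, 2L)))
    o <- oracle_enumerate(m, g)
    expect_identical(o$n_ordered, as.integer(2L * choose(s, 2L)))  # |Aut| = 2
    expect_true(r_on$stats$tree_nodes < r_off$stats$tree_nodes)
  }
})

test_that("rotation pruning explores exactly s!/(s-r)!/r combinations", {
  m <- test_motif("AaA")  # directed 3-cycle, cyclic symmetry of order 3
  for (s in c(4L, 5L)) {
    g <- complete_digraph_A(s)
    want <- s * (s - 1L) * (s - 2L) / 3L
    r_on <- find_motifs_isma(m, g, use_symmetry = TRUE)
    expect_identical(r_on$stats$instances_found, as.integer(want))
    expect_identical(r_on$stats$duplicates_discarded, 0L)
    r_off <- find_motifs_isma(m, g, use_symmetry = FALSE)
    expect_identical(r_off$stats$instances_found, as.integer(want))
    expect_identical(r_off$stats$duplicates_discarded, as.integer(2L * want))
    expect_identical(oracle_enumerate(m, g)$n_ordered, as.integer(3L * want))
  }
})

test_that("directed 6-cycle contains no directed triangle", {
  g <- typed_graph(link_registry(c(A = "d")))
  for (i in 1:6) add_link(g, as.character(i), as.character(i %% 6 + 1), "A")
  m <- test_motif("AaA")
  expect_identical(oracle_enumerate(m, g)$n_unique, 0L)
  expect_identical(find_motifs_isma(m, g)$stats$instances_found, 0L)
})

test_that("disconnected motifs are rejected by the engines", {
  m4 <- parse_motif("A0000A", link_registry(c(A = "d")))
  g <- complete_digraph_A(4)
  expect_error(find_motifs_isma(m4, g), "not connected")
  expect_error(find_motifs_rsma(m4, g), "not connected")
})

test_that("induced mode discards instances whose '0' pairs carry edges", {
  # path 1-2-3 plus closing edge 1-3: the open-path motif X0X matches the
  # path only in induced mode when the closing edge is absent
  reg <- link_registry(c(X = "u"))
  m <- parse_motif("X0X", reg)
  g_open <- typed_graph(reg)
  add_link(g_open, "1", "2", "X"); add_link(g_open, "2", "3", "X")
  g_closed <- typed_graph(reg)
  add_link(g_closed, "1", "2", "X"); add_link(g_closed, "2", "3", "X")
  add_link(g_closed, "1", "3", "X")
  for (alg in c("isma", "isma-recursive", "rsma", "oracle")) {
    expect_identical(find_motifs(g_open, m, algorithm = alg, induced = TRUE)$stats$instances_found, 1L)
    expect_identical(find_motifs(g_closed, m, algorithm = alg, induced = TRUE)$stats$instances_found, 0L)
    # non-induced: every one of the triangle's three open paths matches
    expect_identical(find_motifs(g_closed, m, algorithm = alg, induced = FALSE)$stats$instances_found, 3L)
  }
})

test_that("engines agree with the oracle on random typed graphs", {
  # a fast slice of the full acceptance property (which runs 200 graphs)
  for (ms in c("ABC", "AaA", "X0XX0X")) {
    m <- test_motif(ms)
    auts <- automorphisms(m)
    for (seed in 1:5) {
      g <- random_typed_graph(10L + 2L * seed, test_registry(ms),
                              p = 0.05 + 0.04 * seed, seed = 100L + seed)
      o <- oracle_enumerate(m, g)
      expect_same_instances(find_motifs_rsma(m, g)$instances, o$unique, auts)
      expect_same_instances(find_motifs_isma(m, g)$instances, o$unique, auts)
      expect_same_instances(find_motifs_isma(m, g, use_symmetry = FALSE)$instances,
                            o$unique, auts)
    }
  }
})
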