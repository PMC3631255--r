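# Permutation generation, automorphism groups, symmetry classification.

test_that("plain-changes permutations are complete and adjacent-swap chained", {
  expect_identical(sjt_permutations(1), list(1L))
  expect_length(sjt_permutations(5), 120L)
  for (k in 2:6) {
    perms <- sjt_permutations(k)
    expect_length(perms, factorial(k))
    keys <- vapply(perms, paste, "", collapse = ",")
    expect_false(anyDuplicated(keys) > 0)
    for (i in seq_len(length(perms) - 1L)) {
      diffs <- which(perms[[i]] != perms[[i + 1L]])
      expect_length(diffs, 2L)
      expect_identical(diff(diffs), 1L)  # adjacent positions swapped
    }
  }
  expect_error(sjt_permutations(11), "1..10")
  expect_error(sjt_permutations(0), "1..10")
})

test_that("automorphism groups match brute-force expectations", {
  expect_identical(automorphisms(test_motif("ABC")), list(1:3))
  aAAC <- automorphisms(test_motif("AAC"))
  expect_length(aAAC, 2L)
  expect_true(any(vapply(aAAC, identical, TRUE, c(1L, 3L, 2L))))
  aAaA <- automorphisms(test_motif("AaA"))  # directed 3-cycle: cyclic group
  expect_length(aAaA, 3L)
  expect_true(any(vapply(aAaA, identical, TRUE, c(2L, 3L, 1L))))
  expect_true(any(vapply(aAaA, identical, TRUE, c(3L, 1L, 2L))))
  expect_length(automorphisms(test_motif("XXX")), 6L)       # full S3
  expect_length(automorphisms(test_motif("X0XX0X")), 8L)    # dihedral D4
})

test_that("automorphisms form a group and preserve all pair codes", {
  for (s in c("AAC", "AaA", "XXX", "X0XX0X")) {
    m <- test_motif(s)
    auts <- automorphisms(m)
    keys <- vapply(auts, paste, "", collapse = ",")
    expect_true(any(vapply(auts, perm_is_identity, TRUE)))
    for (p in auts) for (q in auts)
      expect_true(paste(p[q], collapse = ",") %in% keys)
    for (p in auts)
      for (i in seq_len(m$k)) for (j in seq_len(m$k))
        if (i != j)
          expect_identical(link_code_between(m, p[i], p[j]),
                           link_code_between(m, i, j))
  }
})

test_that("reflections, rotations and residual symmetries are classified", {
  s <- classify_symmetries(test_motif("AAC"))
  expect_identical(s$reflection_classes, list(2:3))
  expect_identical(s$sym_lists[[2]], 3L)
  expect_identical(s$sym_lists[[3]], 2L)
  expect_length(s$rotation_cycles, 0L)
  expect_length(s$residual, 0L)

  s <- classify_symmetries(test_motif("AaA"))
  expect_length(s$rotation_cycles, 1L)
  expect_identical(sort(s$rotation_cycles[[1]]$cycle), 1:3)
  expect_identical(s$rotation_cycles[[1]]$first, 1L)
  expect_identical(sort(s$sym_lists[[1]]), 2:3)
  expect_identical(s$sym_lists[[2]], 1L)
  expect_identical(s$sym_lists[[3]], 1L)
  expect_length(s$residual, 0L)

  # undirected 4-cycle: |Aut| = 8; the two swap pairs {1,3} and {2,4} are
  # claimed as reflections (claimed before rotations), the remaining four
  # automorphisms (rotations by one step and the edge reflections) are
  # residual and handled by canonical-form duplicate elimination
  s <- classify_symmetries(test_motif("X0XX0X"))
  expect_identical(s$reflection_classes, list(c(1L, 3L), c(2L, 4L)))
  expect_length(s$rotation_cycles, 0L)
  expect_length(s$residual, 4L)

  # asymmetric motif: nothing to classify
  s <- classify_symmetries(test_motif("ABC"))
  expect_identical(lengths(s$sym_lists), rep(0L, 3L))
})

test_that("residual duplicate elimination canonicalizes under the full group", {
  m <- test_motif("X0XX0X")
  auts <- automorphisms(m)
  a <- submotif:::canonical_instance_key(c("a", "b", "c", "d"), auts)
  b <- submotif:::canonical_instance_key(c("b", "a", "d", "c"), auts)
  expect_identical(a, b)  # same 4-cycle traversed from the other end
  m3 <- test_motif("XXX")
  auts3 <- automorphisms(m3)
  keys <- apply(rbind(c("x", "y", "z"), c("z", "x", "y"), c("y", "z", "x"),
                      c("z", "y", "x"), c("x", "z", "y"), c("y", "x", "z")),
                1L, submotif:::canonical_instance_key, auts = auts3)
  expect_length(unique(keys), 1L)
  # asymmetric motif: all tuples distinct
  autsABC <- automorphisms(test_motif("ABC"))
  expect_false(identical(
    submotif:::canonical_instance_key(c("x", "y", "z"), autsABC),
    submotif:::canonical_instance_key(c("y", "x", "z"), autsABC)))
})
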