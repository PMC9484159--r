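# Sum-formula and Lewis realizations.

test_that("sf-instance validation", {
  f23 <- builtin_fixture("eq23")
  M <- rbind(X = c(2, 0, 1), Y = c(0, 2, 1), Z = c(1, 1, 1))
  expect_true(validate_sf_instance(f23$S, M)$valid)
  # a single strictly positive row is an instance with one atom type
  expect_true(validate_sf_instance(f23$S, rbind(c(1, 1, 1)))$valid)
  # zero column is refused with a diagnostic naming the species
  bad <- validate_sf_instance(f23$S, rbind(c(1, 1, 0)))
  expect_false(bad$valid)
  expect_match(bad$problems, "zero column", all = FALSE)
  # unbalanced matrix names the reaction
  ub <- validate_sf_instance(f23$S, rbind(c(1, 1, 2)))
  expect_match(ub$problems, "r1", all = FALSE)
})

test_that("sf-realization requires spanning the left kernel", {
  f23 <- builtin_fixture("eq23")
  M <- rbind(c(2, 0, 1), c(0, 2, 1), c(1, 1, 1))
  expect_true(validate_sf_realization(f23$S, M))
  # mm-representation is always a realization (conservative case)
  f26 <- builtin_fixture("eq26")
  expect_true(validate_sf_realization(f26$S, mm_representation(f26$S)))
  # the reduced representation U=V=W=D on eq26 is an instance, not a realization
  Ared <- rbind(D = c(1, 1, 1, 2, 2, 3))
  expect_true(validate_sf_instance(f26$S, Ared)$valid)
  expect_false(validate_sf_realization(f26$S, Ared))
})

test_that("default realization and sum formula strings", {
  f23 <- builtin_fixture("eq23")
  A <- default_sf_realization(f23$S)
  expect_setequal_rows(A, rbind(c(2, 0, 1), c(0, 2, 1), c(1, 1, 1)))
  AX <- rbind(X = c(2, 0, 1), Z = c(1, 1, 1))
  expect_identical(sum_formula(AX, 1), "X2Z")
  expect_identical(sum_formula(AX, 3), "XZ")
  expect_error(sum_formula(rbind(X = c(0, 1)), 1), "zero column")
  # monomer/dimer/trimer formulas on the extended Fig-3 system
  f27 <- builtin_fixture("eq26_27")
  A27 <- default_sf_realization(f27$S)
  expect_identical(sum_formula(A27, "U"), "M1")
  expect_identical(sum_formula(A27, "X"), "M12")
  expect_identical(sum_formula(A27, "Z"), "M13")
  expect_error(default_sf_realization(builtin_fixture("eq16")$S))
})

test_that("inequivalent realizations", {
  f23 <- builtin_fixture("eq23")
  out <- inequivalent_sf_realizations(f23$S, count = 3)
  expect_length(out, 3L)
  for (A in out) expect_true(validate_sf_realization(f23$S, A))
  for (i in seq_along(out)) {
    for (j in seq_len(i - 1)) {
      expect_false(chemlike:::.sf_equivalent(out[[i]], out[[j]]))
    }
  }
  # one-dimensional kernel: all realizations equivalent
  f27 <- builtin_fixture("eq26_27")
  expect_error(inequivalent_sf_realizations(f27$S, count = 2), "equivalent")
  expect_length(inequivalent_sf_realizations(f27$S, count = 1), 1L)
})

test_that("cycle structural formulas: degrees, connectivity, loops", {
  g1 <- cycle_structural_formula(c(a = 1))
  expect_identical(length(g1$colors), 1L)
  expect_identical(unname(g1$adj[1, 1]), 1)  # one loop, degree 2
  g3 <- cycle_structural_formula(c(X = 2, Z = 1))
  expect_identical(sort(g3$colors), c("X", "X", "Z"))
  expect_true(all(multigraph_degrees(g3) == 2))
  expect_true(multigraph_connected(g3))
  # k = 2: valency 4 via one extra loop per vertex
  g4 <- cycle_structural_formula(c(X = 2, Z = 1), k = 2)
  expect_true(all(multigraph_degrees(g4) == 4))
  # exhaustive small check: all formulas with <= 8 atoms over two colours
  for (na in 0:4) {
    for (nb in 0:4) {
      if (na + nb == 0) next
      g <- cycle_structural_formula(c(a = na, b = nb))
      expect_true(all(multigraph_degrees(g) == 2))
      expect_true(multigraph_connected(g))
      expect_identical(sum(g$colors == "a"), na)
    }
  }
})

test_that("multigraph isomorphism distinguishes structure, not labels", {
  c1 <- cycle_structural_formula(c(a = 2, b = 1))
  c2 <- cycle_structural_formula(c(b = 1, a = 2))
  expect_true(multigraph_isomorphic(c1, c2))
  # a relabelled copy is isomorphic
  perm <- c(3, 1, 2)
  c3 <- multigraph(c1$colors[perm], c1$adj[perm, perm], c1$val)
  expect_true(multigraph_isomorphic(c1, c3))
  # double-edge variant is not isomorphic to the plain cycle
  g <- cycle_structural_formula(c(a = 4), k = 2)
  h <- g
  h$adj[1, 1] <- h$adj[1, 1] - 1
  h$adj[2, 2] <- h$adj[2, 2] - 1
  h$adj[1, 2] <- h$adj[1, 2] + 2
  h$adj[2, 1] <- h$adj[1, 2]
  expect_false(multigraph_isomorphic(g, h))
  expect_true(all(multigraph_degrees(h) == 4))
})

test_that("Lewis realization of conservative networks validates", {
  f23 <- builtin_fixture("eq23")
  L <- lewis_realization(f23$S)
  expect_true(validate_lewis_realization(f23$network, L)$valid)
  expect_length(L$graphs, 3L)
  expect_error(lewis_realization(builtin_fixture("eq16")$S))
  # single reaction A -> B gives two one-vertex loop graphs
  ab <- parse_rxn("r: A -> B")
  Lab <- lewis_realization(ab)
  expect_true(all(vapply(Lab$graphs, function(g) length(g$colors), integer(1)) == 1L))
})

test_that("edge counts are conserved across reactions", {
  for (fx in c("eq23", "eq26", "eq26_27", "eq18", "eq19")) {
    f <- builtin_fixture(fx)
    L <- lewis_realization(f$S)
    edges <- vapply(rownames(f$S),
                    function(x) multigraph_edge_count(L$graphs[[x]]), numeric(1))
    expect_true(all(t(f$S) %*% edges == 0))
  }
})

test_that("injective Lewis realization separates obligatory isomers", {
  f27 <- builtin_fixture("eq26_27")
  IL <- injective_lewis_realization(f27$S)
  expect_true(validate_lewis_realization(f27$network, IL)$valid)
  gs <- IL$graphs
  expect_length(gs, 6L)
  for (g in gs) expect_true(all(multigraph_degrees(g) == 4))
  for (i in seq_along(gs)) {
    for (j in seq_len(i - 1)) {
      expect_false(multigraph_isomorphic(gs[[i]], gs[[j]]))
    }
  }
  # isomers share colour counts even though their graphs differ
  counts <- function(g) table(factor(g$colors, levels = rownames(IL$A)))
  expect_identical(counts(gs[["U"]]), counts(gs[["V"]]))
  expect_identical(counts(gs[["X"]]), counts(gs[["Y"]]))
  # no-isomer network: base cycles suffice, still pairwise distinct
  f18 <- builtin_fixture("eq18")
  IL18 <- injective_lewis_realization(f18$S)
  g18 <- IL18$graphs
  for (i in seq_along(g18)) {
    for (j in seq_len(i - 1)) {
      expect_false(multigraph_isomorphic(g18[[i]], g18[[j]]))
    }
  }
})

test_that("realizations agree with isomer structure (column equality)", {
  f27 <- builtin_fixture("eq26_27")
  A <- default_sf_realization(f27$S)
  cls <- isomer_classes(f27$S)$classes
  for (cl in cls) {
    for (x in cl) expect_identical(A[, x, drop = FALSE][, 1], A[, cl[1], drop = FALSE][, 1])
  }
  # non-isomers differ in some row
  expect_false(all(A[, "U"] == A[, "X"]))
})

test_that("graph export formats", {
  g <- cycle_structural_formula(c(X = 2, Z = 1))
  path <- tempfile(fileext = ".graphml")
  write_graphml(g, path)
  txt <- readLines(path)
  expect_match(txt, "graphml", all = FALSE)
  expect_identical(sum(grepl("<edge ", txt)), 3L)   # a 3-cycle
  expect_identical(sum(grepl("<node ", txt)), 3L)
  el <- format_edgelist(g)
  expect_length(el, 3L)
})
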