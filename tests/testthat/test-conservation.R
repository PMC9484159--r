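# Conservation laws, MCLs, isomers, oligomers.

test_that("kernel dimensions of the worked examples", {
  expect_identical(nrow(left_kernel_basis(builtin_fixture("eq18")$S)), 2L)
  expect_identical(nrow(left_kernel_basis(builtin_fixture("eq19")$S)), 3L)
  expect_identical(nrow(left_kernel_basis(builtin_fixture("eq26")$S)), 3L)
  expect_identical(nrow(left_kernel_basis(builtin_fixture("eq26_27")$S)), 1L)
  B <- left_kernel_basis(builtin_fixture("eq23")$S)
  expect_true(all(t(builtin_fixture("eq23")$S) %*% t(B) == 0))
})

test_that("conservativity returns exactly one verified certificate", {
  f16 <- builtin_fixture("eq16")
  cert <- conservativity(f16$S)
  expect_false(cert$conservative)
  sv <- f16$S %*% cert$v
  expect_true(all(sv >= 0) && any(sv > 0))
  f18 <- builtin_fixture("eq18")
  cert18 <- conservativity(f18$S)
  expect_true(cert18$conservative)
  expect_true(all(cert18$m > 0))
  expect_true(all(t(f18$S) %*% cert18$m == 0))
  f27 <- builtin_fixture("eq26_27")
  cert27 <- conservativity(f27$S)
  expect_true(cert27$conservative)
  expect_true(all(t(f27$S) %*% cert27$m == 0))
})

test_that("Stiemke exclusivity on random matrices", {
  set.seed(23)
  for (trial in 1:60) {
    S <- random_small_matrix(4, 6)
    cert <- conservativity(S)
    if (cert$conservative) {
      expect_true(all(cert$m > 0))
      expect_true(all(t(S) %*% cert$m == 0))
    } else {
      sv <- S %*% cert$v
      expect_true(all(sv >= 0) && any(sv > 0))
      # no positive law can coexist: m^T S v = 0 but m^T (Sv) > 0 for m >> 0
      B <- left_kernel_basis(S)
      if (nrow(B)) {
        # any nonneg combination of kernel vectors that is >> 0 is impossible:
        # check that the nonneg left-kernel cone misses some species
        rays <- chemlike:::cone_extreme_rays(t(S))
        expect_true(any(colSums(rays) == 0) || nrow(rays) == 0)
      }
    }
  }
})

test_that("minimal MCLs of the abstract dimerization A+B->2C", {
  f23 <- builtin_fixture("eq23")
  M <- minimal_mcls(f23$S)
  expect_false(M$truncated)
  expect_setequal_rows(bare(M$mcls), rbind(c(2, 0, 1), c(0, 2, 1), c(1, 1, 1)))
  # single reaction A -> B
  M2 <- minimal_mcls(matrix(c(-1, 1), ncol = 1, dimnames = list(c("A", "B"), "r")))
  expect_identical(bare(M2$mcls), rbind(c(1, 1)))
  # toluene hydroalkylation: the four cross moiety laws are all minimal
  f19 <- builtin_fixture("eq19")
  M19 <- minimal_mcls(f19$S)$mcls
  for (y in list(c(1, 0, 1, 0), c(1, 0, 0, 1), c(0, 1, 1, 0), c(0, 1, 0, 1))) {
    expect_true(any(apply(M19, 1, function(r) all(r == y))))
  }
})

test_that("minimal MCLs agree with the brute-force oracle", {
  set.seed(31)
  for (trial in 1:25) {
    S <- random_small_matrix(sample(2:5, 1), sample(1:4, 1))
    got <- minimal_mcls(S)$mcls
    want <- oracle_minimal_mcls(S, B = 4)
    # oracle only sees entries <= 4: compare the bounded part
    got_b <- got[apply(got, 1, max) <= 4, , drop = FALSE]
    expect_setequal_rows(got_b, want)
  }
})

test_that("every MCL decomposes into minimal ones (generation property)", {
  set.seed(37)
  for (fx in c("eq23", "eq19", "eq26")) {
    M <- minimal_mcls(builtin_fixture(fx)$S)$mcls
    for (trial in 1:10) {
      y <- as.vector(t(M) %*% sample(0:2, nrow(M), replace = TRUE))
      expect_true(oracle_decomposes(y, M))
    }
  }
})

test_that("mm-representation rows span the left kernel", {
  f23 <- builtin_fixture("eq23")
  M <- mm_representation(f23$S)
  expect_identical(chemlike:::int_rank(M), 2L)
  expect_identical(nrow(M), 3L)
  f27 <- builtin_fixture("eq26_27")
  M27 <- mm_representation(f27$S)
  expect_identical(bare(M27), rbind(c(1, 1, 1, 2, 2, 3)))
  f26 <- builtin_fixture("eq26")
  M26 <- mm_representation(f26$S)
  expect_identical(nrow(M26), 3L)
  # rows correspond to the U=A, V=B, W=C composition of Fig-3 type
  expect_setequal_rows(M26, rbind(c(1, 0, 0, 1, 1, 1),
                                  c(0, 1, 0, 1, 0, 1),
                                  c(0, 0, 1, 0, 1, 1)))
  # non-conservative networks are refused with the certificate attached
  err <- tryCatch(mm_representation(builtin_fixture("eq16")$S),
                  error = function(e) e)
  expect_s3_class(err, "not_conservative")
  expect_false(err$certificate$conservative)
})

test_that("obligatory isomer classes", {
  f27 <- builtin_fixture("eq26_27")
  cls <- isomer_classes(f27$S)$classes
  expect_identical(cls, list(c("U", "V", "W"), c("X", "Y"), "Z"))
  # basic system alone: all singletons
  cls26 <- isomer_classes(builtin_fixture("eq26")$S)$classes
  expect_true(all(lengths(cls26) == 1L))
  # kernel-column criterion coincides with solvability of S v = e_y - e_x
  S <- f27$S
  sp <- rownames(S)
  for (i in seq_along(sp)) {
    for (j in seq_along(sp)[-seq_len(i)]) {
      linked <- !is.null(net_isomerization_flow(S, sp[i], sp[j]))
      same_class <- any(vapply(cls, function(cl) all(c(sp[i], sp[j]) %in% cl),
                               logical(1)))
      expect_identical(linked, same_class)
    }
  }
})

test_that("net isomerization flows verify exactly", {
  f27 <- builtin_fixture("eq26_27")
  nf <- net_isomerization_flow(f27$S, "X", "Y")
  expect_false(is.null(nf))
  sv <- as.vector(f27$S %*% nf$v)
  expect_identical(sv, nf$k * (as.numeric(rownames(f27$S) == "Y") -
                               as.numeric(rownames(f27$S) == "X")))
  expect_null(net_isomerization_flow(builtin_fixture("eq26")$S, "X", "Y"))
  same <- net_isomerization_flow(f27$S, "X", "X")
  expect_identical(same$k, 0)
})

test_that("oligomer ratios from the monomer/dimer/trimer structure", {
  f27 <- builtin_fixture("eq26_27")
  expect_identical(oligomer_ratio(f27$S, "U", "Z"), c(p = 3, q = 1))
  expect_identical(oligomer_ratio(f27$S, "X", "Z"), c(p = 3, q = 2))
  expect_identical(oligomer_ratio(f27$S, "X", "Y"), c(p = 1, q = 1))
  # eq26: U and X have non-proportional kernel coordinates
  expect_null(oligomer_ratio(builtin_fixture("eq26")$S, "U", "X"))
})

test_that("atom-vector validation", {
  f20 <- builtin_fixture("eq20")
  res <- check_conservation_vectors(f20$S, f20$atom_vectors)
  expect_true(all(res$pass))
  expect_identical(res$n_pass, 4L)
  f18 <- builtin_fixture("eq18")
  res18 <- check_conservation_vectors(f18$S, f18$atom_vectors)
  expect_true(all(res18$pass))
  expect_identical(res18$rank, 2L)  # three atom vectors, rank only 2
  bad <- check_conservation_vectors(f18$S, rbind(c(1, 0, 0)))
  expect_false(bad$pass[1])
})

test_that("transport reactions violate every positive law", {
  f18 <- builtin_fixture("eq18")
  m <- conservativity(f18$S)$m
  open_net <- parse_rxn(c("r1: MgCO3 -> MgO + CO2", "imp: 0 -> MgCO3"))
  S <- stoichiometric_matrix(open_net)
  expect_true(all((t(S) %*% m[rownames(S)])[, 1]["imp"] != 0))
})
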