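# Energies, futile cycles, soundness decisions. The worked examples pin the
# published numbers; the property blocks check the alternative-theorem
# exclusivity and the oracle equivalence of the cycle enumeration.

test_that("Hess's law on the two-reaction universe and round trips", {
  f16 <- builtin_fixture("eq16")
  g <- hess_energies(f16$S, f16$G)
  expect_identical(unname(g), c(-2, 0))
  expect_identical(unname(hess_energies(f16$S, rep(0, 4))), c(0, 0))
  # recovery: any G with t(S) G = g; residual must vanish exactly
  G2 <- recover_molecular_energies(f16$S, g)
  expect_identical(unname(hess_energies(f16$S, G2)), unname(g))
  expect_identical(unname(recover_molecular_energies(f16$S, c(0, 0))), rep(0, 4))
})

test_that("thermodynamic test is exact orthogonality against the kernel", {
  f10 <- builtin_fixture("example10")
  expect_false(is_thermodynamic(f10$S, f10$g))          # parallel flows -2 vs -1
  expect_true(is_thermodynamic(f10$S, c(1, -1, -3, -2)))  # g3 = -2 repairs it
  expect_null(recover_molecular_energies(f10$S, f10$g))   # Hess fails too
  # trivial kernel: every g is thermodynamic
  expect_true(is_thermodynamic(builtin_fixture("eq23")$S, 5))
})

test_that("reverse-pair energies must cancel", {
  f10 <- builtin_fixture("example10")
  expect_identical(nrow(reverse_pair_violations(f10$network, f10$g)), 0L)
  v <- reverse_pair_violations(f10$network, c(1, -2, 0, 0))
  expect_identical(v$r, "r1")
  expect_identical(v$sum, -1)
  # any witness from the soundness decision satisfies Lemma-5 antisymmetry
  f15 <- builtin_fixture("example15")
  rep <- thermodynamic_soundness(f15$S, irr = f15$irr)
  expect_true(rep$sound)
  expect_identical(nrow(reverse_pair_violations(f15$network, rep$witness_g)), 0L)
})

test_that("futile cycle enumeration matches the published examples", {
  f10 <- builtin_fixture("example10")
  fc10 <- futile_cycles(f10$network)
  expect_identical(bare(fc10$cycles), rbind(c(1, 1, 0, 0)))
  expect_true(fc10$trivial[1])    # the expanded reversible pair
  f15 <- builtin_fixture("example15")
  fc15 <- futile_cycles(f15$network)
  expect_setequal_rows(fc15$cycles, rbind(c(1, 1, 0, 0), c(1, 0, 1, 1)))
  f2 <- builtin_fixture("fig2_substrate_cycle")
  fc2 <- futile_cycles(f2$network)
  expect_identical(nrow(fc2$cycles), 3L)
  nontrivial <- fc2$cycles[!fc2$trivial, , drop = FALSE]
  expect_identical(bare(nontrivial), rbind(c(1, 0, 1, 1, 0, 1)))
})

test_that("futile cycle enumeration agrees with the brute-force oracle", {
  set.seed(13)
  for (trial in 1:30) {
    S <- random_small_matrix(sample(2:4, 1), sample(2:6, 1))
    expect_true(oracle_check_futile(S, futile_cycles(S)$cycles, B = 3))
  }
  # literal equality on unit-coefficient networks where rays stay small
  for (trial in 1:10) {
    S <- random_small_matrix(3, 4, max_abs = 1)
    got <- futile_cycles(S)$cycles
    if (nrow(got) && max(got) <= 2) {
      W <- oracle_bounded_cycles(S, B = 2)
      # every ray must be among the bounded kernel flows
      expect_true(all(apply(got, 1, function(v) {
        any(apply(W, 1, function(w) all(w == v)))
      })))
    }
  }
})

test_that("perpetuum mobile search", {
  f9 <- builtin_fixture("eq9")
  pm <- perpetuum_mobile(f9$S, c(-1, -1, -1, -1))
  expect_identical(unname(pm), c(1, 1, 1, 1))
  f10 <- builtin_fixture("example10")
  expect_null(perpetuum_mobile(f10$S, f10$g))  # only cycle has zero energy
  # thermodynamic (S, g) never has one
  f16 <- builtin_fixture("eq16")
  expect_null(perpetuum_mobile(f16$S, hess_energies(f16$S, f16$G)))
})

test_that("lax soundness on the worked examples", {
  f9 <- builtin_fixture("eq9")
  rep9 <- thermodynamic_soundness(f9$S, irr = f9$irr)
  expect_false(rep9$sound)
  expect_identical(unname(rep9$certificate), c(1, 1, 1, 1))
  # fully reversible networks are always sound
  revnet <- parse_rxn(c("r1: A <=> B", "r2: B <=> C", "r3: C <=> A"))
  expect_true(thermodynamic_soundness(revnet)$sound)
  f2 <- builtin_fixture("fig2_substrate_cycle")
  rep2 <- thermodynamic_soundness(f2$S, irr = f2$irr)
  expect_true(rep2$sound)
  expect_true(all(rep2$witness_g[f2$irr] < 0))
  expect_true(is_thermodynamic(f2$S, rep2$witness_g))
})

test_that("strict soundness on the worked examples", {
  f2 <- builtin_fixture("fig2_substrate_cycle")
  rep2 <- strict_soundness(f2$S, irr = f2$irr)
  expect_false(rep2$sound)
  expect_identical(unname(rep2$certificate), c(1, 0, 1, 1, 0, 1))
  f15 <- builtin_fixture("example15")
  rep15 <- strict_soundness(f15$S, irr = f15$irr)
  expect_false(rep15$sound)
  expect_true(any(rep15$certificate[f15$irr] > 0))
  ab <- parse_rxn("r: A <=> B")
  for (gam in c(2, 1000)) {
    repab <- strict_soundness(ab, gamma = gam)
    expect_true(repab$sound)
    expect_true(all(abs(repab$witness_g) <= 1))
  }
  # strictly sound with a non-empty irreversible set: witness respects gamma
  f26 <- builtin_fixture("eq26")
  rep26 <- strict_soundness(f26$S, irr = f26$irr, gamma = 50)
  expect_true(rep26$sound)
  expect_true(all(rep26$witness_g <= -50))
  expect_true(is_thermodynamic(f26$S, rep26$witness_g))
})

test_that("exactly one branch of the alternative on random matrices", {
  set.seed(99)
  for (trial in 1:60) {
    S <- random_small_matrix(4, 6)
    m <- ncol(S)
    irr <- sample(seq_len(m), sample(0:m, 1))
    lax <- thermodynamic_soundness(S, irr = colnames(S)[irr])
    if (lax$sound) {
      expect_true(is_thermodynamic(S, lax$witness_g))
      expect_true(all(lax$witness_g[irr] < 0))
      expect_null(lax$certificate)
    } else {
      v <- lax$certificate
      expect_true(all(S %*% v == 0) && all(v >= 0) && any(v > 0))
      expect_true(all(which(v > 0) %in% irr))
      expect_null(lax$witness_g)
    }
    strict <- strict_soundness(S, irr = colnames(S)[irr], gamma = 10)
    if (strict$sound) {
      expect_true(is_thermodynamic(S, strict$witness_g))
      expect_true(all(strict$witness_g[irr] <= -10))
      expect_true(all(abs(strict$witness_g[setdiff(seq_len(m), irr)]) <= 1))
    } else {
      v <- strict$certificate
      expect_true(all(S %*% v == 0))
      expect_true(all(v[irr] >= 0) && any(v[irr] > 0))
    }
    # strict sound implies lax sound
    if (strict$sound) expect_true(lax$sound)
  }
})

test_that("reversible completion preserves thermodynamics", {
  net <- parse_rxn("r1: A -> B")
  rc <- reversible_completion(net, g = c(-1))
  expect_identical(reaction_ids(rc$network), c("r1", "r1__rev"))
  expect_identical(unname(rc$g), c(-1, 1))
  expect_true(is_thermodynamic(rc$network, rc$g))
  # completion of a reversible network adds nothing
  ab <- parse_rxn("r: A <=> B")
  expect_length(reversible_completion(ab)$network$reactions, 2L)
  # non-thermodynamic input is rejected
  f10 <- builtin_fixture("example10")
  expect_error(reversible_completion(f10$network, f10$g), "not thermodynamic")
  # completed eq26 is thermodynamic for any Hess-law energies
  f26 <- builtin_fixture("eq26")
  G <- c(1, 2, 3, 4, 5, 6)
  rc26 <- reversible_completion(f26$network, hess_energies(f26$S, G))
  expect_true(is_thermodynamic(rc26$network, rc26$g))
})

test_that("nonneg_equivalent_flow reroutes negative entries", {
  ab <- parse_rxn("r: A <=> B")
  vt <- nonneg_equivalent_flow(ab, c(1, -1))
  expect_identical(unname(vt), c(2, 0))
  S <- stoichiometric_matrix(ab)
  expect_identical(as.vector(S %*% vt), as.vector(S %*% c(1, -1)))
  # v >= 0 passes through unchanged
  expect_identical(unname(nonneg_equivalent_flow(ab, c(2, 1))), c(2, 1))
  # energy preserved for antisymmetric energies
  g <- c(3, -3)
  expect_identical(sum(g * nonneg_equivalent_flow(ab, c(4, -2), g = g)),
                   sum(g * c(4, -2)))
  # missing reverse is an error
  f9 <- builtin_fixture("eq9")
  expect_error(nonneg_equivalent_flow(f9$network, c(-1, 0, 0, 0)), "no reverse")
})

test_that("soundness is hereditary under reaction deletion", {
  f2 <- builtin_fixture("fig2_substrate_cycle")
  ids <- reaction_ids(f2$network)
  for (drop in ids) {
    keep <- setdiff(ids, drop)
    S <- f2$S[, keep, drop = FALSE]
    expect_true(thermodynamic_soundness(S, irr = intersect(f2$irr, keep))$sound)
  }
})
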