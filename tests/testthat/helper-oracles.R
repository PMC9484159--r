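# Brute-force oracles, independent of the package's cone/Hilbert machinery.
# They enumerate bounded integer vectors directly and are only usable at toy
# sizes, which is exactly what makes them trustworthy reference points.

# all non-negative integer vectors of length n with entries <= B
enumerate_grid <- function(n, B) {
  if (n == 0) return(matrix(0, 1, 0))
  as.matrix(do.call(expand.grid, rep(list(0:B), n)))
}

# all bounded non-trivial flows in the futile cone (entries <= B)
oracle_bounded_cycles <- function(S, B = 3) {
  V <- enumerate_grid(ncol(S), B)
  keep <- rowSums(V) > 0 & apply(V, 1, function(v) all(S %*% v == 0))
  V[keep, , drop = FALSE]
}

# Cross-check an extreme-ray set against exhaustive bounded enumeration.
# The bound prevents literal set equality (rays may have large entries), so
# the check is bidirectional-with-bounds:
#  (1) every reported ray lies in the cone, is coprime, and no bounded cone
#      element has support strictly inside it (support-minimality witness);
#  (2) every support-minimal bounded cone element contains the support of
#      some reported ray (completeness: no minimal region was missed).
oracle_check_futile <- function(S, cycles, B = 3) {
  W <- oracle_bounded_cycles(S, B)
  wsupp <- W != 0
  for (i in seq_len(nrow(cycles))) {
    v <- cycles[i, ]
    if (!all(S %*% v == 0) || any(v < 0) || all(v == 0)) return(FALSE)
    if (chemlike:::gcd_vec(v) != 1) return(FALSE)
    s <- v != 0
    if (nrow(W)) {
      strict_inside <- apply(wsupp, 1, function(w) all(w <= s) && any(w < s))
      if (any(strict_inside)) return(FALSE)
    }
  }
  if (nrow(W)) {
    minimal <- vapply(seq_len(nrow(W)), function(i) {
      !any(vapply(seq_len(nrow(W)), function(j) {
        i != j && all(wsupp[j, ] <= wsupp[i, ]) && any(wsupp[j, ] < wsupp[i, ])
      }, logical(1)))
    }, logical(1))
    csupp <- cycles != 0
    for (i in which(minimal)) {
      covered <- nrow(cycles) > 0 && any(apply(csupp, 1, function(cs) {
        all(cs <= wsupp[i, ])
      }))
      if (!covered) return(FALSE)
    }
  } else if (nrow(cycles) > 0) {
    # no bounded cycles at all: reported rays must still verify (done above)
  }
  TRUE
}

# componentwise-minimal elements of {y >= 0 integer : y^T S = 0} \ {0},
# exhaustively up to entry bound B
oracle_minimal_mcls <- function(S, B = 4) {
  Y <- enumerate_grid(nrow(S), B)
  keep <- rowSums(Y) > 0 & apply(Y, 1, function(y) all(t(S) %*% y == 0))
  Y <- Y[keep, , drop = FALSE]
  if (nrow(Y) == 0) return(Y)
  minimal <- vapply(seq_len(nrow(Y)), function(i) {
    !any(vapply(seq_len(nrow(Y)), function(j) {
      i != j && all(Y[j, ] <= Y[i, ]) && any(Y[j, ] < Y[i, ])
    }, logical(1)))
  }, logical(1))
  Y <- Y[minimal, , drop = FALSE]
  Y[do.call(order, as.data.frame(Y)), , drop = FALSE]
}

# does y decompose as a non-negative integer combination of the rows of M?
oracle_decomposes <- function(y, M) {
  if (all(y == 0)) return(TRUE)
  for (i in seq_len(nrow(M))) {
    if (all(M[i, ] <= y)) {
      if (oracle_decomposes(y - M[i, ], M)) return(TRUE)
    }
  }
  FALSE
}

# random small integer stoichiometric-like matrix
random_small_matrix <- function(n_species = 4, n_reactions = 6, max_abs = 2) {
  matrix(as.numeric(sample(seq(-max_abs, max_abs), n_species * n_reactions,
                           replace = TRUE)),
         nrow = n_species,
         dimnames = list(paste0("X", seq_len(n_species)),
                         paste0("r", seq_len(n_reactions))))
}

expect_setequal_rows <- function(A, B) {
  key <- function(M) {
    M <- rbind(M)
    if (nrow(M) == 0) return(character(0))
    unname(sort(apply(M, 1, paste, collapse = ",")))
  }
  expect_identical(key(A), key(B))
}

# strip names/attrs for exact numeric matrix comparison
bare <- function(M) {
  M <- rbind(M)
  matrix(as.numeric(M), nrow = nrow(M))
}
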