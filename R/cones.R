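# Polyhedral machinery for s-cones (a linear subspace intersected with the
# non-negative orthant). Extreme rays of such cones coincide with their
# support-minimal vectors, which makes the double description update cheap:
# after every equality cut it suffices to discard rays whose support strictly
# contains the support of another ray.

# Extreme rays of {v >= 0 : E v = 0}, E an integer matrix (one equality per
# row). Rays are returned as rows of an integer matrix, content-reduced to
# coprime entries, ordered lexicographically by support and then by entries.
# `cap` guards against combinatorial explosion; when hit, computation stops
# and the attribute "truncated" is set on the result.
cone_extreme_rays <- function(E, cap = 100000L) {
  stopifnot_integer_matrix(E, "equality matrix")
  n <- ncol(E)
  R <- diag(1, n)
  truncated <- FALSE
  todo <- seq_len(nrow(E))
  while (length(todo) > 0) {
    # dynamic row order: cut with the cheapest positive x negative product
    SR <- R %*% t(E[todo, , drop = FALSE])
    check_exact_range(SR, "ray enumeration")
    costs <- vapply(seq_along(todo), function(k) {
      sum(SR[, k] > 0) * sum(SR[, k] < 0)
    }, numeric(1))
    k <- which.min(costs)
    s <- SR[, k]
    todo <- todo[-k]
    zero <- R[s == 0, , drop = FALSE]
    ip <- which(s > 0)
    im <- which(s < 0)
    if (length(ip) * length(im) + nrow(zero) > cap) {
      truncated <- TRUE
      R <- zero
      break
    }
    if (length(ip) > 0 && length(im) > 0) {
      pi <- rep(ip, each = length(im))
      qi <- rep(im, times = length(ip))
      combos <- s[pi] * R[qi, , drop = FALSE] - s[qi] * R[pi, , drop = FALSE]
      check_exact_range(combos, "ray combination")
      R <- rbind(zero, combos)
    } else {
      R <- zero
    }
    R <- .filter_support_minimal(R)
    # content-reduce the survivors (also canonicalizes same-support multiples)
    for (i in seq_len(nrow(R))) {
      g <- gcd_vec(R[i, ])
      if (g > 1) R[i, ] <- R[i, ] / g
    }
    if (nrow(R) == 0) break
  }
  R <- .order_rays(R)
  attr(R, "truncated") <- truncated
  R
}

# Keep one representative per support; drop rays whose support strictly
# contains another ray's support. Valid for s-cones only.
.filter_support_minimal <- function(R) {
  if (nrow(R) <= 1) return(R)
  supp <- R != 0
  keys <- apply(supp, 1, function(z) paste(which(z), collapse = ","))
  R <- R[!duplicated(keys), , drop = FALSE]
  supp <- R != 0
  sizes <- rowSums(supp)
  ord <- order(sizes)
  R <- R[ord, , drop = FALSE]
  supp <- supp[ord, , drop = FALSE]
  sizes <- sizes[ord]
  keep <- rep(TRUE, nrow(R))
  for (i in seq_len(nrow(R))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (sizes[j] < sizes[i] && all(supp[j, ] <= supp[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  R[keep, , drop = FALSE]
}

# ascending lexicographic order by entries (deterministic output contract)
.order_rays <- function(R) {
  if (nrow(R) <= 1) return(R)
  ord <- do.call(order, lapply(seq_len(ncol(R)), function(j) R[, j]))
  R[ord, , drop = FALSE]
}

# Minimal (componentwise) non-negative non-zero integer solutions of the
# homogeneous system A y = 0: the Contejean-Devie completion procedure.
# Guaranteed to terminate with the full set of minimal solutions; `cap`
# bounds the explored frontier for pathological inputs (sets "truncated").
diophantine_min_solutions <- function(A, cap = 200000L) {
  stopifnot_integer_matrix(A, "coefficient matrix")
  n <- ncol(A)
  cols <- lapply(seq_len(n), function(j) A[, j])
  frontier <- lapply(seq_len(n), function(j) {
    y <- numeric(n); y[j] <- 1
    list(y = y, d = cols[[j]])
  })
  sols <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  truncated <- FALSE
  explored <- 0L
  dominated <- function(y) {
    for (s in sols) if (all(s >= 0) && all(s <= y)) return(TRUE)
    FALSE
  }
  while (length(frontier) > 0) {
    explored <- explored + length(frontier)
    if (explored > cap) { truncated <- TRUE; break }
    nxt <- list()
    for (node in frontier) {
      y <- node$y
      d <- node$d
      if (all(d == 0)) {
        if (!dominated(y)) sols[[length(sols) + 1L]] <- y
        next
      }
      for (j in seq_len(n)) {
        # Contejean-Devie descent condition: only step in directions that
        # reduce the defect in the scalar-product sense.
        if (sum(d * cols[[j]]) >= 0) next
        y2 <- y
        y2[j] <- y2[j] + 1
        key <- paste(y2, collapse = ",")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        if (dominated(y2)) next
        nxt[[length(nxt) + 1L]] <- list(y = y2, d = d + cols[[j]])
      }
    }
    frontier <- nxt
  }
  # final minimality sieve (solutions can be found before their dominators)
  keep <- rep(TRUE, length(sols))
  for (i in seq_along(sols)) {
    for (j in seq_along(sols)) {
      if (i == j || !keep[j]) next
      if (all(sols[[j]] <= sols[[i]]) && any(sols[[j]] < sols[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sols <- sols[keep]
  out <- if (length(sols)) do.call(rbind, sols) else matrix(0, 0, n)
  out <- .order_rays(out)
  attr(out, "truncated") <- truncated
  out
}

# Exact feasibility of {x : A x <= b} over the rationals by Fourier-Motzkin
# elimination, returning a rational solution list(num, den) or NULL.
# Row scaling keeps every derived constraint integral; the projection is
# exact, so feasibility is decided without tolerances. Intended for the small
# witness systems arising here (a handful of variables).
fm_solve <- function(A, b) {
  stopifnot_integer_matrix(A, "constraint matrix")
  if (any(b != round(b))) stop("b must be integer")
  n <- ncol(A)
  systems <- vector("list", n + 1L)
  systems[[1L]] <- cbind(A, b)
  cur <- systems[[1L]]
  for (v in seq_len(n)) {
    col <- cur[, 1L]
    zero <- cur[col == 0, -1L, drop = FALSE]
    pos <- cur[col > 0, , drop = FALSE]
    neg <- cur[col < 0, , drop = FALSE]
    if (nrow(pos) > 0 && nrow(neg) > 0) {
      combos <- matrix(0, nrow = nrow(pos) * nrow(neg), ncol = ncol(cur) - 1L)
      k <- 0L
      for (p in seq_len(nrow(pos))) {
        for (q in seq_len(nrow(neg))) {
          k <- k + 1L
          cp <- pos[p, 1L]
          cq <- -neg[q, 1L]
          row <- cq * pos[p, -1L] + cp * neg[q, -1L]
          check_exact_range(row, "Fourier-Motzkin")
          g <- gcd_vec(row)
          if (g > 1) row <- row / g
          combos[k, ] <- row
        }
      }
      nxt <- rbind(zero, combos)
    } else {
      nxt <- zero
    }
    nxt <- unique(nxt)
    systems[[v + 1L]] <- cbind(nxt)
    cur <- nxt
  }
  # after eliminating all variables only constant constraints 0 <= b remain
  if (nrow(cur) > 0 && any(cur[, 1L] < 0)) return(NULL)
  # back-substitute, last variable first
  x <- vector("list", n)
  for (v in rev(seq_len(n))) {
    sys <- systems[[v]]
    lo <- NULL
    hi <- NULL
    for (i in seq_len(nrow(sys))) {
      cv <- sys[i, 1L]
      if (cv == 0) next
      rest <- rat(sys[i, ncol(sys)])
      if (ncol(sys) > 2L) {
        for (w in seq.int(v + 1L, length.out = ncol(sys) - 2L)) {
          coef <- sys[i, 1L + (w - v)]
          if (coef != 0) rest <- rat_add(rest, rat_mul(rat(-coef), x[[w]]))
        }
      }
      bound <- rat_div(rest, rat(cv))
      if (cv > 0) {
        if (is.null(hi) || rat_cmp(bound, hi) < 0) hi <- bound
      } else {
        if (is.null(lo) || rat_cmp(bound, lo) > 0) lo <- bound
      }
    }
    x[[v]] <- if (is.null(lo) && is.null(hi)) {
      rat(0)
    } else if (is.null(lo)) {
      hi
    } else if (is.null(hi)) {
      lo
    } else {
      if (rat_cmp(lo, hi) > 0) stop("internal error: empty interval in back-substitution")
      rat_div(rat_add(lo, hi), rat(2))
    }
  }
  den <- 1
  for (v in seq_len(n)) den <- lcm2(den, x[[v]][2])
  num <- vapply(seq_len(n), function(v) x[[v]][1] * (den / x[[v]][2]), numeric(1))
  check_exact_range(num, "witness construction")
  list(num = num, den = den)
}
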