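# Exact integer linear algebra. All analysis functions in this package reduce
# to kernel computations, linear solves, and ray enumerations over the
# integers/rationals; floating point is never used where a certificate is at
# stake. Integers are carried in doubles and guarded against leaving the
# exactly-representable range.

.INT_GUARD <- 2^52

check_exact_range <- function(x, context = "intermediate value") {
  if (any(abs(x) > .INT_GUARD, na.rm = TRUE)) {
    stop("exact integer arithmetic overflow in ", context,
         "; input coefficients too large", call. = FALSE)
  }
  invisible(x)
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

gcd_vec <- function(v) {
  g <- 0
  for (x in v) {
    g <- gcd2(g, x)
    if (g == 1) break
  }
  g
}

lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  check_exact_range(abs(a / gcd2(a, b) * b), "lcm")
}

#' @noRd
stopifnot_integer_matrix <- function(M, what = "matrix") {
  if (!is.matrix(M) || !is.numeric(M)) stop(what, " must be a numeric matrix")
  if (any(!is.finite(M)) || any(M != round(M))) {
    stop(what, " must have finite integer entries")
  }
  invisible(M)
}

# Integer Gauss-Jordan elimination: rows are rescaled by positive integers
# only, so the row space is preserved exactly. Returns the reduced matrix,
# pivot columns, and rank. Each row is divided by its gcd after every update
# to keep growth in check.
int_gauss_jordan <- function(M) {
  M <- rbind(M)
  storage.mode(M) <- "double"
  n <- ncol(M)
  m <- nrow(M)
  pivots <- integer(0)
  prow <- 0L
  for (col in seq_len(n)) {
    if (prow >= m) break
    cand <- which(M[, col] != 0)
    cand <- cand[cand > prow]
    if (length(cand) == 0) next
    # smallest absolute pivot limits coefficient growth
    piv <- cand[which.min(abs(M[cand, col]))]
    prow <- prow + 1L
    if (piv != prow) M[c(piv, prow), ] <- M[c(prow, piv), ]
    if (M[prow, col] < 0) M[prow, ] <- -M[prow, ]
    p <- M[prow, col]
    for (i in seq_len(m)) {
      if (i == prow || M[i, col] == 0) next
      a <- M[i, col]
      M[i, ] <- p * M[i, ] - a * M[prow, ]
      check_exact_range(M[i, ], "elimination")
      g <- gcd_vec(M[i, ])
      if (g > 1) M[i, ] <- M[i, ] / g
    }
    g <- gcd_vec(M[prow, ])
    if (g > 1) M[prow, ] <- M[prow, ] / g
    pivots <- c(pivots, col)
  }
  list(mat = M, pivots = pivots, rank = length(pivots))
}

#' Exact rank of an integer matrix
#' @param M integer matrix
#' @return integer rank
#' @noRd
int_rank <- function(M) {
  stopifnot_integer_matrix(M)
  if (length(M) == 0) return(0L)
  int_gauss_jordan(M)$rank
}

# Integer basis of the right kernel {v : M v = 0}. Each basis vector is
# content-reduced (gcd 1) with its first non-zero entry positive; vectors are
# returned as rows in a deterministic order (by free column).
int_nullspace <- function(M) {
  stopifnot_integer_matrix(M)
  n <- ncol(M)
  gj <- int_gauss_jordan(M)
  pivots <- gj$pivots
  free <- setdiff(seq_len(n), pivots)
  if (length(free) == 0) {
    return(matrix(0, nrow = 0, ncol = n))
  }
  A <- gj$mat
  basis <- matrix(0, nrow = length(free), ncol = n)
  pvals <- if (length(pivots)) A[cbind(seq_along(pivots), pivots)] else numeric(0)
  for (k in seq_along(free)) {
    f <- free[k]
    v <- numeric(n)
    den <- 1
    for (p in pvals) den <- lcm2(den, p)
    v[f] <- den
    for (i in seq_along(pivots)) {
      v[pivots[i]] <- -A[i, f] * (den / pvals[i])
    }
    check_exact_range(v, "nullspace")
    g <- gcd_vec(v)
    if (g > 1) v <- v / g
    lead <- v[which(v != 0)[1]]
    if (lead < 0) v <- -v
    basis[k, ] <- v
  }
  basis
}

# Exact integer basis of the left kernel {y : y^T M = 0}, rows of the result.
int_left_nullspace <- function(M) int_nullspace(t(M))

# Solve M x = b exactly over the rationals. Returns list(num, den) with
# integer numerators and a positive integer common denominator (x = num/den),
# or NULL when the system is inconsistent. Free variables are set to zero.
int_solve <- function(M, b) {
  stopifnot_integer_matrix(M)
  if (length(b) != nrow(M)) stop("length(b) must equal nrow(M)")
  if (any(b != round(b))) stop("b must be integer")
  aug <- cbind(M, b)
  gj <- int_gauss_jordan(aug)
  A <- gj$mat
  n <- ncol(M)
  pivots <- gj$pivots
  if (any(pivots > n)) return(NULL)  # pivot in the b column: inconsistent
  num <- numeric(n)
  den <- 1
  pvals <- if (length(pivots)) A[cbind(seq_along(pivots), pivots)] else numeric(0)
  for (p in pvals) den <- lcm2(den, p)
  for (i in seq_along(pivots)) {
    num[pivots[i]] <- A[i, n + 1] * (den / pvals[i])
  }
  check_exact_range(num, "linear solve")
  g <- gcd2(gcd_vec(num), den)
  if (g > 1) {
    num <- num / g
    den <- den / g
  }
  list(num = num, den = den)
}

# --- small exact rationals -------------------------------------------------
# Scalars as c(num, den), den > 0. Used only in low-dimensional
# back-substitution (Fourier-Motzkin), so a minimal implementation suffices.

rat <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- gcd2(num, den)
  if (g > 1) { num <- num / g; den <- den / g }
  c(num, den)
}

rat_add <- function(a, b) rat(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
rat_mul <- function(a, b) rat(a[1] * b[1], a[2] * b[2])
rat_div <- function(a, b) {
  if (b[1] == 0) stop("division by zero")
  rat(a[1] * b[2], a[2] * b[1])
}
rat_neg <- function(a) c(-a[1], a[2])
rat_cmp <- function(a, b) sign(a[1] * b[2] - b[1] * a[2])

# Continued-fraction rational reconstruction of a single value.
.reconstruct_fraction <- function(x, max_den = 1e9, tol = 1e-9) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  y <- x
  for (iter in 1:64) {
    a <- floor(y)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(x - p1 / q1) < tol * max(1, abs(x))) return(c(p1, q1))
    frac <- y - a
    if (frac < 1e-12) break
    y <- 1 / frac
  }
  if (abs(x - p1 / q1) < tol * max(1, abs(x))) return(c(p1, q1))
  stop("value not recognizable as an exact rational: ", x)
}

# Convert a numeric vector that encodes rationals (integers, decimals,
# fractions produced by exact solvers) to integer numerators over a common
# denominator.
rationalize <- function(x, max_den = 1e9) {
  if (all(x == round(x))) return(list(num = x, den = 1))
  fr <- lapply(x, .reconstruct_fraction, max_den = max_den)
  den <- 1
  for (f in fr) den <- lcm2(den, f[2])
  num <- vapply(fr, function(f) f[1] * (den / f[2]), numeric(1))
  check_exact_range(num, "rationalize")
  g <- gcd2(gcd_vec(num), den)
  if (g > 1) { num <- num / g; den <- den / g }
  list(num = num, den = den)
}
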