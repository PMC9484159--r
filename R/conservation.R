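# Conservation laws, minimal moiety conservation laws (MCLs), obligatory
# isomers and oligomers. A conservation law is a left-kernel vector of S; the
# network is conservative iff a strictly positive one exists (Stiemke's
# alternative: otherwise there is a cornucopia/abyss flow creating or
# annihilating mass). All kernel computation is exact.

#' Integer basis of the left kernel of S
#'
#' Every conservation law is a combination of these vectors. Basis vectors
#' are content-reduced to gcd 1 with positive leading entry, in a
#' deterministic order.
#'
#' @param net a `reaction_network` or stoichiometric matrix
#' @return integer matrix, one basis vector per row, species as columns;
#'   zero rows if the left kernel is trivial
#' @export
left_kernel_basis <- function(net) {
  S <- as_stoich(net)
  B <- int_left_nullspace(S)
  colnames(B) <- rownames(S)
  B
}

#' Conservativity with certificate
#'
#' Decides the Stiemke alternative: either there is an integer conservation
#' law `m` with all entries positive (`m^T S = 0`, the network is
#' conservative), or there is a flow in the reversible completion that
#' creates mass (`S v > 0`, a cornucopia; `-v` is then an abyss). Exactly one
#' branch holds; both certificates are re-verified in integer arithmetic.
#'
#' The positive law is assembled from the extreme rays of the non-negative
#' left-kernel cone: the network is conservative iff the ray supports jointly
#' cover all species, in which case the sum of the rays is a positive law.
#' The cornucopia is found by exact Fourier-Motzkin feasibility of
#' `S v >= e_x` over signed `v` for some species `x`.
#'
#' @inheritParams left_kernel_basis
#' @return list of class `mass_certificate`: `conservative` (logical),
#'   `kind` (`"conservation_law"` or `"cornucopia"`), and `m` (positive
#'   integer law) or `v` (signed integer flow with `S v > 0`)
#' @export
conservativity <- function(net) {
  S <- as_stoich(net)
  rays <- cone_extreme_rays(t(S))
  if (attr(rays, "truncated")) stop("ray enumeration truncated; network too large")
  covered <- if (nrow(rays)) colSums(rays) > 0 else rep(FALSE, nrow(S))
  if (all(covered)) {
    m <- colSums(rays)
    g <- gcd_vec(m)
    if (g > 1) m <- m / g
    names(m) <- rownames(S)
    stopifnot(all(m > 0), all(t(S) %*% m == 0))
    return(structure(list(conservative = TRUE, kind = "conservation_law", m = m),
                     class = "mass_certificate"))
  }
  # not conservative: find v with S v > 0 (strict on some uncovered species)
  for (x in which(!covered)) {
    A <- rbind(-S, -S[x, ])
    b <- c(numeric(nrow(S)), -1)
    sol <- fm_solve(A, b)
    if (!is.null(sol)) {
      v <- stats::setNames(sol$num, colnames(S))
      sv <- as.vector(S %*% v)
      stopifnot(all(sv >= 0), any(sv > 0))
      return(structure(list(conservative = FALSE, kind = "cornucopia", v = v,
                            produces = stats::setNames(sv, rownames(S))),
                      class = "mass_certificate"))
    }
  }
  stop("internal error: Stiemke alternative violated")
}

#' @export
print.mass_certificate <- function(x, ...) {
  if (x$conservative) {
    cat("Conservative: positive conservation law m =",
        paste(sprintf("%s:%g", names(x$m), x$m), collapse = ", "), "\n")
  } else {
    v <- x$v[x$v != 0]
    np <- x$produces[x$produces != 0]
    cat("NOT conservative: cornucopia v =",
        paste(sprintf("%s:%g", names(v), v), collapse = ", "),
        "creating", paste(sprintf("%g %s", np, names(np)), collapse = " + "), "\n")
  }
  invisible(x)
}

#' Minimal moiety conservation laws
#'
#' The minimal MCLs are the componentwise-minimal non-zero non-negative
#' integer left-kernel vectors of `S`; equivalently (and this is verified by
#' the tests against a brute-force oracle) the indecomposable elements of the
#' monoid of non-negative integer conservation laws, which generate all MCLs.
#' Computed by the Contejean-Devie completion procedure on `y^T S = 0`.
#'
#' @inheritParams left_kernel_basis
#' @param cap exploration guard; when exceeded the result is flagged
#'   `truncated`
#' @return list with `mcls` (integer matrix, one minimal MCL per row) and
#'   `truncated`
#' @export
minimal_mcls <- function(net, cap = 200000L) {
  S <- as_stoich(net)
  rays <- cone_extreme_rays(t(S))
  if (nrow(rays) <= 1) {
    # A zero- or one-ray cone settles the question without completion: the
    # integer points of a single primitive ray are exactly its multiples,
    # so the ray itself is the unique minimal MCL.
    M <- rays
    attr(M, "truncated") <- FALSE
  } else {
    M <- diophantine_min_solutions(t(S), cap = cap)
  }
  colnames(M) <- rownames(S)
  list(mcls = M, truncated = attr(M, "truncated"))
}

#' Minimal moiety representation
#'
#' The mm-representation of a conservative network is the matrix whose rows
#' are all minimal MCLs (abstract moieties x species). Its row space equals
#' the left kernel of `S`, so it is the most coarse-grained sum-formula
#' realization; the number of moieties is at least `dim ker t(S)`.
#'
#' @inheritParams minimal_mcls
#' @return integer matrix with moiety row names `M1, M2, ...`
#' @export
mm_representation <- function(net, cap = 200000L) {
  S <- as_stoich(net)
  cert <- conservativity(S)
  if (!cert$conservative) {
    stop(structure(class = c("not_conservative", "error", "condition"),
                   list(message = "network is not conservative; no mm-representation",
                        call = sys.call(), certificate = cert)))
  }
  M <- minimal_mcls(S, cap = cap)
  if (M$truncated) stop("minimal MCL enumeration truncated; raise cap")
  M <- M$mcls
  rownames(M) <- paste0("M", seq_len(nrow(M)))
  d <- nrow(S) - int_rank(S)
  stopifnot(nrow(M) >= d, int_rank(M) == d)  # Lemma: rows span the left kernel
  M
}

#' Obligatory isomer classes
#'
#' Two species are obligatory isomers when the network (in its reversible
#' completion) admits a net isomerization reaction `k x -> k y`;
#' equivalently, when every left-kernel vector assigns them equal
#' coordinates. The classes are read off as the equal-column classes of a
#' kernel basis matrix.
#'
#' @inheritParams left_kernel_basis
#' @return list with `classes` (list of character vectors, ordered by first
#'   species), and `inert` (species whose `S` row is all zero; they form
#'   free conservation laws of their own and are flagged here)
#' @export
isomer_classes <- function(net) {
  S <- as_stoich(net)
  B <- left_kernel_basis(S)
  keys <- if (nrow(B)) apply(B, 2, paste, collapse = ",") else rep("", ncol(B))
  classes <- split(rownames(S), factor(keys, levels = unique(keys)))
  names(classes) <- NULL
  inert <- rownames(S)[rowSums(abs(S)) == 0]
  list(classes = classes, inert = inert)
}

#' Net isomerization hyperflow
#'
#' Solves `S v = k (e_y - e_x)` exactly; the returned signed integer vector
#' specifies the net isomerization `k x -> k y` in the reversible completion
#' (negative entries run reactions backwards). `k` is obtained from the
#' least common denominator of the rational solution. Returns `NULL` when
#' `x` and `y` are not obligatory isomers, and the zero vector with `k = 0`
#' for `x == y`.
#'
#' @inheritParams left_kernel_basis
#' @param x,y species ids
#' @return list with `v` (named signed integer vector) and `k`, or `NULL`
#' @export
net_isomerization_flow <- function(net, x, y) {
  S <- as_stoich(net)
  ix <- match(x, rownames(S)); iy <- match(y, rownames(S))
  if (is.na(ix) || is.na(iy)) stop("unknown species")
  if (ix == iy) {
    return(list(v = stats::setNames(numeric(ncol(S)), colnames(S)), k = 0))
  }
  w <- numeric(nrow(S))
  w[ix] <- -1; w[iy] <- 1
  sol <- int_solve(S, w)
  if (is.null(sol)) return(NULL)
  v <- stats::setNames(sol$num, colnames(S))
  k <- sol$den
  sv <- as.vector(S %*% v)
  stopifnot(identical(sv, k * w))
  list(v = v, k = k)
}

#' Obligatory oligomer ratio
#'
#' If every left-kernel vector satisfies `p m_x == q m_y` for coprime
#' integers `p, q`, then the reversible completion admits a net reaction
#' `p x -> q y`: the two species are necessarily oligomers of a common
#' monomer, in ratio `p:q`. Returns `NULL` when the kernel coordinates of
#' `x` and `y` are not proportional (or proportional with the wrong sign).
#'
#' @inheritParams net_isomerization_flow
#' @return integer vector `c(p = , q = )`, or `NULL`
#' @export
oligomer_ratio <- function(net, x, y) {
  S <- as_stoich(net)
  B <- left_kernel_basis(S)
  ix <- match(x, rownames(S)); iy <- match(y, rownames(S))
  if (is.na(ix) || is.na(iy)) stop("unknown species")
  if (nrow(B) == 0) return(c(p = 1, q = 1))  # trivial kernel: all coordinates 0
  mx <- B[, ix]; my <- B[, iy]
  if (all(mx == 0) && all(my == 0)) return(c(p = 1, q = 1))
  if (all(mx == 0) || all(my == 0)) return(NULL)
  i <- which(my != 0)[1]
  p <- my[i]; q <- mx[i]      # mass balance: p * m_x = q * m_y
  if (p * q <= 0) return(NULL)
  if (p < 0) { p <- -p; q <- -q }
  g <- gcd2(p, q)
  p <- p / g; q <- q / g
  if (!all(p * mx == q * my)) return(NULL)
  c(p = unname(p), q = unname(q))
}

#' Validate candidate conservation vectors
#'
#' Checks `y^T S == 0` exactly for each supplied vector (e.g. atom
#' composition rows) and reports the rank of the passing set, exposing
#' linear dependence among atom conservation laws.
#'
#' @inheritParams left_kernel_basis
#' @param vectors numeric matrix, one candidate vector per row (columns =
#'   species), or a single vector
#' @return list with `pass` (logical per vector), `n_pass`, and `rank` of
#'   the passing vectors
#' @export
check_conservation_vectors <- function(net, vectors) {
  S <- as_stoich(net)
  V <- rbind(vectors)
  if (ncol(V) != nrow(S)) stop("vectors must have one column per species")
  if (any(V != round(V))) stop("vectors must be integer")
  pass <- apply(V, 1, function(y) all(t(S) %*% y == 0))
  P <- V[pass, , drop = FALSE]
  list(pass = pass, n_pass = sum(pass),
       rank = if (nrow(P)) int_rank(P) else 0L)
}
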