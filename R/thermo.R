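# Energies, futile cycles, perpetuum mobiles and the two soundness notions.
#
# All decisions follow theorems of the alternative (Gordan/Minty/Stiemke):
# a network either has an energy assignment with the required sign pattern or
# a futile-cycle certificate, never both. Decisions are made on extreme rays
# of the futile cone; witnesses are constructed by exact Fourier-Motzkin
# elimination; every certificate is re-verified in integer arithmetic.

#' Reaction energies from molecular energies (Hess's law)
#'
#' Computes `g = t(S) %*% G`: the Gibbs free reaction energy of each reaction
#' from the Gibbs free energies of formation of the species. Arithmetic is
#' exact for integer and simple decimal inputs.
#'
#' @param net a `reaction_network` or stoichiometric matrix
#' @param G numeric vector of molecular energies (one per species)
#' @return named numeric vector of reaction energies
#' @export
hess_energies <- function(net, G) {
  S <- as_stoich(net)
  if (length(G) != nrow(S)) stop("length(G) must equal the number of species")
  r <- rationalize(G)
  g <- as.vector(t(S) %*% r$num) / r$den
  stats::setNames(g, colnames(S))
}

#' Recover molecular energies from reaction energies
#'
#' Finds any exact rational `G` with `t(S) %*% G == g`, or `NULL` when `g`
#' is not in the row space of `S` (equivalently, when the network with these
#' energies is not thermodynamic). `G` is not uniquely determined in general;
#' free components are set to zero.
#'
#' @inheritParams hess_energies
#' @param g numeric vector of reaction energies (one per reaction)
#' @return named numeric vector of molecular energies, or `NULL`
#' @export
recover_molecular_energies <- function(net, g) {
  S <- as_stoich(net)
  if (length(g) != ncol(S)) stop("length(g) must equal the number of reactions")
  r <- rationalize(g)
  sol <- int_solve(t(S), r$num)
  if (is.null(sol)) return(NULL)
  stats::setNames(sol$num / (sol$den * r$den), rownames(S))
}

#' Is (S, g) thermodynamic?
#'
#' True when `g` is orthogonal to the kernel of `S`, checked exactly against
#' an integer kernel basis; equivalently, when molecular energies satisfying
#' Hess's law exist.
#'
#' @inheritParams recover_molecular_energies
#' @return logical
#' @export
is_thermodynamic <- function(net, g) {
  S <- as_stoich(net)
  if (length(g) != ncol(S)) stop("length(g) must equal the number of reactions")
  K <- int_nullspace(S)
  if (nrow(K) == 0) return(TRUE)
  r <- rationalize(g)
  all(as.vector(K %*% r$num) == 0)
}

#' Energy consistency of structurally reverse reaction pairs
#'
#' In any thermodynamic network the energies of a reaction and its reverse
#' cancel. This check finds all structural reverse pairs (educts and products
#' swapped) and reports those with `g_r + g_rbar != 0`. An empty result is a
#' necessary condition for [is_thermodynamic()].
#'
#' @param net a `reaction_network`
#' @param g numeric vector of reaction energies
#' @return data frame with columns `r`, `rbar`, `sum` (one row per violation)
#' @export
reverse_pair_violations <- function(net, g) {
  stopifnot(inherits(net, "reaction_network"))
  ids <- reaction_ids(net)
  if (length(g) != length(ids)) stop("length(g) must equal the number of reactions")
  pairs <- structural_reverse_pairs(net)
  out <- data.frame(r = character(0), rbar = character(0), sum = numeric(0))
  for (p in pairs) {
    s <- g[match(p[1], ids)] + g[match(p[2], ids)]
    if (s != 0) out <- rbind(out, data.frame(r = p[1], rbar = p[2], sum = s))
  }
  out
}

# All unordered pairs {r, rbar} with sides swapped, found structurally.
structural_reverse_pairs <- function(net) {
  key <- function(side) format_formal_sum(side[order(names(side))])
  fwd <- vapply(net$reactions, function(r) paste(key(r$educts), "|", key(r$products)),
                character(1))
  bwd <- vapply(net$reactions, function(r) paste(key(r$products), "|", key(r$educts)),
                character(1))
  ids <- reaction_ids(net)
  pairs <- list()
  for (i in seq_along(ids)) {
    j <- which(bwd == fwd[i])
    for (jj in j[j > i]) pairs[[length(pairs) + 1L]] <- c(ids[i], ids[jj])
  }
  pairs
}

#' Enumerate support-minimal futile cycles
#'
#' A futile cycle is a non-trivial flow `v > 0` with `S v = 0`: concurrent
#' reactions whose net effect is empty. The support-minimal integer cycles
#' are the extreme rays of the pointed cone `{v >= 0 : S v = 0}`, computed by
#' double description and scaled to coprime integers. Cycles whose support is
#' exactly a structural reverse pair are flagged `trivial` (they exist by
#' construction whenever a reversible reaction was expanded into a pair).
#'
#' @param net a `reaction_network` or stoichiometric matrix
#' @param cap guard on the ray count; when exceeded the result carries
#'   `truncated = TRUE`
#' @return list with `cycles` (integer matrix, one cycle per row, reaction
#'   ids as column names), `trivial` (logical per cycle), `truncated`
#' @export
futile_cycles <- function(net, cap = 100000L) {
  S <- as_stoich(net)
  rays <- cone_extreme_rays(S, cap = cap)
  colnames(rays) <- colnames(S)
  trivial <- rep(FALSE, nrow(rays))
  pair_sets <- .reverse_pair_supports(net, S)
  if (length(pair_sets) && nrow(rays)) {
    supp <- apply(rays, 1, function(v) paste(sort(colnames(rays)[v != 0]), collapse = "|"))
    trivial <- supp %in% pair_sets
  }
  list(cycles = rays, trivial = trivial, truncated = attr(rays, "truncated"))
}

.reverse_pair_supports <- function(net, S) {
  if (inherits(net, "reaction_network")) {
    pairs <- structural_reverse_pairs(net)
  } else {
    # from the matrix alone: columns that are exact negations
    pairs <- list()
    for (i in seq_len(ncol(S))) {
      for (j in seq_len(ncol(S))[-seq_len(i)]) {
        if (all(S[, i] == -S[, j])) pairs[[length(pairs) + 1L]] <- colnames(S)[c(i, j)]
      }
    }
  }
  vapply(pairs, function(p) paste(sort(p), collapse = "|"), character(1))
}

#' Search for a perpetuum mobile
#'
#' A perpetuum mobile is a futile cycle with non-vanishing total energy
#' `<g, v> != 0`, violating energy conservation. Since the energy of any
#' flow in the futile cone is a conic combination of the ray energies, a
#' perpetuum mobile exists iff some extreme ray has non-zero energy; the ray
#' with the largest absolute energy is returned.
#'
#' @inheritParams recover_molecular_energies
#' @return named integer flow, or `NULL` if no perpetuum mobile exists
#' @export
perpetuum_mobile <- function(net, g) {
  S <- as_stoich(net)
  if (length(g) != ncol(S)) stop("length(g) must equal the number of reactions")
  fc <- futile_cycles(net)
  if (nrow(fc$cycles) == 0) return(NULL)
  r <- rationalize(g)
  en <- as.vector(fc$cycles %*% r$num)
  if (all(en == 0)) return(NULL)
  v <- fc$cycles[which.max(abs(en)), ]
  stopifnot(all(S %*% v == 0))
  v
}

.new_soundness_report <- function(sound, mode, witness_g = NULL, witness_G = NULL,
                                  certificate = NULL, gamma = NA_real_,
                                  trivial_kernel = FALSE) {
  structure(list(sound = sound, mode = mode, witness_g = witness_g,
                 witness_G = witness_G, certificate = certificate,
                 gamma_used = gamma, trivial_kernel = trivial_kernel),
            class = "soundness_report")
}

#' @export
print.soundness_report <- function(x, ...) {
  cat(sprintf("Thermodynamic soundness (%s): %s\n", x$mode,
              if (x$sound) "SOUND" else "NOT sound"))
  if (x$trivial_kernel) cat("  (trivial kernel: no futile cycles at all)\n")
  if (!is.null(x$witness_g)) {
    cat("  witness g:", paste(sprintf("%s=%g", names(x$witness_g), x$witness_g),
                              collapse = ", "), "\n")
  }
  if (!is.null(x$certificate)) {
    v <- x$certificate[x$certificate != 0]
    cat("  futile cycle:", paste(sprintf("%s:%g", names(v), v), collapse = ", "), "\n")
  }
  invisible(x)
}

# Split a reaction id set argument into irreversible column indices.
.irr_indices <- function(net, S, irr) {
  if (is.null(irr)) {
    if (inherits(net, "reaction_network")) {
      return(which(!reversible_flags(net)))
    }
    return(seq_len(ncol(S)))  # matrix input defaults to all irreversible
  }
  if (is.character(irr)) {
    idx <- match(irr, colnames(S))
    if (anyNA(idx)) stop("unknown reaction id in irr: ", paste(irr[is.na(idx)], collapse = ", "))
    return(idx)
  }
  as.integer(irr)
}

#' Thermodynamic soundness (lax sense) with certificate
#'
#' Decides whether reaction energies exist that make the network
#' thermodynamic while all irreversible reactions are exergonic
#' (`g_r < 0`). By the theorem of the alternative this holds iff there is no
#' futile cycle supported entirely on irreversible reactions. Exactly one
#' branch is returned: a witness `g = t(S) G` (with the explicit `G`), or a
#' futile-cycle certificate supported in the irreversible set.
#'
#' @param net a `reaction_network` or stoichiometric matrix
#' @param irr irreversible reactions: reaction ids or column indices. Default
#'   for a network: its non-reversible reactions; for a bare matrix: all
#'   columns.
#' @return a `soundness_report`
#' @export
thermodynamic_soundness <- function(net, irr = NULL) {
  S <- as_stoich(net)
  irr_idx <- .irr_indices(net, S, irr)
  trivial <- int_rank(S) == ncol(S)
  # decision: extreme rays of the futile cone restricted to irr columns
  if (length(irr_idx)) {
    rays <- cone_extreme_rays(S[, irr_idx, drop = FALSE])
    if (attr(rays, "truncated")) stop("ray enumeration truncated; network too large")
    if (nrow(rays) > 0) {
      v <- stats::setNames(numeric(ncol(S)), colnames(S))
      v[irr_idx] <- rays[1, ]
      stopifnot(all(S %*% v == 0), all(v >= 0), any(v > 0))
      return(.new_soundness_report(FALSE, "lax", certificate = v,
                                   trivial_kernel = trivial))
    }
  }
  # witness: G with (S^T G)_r <= -1 for irreversible r
  if (length(irr_idx)) {
    A <- t(S[, irr_idx, drop = FALSE])
    sol <- fm_solve(A, rep(-1, nrow(A)))
    if (is.null(sol)) stop("internal error: alternative theorem violated")
    G <- stats::setNames(sol$num / sol$den, rownames(S))
  } else {
    G <- stats::setNames(2^seq(0, nrow(S) - 1L), rownames(S))
  }
  g <- hess_energies(S, G)
  stopifnot(is_thermodynamic(S, g), all(g[irr_idx] < 0))
  .new_soundness_report(TRUE, "lax", witness_g = g, witness_G = G,
                        trivial_kernel = trivial)
}

#' Strict thermodynamic soundness with certificate
#'
#' In the strict sense, irreversible reactions must admit energies that are
#' arbitrarily more negative than those of the reversible reactions (after
#' scaling, `|g_r| <= 1` on the reversible set and `g_r <= -gamma` on the
#' irreversible set, for every `gamma > 1`). This holds iff *no* futile cycle
#' of the reversible completion contains an irreversible reaction, which is
#' how the decision is made (a gamma-free support condition). The witness is
#' constructed for the concrete `gamma` requested.
#'
#' @inheritParams thermodynamic_soundness
#' @param gamma scale separating irreversible from reversible energies in the
#'   witness (default 1000)
#' @return a `soundness_report` with `gamma_used` set on the witness branch
#' @export
strict_soundness <- function(net, irr = NULL, gamma = 1000) {
  if (gamma <= 1) stop("gamma must exceed 1")
  S <- as_stoich(net)
  irr_idx <- .irr_indices(net, S, irr)
  rev_idx <- setdiff(seq_len(ncol(S)), irr_idx)
  # Decision in kernel coordinates: futile cycles of the reversible
  # completion touching the irreversible set correspond to kernel elements
  # v = t(K) lambda with v >= 0 on irr and v != 0 there. Working in
  # lambda-space (dimension = nullity of S) keeps the ray enumeration small.
  K <- int_nullspace(S)
  if (nrow(K) > 0 && length(irr_idx) > 0) {
    A <- t(K[, irr_idx, drop = FALSE])          # |irr| x d
    d <- nrow(K)
    # slack form: A lp - A lm - s = 0, (lp, lm, s) >= 0
    E <- cbind(A, -A, -diag(1, length(irr_idx)))
    rays <- cone_extreme_rays(E)
    if (attr(rays, "truncated")) stop("ray enumeration truncated; network too large")
    spart <- rays[, 2 * d + seq_along(irr_idx), drop = FALSE]
    hits <- which(rowSums(spart) > 0)
    if (length(hits)) {
      u <- rays[hits[1], ]
      lambda <- u[seq_len(d)] - u[d + seq_len(d)]
      v <- as.vector(t(K) %*% lambda)
      g0 <- gcd_vec(v)
      if (g0 > 1) v <- v / g0
      names(v) <- colnames(S)
      stopifnot(all(S %*% v == 0), all(v[irr_idx] >= 0), any(v[irr_idx] > 0))
      return(.new_soundness_report(FALSE, "strict", certificate = v, gamma = gamma))
    }
  }
  # Witness construction. Strict soundness is equivalent to feasibility of
  # { t(S_rev) G = 0, t(S_irr) G <= -1 } (Farkas: infeasibility would yield a
  # completion futile cycle touching irr). Eliminating the equalities through
  # a nullspace leaves |irr| inequalities in few variables for exact
  # Fourier-Motzkin; scaling by gamma gives g <= -gamma on irr while all
  # reversible energies are exactly zero (|g_r| <= 1 trivially).
  n <- nrow(S)
  if (length(irr_idx) == 0) {
    G <- stats::setNames(numeric(n), rownames(S))
  } else {
    N <- int_nullspace(t(S[, rev_idx, drop = FALSE]))  # rows span {G : t(S_rev) G = 0}
    if (nrow(N) == 0) stop("internal error: alternative theorem violated (strict)")
    Airr <- t(S[, irr_idx, drop = FALSE]) %*% t(N)
    check_exact_range(Airr, "strict witness constraints")
    sol <- fm_solve(Airr, rep(-1, length(irr_idx)))
    if (is.null(sol)) stop("internal error: alternative theorem violated (strict)")
    G <- stats::setNames(gamma * as.vector(t(N) %*% sol$num) / sol$den, rownames(S))
  }
  g <- hess_energies(S, G)
  stopifnot(is_thermodynamic(S, g),
            all(g[irr_idx] <= -gamma), all(abs(g[rev_idx]) <= 1))
  .new_soundness_report(TRUE, "strict", witness_g = g, witness_G = G, gamma = gamma)
}

#' Reversible completion of a network
#'
#' Adds the reverse of every non-reversible reaction, with negated energy if
#' energies are supplied. A thermodynamic network stays thermodynamic under
#' completion (the same molecular energies still satisfy Hess's law).
#'
#' @param net a `reaction_network`
#' @param g optional reaction energies; when given, `(net, g)` must be
#'   thermodynamic.
#' @return list with `network` and `g` (extended energies, or `NULL`)
#' @export
reversible_completion <- function(net, g = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  if (!is.null(g)) {
    if (!is_thermodynamic(net, g)) {
      stop("input energies are not thermodynamic; completion undefined")
    }
  }
  rev <- reversible_flags(net)
  reactions <- lapply(net$reactions, function(r) { r$reversible <- TRUE; r })
  gout <- g
  for (j in which(!rev)) {
    r <- net$reactions[[j]]
    rb <- reverse_reaction(r)
    rb$reversible <- TRUE
    reactions[[j]]$pair <- rb$id
    reactions[[length(reactions) + 1L]] <- rb
    if (!is.null(g)) gout <- c(gout, -g[j])
  }
  out <- reaction_network(net$species, reactions)
  if (!is.null(gout)) names(gout) <- reaction_ids(out)
  list(network = out, g = gout)
}

#' Equivalent non-negative flow in a reversible network
#'
#' Rewrites a signed vector over reactions as a genuine flow with the same
#' net effect, by routing negative entries through the structurally reverse
#' reactions. Requires every reaction carrying a negative entry to have its
#' reverse present. If antisymmetric energies are supplied the total energy
#' is preserved.
#'
#' @param net a `reaction_network` (reverse pairs present for all reactions
#'   used backwards)
#' @param v signed integer vector over reactions
#' @param g optional reaction energies (checked for energy preservation)
#' @return named non-negative flow `vtilde` with `S vtilde == S v`
#' @export
nonneg_equivalent_flow <- function(net, v, g = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  ids <- reaction_ids(net)
  v <- .check_flow_vector(net, v)
  pairs <- structural_reverse_pairs(net)
  partner <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (p in pairs) { partner[p[1]] <- p[2]; partner[p[2]] <- p[1] }
  vt <- stats::setNames(pmax(v, 0), ids)
  for (j in which(v < 0)) {
    pj <- partner[ids[j]]
    if (is.na(pj)) {
      stop("reaction ", ids[j], " runs backwards but has no reverse in the network")
    }
    vt[pj] <- vt[pj] - v[j]
  }
  S <- stoichiometric_matrix(net)
  stopifnot(all(S %*% vt == S %*% v))
  if (!is.null(g)) stopifnot(sum(g * vt) == sum(g * v))
  vt
}
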