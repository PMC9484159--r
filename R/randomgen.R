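# Random chemistry-like networks: conservative and thermodynamically sound by
# construction. A positive integer mass vector is fixed first; every sampled
# reaction column is mass-balanced against it (conservativity), and reaction
# energies are derived from random molecular energies via Hess's law
# (thermodynamic soundness). Only exergonic reactions may be marked
# irreversible; under strict mode, only reactions provably outside every
# futile cycle.

#' Augment a stoichiometric matrix with catalysts
#'
#' Splits `S` into educt and product coefficient matrices and adds the
#' non-negative catalyst matrix `C` to both sides:
#' `s- = C + max(-S, 0)` and `s+ = C + max(S, 0)`. The reconstructed net
#' matrix `s+ - s-` always equals `S`; catalysts never affect the analyses.
#'
#' @param S integer stoichiometric matrix
#' @param C non-negative integer matrix of the same shape
#' @return list with `s_minus`, `s_plus`, and `network` (a
#'   `reaction_network` carrying the explicit catalysts)
#' @export
add_catalysts <- function(S, C) {
  S <- as_stoich(S)
  C <- rbind(C)
  if (!all(dim(C) == dim(S))) stop("C must have the shape of S")
  if (any(C < 0) || any(C != round(C))) stop("C must be a non-negative integer matrix")
  s_minus <- C + pmax(-S, 0)
  s_plus <- C + pmax(S, 0)
  dimnames(s_minus) <- dimnames(s_plus) <- dimnames(S)
  reactions <- lapply(seq_len(ncol(S)), function(j) {
    em <- stats::setNames(s_minus[, j], rownames(S))
    ep <- stats::setNames(s_plus[, j], rownames(S))
    reaction(colnames(S)[j], educts = em[em > 0], products = ep[ep > 0])
  })
  list(s_minus = s_minus, s_plus = s_plus,
       network = reaction_network(rownames(S), reactions))
}

#' Generate a random conservative, thermodynamically sound network
#'
#' Construction: (a) draw an integer mass vector `m` (entries from
#' `mass_range`, all positive); (b) draw proper reaction columns whose educt
#' and product multisets have equal total mass (bounded-knapsack completion
#' of the product side), so `m` is a positive conservation law by
#' construction; (c) draw integer molecular energies `G` and set
#' `g = t(S) G` (thermodynamic by Hess's law); (d) mark irreversible only
#' reactions with `g_r < 0` — under `strict = TRUE` only those additionally
#' not supporting any futile cycle, so the result is strictly sound.
#'
#' @param n_species,n_reactions network size (defaults: 10 species, 15
#'   reactions, a small metabolism-like density)
#' @param max_coeff largest stoichiometric coefficient (default 3)
#' @param mass_range inclusive integer range for the mass vector (default
#'   1..6, small-molecule moiety counts)
#' @param sparsity target fraction of species absent from each reaction
#'   (default 0.7)
#' @param irreversible_fraction fraction of eligible (exergonic) reactions
#'   marked irreversible (default 0.5)
#' @param strict restrict irreversibility so that no futile cycle touches an
#'   irreversible reaction
#' @param seed integer seed; the same seed and configuration reproduce the
#'   network exactly
#' @param max_tries rejection-sampling budget per reaction
#' @return list with `network`, `S`, `m` (mass law), `G`, `g`, and
#'   `irr` (irreversible reaction ids)
#' @export
random_reaction_network <- function(n_species = 10L, n_reactions = 15L,
                                    max_coeff = 3L, mass_range = c(1L, 6L),
                                    sparsity = 0.7, irreversible_fraction = 0.5,
                                    strict = FALSE, seed = 1L,
                                    max_tries = 500L) {
  if (n_species < 2 || n_reactions < 1 || max_coeff < 1) {
    stop("need n_species >= 2, n_reactions >= 1, max_coeff >= 1")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  # sample() with the 1:x surprise disabled
  resample <- function(x, size = length(x), replace = FALSE) {
    x[sample.int(length(x), size, replace = replace)]
  }

  species <- sprintf("X%02d", seq_len(n_species))
  m <- resample(seq(mass_range[1], mass_range[2]), n_species, replace = TRUE)
  names(m) <- species
  support_size <- max(1L, round((1 - sparsity) * n_species / 2))

  sample_side <- function(excl = integer(0)) {
    k <- max(1L, min(n_species, support_size + resample(-1:1, 1)))
    idx <- resample(setdiff(seq_len(n_species), excl), min(k, n_species - length(excl)))
    stats::setNames(resample(seq_len(max_coeff), length(idx), replace = TRUE),
                    species[idx])
  }
  # bounded knapsack: find a multiset over `avail` species with total mass
  # `target`, coefficients <= max_coeff, via randomized depth-first search
  knapsack <- function(target, avail) {
    if (target <= 0 || length(avail) == 0) return(NULL)
    avail <- resample(avail)
    res <- integer(0)
    dfs <- function(t, pool) {
      if (t == 0) return(TRUE)
      if (length(pool) == 0) return(FALSE)
      x <- pool[1]
      for (cnt in resample(0:min(max_coeff, t %/% m[x]))) {
        if (cnt > 0) res[species[x]] <<- cnt
        if (dfs(t - cnt * m[x], pool[-1])) return(TRUE)
        if (cnt > 0) res <<- res[names(res) != species[x]]
      }
      FALSE
    }
    if (dfs(target, avail)) res else NULL
  }

  reactions <- vector("list", n_reactions)
  for (j in seq_len(n_reactions)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ed <- sample_side()
      mass <- sum(m[names(ed)] * ed)
      pr <- knapsack(mass, setdiff(seq_len(n_species), match(names(ed), species)))
      if (is.null(pr)) next
      r <- reaction(sprintf("r%02d", j), educts = ed, products = pr)
      col <- numeric(n_species)
      names(col) <- species
      col[names(ed)] <- col[names(ed)] - ed
      col[names(pr)] <- col[names(pr)] + pr
      if (any(col > 0) && any(col < 0)) { ok <- TRUE; break }
    }
    if (!ok) stop("infeasible configuration: no mass-balanced proper column found")
    reactions[[j]] <- r
  }
  net <- reaction_network(species, reactions)
  S <- stoichiometric_matrix(net)
  stopifnot(all(t(S) %*% m == 0))

  G <- stats::setNames(sample(-10:10, n_species, replace = TRUE), species)
  g <- hess_energies(S, G)

  eligible <- which(g < 0)
  if (strict && length(eligible)) {
    # Before marking, every reaction is reversible, so futile cycles of the
    # completion reach every reaction with a non-zero kernel coordinate.
    # Eligible are exactly the reactions on which the kernel vanishes; then
    # no futile cycle can touch the irreversible set.
    K <- int_nullspace(S)
    in_cycle <- if (nrow(K)) colSums(K != 0) > 0 else rep(FALSE, ncol(S))
    eligible <- eligible[!in_cycle[eligible]]
  }
  irr <- eligible[stats::runif(length(eligible)) < irreversible_fraction]
  for (j in seq_len(n_reactions)) net$reactions[[j]]$reversible <- !(j %in% irr)

  list(network = net, S = stoichiometric_matrix(net), m = m, G = G, g = g,
       irr = colnames(S)[irr])
}

#' Random subnetwork
#'
#' Samples `k` reactions uniformly and keeps the species in their supports.
#' Reactions of the parent whose support lies entirely inside the kept
#' species are then forced in by the subnetwork closure condition; forced
#' additions are reported in the `forced` attribute. Thermodynamic soundness
#' and conservativity certificates restrict to subnetworks, so subnetworks
#' of chemistry-like networks stay chemistry-like.
#'
#' @param net a `reaction_network`
#' @param k number of reactions to sample (`1 <= k <= |reactions|`)
#' @param seed integer seed
#' @return a `reaction_network` with attribute `forced`
#' @export
random_subnetwork <- function(net, k, seed = 1L) {
  stopifnot(inherits(net, "reaction_network"))
  ids <- reaction_ids(net)
  if (k < 1 || k > length(ids)) stop("k out of range")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  pick <- sort(sample(seq_along(ids), k))
  keep_species <- sort(unique(unlist(lapply(net$reactions[pick], reaction_support))))
  forced <- character(0)
  for (i in seq_along(ids)) {
    if (i %in% pick) next
    if (all(reaction_support(net$reactions[[i]]) %in% keep_species)) {
      pick <- sort(c(pick, i))
      forced <- c(forced, ids[i])
    }
  }
  out <- subnetwork(net, keep_species, ids[pick])
  attr(out, "forced") <- forced
  out
}
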