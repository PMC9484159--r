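#' Construct a reaction network
#'
#' A reaction network is a pair of a species set and a list of reactions,
#' equivalently a directed integer-weighted hypergraph. Each reaction converts
#' a multiset of educts into a multiset of products; stoichiometric
#' coefficients are non-negative integers. Explicit catalysis (a species
#' appearing on both sides) is retained in the reaction objects even though it
#' cancels in the stoichiometric matrix.
#'
#' @param species character vector of unique, non-empty species ids, in
#'   canonical order (first appearance in the input).
#' @param reactions list of reactions created with [reaction()].
#' @return an object of class `reaction_network`
#' @seealso [parse_rxn()], [stoichiometric_matrix()]
#' @export
reaction_network <- function(species, reactions) {
  species <- as.character(species)
  if (length(species) == 0 || length(reactions) == 0) {
    stop("a reaction network needs at least one species and one reaction")
  }
  if (anyDuplicated(species) || any(!nzchar(species))) {
    stop("species ids must be unique and non-empty")
  }
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate reaction id: ", ids[duplicated(ids)][1])
  }
  for (r in reactions) {
    used <- union(names(r$educts), names(r$products))
    missing <- setdiff(used, species)
    if (length(missing)) {
      stop("reaction ", r$id, " references unknown species: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' Construct a single reaction
#'
#' @param id reaction id (unique within a network)
#' @param educts,products named non-negative integer vectors (names are
#'   species ids); entries of value zero are dropped. Both sides may share
#'   species (explicit catalysis). At least one side must be non-empty.
#' @param reversible logical; marks membership in the reversible subset. In
#'   networks built by [parse_rxn()], a reversible input reaction is expanded
#'   into the two opposite irreversible columns, both flagged reversible and
#'   linked via `pair`.
#' @param pair id of the structurally reverse reaction, or `NA`
#' @return a `reaction` object
#' @export
reaction <- function(id, educts = numeric(0), products = numeric(0),
                     reversible = FALSE, pair = NA_character_) {
  educts <- .clean_side(educts, id, "educt")
  products <- .clean_side(products, id, "product")
  if (length(educts) == 0 && length(products) == 0) {
    stop("reaction ", id, " has empty support")
  }
  structure(list(id = as.character(id), educts = educts, products = products,
                 reversible = isTRUE(reversible), pair = pair),
            class = "reaction")
}

.clean_side <- function(side, id, what) {
  if (length(side) == 0) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(side)) || any(!nzchar(names(side)))) {
    stop("reaction ", id, ": ", what, " coefficients must be named by species")
  }
  if (any(side < 0) || any(side != round(side))) {
    stop("reaction ", id, ": ", what, " coefficients must be non-negative integers")
  }
  side <- tapply(side, names(side), sum)  # merge duplicate species
  side <- side[side > 0]
  stats::setNames(as.numeric(side), names(side))
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  cat("Species:", paste(x$species, collapse = ", "), "\n")
  for (r in x$reactions) cat(" ", format_reaction(r), "\n")
  invisible(x)
}

#' @export
print.reaction <- function(x, ...) {
  cat(format_reaction(x), "\n")
  invisible(x)
}

#' Format a reaction or formal sum as text
#'
#' @param r a `reaction`
#' @return a string such as `"r1: A + B -> 2 C"`
#' @export
format_reaction <- function(r) {
  arrow <- if (r$reversible) "->" else "->"
  sprintf("%s: %s %s %s", r$id, format_formal_sum(r$educts), arrow,
          format_formal_sum(r$products))
}

#' @rdname format_reaction
#' @param coeffs named non-negative vector over species (a formal sum); an
#'   empty sum prints as the empty-set symbol.
#' @export
format_formal_sum <- function(coeffs) {
  coeffs <- coeffs[coeffs != 0]
  if (length(coeffs) == 0) return("0")
  paste(ifelse(coeffs == 1, names(coeffs), paste(coeffs, names(coeffs))),
        collapse = " + ")
}

reaction_ids <- function(net) vapply(net$reactions, `[[`, character(1), "id")

#' Reversibility flags of a network
#'
#' @param net a `reaction_network`
#' @return named logical vector over reactions (`TRUE` = reversible)
#' @export
reversible_flags <- function(net) {
  stats::setNames(vapply(net$reactions, `[[`, logical(1), "reversible"),
                  reaction_ids(net))
}

#' Stoichiometric matrix of a network
#'
#' Builds the integer matrix with entries `s+ - s-` (net production of each
#' species in each reaction). Rows follow the species order of the network,
#' columns the reaction order. Catalytic contributions cancel here by
#' construction.
#'
#' @param net a `reaction_network`
#' @return integer matrix (species x reactions) with dimnames
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  S <- matrix(0, nrow = length(net$species), ncol = length(net$reactions),
              dimnames = list(net$species, reaction_ids(net)))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    S[names(r$educts), j] <- S[names(r$educts), j] - r$educts
    S[names(r$products), j] <- S[names(r$products), j] + r$products
  }
  S
}

# Accept either a stoichiometric matrix or a network everywhere downstream.
as_stoich <- function(x) {
  if (inherits(x, "reaction_network")) return(stoichiometric_matrix(x))
  stopifnot_integer_matrix(x, "stoichiometric matrix")
  if (is.null(rownames(x))) rownames(x) <- paste0("X", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("r", seq_len(ncol(x)))
  x
}

#' Classify reactions as proper, import, or export
#'
#' Classification uses the *net* coefficients (columns of the stoichiometric
#' matrix), so a catalyzed import such as `C -> C + A` is recognized as an
#' import. A reaction is proper when its column has entries of both signs,
#' an import when all entries are non-negative, an export when all are
#' non-positive. An all-zero column (pure catalysis) is an import and an
#' export simultaneously; it is reported as `"null"` with a warning.
#'
#' @param net a `reaction_network` or stoichiometric matrix
#' @return named character vector with values `"proper"`, `"import"`,
#'   `"export"`, or `"null"`
#' @export
classify_reactions <- function(net) {
  S <- as_stoich(net)
  out <- apply(S, 2, function(col) {
    if (all(col == 0)) return("null")
    if (any(col < 0) && any(col > 0)) return("proper")
    if (all(col >= 0)) return("import")
    "export"
  })
  if (any(out == "null")) {
    warning("null reaction(s) with all-zero net column: ",
            paste(names(out)[out == "null"], collapse = ", "))
  }
  out
}

#' Is the network closed?
#'
#' A network is closed when every reaction is proper, i.e. it exchanges no
#' matter with the environment.
#' @inheritParams classify_reactions
#' @return logical
#' @export
is_closed <- function(net) {
  all(suppressWarnings(classify_reactions(net)) == "proper")
}

#' Proper part of a network
#'
#' Restricts the reaction set to the proper reactions, yielding the unique
#' inclusion-maximal closed subnetwork on the same species set.
#'
#' @param net a `reaction_network`
#' @return a `reaction_network` containing only proper reactions
#' @export
proper_part <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  cls <- suppressWarnings(classify_reactions(net))
  keep <- cls == "proper"
  if (!any(keep)) stop("no proper reactions: the proper part would be empty")
  reaction_network(net$species, net$reactions[keep])
}

#' Reverse a reaction
#'
#' Swaps educts and products; the id gains the suffix `"__rev"` (or loses it,
#' so that reversing twice restores the original id).
#'
#' @param r a `reaction`
#' @return the reversed `reaction`
#' @export
reverse_reaction <- function(r) {
  stopifnot(inherits(r, "reaction"))
  new_id <- if (grepl("__rev$", r$id)) sub("__rev$", "", r$id) else paste0(r$id, "__rev")
  reaction(new_id, educts = r$products, products = r$educts,
           reversible = r$reversible, pair = r$id)
}

#' Composite and net reaction of an integer hyperflow
#'
#' `composite_reaction()` forms the literal sum of the participating
#' reactions' sides (no cancellation): for a flow `v >= 0`, the educt side
#' carries the coefficients `sum_r s-_{xr} v_r` and the product side
#' `sum_r s+_{xr} v_r`. `net_reaction()` cancels intermediates: the educt
#' side carries the negative parts of `S v` and the product side the positive
#' parts, so formal catalysts disappear.
#'
#' @param net a `reaction_network`
#' @param v integer vector over reactions. For `composite_reaction`, `v` must
#'   be non-negative. `net_reaction` also accepts signed entries, which stand
#'   for running the reverse reaction; negative entries are only admitted on
#'   reactions flagged reversible unless `allow_reverse = TRUE` (the
#'   reversible-completion reading of net isomerization vectors).
#' @param allow_reverse permit negative entries on irreversible reactions
#' @return list with named vectors `educts` and `products`
#' @export
composite_reaction <- function(net, v) {
  stopifnot(inherits(net, "reaction_network"))
  v <- .check_flow_vector(net, v)
  if (any(v < 0)) stop("not a flow: negative entries in v")
  ed <- stats::setNames(numeric(length(net$species)), net$species)
  pr <- ed
  for (j in seq_along(net$reactions)) {
    if (v[j] == 0) next
    r <- net$reactions[[j]]
    ed[names(r$educts)] <- ed[names(r$educts)] + v[j] * r$educts
    pr[names(r$products)] <- pr[names(r$products)] + v[j] * r$products
  }
  list(educts = ed[ed != 0], products = pr[pr != 0])
}

#' @rdname composite_reaction
#' @export
net_reaction <- function(net, v, allow_reverse = FALSE) {
  S <- as_stoich(net)
  v <- .check_flow_vector(net, v)
  if (any(v < 0) && !allow_reverse && inherits(net, "reaction_network")) {
    rev <- reversible_flags(net)
    bad <- which(v < 0 & !rev)
    if (length(bad)) {
      stop("negative flow entries on irreversible reaction(s): ",
           paste(colnames(S)[bad], collapse = ", "),
           " (set allow_reverse = TRUE for reversible-completion semantics)")
    }
  }
  sv <- as.vector(S %*% v)
  names(sv) <- rownames(S)
  list(educts = -sv[sv < 0], products = sv[sv > 0])
}

.check_flow_vector <- function(net, v) {
  n <- if (inherits(net, "reaction_network")) length(net$reactions) else ncol(net)
  if (length(v) != n) stop("flow vector has wrong length")
  if (any(v != round(v))) stop("flow vector must be integer")
  as.numeric(v)
}

#' Complex decomposition S = Y Z
#'
#' Collects the distinct complexes (educt and product sides) across all
#' reactions and factors the stoichiometric matrix into the complex matrix
#' `Y` (species x complexes) and the incidence matrix `Z` (complexes x
#' reactions) of the complex-reaction graph, with `Z[c, r] = -1` for the
#' educt complex and `+1` for the product complex of `r` (both zero when the
#' two sides coincide).
#'
#' @param net a `reaction_network`
#' @return list with `complexes` (list of named coefficient vectors), `Y`,
#'   and `Z`; the identity `Y %*% Z == stoichiometric_matrix(net)` holds
#'   exactly.
#' @export
complex_decomposition <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  key <- function(side) format_formal_sum(side[order(names(side))])
  complexes <- list()
  keys <- character(0)
  idx <- function(side) {
    k <- key(side)
    i <- match(k, keys)
    if (is.na(i)) {
      complexes[[length(complexes) + 1L]] <<- side
      keys <<- c(keys, k)
      i <- length(keys)
    }
    i
  }
  m <- length(net$reactions)
  ed_idx <- integer(m)
  pr_idx <- integer(m)
  for (j in seq_len(m)) {
    ed_idx[j] <- idx(net$reactions[[j]]$educts)
    pr_idx[j] <- idx(net$reactions[[j]]$products)
  }
  nc <- length(complexes)
  Y <- matrix(0, nrow = length(net$species), ncol = nc,
              dimnames = list(net$species, keys))
  for (i in seq_len(nc)) {
    side <- complexes[[i]]
    Y[names(side), i] <- side
  }
  Z <- matrix(0, nrow = nc, ncol = m, dimnames = list(keys, reaction_ids(net)))
  for (j in seq_len(m)) {
    if (ed_idx[j] != pr_idx[j]) {
      Z[ed_idx[j], j] <- -1
      Z[pr_idx[j], j] <- 1
    }
  }
  S <- stoichiometric_matrix(net)
  if (!identical(unname(Y %*% Z), unname(S))) {
    stop("internal error: Y Z != S")  # cannot happen for valid networks
  }
  list(complexes = stats::setNames(complexes, keys), Y = Y, Z = Z)
}

#' Extract a subnetwork
#'
#' Validates the closure condition of subnetworks: every reaction of the
#' parent whose support lies inside the kept species must itself be kept.
#'
#' @param net a `reaction_network`
#' @param species_subset character vector of species to keep
#' @param reaction_subset character vector of reaction ids to keep
#' @return a `reaction_network`
#' @export
subnetwork <- function(net, species_subset, reaction_subset) {
  stopifnot(inherits(net, "reaction_network"))
  if (!all(species_subset %in% net$species)) stop("unknown species in subset")
  ids <- reaction_ids(net)
  if (!all(reaction_subset %in% ids)) stop("unknown reaction ids in subset")
  for (r in net$reactions) {
    supp <- union(names(r$educts), names(r$products))
    if (all(supp %in% species_subset) && !(r$id %in% reaction_subset)) {
      stop("subnetwork closure violated: reaction ", r$id,
           " has support inside the species subset but is not included")
    }
  }
  keep <- net$reactions[ids %in% reaction_subset]
  reaction_network(net$species[net$species %in% species_subset], keep)
}

#' Support of a reaction
#' @param r a `reaction`
#' @return character vector of species appearing as educt, product or catalyst
#' @export
reaction_support <- function(r) union(names(r$educts), names(r$products))
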