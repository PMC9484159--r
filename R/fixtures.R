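# Built-in example networks. Each fixture records the network (as .rxn
# text), optional energies, the irreversible set, and the documented expected
# outcomes exercised in the test suite. The registry names follow the worked
# examples they reproduce: small abstract universes, a pair of textbook
# inorganic/organic reactions, the enzyme-driven substrate cycle from
# glycolysis/gluconeogenesis, and a synthetic formose-like aldol network.

.fixture_registry <- function() {
  list(
    # A <=> B -> C plus the shortcut A -> C; the reversible pair gives the
    # single futile cycle. With g = (1,-1,-3,-1) the two A-to-C routes carry
    # different energies (-2 vs -1), so these energies are not thermodynamic;
    # g3 = -2 repairs them.
    example10 = list(
      rxn = c("r1: A -> B", "r1b: B -> A", "r2: B -> C", "r3: A -> C"),
      rev_pairs = list(c("r1", "r1b")),
      irr = c("r2", "r3"),
      g = c(r1 = 1, r1b = -1, r2 = -3, r3 = -1)
    ),
    # A <=> B -> C -> A: two futile cycles, one through the irreversible part.
    # Sound in the lax sense (set g = 1/2 on the cycle) but not strictly.
    example15 = list(
      rxn = c("r1: A -> B", "r1b: B -> A", "r2: B -> C", "r3: C -> A"),
      rev_pairs = list(c("r1", "r1b")),
      irr = c("r2", "r3"),
      g = c(r1 = 1, r1b = -1, r2 = -0.5, r3 = -0.5)
    ),
    # four fully irreversible pair reactions whose sum is a futile cycle:
    # a particle-count-preserving artificial chemistry that admits a
    # perpetuum mobile and hence is not thermodynamically sound.
    eq9 = list(
      rxn = c("r1: A + B -> C + D", "r2: A + C -> E + B",
              "r3: B + D -> F + A", "r4: E + F -> A + B"),
      irr = c("r1", "r2", "r3", "r4")
    ),
    # two-reaction random-energies universe that spontaneously creates mass:
    # the composite of both reactions nets 0 -> X (a cornucopia).
    eq16 = list(
      rxn = c("r1: A + B -> C + X", "r2: C -> A + B"),
      irr = c("r1", "r2"),
      G = c(A = -5, B = -5, C = -10, X = -2)
    ),
    # MgCO3 -> MgO + CO2: two independent conservation laws, three atoms.
    eq18 = list(
      rxn = "r1: MgCO3 -> MgO + CO2",
      irr = "r1",
      atom_vectors = rbind(Mg = c(1, 1, 0), C = c(1, 0, 1), O = c(3, 1, 2))
    ),
    # hydroalkylation of toluene: 4 species, 1 reaction, 3 conservation laws
    # but only 2 atom types.
    eq19 = list(
      rxn = "r1: C6H5CH3 + H2 -> C6H6 + CH4",
      irr = "r1",
      atom_vectors = rbind(C = c(7, 0, 6, 1), H = c(8, 2, 6, 4))
    ),
    # same stoichiometric matrix realized inorganically, four atom laws.
    eq20 = list(
      rxn = "r1: MgO + H2SO4 -> MgSO4 + H2O",
      irr = "r1",
      atom_vectors = rbind(Mg = c(1, 0, 1, 0), O = c(1, 4, 4, 1),
                           H = c(0, 2, 0, 2), S = c(0, 1, 1, 0))
    ),
    # A + B -> 2 C: the minimal example with three minimal MCLs.
    eq23 = list(rxn = "r1: A + B -> 2 C", irr = "r1"),
    # dimerization square: U+V->X, U+W->Y, X+W->Z, Y+V->Z.
    eq26 = list(
      rxn = c("r1: U + V -> X", "r2: U + W -> Y",
              "r3: X + W -> Z", "r4: Y + V -> Z"),
      irr = c("r1", "r2", "r3", "r4"),
      species_order = c("U", "V", "W", "X", "Y", "Z")
    ),
    # eq26 extended by the three isomerizations U->V, V->W, U->W, collapsing
    # the kernel to dimension 1 (monomer/dimer/trimer structure).
    eq26_27 = list(
      rxn = c("r1: U + V -> X", "r2: U + W -> Y",
              "r3: X + W -> Z", "r4: Y + V -> Z",
              "r5: U -> V", "r6: V -> W", "r7: U -> W"),
      irr = paste0("r", 1:7),
      species_order = c("U", "V", "W", "X", "Y", "Z")
    ),
    # substrate cycle: S+E <=> ES -> E+P, P+F <=> FP -> F+S, with the two
    # catalytic steps irreversible. Thermodynamically sound but not strictly:
    # the non-trivial futile cycle (1,0,1,1,0,1) uses both irreversible
    # reactions.
    fig2_substrate_cycle = list(
      rxn = c("r1: S + E -> ES", "r2: ES -> S + E", "r3: ES -> E + P",
              "r4: P + F -> FP", "r5: FP -> P + F", "r6: FP -> F + S"),
      rev_pairs = list(c("r1", "r2"), c("r4", "r5")),
      irr = c("r3", "r6")
    )
  )
}

#' Built-in example networks
#'
#' Returns a registered fixture: the network, its irreversible set, and any
#' documented energies or atom-composition vectors. `fixture_names()` lists
#' the registry. The fixture `formose_synthetic` (see
#' [formose_like_network()]) is a generated stand-in for the formose
#' carbohydrate network and is labelled synthetic: it reproduces the
#' qualitative structure (aldol condensations among C1..C6 sugars, equal
#' carbon count forcing obligatory isomerism), not the published 29x38
#' matrix.
#'
#' @param name fixture name, see [fixture_names()]
#' @return list with `network`, `S`, `irr`, and optionally `g`, `G`,
#'   `atom_vectors`
#' @export
builtin_fixture <- function(name) {
  if (identical(name, "formose_synthetic")) {
    net <- formose_like_network()
    return(list(network = net, S = stoichiometric_matrix(net),
                irr = character(0)))
  }
  reg <- .fixture_registry()
  if (!name %in% names(reg)) {
    stop("unknown fixture '", name, "'; see fixture_names()")
  }
  fx <- reg[[name]]
  net <- parse_rxn(fx$rxn)
  # some fixtures fix the species order of the source figure explicitly
  if (!is.null(fx$species_order)) {
    stopifnot(setequal(fx$species_order, net$species))
    net$species <- fx$species_order
  }
  # mark declared reverse pairs as reversible
  if (!is.null(fx$rev_pairs)) {
    ids <- reaction_ids(net)
    for (p in fx$rev_pairs) {
      i <- match(p, ids)
      net$reactions[[i[1]]]$reversible <- TRUE
      net$reactions[[i[1]]]$pair <- p[2]
      net$reactions[[i[2]]]$reversible <- TRUE
      net$reactions[[i[2]]]$pair <- p[1]
    }
  }
  out <- list(network = net, S = stoichiometric_matrix(net), irr = fx$irr)
  for (f in c("g", "G", "atom_vectors")) if (!is.null(fx[[f]])) out[[f]] <- fx[[f]]
  if (!is.null(out$atom_vectors)) colnames(out$atom_vectors) <- net$species
  out
}

#' @rdname builtin_fixture
#' @export
fixture_names <- function() {
  c(names(.fixture_registry()), "formose_synthetic")
}

#' Synthetic formose-like aldol network
#'
#' A generated reversible network of aldol condensations
#' `Cn + Cm <-> C(n+m)` among linear sugars of 1..`max_c` carbons (several
#' isomers per carbon count, as in the formose reaction where e.g.
#' glycolaldehyde, glyceraldehyde and dihydroxyacetone appear). The carbon
#' count is the unique conserved moiety, so all same-carbon compounds are
#' obligatory isomers and every sum formula is a multiple of the C1 unit.
#' This object is synthetic: it mimics the structure of the published
#' formose network but not its exact species or reaction list.
#'
#' @param max_c largest carbon count (default 6)
#' @param isomers_per_size number of distinct isomer species per carbon
#'   count from C2 upward (default 3, capped by combinatorics)
#' @return a `reaction_network` (all reactions reversible, expanded pairs)
#' @export
formose_like_network <- function(max_c = 6L, isomers_per_size = 3L) {
  species <- "C1a"
  carbons <- c(1L)
  for (n in 2:max_c) {
    k <- min(isomers_per_size, n)  # a few isomers per size
    species <- c(species, paste0("C", n, letters[seq_len(k)]))
    carbons <- c(carbons, rep(n, k))
  }
  lines <- character(0)
  rid <- 0L
  by_size <- split(species, carbons)
  for (n in seq_len(max_c - 1L)) {
    for (m in n:(max_c - 1L)) {
      if (n + m > max_c) next
      for (a in by_size[[as.character(n)]]) {
        for (b in by_size[[as.character(m)]]) {
          if (n == m && b < a) next
          tgt <- by_size[[as.character(n + m)]]
          # connect to alternating targets so every isomer is reachable
          t1 <- tgt[1 + (rid %% length(tgt))]
          rid <- rid + 1L
          lhs <- if (a == b) paste("2", a) else paste(a, "+", b)
          lines <- c(lines, sprintf("r%02d: %s <=> %s", rid, lhs, t1))
        }
      }
    }
  }
  # isomerizations within each size keep all isomer groups connected
  for (n in 2:max_c) {
    grp <- by_size[[as.character(n)]]
    if (length(grp) < 2) next
    for (i in seq_len(length(grp) - 1L)) {
      rid <- rid + 1L
      lines <- c(lines, sprintf("r%02d: %s <=> %s", rid, grp[i], grp[i + 1L]))
    }
  }
  parse_rxn(lines)
}
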