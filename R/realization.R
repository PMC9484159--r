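# Sum-formula and structural-formula (Lewis) realizations. A sum-formula
# instance assigns atom counts to species such that every reaction balances
# atoms; a realization additionally spans the left kernel so that exactly the
# obligatory isomers share sum formulas. Lewis realizations turn each sum
# formula into a connected vertex-coloured multigraph with fixed valency per
# colour, loops standing for non-bonding electron pairs; reactions then only
# rearrange edges.

#' Validate a sum-formula instance
#'
#' Checks that `A` is a non-negative integer matrix (atoms x species) with
#' non-zero columns and `A %*% S == 0` (atom conservation in every reaction).
#'
#' @param net a `reaction_network` or stoichiometric matrix
#' @param A candidate matrix, atoms as rows, species as columns
#' @return list with `valid` and `problems` (character vector naming failing
#'   species columns / reactions)
#' @export
validate_sf_instance <- function(net, A) {
  S <- as_stoich(net)
  A <- rbind(A)
  if (ncol(A) != nrow(S)) stop("A must have one column per species")
  problems <- character(0)
  if (any(A < 0) || any(A != round(A))) {
    problems <- c(problems, "entries must be non-negative integers")
  }
  zc <- which(colSums(A) == 0)
  if (length(zc)) {
    problems <- c(problems, paste0("zero column for species ", rownames(S)[zc]))
  }
  AS <- A %*% S
  bad <- which(colSums(AS != 0) > 0)
  if (length(bad)) {
    problems <- c(problems, paste0("atom balance violated in reaction ",
                                   colnames(S)[bad]))
  }
  list(valid = length(problems) == 0, problems = problems)
}

#' Validate a sum-formula realization
#'
#' A realization is an instance whose rows span the left kernel of `S`
#' exactly, so that species get equal columns iff they are obligatory
#' isomers.
#'
#' @inheritParams validate_sf_instance
#' @return logical
#' @export
validate_sf_realization <- function(net, A) {
  S <- as_stoich(net)
  A <- rbind(A)
  if (!validate_sf_instance(S, A)$valid) return(FALSE)
  d <- nrow(S) - int_rank(S)
  int_rank(A) == d
}

#' Default sum-formula realization
#'
#' Returns the mm-representation (rows = all minimal MCLs) with canonical
#' moiety names; it is an sf-realization for every conservative network.
#' For a non-conservative network the error carries the cornucopia/abyss
#' certificate.
#'
#' @inheritParams validate_sf_instance
#' @return integer matrix (moieties x species)
#' @export
default_sf_realization <- function(net) {
  mm_representation(net)
}

# named column extraction that survives single-row matrices
sf_column <- function(A, x) {
  stats::setNames(A[, x], rownames(A))
}

#' Sum formula of a species under an atom matrix
#'
#' Hill-like deterministic formatting: atoms in row order of `A`, counts of
#' one omitted (`(2,0,1)` over atoms X,Y,Z prints as `"X2Z"`).
#'
#' @param A atom matrix with row names (atoms) and column names (species)
#' @param x species id or column index
#' @return string
#' @export
sum_formula <- function(A, x) {
  col <- A[, x]
  if (all(col == 0)) stop("zero column: species has no atoms")
  atoms <- rownames(A)
  if (is.null(atoms)) atoms <- paste0("M", seq_len(nrow(A)))
  parts <- ifelse(col == 0, "",
                  ifelse(col == 1, atoms, paste0(atoms, col)))
  paste(parts, collapse = "")
}

#' Pairwise inequivalent sum-formula realizations
#'
#' Two realizations are equivalent when they are integer-proportional
#' (`p A == q A'`). For `dim ker t(S) > 1` infinitely many inequivalent
#' realizations exist: scale `k` linearly independent minimal MCLs by
#' distinct primes. This returns `count` of them (the first is the plain
#' independent-MCL matrix); pairwise inequivalence is verified.
#'
#' @inheritParams validate_sf_instance
#' @param count number of realizations requested
#' @return list of integer matrices
#' @export
inequivalent_sf_realizations <- function(net, count = 2L) {
  S <- as_stoich(net)
  M <- mm_representation(S)
  d <- nrow(S) - int_rank(S)
  if (d <= 1) {
    if (count == 1) return(list(M))
    stop("dim ker t(S) <= 1: all sf-realizations are equivalent")
  }
  # greedily pick d linearly independent rows of the mm-representation
  pick <- integer(0)
  for (i in seq_len(nrow(M))) {
    if (int_rank(M[c(pick, i), , drop = FALSE]) > length(pick)) pick <- c(pick, i)
    if (length(pick) == d) break
  }
  Y <- M[pick, , drop = FALSE]
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53, 59,
              61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107, 109, 113)
  out <- vector("list", count)
  out[[1]] <- Y
  pi <- 0L
  for (j in seq_len(count - 1L)) {
    if (pi + d > length(primes)) stop("count too large for the built-in prime table")
    t <- primes[pi + seq_len(d)]
    pi <- pi + d
    out[[j + 1L]] <- Y * t  # row i scaled by t[i] (column recycling over rows)
  }
  for (j in seq_along(out)) {
    rownames(out[[j]]) <- paste0("A", seq_len(d))
    stopifnot(validate_sf_realization(S, out[[j]]))
  }
  for (i in seq_along(out)) {
    for (j in seq_len(i - 1L)) {
      if (.sf_equivalent(out[[i]], out[[j]])) stop("internal error: equivalent pair")
    }
  }
  out
}

.sf_equivalent <- function(A, B) {
  if (!all(dim(A) == dim(B))) return(FALSE)
  nzA <- which(A != 0)
  nzB <- which(B != 0)
  if (!identical(nzA, nzB)) return(FALSE)
  if (length(nzA) == 0) return(TRUE)
  i <- nzA[1]
  all(B[i] * A == A[i] * B)
}

# --- coloured multigraphs --------------------------------------------------

#' Construct a vertex-coloured multigraph
#'
#' @param colors character vector: the atom/moiety colour of each vertex
#' @param adj symmetric non-negative integer matrix; off-diagonal entries
#'   count parallel edges, diagonal entries count loops (each loop adds two
#'   to its vertex degree)
#' @param val named integer vector: valency per colour
#' @return object of class `multigraph`
#' @export
multigraph <- function(colors, adj, val) {
  n <- length(colors)
  adj <- rbind(adj)
  stopifnot(nrow(adj) == n, ncol(adj) == n, all(adj == t(adj)),
            all(adj >= 0), all(adj == round(adj)))
  if (!all(colors %in% names(val))) stop("every colour needs a valency")
  structure(list(colors = colors, adj = adj, val = val), class = "multigraph")
}

#' @rdname multigraph
#' @param g a `multigraph`
#' @return `multigraph_degrees`: integer vector of vertex degrees
#' @export
multigraph_degrees <- function(g) {
  d <- rowSums(g$adj) + diag(g$adj)  # loops count twice
  as.numeric(d)
}

#' @rdname multigraph
#' @return `multigraph_edge_count`: number of edges, loops counted once
#' @export
multigraph_edge_count <- function(g) {
  (sum(g$adj) - sum(diag(g$adj))) / 2 + sum(diag(g$adj))
}

#' @rdname multigraph
#' @return `multigraph_connected`: logical
#' @export
multigraph_connected <- function(g) {
  n <- length(g$colors)
  if (n <= 1) return(TRUE)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(g$adj[u, ] > 0 & !seen)
    nb <- nb[nb != u]
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' @export
print.multigraph <- function(x, ...) {
  cat(sprintf("Coloured multigraph: %d vertices (%s), %d edges\n",
              length(x$colors),
              paste(sprintf("%s:%d", names(table(x$colors)), table(x$colors)),
                    collapse = ", "),
              multigraph_edge_count(x)))
  invisible(x)
}

#' Structural formula of a sum formula (cycle construction)
#'
#' Builds the canonical valency-`2k` structural formula: a single moiety
#' becomes one vertex with `k` loops; otherwise all atoms are arranged in a
#' cycle (an edge between consecutive vertices, or a double edge for exactly
#' two atoms) with `k - 1` extra loops per vertex. The result is connected
#' with all degrees equal to `2k`.
#'
#' @param formula named non-negative integer vector of atom counts
#' @param k half-valency; all colours get valency `2k`
#' @return a `multigraph`
#' @export
cycle_structural_formula <- function(formula, k = 1L) {
  formula <- formula[formula > 0]
  if (length(formula) == 0) stop("empty sum formula")
  if (any(formula != round(formula))) stop("atom counts must be integer")
  atoms <- rep(names(formula), times = formula)
  n <- length(atoms)
  val <- stats::setNames(rep(2 * k, length(formula)), names(formula))
  adj <- matrix(0, n, n)
  if (n == 1) {
    adj[1, 1] <- k
  } else if (n == 2) {
    adj[1, 2] <- adj[2, 1] <- 2
    diag(adj) <- k - 1
  } else {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      adj[i, j] <- adj[i, j] + 1
      adj[j, i] <- adj[i, j]
    }
    diag(adj) <- k - 1
  }
  g <- multigraph(atoms, adj, val)
  stopifnot(all(multigraph_degrees(g) == 2 * k), multigraph_connected(g))
  g
}

#' Coloured multigraph isomorphism
#'
#' Exact isomorphism of loops-and-multiplicities multigraphs respecting
#' vertex colours, by backtracking over colour- and degree-compatible vertex
#' assignments. Intended for the small near-cyclic graphs generated here.
#'
#' @param g1,g2 `multigraph` objects with identical valency functions
#' @return logical
#' @export
multigraph_isomorphic <- function(g1, g2) {
  n <- length(g1$colors)
  if (length(g2$colors) != n) return(FALSE)
  inv <- function(g) paste(g$colors, multigraph_degrees(g), diag(g$adj))
  if (!identical(sort(inv(g1)), sort(inv(g2)))) return(FALSE)
  A1 <- g1$adj; A2 <- g2$adj
  key1 <- inv(g1); key2 <- inv(g2)
  map <- integer(n)            # map[i] = vertex of g2 matched to i of g1
  used <- logical(n)
  bt <- function(i) {
    if (i > n) return(TRUE)
    for (cand in which(!used & key2 == key1[i])) {
      ok <- TRUE
      for (j in seq_len(i - 1L)) {
        if (A1[i, j] != A2[cand, map[j]]) { ok <- FALSE; break }
      }
      if (A1[i, i] != A2[cand, cand]) ok <- FALSE
      if (ok) {
        map[i] <<- cand
        used[cand] <<- TRUE
        if (bt(i + 1L)) return(TRUE)
        used[cand] <<- FALSE
      }
    }
    FALSE
  }
  bt(1L)
}

#' Lewis realization of a conservative network
#'
#' Assigns to each species the cycle structural formula (valency 2) of its
#' column in the default sf-realization. The resulting map is a Lewis
#' realization: colour counts reproduce the sf-realization and every
#' reaction balances both per-colour vertex counts and total edge counts.
#'
#' @inheritParams validate_sf_instance
#' @return list of class `lewis_realization`: `graphs` (named list of
#'   `multigraph`s), `A` (the sf matrix), `val`
#' @export
lewis_realization <- function(net) {
  S <- as_stoich(net)
  A <- default_sf_realization(S)
  graphs <- lapply(colnames(A), function(x) cycle_structural_formula(sf_column(A, x), k = 1L))
  names(graphs) <- colnames(A)
  out <- structure(list(graphs = graphs, A = A,
                        val = stats::setNames(rep(2, nrow(A)), rownames(A))),
                   class = "lewis_realization")
  rep <- validate_lewis_realization(net, out)
  stopifnot(rep$valid)
  out
}

# Crossing-free partial matchings of positions 1..n on a circle, in canonical
# order (by number of pairs, then lexicographically by pairs). Each matching
# is a 2-column matrix of position pairs.
noncrossing_matchings <- function(n, need) {
  out <- list(matrix(0L, 0, 2))  # empty matching = base pattern
  if (n < 2) return(out)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  crossing <- function(a, b) {
    (a[1] < b[1] && b[1] < a[2] && a[2] < b[2]) ||
      (b[1] < a[1] && a[1] < b[2] && b[2] < a[2])
  }
  grow <- function(mat, start) {
    if (length(out) >= need) return()
    for (p in seq.int(start, length.out = max(0L, nrow(pairs) - start + 1L))) {
      cand <- pairs[p, ]
      if (any(cand %in% mat)) next
      ok <- TRUE
      if (nrow(rbind(mat))) {
        for (q in seq_len(nrow(mat))) {
          if (crossing(mat[q, ], cand)) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      m2 <- rbind(mat, cand)
      out[[length(out) + 1L]] <<- m2
      if (length(out) >= need) return()
      grow(m2, p + 1L)
    }
  }
  grow(matrix(0L, 0, 2), 1L)
  out
}

#' Injective Lewis realization
#'
#' Constructs a Lewis realization (valency 4 everywhere) in which all species
#' receive pairwise non-isomorphic multigraphs, including within classes of
#' obligatory isomers (which necessarily share sum formulas). Each species
#' starts from a cycle with one loop per vertex; the members of an isomer
#' class are then distinguished by converting pairs of loops into double
#' edges along distinct crossing-free matchings of cycle positions, verified
#' non-isomorphic. If a class is too large for the current vertex count, the
#' whole sf-realization is scaled by an integer factor (which preserves the
#' realization property) until enough patterns exist.
#'
#' @inheritParams validate_sf_instance
#' @return a `lewis_realization` with pairwise non-isomorphic graphs
#' @export
injective_lewis_realization <- function(net) {
  S <- as_stoich(net)
  A0 <- default_sf_realization(S)
  classes <- isomer_classes(S)$classes
  scale <- 1L
  repeat {
    A <- A0 * scale
    graphs <- .injective_graphs_attempt(A, classes)
    if (!is.null(graphs)) break
    scale <- scale * 2L
    if (scale > 2^12) stop("internal error: could not realize isomer classes")
  }
  out <- structure(list(graphs = graphs, A = A,
                        val = stats::setNames(rep(4, nrow(A)), rownames(A))),
                   class = "lewis_realization")
  rep <- validate_lewis_realization(net, out)
  stopifnot(rep$valid)
  for (i in seq_along(graphs)) {
    for (j in seq_len(i - 1L)) {
      stopifnot(!multigraph_isomorphic(graphs[[i]], graphs[[j]]))
    }
  }
  out
}

.injective_graphs_attempt <- function(A, classes) {
  graphs <- vector("list", ncol(A))
  names(graphs) <- colnames(A)
  for (cl in classes) {
    base <- cycle_structural_formula(sf_column(A, cl[1]), k = 2L)
    n <- length(base$colors)
    if (length(cl) > 1 && n < 2) return(NULL)
    variants <- list()
    matchings <- noncrossing_matchings(n, need = 4L * length(cl) + 8L)
    for (m in matchings) {
      g <- base
      if (nrow(m)) {
        for (q in seq_len(nrow(m))) {
          u <- m[q, 1]; v <- m[q, 2]
          if (g$adj[u, u] < 1 || g$adj[v, v] < 1) next
          g$adj[u, u] <- g$adj[u, u] - 1
          g$adj[v, v] <- g$adj[v, v] - 1
          g$adj[u, v] <- g$adj[u, v] + 2
          g$adj[v, u] <- g$adj[u, v]
        }
      }
      if (!all(multigraph_degrees(g) == 4) || !multigraph_connected(g)) next
      new <- TRUE
      for (h in variants) if (multigraph_isomorphic(g, h)) { new <- FALSE; break }
      if (new) variants[[length(variants) + 1L]] <- g
      if (length(variants) == length(cl)) break
    }
    if (length(variants) < length(cl)) return(NULL)
    for (i in seq_along(cl)) graphs[[cl[i]]] <- variants[[i]]
  }
  graphs
}

#' Validate a Lewis instance/realization
#'
#' Checks, per species, the structural-formula conditions (colour counts
#' match the sf matrix, all degrees equal the colour valency, connectivity),
#' and per reaction, that per-colour vertex counts balance (`A S` column
#' zero) and that the total edge count (loops counted once) of the educt
#' multiset equals that of the product multiset.
#'
#' @param net a `reaction_network`
#' @param L a `lewis_realization`
#' @return list with `valid` and `problems`
#' @export
validate_lewis_realization <- function(net, L) {
  S <- as_stoich(net)
  problems <- character(0)
  if (!all(rownames(S) %in% names(L$graphs))) {
    problems <- c(problems, "not all species have graphs")
  } else {
    for (x in rownames(S)) {
      g <- L$graphs[[x]]
      counts <- table(factor(g$colors, levels = rownames(L$A)))
      if (!all(counts == L$A[, x])) {
        problems <- c(problems, paste0("colour counts of ", x, " do not match A"))
      }
      d <- multigraph_degrees(g)
      bad <- which(d != L$val[g$colors])
      if (length(bad)) {
        problems <- c(problems,
                      paste0("degree mismatch in ", x, " at vertex ", bad[1]))
      }
      if (!multigraph_connected(g)) {
        problems <- c(problems, paste0("graph of ", x, " is disconnected"))
      }
    }
    inst <- validate_sf_instance(S, L$A)
    if (!inst$valid) problems <- c(problems, inst$problems)
    edges <- vapply(rownames(S),
                    function(x) multigraph_edge_count(L$graphs[[x]]), numeric(1))
    if (inherits(net, "reaction_network")) {
      for (r in net$reactions) {
        e_ed <- sum(r$educts * edges[names(r$educts)])
        e_pr <- sum(r$products * edges[names(r$products)])
        if (e_ed != e_pr) {
          problems <- c(problems, paste0("edge count not conserved in ", r$id))
        }
      }
    } else {
      # from the matrix: compare via net column (catalysts cancel on both sides)
      for (j in seq_len(ncol(S))) {
        if (sum(edges * S[, j]) != 0) {
          problems <- c(problems,
                        paste0("edge count not conserved in ", colnames(S)[j]))
        }
      }
    }
  }
  list(valid = length(problems) == 0, problems = problems)
}

#' Export a multigraph
#'
#' `write_graphml()` writes GraphML with loops as self-edges, parallel edges
#' as separate elements, and colour/valency as attributes. `format_edgelist()`
#' renders a plain text edge list.
#'
#' @param g a `multigraph`
#' @param path output file
#' @return `write_graphml`: the path, invisibly
#' @export
write_graphml <- function(g, path) {
  n <- length(g$colors)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="color" for="node" attr.name="color" attr.type="string"/>',
    '  <key id="valency" for="node" attr.name="valency" attr.type="int"/>',
    '  <graph edgedefault="undirected">')
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      '    <node id="v%d"><data key="color">%s</data><data key="valency">%d</data></node>',
      i, g$colors[i], g$val[g$colors[i]]))
  }
  eid <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      mult <- if (i == j) g$adj[i, i] else g$adj[i, j]
      for (k in seq_len(mult)) {
        eid <- eid + 1L
        lines <- c(lines, sprintf('    <edge id="e%d" source="v%d" target="v%d"/>',
                                  eid, i, j))
      }
    }
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graphml
#' @return `format_edgelist`: character vector of `"u -- v"` lines (loops as
#'   `"u -- u"`), one per edge
#' @export
format_edgelist <- function(g) {
  n <- length(g$colors)
  out <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      mult <- if (i == j) g$adj[i, i] else g$adj[i, j]
      out <- c(out, rep(sprintf("%d[%s] -- %d[%s]", i, g$colors[i], j, g$colors[j]),
                        mult))
    }
  }
  out
}

#' @export
print.lewis_realization <- function(x, ...) {
  cat(sprintf("Lewis realization: %d species, %d moieties, valency %s\n",
              length(x$graphs), nrow(x$A),
              paste(unique(x$val), collapse = "/")))
  for (nm in names(x$graphs)) {
    cat(sprintf("  %s = %s: %d vertices, %d edges\n", nm, sum_formula(x$A, nm),
                length(x$graphs[[nm]]$colors),
                multigraph_edge_count(x$graphs[[nm]])))
  }
  invisible(x)
}
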