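# Text formats: the .rxn reaction-equation format, TSV stoichiometric
# matrices, and TSV energy vectors.

#' Parse the plain-text reaction format
#'
#' One reaction per line: `id: 2 A + B -> C` (irreversible) or
#' `id: A <=> B` (reversible; expanded into the two opposite columns `id`
#' and `id__rev`, both flagged reversible and linked as a pair). Coefficients
#' default to 1; the empty complex is written `0` (also accepted:
#' the empty-set sign), so `b1: 0 -> A` is an import reaction. `#` starts a
#' comment; blank lines are ignored. Species order is first appearance.
#'
#' @param text character vector of lines, or a single string with newlines
#' @return a `reaction_network`
#' @export
parse_rxn <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  species <- character(0)
  reactions <- list()
  ids <- character(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    m <- regmatches(line, regexec("^([^:]+):(.*)$", line))[[1]]
    if (length(m) != 3) stop("line ", ln, ": expected 'id: educts -> products'")
    id <- trimws(m[2])
    body <- m[3]
    reversible <- grepl("<=>", body, fixed = TRUE)
    arrow <- if (reversible) "<=>" else "->"
    sides <- strsplit(body, arrow, fixed = TRUE)[[1]]
    if (length(sides) != 2) stop("line ", ln, ": expected exactly one '", arrow, "'")
    parse_side <- function(s) {
      s <- trimws(s)
      if (!nzchar(s)) stop("line ", ln, ": empty side (use '0' for the empty complex)")
      if (s %in% c("0", "∅")) return(stats::setNames(numeric(0), character(0)))
      terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
      coeffs <- numeric(0)
      for (t in terms) {
        if (!nzchar(t)) stop("line ", ln, ": empty term")
        tm <- regmatches(t, regexec("^([0-9]+)?\\s*(\\S+)$", t))[[1]]
        if (length(tm) != 3 || !nzchar(tm[3])) stop("line ", ln, ": bad term '", t, "'")
        cnt <- if (nzchar(tm[2])) as.numeric(tm[2]) else 1
        sp <- tm[3]
        if (!(sp %in% species)) species <<- c(species, sp)
        coeffs[sp] <- (if (sp %in% names(coeffs)) coeffs[sp] else 0) + cnt
      }
      coeffs
    }
    ed <- parse_side(sides[1])
    pr <- parse_side(sides[2])
    if (id %in% ids) stop("line ", ln, ": duplicate reaction id '", id, "'")
    ids <- c(ids, id)
    if (reversible) {
      rid <- paste0(id, "__rev")
      if (rid %in% ids) stop("line ", ln, ": duplicate reaction id '", rid, "'")
      ids <- c(ids, rid)
      reactions[[length(reactions) + 1L]] <-
        reaction(id, ed, pr, reversible = TRUE, pair = rid)
      reactions[[length(reactions) + 1L]] <-
        reaction(rid, pr, ed, reversible = TRUE, pair = id)
    } else {
      reactions[[length(reactions) + 1L]] <- reaction(id, ed, pr)
    }
  }
  if (length(reactions) == 0) stop("no reactions found")
  reaction_network(species, reactions)
}

#' Write a network in the .rxn format
#'
#' Reversible pairs created by [parse_rxn()] are re-merged into a single
#' `<=>` line, so `parse_rxn(format_rxn(net))` reproduces `net` exactly on
#' canonical input.
#'
#' @param net a `reaction_network`
#' @return character vector of lines
#' @export
format_rxn <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  ids <- reaction_ids(net)
  skip <- logical(length(ids))
  out <- character(0)
  for (i in seq_along(ids)) {
    if (skip[i]) next
    r <- net$reactions[[i]]
    arrow <- "->"
    if (r$reversible && !is.na(r$pair)) {
      j <- match(r$pair, ids)
      if (!is.na(j) && identical(net$reactions[[j]]$pair, r$id)) {
        skip[j] <- TRUE
        arrow <- "<=>"
      }
    }
    out <- c(out, sprintf("%s: %s %s %s", r$id, format_formal_sum(r$educts),
                          arrow, format_formal_sum(r$products)))
  }
  out
}

#' Read a stoichiometric matrix from TSV
#'
#' Expects reaction ids in the first row and species ids in the first
#' column; the delimiter (tab or general whitespace) and the presence of a
#' corner label are auto-detected. Cells must be integers. Reversibility is
#' supplied as a sidecar vector of irreversible reaction ids (default: all
#' reactions irreversible).
#'
#' @param path file path
#' @param irreversible_ids character vector of irreversible reaction ids, or
#'   `NULL` for all
#' @return list with `S` (labelled integer matrix) and `irr` (character ids)
#' @export
read_stoichiometry_tsv <- function(path, irreversible_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("matrix file needs a header and at least one row")
  sep <- if (grepl("\t", lines[1])) "\t" else "[[:space:]]+"
  split1 <- function(x) {
    parts <- strsplit(trimws(x), sep)[[1]]
    parts[nzchar(parts)]
  }
  header <- split1(lines[1])
  first <- split1(lines[2])
  # corner label present when the header is as wide as a data row
  has_corner <- length(header) == length(first)
  rxn_ids <- if (has_corner) header[-1] else header
  n <- length(rxn_ids)
  rows <- lapply(lines[-1], split1)
  if (any(vapply(rows, length, integer(1)) != n + 1)) {
    stop("ragged rows in matrix file")
  }
  sp <- vapply(rows, `[[`, character(1), 1)
  vals <- suppressWarnings(lapply(rows, function(r) as.numeric(r[-1])))
  S <- do.call(rbind, vals)
  if (any(is.na(S)) || any(S != round(S))) {
    stop("non-integer cell in matrix file")
  }
  dimnames(S) <- list(sp, rxn_ids)
  if (nrow(S) > ncol(S)) {
    warning("more species than reactions; check that the file is not transposed")
  }
  if (any(colSums(S != 0) == 0)) warning("null reaction (all-zero column) in matrix")
  irr <- if (is.null(irreversible_ids)) rxn_ids else as.character(irreversible_ids)
  if (!all(irr %in% rxn_ids)) stop("unknown reaction id among irreversible_ids")
  list(S = S, irr = irr)
}

#' Write a stoichiometric matrix as TSV
#' @param S labelled integer matrix
#' @param path file path
#' @return the path, invisibly
#' @export
write_stoichiometry_tsv <- function(S, path) {
  utils::write.table(S, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read or write an energies vector (two-column TSV: id, value)
#'
#' @param path file path
#' @return named numeric vector
#' @export
read_energies_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("id", "value"),
                         colClasses = c("character", "numeric"))
  stats::setNames(d$value, d$id)
}

#' @rdname read_energies_tsv
#' @param x named numeric vector
#' @export
write_energies_tsv <- function(x, path) {
  utils::write.table(data.frame(id = names(x), value = unname(x)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Build a network from a bare stoichiometric matrix
#'
#' Uses the minimal educt/product split (no catalysts); columns listed in
#' `irr` are marked non-reversible, the rest reversible (without expanding
#' explicit reverse columns).
#'
#' @param S labelled integer matrix
#' @param irr character ids or indices of irreversible reactions (default
#'   all)
#' @return a `reaction_network`
#' @export
network_from_matrix <- function(S, irr = NULL) {
  S <- as_stoich(S)
  irr_idx <- .irr_indices(NULL, S, if (is.null(irr)) colnames(S) else irr)
  reactions <- lapply(seq_len(ncol(S)), function(j) {
    col <- S[, j]
    reaction(colnames(S)[j],
             educts = -col[col < 0], products = col[col > 0],
             reversible = !(j %in% irr_idx))
  })
  reaction_network(rownames(S), reactions)
}
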