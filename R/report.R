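# Aggregate analysis: one call that runs every certificate-producing check
# and collects the results into a structured, JSON-serializable report.

#' Full chemistry-likeness analysis
#'
#' Runs the complete battery on a network: classification and closedness,
#' conservativity (with positive law or cornucopia certificate), lax and
#' strict thermodynamic soundness (with energy witness or futile-cycle
#' certificate), left-kernel dimension, minimal MCLs, and obligatory isomer
#' classes. Import/export reactions are excluded first (the theory addresses
#' the proper part of an open network); the report records how many were
#' dropped. A network counts as chemistry-like when its proper part is
#' conservative and thermodynamically sound in the lax sense.
#'
#' @param net a `reaction_network` or stoichiometric matrix
#' @param irr irreversible reactions (ids or indices); defaults as in
#'   [thermodynamic_soundness()]
#' @param gamma witness scale for strict soundness
#' @param mcl_cap guard for the minimal-MCL enumeration
#' @return an `analysis_report` list
#' @export
analyze_network <- function(net, irr = NULL, gamma = 1000, mcl_cap = 200000L) {
  S_full <- as_stoich(net)
  irr_idx <- .irr_indices(net, S_full, irr)
  cls <- suppressWarnings(classify_reactions(S_full))
  closed <- all(cls == "proper")
  keep <- which(cls == "proper")
  if (length(keep) == 0) stop("no proper reactions: nothing to analyze")
  S <- S_full[, keep, drop = FALSE]
  irr_ids <- intersect(colnames(S_full)[irr_idx], colnames(S))

  cons <- conservativity(S)
  lax <- thermodynamic_soundness(S, irr = irr_ids)
  strict <- strict_soundness(S, irr = irr_ids, gamma = gamma)
  B <- left_kernel_basis(S)
  mcl <- minimal_mcls(S, cap = mcl_cap)
  iso <- isomer_classes(S)
  fc <- futile_cycles(if (inherits(net, "reaction_network") && closed) net else S)

  structure(list(
    n_species = nrow(S_full),
    n_reactions = ncol(S_full),
    closed = closed,
    classification = cls,
    n_proper = length(keep),
    conservativity = cons,
    soundness_lax = lax,
    soundness_strict = strict,
    kernel_dim = nrow(B),
    kernel_basis = B,
    minimal_mcls = mcl$mcls,
    mcl_truncated = mcl$truncated,
    isomer_classes = iso$classes,
    inert_species = iso$inert,
    futile_cycles = fc,
    chemistry_like = cons$conservative && lax$sound
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Network: %d species, %d reactions (%d proper)%s\n",
              x$n_species, x$n_reactions, x$n_proper,
              if (x$closed) ", closed" else ", open (analysis on proper part)"))
  print(x$conservativity)
  print(x$soundness_lax)
  print(x$soundness_strict)
  cat(sprintf("dim ker t(S) = %d; %d minimal MCL(s)%s\n", x$kernel_dim,
              nrow(x$minimal_mcls), if (x$mcl_truncated) " (truncated)" else ""))
  cls <- vapply(x$isomer_classes, paste, character(1), collapse = ",")
  cat("Obligatory isomer classes:", paste0("{", cls, "}", collapse = " "), "\n")
  nt <- sum(!x$futile_cycles$trivial)
  cat(sprintf("Futile cycles: %d (%d non-trivial)\n",
              nrow(x$futile_cycles$cycles), nt))
  cat("Chemistry-like:", if (x$chemistry_like) "YES" else "NO", "\n")
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Vectors are serialized as label:value maps; the schema is versioned.
#'
#' @param x an `analysis_report`
#' @return JSON string
#' @export
report_to_json <- function(x) {
  stopifnot(inherits(x, "analysis_report"))
  vecmap <- function(v) if (is.null(v)) NULL else as.list(v[v != 0])
  cons <- x$conservativity
  out <- list(
    schema = "chemlike-report/1",
    species = x$n_species,
    reactions = x$n_reactions,
    proper = x$n_proper,
    closed = x$closed,
    conservative = cons$conservative,
    conservativity_certificate = if (cons$conservative) {
      list(kind = "conservation_law", m = as.list(cons$m))
    } else {
      list(kind = "cornucopia", v = vecmap(cons$v))
    },
    sound_lax = x$soundness_lax$sound,
    sound_lax_certificate = if (x$soundness_lax$sound) {
      list(kind = "witness_g", g = as.list(x$soundness_lax$witness_g))
    } else {
      list(kind = "futile_cycle", v = vecmap(x$soundness_lax$certificate))
    },
    sound_strict = x$soundness_strict$sound,
    sound_strict_certificate = if (x$soundness_strict$sound) {
      list(kind = "witness_g", g = as.list(x$soundness_strict$witness_g),
           gamma = x$soundness_strict$gamma_used)
    } else {
      list(kind = "futile_cycle", v = vecmap(x$soundness_strict$certificate))
    },
    kernel_dim = x$kernel_dim,
    minimal_mcl_count = nrow(x$minimal_mcls),
    isomer_classes = x$isomer_classes,
    chemistry_like = x$chemistry_like
  )
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
}
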