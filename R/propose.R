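#' Propose a unified name for a new variant sequence
#'
#' Composes the sequence diagnostics into a naming suggestion following the
#' default rule for new variants: assign the family by nearest reference in
#' the panel, then suggest the smallest free paralog number among the
#' registry's unified names scoped to the organism. Letter suffixes and
#' prefixes are never invented -- those call for phylogenetic judgement. A
#' canonical C-terminal SQ(E/D)\eqn{\Phi} motif is reported as H2A.X-like
#' evidence but does not change the numeric suggestion.
#'
#' @param seq A sequence string or record with a `sequence` field.
#' @param organism Organism label used to scope existing names.
#' @param registry A registry tibble; default the bundled one.
#' @param panel Reference panel (`id`, `family`, `sequence`).
#' @param scoring An [alignment_scoring()] scheme.
#' @return A list of class `hv_name_proposal`: `suggestion` (a
#'   `histone_name`), `family`, `evidence` (character vector), `motif`
#'   (the `hv_motif_call`), and `scores` (per-reference score table).
#' @export
propose_name <- function(seq, organism, registry = default_registry(),
                         panel, scoring = alignment_scoring()) {
  fam_call <- assign_family(seq, panel, scoring)
  family <- fam_call$family
  evidence <- sprintf("family %s by best global-alignment score (reference %s, score %g)",
                      family, fam_call$best_id, fam_call$scores$score[1])
  motif <- detect_h2ax_motif(seq)
  if (motif$status == "canonical") {
    evidence <- c(evidence,
                  sprintf("H2A.X-like terminal motif (%s)", motif$matched_window))
  } else if (motif$status == "noncanonical") {
    evidence <- c(evidence,
                  sprintf("noncanonical SQ-x-hydrophobic terminal window (%s)",
                          motif$matched_window))
  }
  scoped <- registry[scope_matches(registry$organism_scope, organism), ,
                     drop = FALSE]
  existing <- unique(scoped$unified_name)
  suggestion <- suggest_paralog_number(family, existing = existing)
  evidence <- c(evidence,
                sprintf("smallest free paralog number among %d %s name(s) scoped to '%s'",
                        sum(vapply(existing, function(x)
                          tryCatch(as_histone_name(x, "lenient")$family == family,
                                   error = function(e) FALSE), logical(1))),
                        family, organism))
  structure(list(suggestion = suggestion, family = family,
                 evidence = evidence, motif = motif, scores = fam_call$scores),
            class = "hv_name_proposal")
}

#' @export
print.hv_name_proposal <- function(x, ...) {
  cat("<name_proposal> ", format_histone_name(x$suggestion), "\n", sep = "")
  for (e in x$evidence) cat("  - ", e, "\n", sep = "")
  invisible(x)
}
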