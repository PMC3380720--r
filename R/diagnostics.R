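## Bundled diagnostic residue table for 'H3.3'-class and 'H2A.X'-class calls.
## Replication-independent (RI) and replication-coupled (RC) H3 variants in an
## organism typically differ at residue 31 and in the residue 85-89 window;
## H2A.X-class variants carry a C-terminal SQ(E/D)-hydrophobic phospho motif.

#' Diagnostic residue table for H3 class calls
#'
#' One row per organism/variant with the residue-31 string and the residue
#' (85)86-89 window that separate replication-independent (RI, the `H3.3`
#' usage) from replication-coupled (RC) H3 variants in that organism. Labels
#' carrying a trailing `?` mark organisms where the assignment is uncertain;
#' their class is `uncertain`. The distinguishing residues vary across
#' kingdoms, which is why calls outside the tabulated organisms fall back to
#' a flagged heuristic rather than a confident label.
#'
#' @return A tibble with columns `kingdom`, `organism`, `variant_label`,
#'   `uncertain`, `residue31`, `window_85_89`, `class`.
#' @export
#' @examples
#' h3_diagnostic_rows()
h3_diagnostic_rows <- function() {
  rows <- tibble::tribble(
    ~kingdom,       ~organism,        ~variant_label, ~residue31, ~window_85_89, ~class,
    "Animals",      "Homo",           "H3.3",         "S",        "AAIG",        "RI_like",
    "Animals",      "Homo",           "H3.2",         "A",        "SAVM",        "RC_like",
    "Fungi",        "Saccharomyces",  "H3",           "S",        "SAIG",        "RI_like",
    "Plants",       "Arabidopsis",    "H3.3",         "T",        "HAVL",        "RI_like",
    "Plants",       "Arabidopsis",    "H3.1",         "A",        "SAVA",        "RC_like",
    "Rhodophytes",  "Porphyra",       "H3.3?",        "S-",       "TAVL",        "uncertain",
    "Rhodophytes",  "Porphyra",       "H3.1?",        "VG",       "SAVL",        "uncertain",
    "Alveolates",   "Tetrahymena",    "H3.3",         "VS",       "QAIL",        "RI_like",
    "Alveolates",   "Tetrahymena",    "H3.1",         "AT",       "SAVL",        "RC_like",
    "Heterokonts",  "Thalassiosira",  "H3.3?",        "TA",       "STAVL",       "uncertain",
    "Heterokonts",  "Thalassiosira",  "H3.1?",        "AT",       "GSAVL",       "uncertain",
    "Amoebozoa",    "Dictyostelium",  "H3.3?",        "STQP",     "AAIQ",        "uncertain",
    "Amoebozoa",    "Dictyostelium",  "H3.1?",        "VNEV",     "AAIE",        "uncertain",
    "Excavates",    "Euglena",        "H3",           "A",        "NAIL",        "unknown"
  )
  rows$uncertain <- endsWith(rows$variant_label, "?")
  rows[, c("kingdom", "organism", "variant_label", "uncertain",
           "residue31", "window_85_89", "class")]
}

#' Diagnostic C-terminal fragments for H2A.X class calls
#'
#' One row per organism/variant with the printed C-terminal fragment
#' (the region from roughly residue 109 onward). Fragments of `H2A.X`-class
#' variants end in the SQ(E/D)\eqn{\Phi} motif; fragments of other H2A
#' variants do not. The `?`-flagged row ends in a noncanonical SQ-x-\eqn{\Phi}
#' window.
#'
#' @return A tibble with columns `kingdom`, `organism`, `variant_label`,
#'   `uncertain`, `cterm_fragment`.
#' @export
#' @examples
#' h2a_diagnostic_rows()
h2a_diagnostic_rows <- function() {
  rows <- tibble::tribble(
    ~kingdom,      ~organism,          ~variant_label, ~cterm_fragment,
    "Animals",     "Homo",             "H2A.X",        "PNIQAVLLPKKSATVGPKAPSGGKKATQASQEY",
    "Animals",     "Homo",             "H2A.2.2",      "PNIQAVLLPKKTSHKPGKNK",
    "Fungi",       "Saccharomyces",    "H2A.X",        "PNIHQNLLPKKSAKATKASQEL",
    "Plants",      "Arabidopsis",      "H2A.X.3",      "PNIHQTLLPSKVGKNKGDIGSASQEF",
    "Plants",      "Arabidopsis",      "H2A.1",        "PNIHNLLLPKKAGASKPQED",
    "Rhodophytes", "Griffithsia",      "H2A.X",        "PNIHQVLMPRKKTKGDASQEV",
    "Rhodophytes", "Cyanidioschyzon",  "H2A",          "PNIHAVLLPKKKAKGE",
    "Alveolates",  "Tetrahymena",      "H2A.X",        "PNINPMLLPSKSKKTESRGGASQDL",
    "Alveolates",  "Tetrahymena",      "H2A.1",        "PNINPMLLPSKTKKSTEPEH",
    "Heterokonts", "Phaeodactylum",    "H2A.X",        "PNIHAILLPKKTIKTKGPSQDY",
    "Heterokonts", "Phaeodactylum",    "H2A.3",        "PNIHAILLPKKSGPTK",
    "Amoebozoa",   "Dictyostelium",    "H2A.X?",       "PTPQQSTGEKKKKPSKKAAEGSSQIY",
    "Amoebozoa",   "Dictyostelium",    "H2A",          "PTPQSNTEGKKKKATSKKS",
    "Excavates",   "Giardia",          "H2A.X",        "RSAKEGREGKGSHRSQDL",
    "Excavates",   "Trypanosoma",      "H2A",          "PSLNKALAKKQKSGKHAKATPSV"
  )
  rows$uncertain <- endsWith(rows$variant_label, "?")
  rows[, c("kingdom", "organism", "variant_label", "uncertain", "cterm_fragment")]
}

#' Detect the H2A.X terminal phosphorylation motif
#'
#' Examines exactly the last four residues of a protein sequence.
#' `S,Q,[E|D],\eqn{\Phi}` is a canonical SQ(E/D)\eqn{\Phi} motif;
#' `S,Q,x,\eqn{\Phi}` with `x` outside \{E, D\} is a noncanonical variant of
#' it (seen, with uncertainty, in amoebozoa); anything else is `absent`.
#' No internal scanning is done: the motif defines the H2A.X class only at
#' the C-terminus.
#'
#' @param seq An amino-acid string, or a list/one-row tibble with a
#'   `sequence` field.
#' @param phi The hydrophobic residue set; default [phi_set()].
#' @return A list of class `hv_motif_call` with `status` (`"canonical"`,
#'   `"noncanonical"`, `"absent"`) and `matched_window` (the terminal 4-mer,
#'   or `NA` when absent).
#' @export
#' @examples
#' detect_h2ax_motif("PNIQAVLLPKKSATVGPKAPSGGKKATQASQEY")$status  # canonical
detect_h2ax_motif <- function(seq, phi = phi_set()) {
  s <- extract_sequence(seq)
  if (nchar(s) < 4) {
    rlang::abort("sequence must have at least 4 residues", class = "hv_seq_error")
  }
  window <- substr(s, nchar(s) - 3L, nchar(s))
  res <- strsplit(window, "")[[1]]
  status <-
    if (res[1] == "S" && res[2] == "Q" && res[4] %in% phi) {
      if (res[3] %in% c("E", "D")) "canonical" else "noncanonical"
    } else "absent"
  structure(list(status = status,
                 matched_window = if (status == "absent") NA_character_ else window),
            class = "hv_motif_call")
}

#' @export
print.hv_motif_call <- function(x, ...) {
  cat("<motif_call> ", x$status,
      if (!is.na(x$matched_window)) paste0(" (", x$matched_window, ")"), "\n",
      sep = "")
  invisible(x)
}

extract_sequence <- function(seq) {
  if (is.character(seq) && length(seq) == 1) return(toupper(seq))
  if (is.list(seq) && !is.null(seq$sequence)) {
    s <- seq$sequence
    if (is.character(s) && length(s) >= 1) return(toupper(s[[1]]))
  }
  rlang::abort("expected a sequence string or a record with a 'sequence' field")
}

#' Classify an H3 site pair as replication-independent or -coupled
#'
#' Looks the supplied residue-31 string and 85-89 window up against the
#' bundled diagnostic table. An exact match returns that row's class
#' (`RI_like` for the `H3.3`-type rows, `RC_like` for `H3.1`/`H3.2`-type
#' rows, `uncertain` for `?`-flagged rows) together with the organism
#' matched, at confidence `"exact"`. Without an exact match a conservative
#' heuristic applies: residue 31 beginning with a phosphorylatable S or T
#' while the window matches no RC row suggests `RI_like` at confidence
#' `"low"`; otherwise the call is `unknown`. It never silently guesses:
#' anything not tabulated is flagged.
#'
#' @param res31 Residue-31 string (1-4 letters; may contain `-`).
#' @param window The residue (85)86-89 window (4-5 letters).
#' @param table Diagnostic rows; default [h3_diagnostic_rows()].
#' @return A list of class `hv_h3_call` with `class` (`RI_like`, `RC_like`,
#'   `uncertain`, `unknown`), `organism` (or `NA`), and `confidence`
#'   (`"exact"`, `"low"`, `"none"`).
#' @export
#' @examples
#' classify_h3_site("S", "AAIG")$class    # RI_like (Homo H3.3)
#' classify_h3_site("A", "SAVM")$class    # RC_like (Homo H3.2)
classify_h3_site <- function(res31, window, table = h3_diagnostic_rows()) {
  stopifnot(nzchar(res31), nzchar(window))
  res31 <- toupper(trimws(res31))
  window <- toupper(trimws(window))
  hit <- table[table$residue31 == res31 & table$window_85_89 == window, ,
               drop = FALSE]
  if (nrow(hit) >= 1) {
    return(structure(list(class = hit$class[1], organism = hit$organism[1],
                          confidence = "exact"), class = "hv_h3_call"))
  }
  rc_windows <- table$window_85_89[table$class == "RC_like"]
  if (grepl("^[ST]", res31) && !(window %in% rc_windows)) {
    return(structure(list(class = "RI_like", organism = NA_character_,
                          confidence = "low"), class = "hv_h3_call"))
  }
  structure(list(class = "unknown", organism = NA_character_,
                 confidence = "none"), class = "hv_h3_call")
}

#' @export
print.hv_h3_call <- function(x, ...) {
  cat("<h3_call> ", x$class,
      if (!is.na(x$organism)) paste0(" (", x$organism, ")"),
      " [", x$confidence, "]\n", sep = "")
  invisible(x)
}
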