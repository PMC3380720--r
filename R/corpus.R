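## The in-paper name corpus: every name printed in the renaming tables, the
## mammalian H1 table and the Arabidopsis application table, plus the worked
## in-text examples, with the expected normalization target for historical
## names. Typed out independently of the registry TSV so the two can be
## checked against each other.

corpus_row <- function(text, role, expected, organism = NA_character_,
                       descriptors = "", source) {
  tibble::tibble(text = text, organism = organism, role = role,
                 expected = expected, descriptors = descriptors,
                 source = source)
}

#' In-paper name corpus
#'
#' Every variant name printed in the bundled tables and worked examples,
#' with its expected outcome. `role` is `"canonical"` (the name is already
#' unified; it must strict-parse and round-trip through
#' [format_histone_name()]) or `"historical"` (the name must normalize to
#' `expected`, with `descriptors` as the recommended detached descriptors).
#'
#' @return A tibble with columns `text`, `organism`, `role`, `expected`,
#'   `descriptors`, `source` (one of `"renaming_table"`, `"h1_table"`,
#'   `"arabidopsis_table"`, `"in_text"`).
#' @export
#' @examples
#' dplyr::count(name_corpus(), role, source)
name_corpus <- function() {
  canon <- function(x, source) {
    dplyr::bind_rows(lapply(x, function(s)
      corpus_row(s, "canonical", s, source = source)))
  }
  hist <- function(triples, source) {
    dplyr::bind_rows(lapply(triples, function(tr)
      corpus_row(tr[[1]], "historical", tr[[3]], organism = tr[[2]],
                 descriptors = if (length(tr) >= 4) tr[[4]] else "",
                 source = source)))
  }

  renaming_old <- list(
    list("H2A (with SPKK motifs)", "plants", "H2A.W"),
    list("H2A.Bbd", "mammals", "H2A.B"),
    list("H2Abd1", "bdelloid rotifers", "H2A.1", "bdelloid"),
    list("H2Abd2", "bdelloid rotifers", "H2A.2", "bdelloid"),
    list("H2Abd", "bdelloid rotifers", "H2A.3", "bdelloid"),
    list("H2AL", "mammals", "H2A.L"),
    list("H2Av", "Drosophila", "H2A.Z"),
    list("H2AvD", "Drosophila", "H2A.Z"),
    list("D2", "Drosophila", "H2A.Z"),
    list("hv1", "Tetrahymena", "H2A.Z"),
    list("Htz1p", "Saccharomyces", "H2A.Z"),
    list("SubH2Bv", "mammals", "subH2B"),
    list("H2BL1", "mammals", "subH2B"),
    list("H2Bv", "apicomplexans", "H2B.Z"),
    list("H2BV", "trypanosomes", "H2B.V"),
    list("H2BFWT", "mammals", "H2B.W"),
    list("TH2B", "mammals", "H2B.1", "TS"),
    list("hTSH2B", "mammals", "H2B.1", "TS"),
    list("H3(P)", "Moneuplotes", "H3.P"),
    list("H3t", "mammals", "H3.4", "TS"),
    list("H3v1", "Stylonychia", "H3.1"),
    list("H3v2", "Stylonychia", "H3.2"),
    list("H3v3", "Stylonychia", "H3.3"),
    list("H3v4", "Stylonychia", "H3.4"),
    list("H3v5", "Stylonychia", "H3.5"),
    list("H3v6", "Stylonychia", "H3.6"),
    list("H3v7", "Stylonychia", "H3.7"),
    list("H3v8", "Stylonychia", "H3.8"),
    list("H3v9", "Stylonychia", "H3.9"),
    list("H3v10", "Stylonychia", "H3.10"),
    list("H3V", "trypanosomes", "H3.V"),
    list("H3.X", "human", "H3.Y.2"),
    list("H3.Y", "human", "H3.Y.1"),
    list("H4V", "trypanosomes", "H4.V"),
    list("H1\u00b0", "animals", "H1.0"),
    list("H5", "birds", "H1.0"),
    list("H1\u03b4", "echinoderms", "H1.0"),
    list("H1t", "mammals", "H1.6", "TS"),
    list("H1T2", "mammals", "H1.7", "TS"),
    list("H1oo", "mammals", "H1.8", "OO"),
    list("Hils1", "mammals", "H1.9", "TS"),
    list("H1x", "vertebrates", "H1.10"),
    list("B4", "frogs", "H1.4", "amphibian")
  )

  h1_old <- list(
    list("H1.1", "human", "H1.1"),
    list("H1.2", "human", "H1.2"),
    list("H1.3", "human", "H1.3"),
    list("H1.4", "human", "H1.4"),
    list("H1.5", "human", "H1.5"),
    list("H1t", "human", "H1.6", "TS"),
    list("H1.0", "human", "H1.0"),
    list("H1\u00b0", "human", "H1.0"),
    list("H1T2", "human", "H1.7", "TS"),
    list("H1oo", "human", "H1.8", "OO"),
    list("Hils1", "human", "H1.9", "TS"),
    list("H1x", "human", "H1.10"),
    list("H1a", "mouse", "H1.1"),
    list("H1b", "mouse", "H1.5"),
    list("H1c", "mouse", "H1.2"),
    list("H1d", "mouse", "H1.3"),
    list("H1e", "mouse", "H1.4"),
    list("H1s-1", "mouse", "H1.2"),
    list("H1s-2", "mouse", "H1.3"),
    list("H1s-3", "mouse", "H1.5"),
    list("H1s-4", "mouse", "H1.4"),
    list("H1(0)", "mouse", "H1.0"),
    list("H1t2", "mouse", "H1.7", "TS"),
    list("TISP64", "mouse", "H1.9", "TS"),
    list("H1a", "human", "H1.5"),
    list("H1b", "human", "H1.4"),
    list("H1c", "human", "H1.3"),
    list("H1d", "human", "H1.2")
  )

  in_text_old <- list(
    list("H2Az", NA_character_, "H2A.Z"),
    list("H2A.F", NA_character_, "H2A.Z"),
    list("H2A.F/Z", NA_character_, "H2A.Z"),
    list("Htz1", "Saccharomyces", "H2A.Z"),
    list("CENP-A", "animals", "cenH3"),
    list("Cse4p", "Saccharomyces", "cenH3"),
    list("mH2A", NA_character_, "macroH2A"),
    list("H1M", "frogs", "H1.4", "amphibian"),
    list("H1\u2202", "echinoderms", "H1.0"),
    list("AtMGH3", "Arabidopsis", "H3.10", "GC"),
    list("HTR10", "Arabidopsis", "H3.10", "GC"),
    list("H2Asq.1", "Oikopleura", "H2A.Q.1"),
    list("H2Asq.2", "Oikopleura", "H2A.Q.2"),
    list("H2Asq.3", "Oikopleura", "H2A.Q.3"),
    list("H2A.Z-1", "vertebrates", "H2A.Z.1"),
    list("H2A.Z-2", "vertebrates", "H2A.Z.2"),
    list("H2A.Za", "Oikopleura", "H2A.Z.1"),
    list("H2A.Zb", "Oikopleura", "H2A.Z.2"),
    list("H2A.Zc", "Oikopleura", "H2A.Z.3"),
    list("macroH2A1", "vertebrates", "macroH2A.1"),
    list("macroH2A2", "vertebrates", "macroH2A.2"),
    list("macroH2A1.1", "vertebrates", "macroH2A.1.s1"),
    list("macroH2A1.2", "vertebrates", "macroH2A.1.s2"),
    list("H2AL1", "mouse", "H2A.L.1"),
    list("H2AL2", "mouse", "H2A.L.2")
  )

  renaming_new <- c(
    "H2A.W", "H2A.B", "H2A.1", "H2A.2", "H2A.3", "H2A.L", "H2A.Z", "subH2B",
    "H2B.Z", "H2B.V", "H2B.W", "TS H2B.1", "H3.P", "TS H3.4",
    paste0("H3.", 1:10), "H3.V", "H3.Y.2", "H3.Y.1", "H4.V", "H1.0",
    "TS H1.6", "TS H1.7", "OO H1.8", "TS H1.9", "H1.10", "Amphibian H1.4")

  h1_new <- c(paste0("H1.", 1:5), "TS H1.6", "H1.0", "TS H1.7", "OO H1.8",
              "TS H1.9", "H1.10")

  arabidopsis <- c(
    "H1.1", "H1.2", "H1.3",
    "H2A.1", "H2A.2", "H2A.10", "H2A.13", "H2A.X.3", "H2A.X.5",
    "H2A.W.6", "H2A.W.7", "H2A.W.12", "H2A.Z.8", "H2A.Z.9", "H2A.Z.11",
    "H2A.Z.4", paste0("H2B.", 1:11),
    "H3.1", "H3.3", "H3.6", "H3.10", "H3.14", "cenH3", "H3.7", "H4")

  in_text_new <- c(
    "H2A.Z.1", "H2A.Z.2", "H2A.L.1", "H2A.L.2", "H2A.Q.1", "H2A.Q.2",
    "H2A.Q.3", "macroH2A.1", "macroH2A.2", "macroH2A.1.1", "macroH2A.1.2",
    "macroH2A.1.s1", "macroH2A.1.s2", "H2A.Z.s2", "H2A.Z.s3", "H3.3K4me3",
    "H2BK123ub1", "cenH3", "macroH2A", "H2A.B.1", "H2A.B.2", "H2A.Y",
    "H3.5", "H2A.ZS138ph", "\u03b3H2A.X", "\u03b3H2A.Z.X", "H3S10ph",
    "H3K27me3", "H2A.Z.X", "H3.2.1", "H3.2.2", "H3.3.10", "TS H3.4.1",
    "TS H3.4.2", "TS H3.4.3")

  dplyr::bind_rows(
    hist(renaming_old, "renaming_table"),
    hist(h1_old, "h1_table"),
    hist(in_text_old, "in_text"),
    canon(renaming_new, "renaming_table"),
    canon(h1_new, "h1_table"),
    canon(arabidopsis, "arabidopsis_table"),
    canon(in_text_new, "in_text")
  )
}
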