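Package: histvar
Title: Unified Phylogeny-Based Nomenclature for Histone Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the unified phylogeny-based nomenclature for
    histone variants. Parses, validates, canonically formats and compares variant
    names in which each period marks a phylogenetic branch point; normalizes
    historical names and homographs to unified names through a bundled synonym
    registry; expands renamed paralog series and builds literature-search queries;
    types protein sequences with the diagnostic C-terminal SQ(E/D)-hydrophobic
    motif of H2A.X-class variants and residue 31/85-89 diagnostics separating
    replication-independent from replication-coupled H3; assigns families by
    global alignment against a reference panel and places sequences on
    neighbor-joining trees; and generates deterministic synthetic protein
    fixtures embedding the diagnostic fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
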