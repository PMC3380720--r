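# histvar — unified phylogeny-based nomenclature for histone variants

Histone variants — non-allelic isoforms of the five histone families H1,
H2A, H2B, H3 and H4 — are named in the literature with a chaos of synonyms
and homographs: `D2`, `hv1`, `Htz1p`, `H2Av` and `H2A.F/Z` all mean H2A.Z,
while apicomplexan `H2Bv` and trypanosome `H2BV` are unrelated proteins
with nearly the same name. The unified nomenclature implemented here fixes
a single written grammar for variant names and gives its punctuation a
phylogenetic meaning: **each period marks a branch point**, so `H2A.Z.1`
and `H2A.Z.2` are the two branches of the H2A.Z subfamily, and the parent
of `H2A.Z.1` is `H2A.Z`. New variants get organism-specific paralog
numbers by default (`H2A.3`); single letter suffixes are reserved for
structurally distinct clades (`H2A.Z`, `H2A.W`); lowercase prefixes mark
high-level clades (`macroH2A`, `cenH3`, `subH2B`); descriptors (`TS`,
`OO`, organism names) sit outside the name and outside variant identity;
Brno modification suffixes (`H3K27me3`, `H2A.ZS138ph`) attach without
punctuation.

`histvar` is an R toolkit for working with that scheme:

* **Grammar** — `parse_histone_name()`, `format_histone_name()`,
  `validate_name()`, `parent_name()`, `common_ancestor()`,
  `same_variant()`, JSON rendering.
* **Synonym registry** — a bundled TSV of ~90 historical-to-unified
  renamings with organism scopes: `normalize_name()`, `synonyms_of()`,
  `build_search_query()`, `expand_series()`, `suggest_paralog_number()`.
* **Sequence diagnostics** — the C-terminal SQ(E/D)Φ motif that defines
  H2A.X-class variants (`detect_h2ax_motif()`), residue-31/85–89
  diagnostics separating replication-independent from replication-coupled
  H3 (`classify_h3_site()`), nearest-reference family assignment by global
  alignment (`assign_family()`), deterministic neighbor joining
  (`build_nj_tree()`), and `propose_name()` composing them.
* **Fixtures** — deterministic synthetic scaffolds embedding the
  diagnostic fragments (`make_scaffold()`, `simulate_clades()`) and the
  full in-paper name corpus (`name_corpus()`).
* **CLI** — `histvar_cli()` plus a launcher script in `inst/cli/histvar`
  (`parse`, `normalize`, `validate`, `synonyms`, `query`, `expand`,
  `type`, `tree`, `suggest`).

## Worked example

```r
library(histvar)

parse_histone_name("H2A.ZS138ph")
#> <histone_name> H2A.ZS138ph
#>   path: clade_letter(Z)
#>   mods: S138ph
```

The parser separates the clade letter Z from the Brno phospho suffix:
this is the fly H2A.Z variant phosphorylated on serine 138, not a variant
called "ZS138ph".

```r
normalize_name("H5", organism = "birds")
#> <normalization> 'H5' -> H1.0

normalize_name("H2Bv")
#> <normalization> 'H2Bv' is ambiguous among:
#> # A tibble: 2 × 3
#>   old_name organism_scope unified_name
#>   <chr>    <chr>          <chr>
#> 1 H2Bv     apicomplexans  H2B.Z
#> 2 H2BV     trypanosomes   H2B.V
```

Avian `H5` is a historical name for `H1.0`; `H2Bv` without an organism is
a homograph and the registry refuses to guess (pass
`organism = "apicomplexans"` to get `H2B.Z`).

```r
build_search_query("H2A.Z")
#> "H2A.Z" OR "H2A.Z*" OR "D2" OR "H2A.F" OR "H2A.F/Z" OR "H2Av" OR
#> "H2AvD" OR "H2Az" OR "Htz1" OR "Htz1p" OR "hv1"
```

A literature query covering every name this variant has gone by.

```r
detect_h2ax_motif("PNIQAVLLPKKSATVGPKAPSGGKKATQASQEY")
#> <motif_call> canonical (SQEY)

classify_h3_site("S", "AAIG")
#> <h3_call> RI_like (Homo) [exact]
```

The first call reads the terminal four residues of the human H2A.X
C-terminus and finds the canonical SQ(E/D)Φ phosphorylation motif; the
second recognizes serine 31 with window AAIG as the human H3.3
(replication-independent) diagnostic.

```r
d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
            dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
build_nj_tree(d)$newick
#> (A:2,B:3,C:7);

format_histone_name(suggest_paralog_number("H2A", c("H2A.1", "H2A.3")))
#> "H2A.2"
```

Three-taxon neighbor joining uses the closed form
b_A = (d_AB + d_AC − d_BC)/2; the naming suggestion takes the smallest
free paralog number at the requested branch level.

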