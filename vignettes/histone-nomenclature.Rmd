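---
title: "A unified grammar for histone variant names: model, registry and sequence diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A unified grammar for histone variant names}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histvar)
```

## The problem

Histone variants — non-allelic protein isoforms of the five families H1,
H2A, H2B, H3 and H4 — have accumulated decades of inconsistent names:
synonyms (`D2`, `hv1`, `Htz1p`, `H2Av` all denote H2A.Z), misleading
homographs (apicomplexan `H2Bv` versus trypanosome `H2BV`, which are not
closely related), and ad hoc punctuation. The unified nomenclature this
package implements fixes a small grammar over those names and gives its
punctuation a phylogenetic meaning: **every period marks a branch point**.
`histvar` makes that scheme executable: a parser/validator/formatter, a
lineage model, a synonym registry, and a sequence-diagnostics layer.

## The name grammar

A name is

```
[descriptor ...] [γ][prefix]FAMILY[.label]*[BrnoMods]
```

* **Family** — one of H1, H2A, H2B, H3, H4. Case is never significant;
  uppercase is canonical.
* **Prefix** — a lowercase marker for a structurally distinct high-level
  clade (`macroH2A`, `cenH3`, `subH2B`).
* **Branch labels**, each preceded by a period:
  * *clade letters* (`H2A.Z`) — single uppercase letters naming
    structurally distinct, ideally monophyletic subfamilies;
  * *paralog numbers* (`H2A.1`, `H1.0`) — organism-specific, with no
    orthology implied; the default for new variants;
  * *splice labels* (`macroH2A.1.s1`) — a lowercase `s` plus a number,
    terminal only.
* **Descriptors** (`TS`, `OO`, `GC`, `RC`, `RI`, organism names) are
  detached, space-separated qualifiers. They are deliberately *not* part of
  variant identity: `TS H2B.1` and `H2B.1` are the same variant
  (`same_variant()`), and `parent_name()`/`common_ancestor()` drop them.
* **Brno modifications** attach without punctuation (`H3K27me3`,
  `H2A.ZS138ph`): residue letter, 1-based position, lowercase type,
  optional multiplicity. The γ marker (`γH2A.X`) is a phospho-state flag,
  also outside identity.

Because periods are branch points, `parent_name("H2A.Z.1")` is `H2A.Z` and
`common_ancestor("H2A.Z", "H2A.1")` is `H2A`:

```{r}
format_histone_name(parent_name("H2A.Z.1"))
format_histone_name(common_ancestor("H2A.Z.1", "H2A.Z.2"))
same_variant("γH2A.X", "H2A.X")
```

### Strict versus lenient mode

Strict mode is the grammar of the guidelines; lenient mode additionally
accepts superseded styles and flags them with warning-level findings:
dash separators (`H2A.Z-1`), multi-letter clade labels (`H2A.Bbd`),
unpunctuated subtype numbers (`H2A.Z2K4ac`), the spelled-out `gamma`, and
the legacy `°` glyph (read as paralog 0, so `H1°` parses as `H1.0`).
`validate_name()` returns the findings as a tibble; an empty report is
exactly equivalent to the name being strict-canonical.

Design points the guidelines leave open, decided here once:

* **Clade letters may chain** (`H2A.Z.X` is a sanctioned hypothetical), but
  a clade letter may never follow a paralog number — no printed name does
  that, and allowing it would let one string encode two different
  lineages. Strict mode rejects it.
* **Multi-letter clade labels** have no defined grammar yet ("may
  eventually be necessary"); lenient mode parses them verbatim with a
  warning, strict mode rejects them, and the registry renames the known
  cases (`H2A.Bbd` → `H2A.B`).
* **Paralog 0** is legal everywhere (H1.0 exists) but flagged outside H1,
  where it has no established use.
* **Descriptor boundary** — the rightmost whitespace-separated token that
  parses as a core name is the name; everything before it is descriptors,
  with surrounding parentheses stripped (`(TS) H3.4`). The descriptor
  vocabulary is intentionally open, and no ordering is enforced.
* **Case folding of splice labels** — since upper and lower case are
  equivalent in meaning, `.S2` is read as a splice label like `.s2`; a
  clade-S subtype must be written `.S.2`.
* **Label versus modification** — labels require a preceding period, so in
  `H2A.ZS138ph` the `Z` after the period is a label and `S138ph`, which
  matches the Brno shape with a valid residue letter, is a modification.
  The longest valid Brno suffix of the final chunk is split off.
* **The `δ` glyph** has no structural reading (it is not a paralog number),
  so names like `H1δ` are resolved by the synonym registry
  (`normalize_name("H1δ")` → `H1.0`) rather than by the parser.

## The synonym registry

`inst/extdata/synonym_registry.tsv` (≈90 records) compiles the published
renaming tables for core histones and mammalian H1, plus the in-text
synonyms. Columns: `old_name`, `organism_scope`, `unified_name`,
`descriptors`, `case_sensitive`, `note`; every `unified_name` must parse
strictly and `(old_name, organism_scope)` keys are unique. Users may pass
an override file whose rows shadow bundled ones.

Lookup is case-insensitive. Organism scopes are free-text labels matched
by string equality plus a small fixed alias list (`"human"` reaches
`mammals`, `vertebrates`, `animals`); taxonomic containment is never
inferred beyond that list. When several scoped records match and no
organism is given, the result is *ambiguous* and carries the candidates —
deliberately including the case homographs, where trusting the
capitalization the author happened to use would be unsafe:

```{r}
normalize_name("H2Bv")                   # ambiguous: H2B.Z or H2B.V?
normalize_name("H2Bv", "apicomplexans")  # resolved
```

Renamed series (`H3v1`…`H3v10` → `H3.1`…`H3.10`) are stored one record per
member so each printed old name normalizes directly; `expand_series()`
walks the inclusive range and extrapolates the trailing integer for
members without their own record. `synonyms_of()` inverts the registry
under variant identity, and `build_search_query()` turns that into an
OR-joined literature query so searches stop missing the older literature.
`suggest_paralog_number()` implements the default naming rule for new
variants: the smallest positive integer free at the given branch level.

## Sequence diagnostics

Two residue-level rules from the tables are bundled verbatim:

* **H2A.X-class variants** carry a C-terminal SQ(E/D)Φ phosphorylation
  motif. `detect_h2ax_motif()` examines *exactly* the last four residues —
  every tabulated H2A.X fragment ends in its motif, and the class is
  defined at the terminus, so no internal scanning is done. Φ defaults to
  {L, I, V, M, F, W, Y}, covering every tabulated terminal residue
  (Y, L, F, V); alanine is excluded as unattested. The set is a
  configurable option because the motif definition, not this package,
  owns it. `S,Q,x,Φ` with `x` outside {E, D} is reported `noncanonical`
  (seen, with uncertainty, in *Dictyostelium*).
* **RI versus RC H3** (`H3.3`-type versus `H3.1`/`H3.2`-type) typically
  differ at residue 31 and in the residue (85)86–89 window, but the
  distinguishing residues vary by kingdom. `classify_h3_site()` is
  lookup-first over the bundled rows (including the multi-character
  residue-31 strings such as `VS`, `STQP`, `S-`, and the `?`-flagged rows,
  which return `uncertain`); outside the table a conservative heuristic
  (phosphorylatable S/T at position 31 and a window unlike every RC row)
  returns `RI_like` at explicitly *low* confidence, and anything else is
  `unknown`. The classifier never silently guesses, and callers must
  supply the site strings — mapping an unnumbered query sequence onto the
  human numbering is alignment-dependent and out of scope.

Family assignment (`assign_family()`) is nearest-reference under global
alignment; ties break toward the lexicographically smallest reference id
so panel order never matters. The default scoring — match +1, mismatch 0,
linear gap −1 — is the simplest auditable scheme; a substitution matrix
can be supplied. The Needleman–Wunsch implementation uses a fixed
traceback preference (diagonal > up > left) so aligned output is
deterministic.

## Trees

`build_nj_tree()` is standard neighbor joining on a symmetric
non-negative distance matrix (Q-criterion; branch lengths
\(b_i = d_{ij}/2 + (r_i - r_j)/(2(n-2))\); final three lineages joined by
the closed form). Two numerical choices are fixed for determinism:
Q-ties are broken toward the candidate pair first in (row, column) order
of the current matrix, and negative branch lengths are clamped to zero.
`p_distance()` (mismatches over gap-free columns; an error when no such
column exists) feeds the matrix from pairwise alignments via
`distance_matrix()`. The implementation is written here because these
tie-break and clamping rules are part of the contract; `ape::nj` serves
as an independent cross-check in the test suite.

## Synthetic fixtures

`make_scaffold()` draws a random sequence from a residue composition
(uniform over the 20 standard residues by default) and overwrites it with
diagnostic fragments at fixed anchors; a C-terminal anchor ends exactly at
the last residue. `simulate_clades()` evolves a root sequence along a tree
by *counted* substitutions per edge rather than rates — counts make every
property of the fixture exactly reproducible for a given seed, at the cost
of realism. What these fixtures emulate is the *presence and position* of
the diagnostic signals; they do not emulate histone fold domains,
composition bias, indels, or back-substitution saturation. Passing tests
on them therefore demonstrate that the callers read the signals correctly,
not that the signals themselves generalize to real proteomes — the signal
definitions are taken from the published tables, which is where their
biological authority lives.

## Problem sizes used by the test suite

The suite checks the alignment implementation against an exhaustive
enumeration oracle on all string pairs up to length 2 over a 4-letter
alphabet plus 100 seeded pairs up to length 6 (the enumeration oracle is
exponential, which is the point of having it), and cross-checks scores
against an independent implementation. Neighbor joining is required to
recover the generating topology for additive matrices from 100 seeded
random trees of 4–8 taxa. Round-tripping is checked over the full
in-paper canonical corpus and 10,000 seeded random structurally valid
names. These sizes were chosen as the smallest that exercise every code
path and tie-break; all are deterministic under fixed seeds.

## Known limitations

* Organism scoping is label matching plus a fixed alias list, not a
  taxonomy; `normalize_name("H5", "Gallus gallus")` will not find the
  birds-scoped record unless the caller uses the table's label.
* The registry maps both `SubH2Bv` and `H2BL1` to bare `subH2B`; whether
  the mouse gene deserves a paralog suffix is not settled, so none is
  invented.
* `H2A.Bbd` is treated as a deprecated synonym (warning + registry
  renaming to `H2A.B`), though the older spelling remains searchable.
* Query-string generation is offline; no literature database is contacted.
* `propose_name()` only ever proposes paralog numbers. Letter suffixes and
  prefixes encode phylogenetic judgements that should not be automated
  from a single pairwise-alignment score.
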