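#' @keywords internal
"_PACKAGE"

## Ciba family names; order matters for leftmost-longest matching inside tokens.
hv_families <- c("H2A", "H2B", "H1", "H3", "H4")

## The 20 standard amino-acid one-letter codes.
hv_aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Seed vocabulary of Brno modification-type tokens; extensible via option.
hv_mod_seed <- c("me", "ac", "ph", "ub", "cit", "ar")

#' Modification-type vocabulary
#'
#' The Brno notation appends unpunctuated modification tokens (residue letter,
#' 1-based position, lowercase type, optional multiplicity) to a variant name,
#' as in `H3K27me3`. The seed vocabulary covers me, ac, ph, ub, cit and ar;
#' unknown types parse with a warning rather than an error, since the notation
#' keeps acquiring new types. Extend the vocabulary for a session with
#' `options(histvar.mod_types = c("su", ...))`.
#'
#' @return Character vector of recognized modification-type tokens.
#' @export
#' @examples
#' mod_vocabulary()
mod_vocabulary <- function() {
  unique(c(hv_mod_seed, getOption("histvar.mod_types", character())))
}

#' Hydrophobic residue set for the H2A.X terminal motif
#'
#' The SQ(E/D)\eqn{\Phi} motif that defines H2A.X-class variants ends in a
#' hydrophobic residue \eqn{\Phi}. The default set \{L, I, V, M, F, W, Y\}
#' covers every terminal residue observed in the bundled diagnostic fragments
#' (Y, L, F, V); alanine is excluded as unattested. Override for a session
#' with `options(histvar.phi = ...)`.
#'
#' @return Character vector of one-letter hydrophobic residue codes.
#' @export
#' @examples
#' phi_set()
phi_set <- function() {
  getOption("histvar.phi", c("L", "I", "V", "M", "F", "W", "Y"))
}
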