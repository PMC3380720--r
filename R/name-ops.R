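as_histone_name <- function(x, mode = "strict") {
  if (is_histone_name(x)) return(x)
  if (is.character(x) && length(x) == 1) return(parse_histone_name(x, mode))
  rlang::abort("expected a histone_name or a single name string")
}

format_label <- function(label) {
  switch(label$kind,
         clade_letter   = as.character(label$value),
         paralog_number = as.character(label$value),
         splice_number  = paste0("s", label$value))
}

format_modifications <- function(mods) {
  if (nrow(mods) == 0) return("")
  paste0(mods$residue, mods$position, mods$type,
         ifelse(is.na(mods$multiplicity), "", mods$multiplicity),
         collapse = "")
}

#' Canonical form of a histone variant name
#'
#' Renders a parsed name in its canonical written form: uppercase family and
#' clade letters, lowercase prefix and modification types, a single period
#' before each branch label, a single space after each descriptor, and the
#' \eqn{\gamma} phospho-state marker (when present) ahead of the name. The
#' output is deterministic, so `format_histone_name(parse_histone_name(s))`
#' is the identity on canonical strings.
#'
#' @param name A `histone_name` or a name string.
#' @param descriptors Include the detached descriptors? Default `TRUE`.
#' @param modifications Include Brno modifications and the \eqn{\gamma}
#'   marker? Default `TRUE`.
#' @return A single string.
#' @export
#' @examples
#' format_histone_name(parse_histone_name("h2a.z"))      # "H2A.Z"
#' format_histone_name("TS H3.4", descriptors = FALSE)   # "H3.4"
format_histone_name <- function(name, descriptors = TRUE, modifications = TRUE) {
  name <- as_histone_name(name, mode = "lenient")
  core <- paste0(
    if (isTRUE(name$gamma) && modifications) "\u03b3" else "",
    if (is.null(name$prefix)) "" else name$prefix,
    name$family,
    paste0(vapply(name$suffix_path,
                  function(l) paste0(".", format_label(l)), character(1)),
           collapse = "")
  )
  if (modifications) core <- paste0(core, format_modifications(name$modifications))
  if (descriptors && length(name$descriptors) > 0) {
    core <- paste(c(name$descriptors, core), collapse = " ")
  }
  core
}

#' @export
format.histone_name <- function(x, ...) format_histone_name(x, ...)

#' @export
as.character.histone_name <- function(x, ...) format_histone_name(x, ...)

#' @export
print.histone_name <- function(x, ...) {
  cat("<histone_name> ", format_histone_name(x), "\n", sep = "")
  if (length(x$suffix_path) > 0) {
    kinds <- vapply(x$suffix_path, function(l) l$kind, character(1))
    vals <- vapply(x$suffix_path, function(l) as.character(l$value), character(1))
    cat("  path: ", paste(sprintf("%s(%s)", kinds, vals), collapse = " > "), "\n",
        sep = "")
  }
  if (nrow(x$modifications) > 0) {
    cat("  mods: ", format_modifications(x$modifications), "\n", sep = "")
  }
  invisible(x)
}

#' Parent of a variant name in the branch-point hierarchy
#'
#' Each period in a unified name marks a phylogenetic branch point, so the
#' parent of a name is obtained by removing its last branch label:
#' `H2A.Z.1 -> H2A.Z -> H2A`. Descriptors, modifications and the
#' \eqn{\gamma} marker are dropped, since they are not part of variant
#' identity.
#'
#' @param name A `histone_name` or name string.
#' @return The parent `histone_name`.
#' @export
#' @examples
#' format_histone_name(parent_name("H2A.Z.1"))  # "H2A.Z"
parent_name <- function(name) {
  name <- as_histone_name(name, mode = "lenient")
  if (length(name$suffix_path) == 0) {
    rlang::abort(sprintf("family %s has no parent", name$family),
                 class = "hv_root_error")
  }
  new_histone_name(family = name$family, prefix = name$prefix,
                   suffix_path = name$suffix_path[-length(name$suffix_path)])
}

#' Most recent common ancestor of two variant names
#'
#' Returns the longest shared suffix-path prefix of two names in the same
#' family -- the deepest branch point both lie under. The operation is
#' commutative and idempotent. Names with different prefixes (for example
#' `macroH2A.1` and `H2A.1`) share only the family root.
#'
#' @param a,b `histone_name` objects or name strings.
#' @return A `histone_name`.
#' @export
#' @examples
#' format_histone_name(common_ancestor("H2A.Z.1", "H2A.Z.2"))  # "H2A.Z"
#' format_histone_name(common_ancestor("H2A.Z", "H2A.1"))      # "H2A"
common_ancestor <- function(a, b) {
  a <- as_histone_name(a, mode = "lenient")
  b <- as_histone_name(b, mode = "lenient")
  if (a$family != b$family) {
    rlang::abort("no common ancestor within a family", class = "hv_family_error")
  }
  pa <- if (is.null(a$prefix)) "" else tolower(a$prefix)
  pb <- if (is.null(b$prefix)) "" else tolower(b$prefix)
  if (pa != pb) {
    return(new_histone_name(family = a$family))
  }
  shared <- list()
  for (i in seq_len(min(length(a$suffix_path), length(b$suffix_path)))) {
    if (identical_label(a$suffix_path[[i]], b$suffix_path[[i]])) {
      shared[[i]] <- a$suffix_path[[i]]
    } else break
  }
  new_histone_name(family = a$family, prefix = a$prefix, suffix_path = shared)
}

identical_label <- function(x, y) {
  x$kind == y$kind &&
    toupper(as.character(x$value)) == toupper(as.character(y$value))
}

#' Do two names denote the same variant?
#'
#' Variant identity is carried by the prefix, the family, and the suffix path
#' alone: descriptors, Brno modifications and the \eqn{\gamma} phospho-state
#' marker never alter identity, and case is not significant. So
#' `"TS H2B.1"` and `"H2B.1"` are the same variant, as are \eqn{\gamma}`H2A.X` and
#' `"H2A.X"`.
#'
#' @param a,b `histone_name` objects or name strings (parsed leniently).
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' same_variant("TS H2B.1", "H2B.1")      # TRUE
#' same_variant("H2A.Z.1", "H2A.Z.2")     # FALSE
same_variant <- function(a, b) {
  a <- as_histone_name(a, mode = "lenient")
  b <- as_histone_name(b, mode = "lenient")
  pa <- if (is.null(a$prefix)) "" else tolower(a$prefix)
  pb <- if (is.null(b$prefix)) "" else tolower(b$prefix)
  if (pa != pb || a$family != b$family) return(FALSE)
  if (length(a$suffix_path) != length(b$suffix_path)) return(FALSE)
  if (length(a$suffix_path) == 0) return(TRUE)
  all(mapply(identical_label, a$suffix_path, b$suffix_path))
}

#' JSON rendering of a parsed name
#'
#' Serializes a `histone_name` with stable field names: `family`, `prefix`,
#' `suffix_path` (a list of `kind`/`value` pairs), `descriptors`,
#' `modifications` and `gamma`.
#'
#' @param name A `histone_name` or name string.
#' @param pretty Pretty-print the JSON?
#' @return A JSON string.
#' @export
#' @examples
#' histone_name_json("H2A.Z.1")
histone_name_json <- function(name, pretty = FALSE) {
  name <- as_histone_name(name, mode = "lenient")
  payload <- list(
    family = name$family,
    prefix = if (is.null(name$prefix)) NA_character_ else name$prefix,
    suffix_path = lapply(name$suffix_path, function(l)
      list(kind = l$kind, value = l$value)),
    descriptors = as.list(name$descriptors),
    modifications = name$modifications,
    gamma = name$gamma
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = pretty,
                                na = "null"))
}
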