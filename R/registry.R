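## Synonym registry: historical name -> unified name, with organism scopes.

hv_env <- new.env(parent = emptyenv())

registry_columns <- c("old_name", "organism_scope", "unified_name",
                      "descriptors", "case_sensitive", "note")

## Minimal organism alias map. Each alias lists the registry scopes a common
## organism label may reach; taxonomic containment is deliberately NOT
## inferred beyond this fixed list.
.mam <- c("mammals", "vertebrates", "animals")
organism_aliases <- list(
  human = .mam, homo = .mam, mouse = .mam, mus = .mam, rat = .mam,
  bovine = .mam, mammal = .mam, mammals = c("vertebrates", "animals"),
  chicken = c("birds", "vertebrates", "animals"),
  avian = c("birds", "vertebrates", "animals"),
  bird = c("birds", "vertebrates", "animals"),
  birds = c("vertebrates", "animals"),
  xenopus = c("frogs", "amphibians", "vertebrates", "animals"),
  frog = c("frogs", "amphibians", "vertebrates", "animals"),
  frogs = c("amphibians", "vertebrates", "animals"),
  "sea urchin" = c("echinoderms", "animals"),
  echinoderms = "animals", vertebrate = c("vertebrates", "animals"),
  vertebrates = "animals", plant = "plants",
  apicomplexan = "apicomplexans", trypanosome = "trypanosomes",
  urochordate = "urochordates", drosophila = "animals"
)

norm_scope <- function(x) tolower(trimws(x))

#' Load a synonym registry
#'
#' Reads a tab-separated registry of historical-to-unified name mappings.
#' The file must be UTF-8 with a header row and exactly the columns
#' `old_name`, `organism_scope`, `unified_name`, `descriptors`
#' (comma-joined), `case_sensitive` (0/1) and `note`. Every `unified_name`
#' must parse in strict mode, and `(old_name, organism_scope)` pairs must be
#' unique. Rows in `overrides` shadow rows of the base file with the same
#' key, so users can locally amend the bundled registry.
#'
#' @param path Path to a registry TSV; default is the bundled registry.
#' @param overrides Optional path to a second TSV whose records shadow the
#'   base records.
#' @return A tibble of class `hv_registry`.
#' @export
#' @examples
#' reg <- load_registry()
#' nrow(reg)
load_registry <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synonym_registry.tsv", package = "histvar")
  }
  base <- read_registry_file(path)
  if (!is.null(overrides)) {
    extra <- read_registry_file(overrides)
    key <- function(d) paste(tolower(d$old_name), norm_scope(d$organism_scope),
                             sep = "\r")
    base <- dplyr::bind_rows(extra, base[!(key(base) %in% key(extra)), ])
  }
  class(base) <- c("hv_registry", class(base))
  base
}

read_registry_file <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no registry file at '%s'", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) rlang::abort("registry file is empty")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, registry_columns)) {
    rlang::abort(sprintf("registry header must be: %s",
                         paste(registry_columns, collapse = ", ")))
  }
  body <- lines[-1]
  body_no <- which(nzchar(trimws(body))) + 1L
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ## a row whose final fields are empty may split short; pad, but reject excess
  n_fields <- vapply(fields, length, integer(1))
  bad <- which(n_fields > 6L | n_fields < 3L)
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed registry row at line %d: expected 6 tab-separated fields",
                         body_no[bad[1]]))
  }
  fields <- lapply(fields, function(f) c(f, rep("", 6L - length(f))))
  tab <- tibble::as_tibble(stats::setNames(
    as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE),
    registry_columns))
  if (!all(tab$case_sensitive %in% c("0", "1"))) {
    bad <- which(!(tab$case_sensitive %in% c("0", "1")))[1]
    rlang::abort(sprintf("malformed registry row at line %d: case_sensitive must be 0 or 1",
                         body_no[bad]))
  }
  tab$case_sensitive <- tab$case_sensitive == "1"
  for (i in seq_len(nrow(tab))) {
    ok <- tryCatch({parse_histone_name(tab$unified_name[i], "strict"); TRUE},
                   hv_parse_error = function(e) FALSE)
    if (!ok) {
      rlang::abort(sprintf("registry row at line %d: unified name '%s' does not parse in strict mode",
                           body_no[i], tab$unified_name[i]))
    }
  }
  key <- paste(tolower(tab$old_name), norm_scope(tab$organism_scope), sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    rlang::abort(sprintf("registry row at line %d: duplicate key (%s, %s)",
                         body_no[d], tab$old_name[d], tab$organism_scope[d]))
  }
  tab
}

#' Bundled synonym registry
#'
#' Returns the registry shipped with the package (cached after first load).
#' @return A tibble of class `hv_registry`.
#' @export
default_registry <- function() {
  if (is.null(hv_env$registry)) hv_env$registry <- load_registry()
  hv_env$registry
}

#' Export a registry as JSON
#' @param registry A registry tibble (default: bundled).
#' @return A JSON string mirroring the TSV fields.
#' @export
registry_json <- function(registry = default_registry()) {
  as.character(jsonlite::toJSON(as.data.frame(registry), auto_unbox = FALSE))
}

split_descriptors <- function(x) {
  if (!nzchar(x)) character() else trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

scope_matches <- function(scopes, organism) {
  org <- norm_scope(organism)
  reach <- c(org, organism_aliases[[org]], "")
  norm_scope(scopes) %in% reach
}

#' Normalize a historical histone name to its unified name
#'
#' Looks the name up in the synonym registry (case-insensitively), filtered
#' by organism when one is given; exact organism-scope matches are preferred
#' over alias matches (e.g. `"human"` reaching mammal-scoped records) and
#' unscoped records match any organism. If several scoped records match and
#' no organism is given -- the historical homographs, such as apicomplexan
#' `H2Bv` versus trypanosome `H2BV` -- the result carries the candidates and
#' no unified name; supplying the organism resolves it. A name with no
#' registry record is parsed leniently and returned in canonical form, so
#' already-unified names pass through unchanged.
#'
#' @param text The name to normalize.
#' @param organism Optional organism or taxon label.
#' @param registry A registry tibble; default the bundled one.
#' @return An object of class `hv_normalization`: a list with elements
#'   `input`, `unified` (a `histone_name`, or `NULL` when ambiguous),
#'   `matched_record` (the registry row, or `NULL` if the input was already
#'   canonical), `recommended_descriptors`, `ambiguous_candidates` (tibble),
#'   and `organism_used`.
#' @export
#' @examples
#' normalize_name("H5", "birds")           # H1.0
#' normalize_name("H2BFWT")                # H2B.W
#' normalize_name("H2Bv")                  # ambiguous without an organism
#' normalize_name("H2Bv", "apicomplexans") # H2B.Z
normalize_name <- function(text, organism = NULL, registry = default_registry()) {
  stopifnot(is.character(text), length(text) == 1)
  query <- trimws(text)
  cand <- registry[tolower(registry$old_name) == tolower(query), , drop = FALSE]
  organism_used <- FALSE

  if (nrow(cand) > 0 && !is.null(organism)) {
    s <- norm_scope(cand$organism_scope)
    exact <- cand[s == norm_scope(organism), , drop = FALSE]
    scoped <- cand[scope_matches(cand$organism_scope, organism), , drop = FALSE]
    picked <- if (nrow(exact) > 0) exact else scoped
    if (nrow(picked) > 0) {
      cand <- picked
      organism_used <- TRUE
    } else {
      cand <- cand[0, , drop = FALSE]
    }
  }

  if (nrow(cand) > 1) {
    uni <- unique(cand$unified_name)
    if (length(uni) > 1 || !all(vapply(
          cand$unified_name[-1], same_variant, logical(1), b = cand$unified_name[1]))) {
      return(structure(list(input = query, unified = NULL,
                            matched_record = NULL,
                            recommended_descriptors = character(),
                            ambiguous_candidates = cand,
                            organism_used = organism_used),
                       class = "hv_normalization"))
    }
    cand <- cand[1, , drop = FALSE]
  }

  if (nrow(cand) == 1) {
    return(structure(list(
      input = query,
      unified = parse_histone_name(cand$unified_name, "strict"),
      matched_record = cand,
      recommended_descriptors = split_descriptors(cand$descriptors),
      ambiguous_candidates = registry[0, , drop = FALSE],
      organism_used = organism_used), class = "hv_normalization"))
  }

  parsed <- tryCatch(parse_histone_name(query, "lenient"),
                     hv_parse_error = function(e) NULL)
  if (is.null(parsed)) {
    rlang::abort(sprintf("'%s' is neither in the registry nor parsable as a variant name",
                         query), class = "hv_unresolvable")
  }
  canonical <- new_histone_name(family = parsed$family, prefix = parsed$prefix,
                                suffix_path = parsed$suffix_path)
  structure(list(input = query, unified = canonical, matched_record = NULL,
                 recommended_descriptors = parsed$descriptors,
                 ambiguous_candidates = registry[0, , drop = FALSE],
                 organism_used = FALSE),
            class = "hv_normalization")
}

#' @export
print.hv_normalization <- function(x, ...) {
  if (is.null(x$unified)) {
    cat("<normalization> '", x$input, "' is ambiguous among:\n", sep = "")
    print(x$ambiguous_candidates[, c("old_name", "organism_scope", "unified_name")])
  } else {
    cat("<normalization> '", x$input, "' -> ",
        format_histone_name(x$unified), "\n", sep = "")
    if (length(x$recommended_descriptors) > 0) {
      cat("  recommended descriptors: ",
          paste(x$recommended_descriptors, collapse = " "), "\n", sep = "")
    }
    if (is.null(x$matched_record)) cat("  (no registry record: already canonical)\n")
  }
  invisible(x)
}

#' Batch normalization to a tibble
#'
#' @param names Character vector of names.
#' @param organisms Optional character vector (recycled) of organisms.
#' @param registry A registry tibble.
#' @return A tibble with columns `input`, `organism`, `unified`, `status`.
#' @export
normalize_table <- function(names, organisms = NULL, registry = default_registry()) {
  organisms <- if (is.null(organisms)) rep(NA_character_, length(names)) else
    rep_len(organisms, length(names))
  rows <- purrr::map2(names, organisms, function(nm, org) {
    res <- tryCatch(
      normalize_name(nm, if (is.na(org)) NULL else org, registry),
      hv_unresolvable = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(input = nm, organism = org, unified = NA_character_,
                     status = "unresolvable")
    } else if (is.null(res$unified)) {
      tibble::tibble(input = nm, organism = org, unified = NA_character_,
                     status = "ambiguous")
    } else {
      tibble::tibble(input = nm, organism = org,
                     unified = format_histone_name(res$unified),
                     status = if (is.null(res$matched_record)) "canonical" else "renamed")
    }
  })
  dplyr::bind_rows(rows)
}

#' Expand a renamed paralog series
#'
#' Some renamings cover whole numbered series (for example a set of old names
#' ending v1..v10 whose 'v' becomes a period). Given the first and last old
#' name -- which must differ only in a trailing integer -- every member of
#' the inclusive range is normalized through the registry; members without
#' their own record inherit the series rule by swapping the trailing paralog
#' number of a sibling's unified name.
#'
#' @param old_start,old_end First and last old names of the series.
#' @param registry A registry tibble.
#' @return A tibble with columns `old_name`, `unified_name`.
#' @export
#' @examples
#' expand_series("H3v1", "H3v10")
expand_series <- function(old_start, old_end, registry = default_registry()) {
  pat <- "^(.*?)([0-9]+)$"
  if (!grepl(pat, old_start) || !grepl(pat, old_end)) {
    rlang::abort("series endpoints must end in an integer", class = "hv_series_error")
  }
  stem1 <- sub(pat, "\\1", old_start)
  stem2 <- sub(pat, "\\1", old_end)
  n1 <- as.integer(sub(pat, "\\2", old_start))
  n2 <- as.integer(sub(pat, "\\2", old_end))
  if (!identical(stem1, stem2) || n1 > n2) {
    rlang::abort("series endpoints must share a stem and run start <= end",
                 class = "hv_series_error")
  }
  template <- registry[grepl(paste0("^", rexq(stem1), "[0-9]+$"),
                             registry$old_name, ignore.case = TRUE), ,
                       drop = FALSE]
  rows <- lapply(seq.int(n1, n2), function(n) {
    old <- paste0(stem1, n)
    hit <- template[tolower(template$old_name) == tolower(old), , drop = FALSE]
    if (nrow(hit) >= 1) {
      unified <- hit$unified_name[1]
    } else if (nrow(template) >= 1) {
      unified <- sub("[0-9]+$", n, template$unified_name[1])
    } else {
      rlang::abort(sprintf("no registry series rule matches '%s'", old),
                   class = "hv_series_error")
    }
    tibble::tibble(old_name = old, unified_name = unified)
  })
  dplyr::bind_rows(rows)
}

rexq <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Historical synonyms of a unified name
#'
#' All registry old names whose unified form denotes the same variant
#' (descriptors, modifications and case ignored), in deterministic order.
#'
#' @param name A `histone_name` or name string.
#' @param registry A registry tibble.
#' @return Character vector (possibly empty).
#' @export
#' @examples
#' synonyms_of("H2A.Z")
#' synonyms_of("cenH3")
synonyms_of <- function(name, registry = default_registry()) {
  name <- as_histone_name(name, mode = "lenient")
  hits <- vapply(registry$unified_name, same_variant, logical(1), b = name)
  old <- unique(registry$old_name[hits])
  old[order(tolower(old), old)]
}

#' Literature-search query for a variant
#'
#' Builds an OR-joined quoted query from the canonical name, its wildcard
#' form (`name*`), and every historical synonym in the registry, so a single
#' search finds papers using any of the names a variant has gone by.
#'
#' @param name A `histone_name` or name string.
#' @param dialect Query dialect; only `"boolean_or"` is defined.
#' @param registry A registry tibble.
#' @return A single query string.
#' @export
#' @examples
#' build_search_query("H2A.Z")
build_search_query <- function(name, dialect = "boolean_or",
                               registry = default_registry()) {
  dialect <- match.arg(dialect, "boolean_or")
  name <- as_histone_name(name, mode = "lenient")
  canon <- format_histone_name(name, descriptors = FALSE, modifications = FALSE)
  terms <- unique(c(canon, paste0(canon, "*"), synonyms_of(name, registry)))
  paste(sprintf("\"%s\"", terms), collapse = " OR ")
}

#' Suggest the next paralog number
#'
#' New variants get a paralog number by default. The suggestion extends the
#' given parent path (or the bare family) with the smallest positive integer
#' not already taken at that level -- numbering need not be sequential, so
#' gaps left intentionally are reused only in the sense that the smallest
#' free number is proposed.
#'
#' @param family One of `"H1"`, `"H2A"`, `"H2B"`, `"H3"`, `"H4"`.
#' @param existing Character vector or list of `histone_name`s already in use.
#' @param parent Optional parent name (e.g. `"H2A.Z"`) under which to number.
#' @return A `histone_name` for the suggested new variant.
#' @export
#' @examples
#' format_histone_name(suggest_paralog_number("H2A", c("H2A.1", "H2A.3")))
#' format_histone_name(
#'   suggest_paralog_number("H2A", c("H2A.Z.1", "H2A.Z.2"), parent = "H2A.Z"))
suggest_paralog_number <- function(family, existing = character(),
                                   parent = NULL) {
  family <- match.arg(toupper(family), hv_families)
  parent <- if (is.null(parent)) new_histone_name(family = family) else
    as_histone_name(parent, mode = "lenient")
  if (parent$family != family) {
    rlang::abort("parent must belong to the stated family")
  }
  plen <- length(parent$suffix_path)
  ppre <- if (is.null(parent$prefix)) "" else tolower(parent$prefix)
  taken <- integer()
  for (e in existing) {
    nm <- tryCatch(as_histone_name(e, mode = "lenient"), error = function(e) NULL)
    if (is.null(nm) || nm$family != family) next
    npre <- if (is.null(nm$prefix)) "" else tolower(nm$prefix)
    if (npre != ppre) next
    if (length(nm$suffix_path) != plen + 1L) next
    if (plen > 0 && !all(mapply(identical_label, nm$suffix_path[seq_len(plen)],
                                parent$suffix_path))) next
    leaf <- nm$suffix_path[[plen + 1L]]
    if (leaf$kind == "paralog_number") taken <- c(taken, leaf$value)
  }
  n <- 1L
  while (n %in% taken) n <- n + 1L
  new_histone_name(family = family, prefix = parent$prefix,
                   suffix_path = c(parent$suffix_path,
                                   list(new_branch_label("paralog_number", n))))
}
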