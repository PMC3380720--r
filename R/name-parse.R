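## Internal representation -----------------------------------------------------

new_branch_label <- function(kind, value) {
  stopifnot(kind %in% c("clade_letter", "paralog_number", "splice_number"))
  list(kind = kind, value = value)
}

## shared constants: tibble construction is costly and these are immutable
.empty_mods <- tibble::new_tibble(
  list(residue = character(), position = integer(),
       type = character(), multiplicity = integer()), nrow = 0L)
.empty_findings <- tibble::new_tibble(
  list(rule = character(), level = character(), message = character(),
       start = integer(), end = integer()), nrow = 0L)

empty_modifications <- function() .empty_mods

new_histone_name <- function(family, prefix = NULL, suffix_path = list(),
                             descriptors = character(),
                             modifications = empty_modifications(),
                             gamma = FALSE) {
  structure(
    list(family = family, prefix = prefix, suffix_path = suffix_path,
         descriptors = descriptors, modifications = modifications,
         gamma = gamma),
    class = "histone_name"
  )
}

#' Test for histone_name objects
#' @param x An object.
#' @return `TRUE` if `x` is a parsed histone variant name.
#' @export
is_histone_name <- function(x) inherits(x, "histone_name")

## Findings collector ----------------------------------------------------------

new_findings <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env
}

add_finding <- function(fb, rule, level, message, start = NA_integer_,
                        end = NA_integer_) {
  fb$rows[[length(fb$rows) + 1L]] <-
    list(rule = rule, level = level, message = message,
         start = as.integer(start), end = as.integer(end))
  invisible(fb)
}

findings_tbl <- function(fb) {
  if (length(fb$rows) == 0) return(.empty_findings)
  tibble::new_tibble(list(
    rule = vapply(fb$rows, `[[`, character(1), "rule"),
    level = vapply(fb$rows, `[[`, character(1), "level"),
    message = vapply(fb$rows, `[[`, character(1), "message"),
    start = vapply(fb$rows, `[[`, integer(1), "start"),
    end = vapply(fb$rows, `[[`, integer(1), "end")),
    nrow = length(fb$rows))
}

stop_parse <- function(message, rule = "parse_error") {
  rlang::abort(message, class = "hv_parse_error", rule = rule)
}

## Brno modification suffix ----------------------------------------------------

## A Brno suffix is one or more of: residue letter, position, lowercase type,
## optional multiplicity -- all unpunctuated (H3K27me3, H2A.Z2K4acK11ac).
brno_pattern <- "^([A-Z][0-9]+[a-z]+[0-9]*)+$"

parse_brno <- function(text, fb) {
  if (!grepl(brno_pattern, text)) return(NULL)
  pieces <- regmatches(text, gregexpr("([A-Z])([0-9]+)([a-z]+)([0-9]*)", text))[[1]]
  if (sum(nchar(pieces)) != nchar(text)) return(NULL)
  residue <- substr(pieces, 1, 1)
  rest <- sub("^[A-Z]", "", pieces)
  position <- as.integer(sub("^([0-9]+).*$", "\\1", rest))
  tails <- sub("^[0-9]+", "", rest)
  type <- sub("([0-9]*)$", "", tails)
  mult <- sub("^[a-z]+", "", tails)
  mods <- tibble::new_tibble(list(
    residue = residue, position = position, type = type,
    multiplicity = ifelse(nzchar(mult), suppressWarnings(as.integer(mult)),
                          NA_integer_)),
    nrow = length(pieces))
  if (any(!(mods$residue %in% hv_aa20))) return(NULL)
  if (any(mods$position < 1) ||
      any(grepl("^0[0-9]", sub("^[A-Z]", "", pieces)))) return(NULL)
  unknown <- setdiff(unique(mods$type), mod_vocabulary())
  for (u in unknown) {
    add_finding(fb, "unknown_mod_type", "warning",
                sprintf("unknown modification type '%s'", u))
  }
  mods
}

## Split a suffix chunk into (label text, Brno suffix). Preference is for the
## longest valid Brno suffix, so 'ZS138ph' becomes label Z + mod S138ph and
## 'Z2K4acK11ac' becomes label Z2 + mods K4acK11ac.
peel_brno <- function(chunk, fb) {
  n <- nchar(chunk)
  if (!grepl("[0-9]", chunk) || !grepl("[a-z]", chunk)) {
    return(list(label = chunk, mods = NULL))
  }
  for (i in seq_len(n)) {
    sfx <- substr(chunk, i, n)
    if (grepl("^[A-Z]", sfx) && grepl(brno_pattern, sfx)) {
      probe <- new_findings()
      mods <- parse_brno(sfx, probe)
      if (!is.null(mods)) {
        fb$rows <- c(fb$rows, probe$rows)
        return(list(label = substr(chunk, 1, i - 1L), mods = mods))
      }
    }
  }
  list(label = chunk, mods = NULL)
}

## Suffix labels ---------------------------------------------------------------

parse_label <- function(chunk, family, mode, fb) {
  if (grepl("^[0-9]+$", chunk)) {
    if (nchar(chunk) > 1 && substr(chunk, 1, 1) == "0") {
      add_finding(fb, "leading_zero", "error",
                  sprintf("paralog number '%s' has a leading zero", chunk))
    }
    value <- as.integer(chunk)
    if (value == 0L && family != "H1") {
      add_finding(fb, "paralog_zero", "warning",
                  sprintf("paralog number 0 is only in established use for H1, not %s", family))
    }
    return(list(new_branch_label("paralog_number", value)))
  }
  if (grepl("^[Ss][0-9]+$", chunk)) {
    value <- as.integer(substr(chunk, 2, nchar(chunk)))
    if (value < 1L) {
      add_finding(fb, "splice_number", "error", "splice-variant numbers start at 1")
    }
    return(list(new_branch_label("splice_number", value)))
  }
  if (grepl("^[A-Za-z]$", chunk)) {
    return(list(new_branch_label("clade_letter", toupper(chunk))))
  }
  if (grepl("^[A-Za-z]{2,}$", chunk)) {
    add_finding(fb, "multi_letter_clade",
                if (mode == "strict") "error" else "warning",
                sprintf("multi-letter clade suffix '%s'; single letters are preferred -- consider registry normalization", chunk))
    return(list(new_branch_label("clade_letter", chunk)))
  }
  if (grepl("^[A-Za-z][0-9]+$", chunk)) {
    ## e.g. 'Z2' in H2A.Z2K4acK11ac: subtype number missing its period
    add_finding(fb, "missing_period",
                if (mode == "strict") "error" else "warning",
                sprintf("'%s' runs a letter suffix into a number; use a period between subtypes", chunk))
    num <- as.integer(sub("^[A-Za-z]", "", chunk))
    return(list(new_branch_label("clade_letter", toupper(substr(chunk, 1, 1))),
                new_branch_label("paralog_number", num)))
  }
  NULL
}

check_path_grammar <- function(path, mode, fb) {
  kinds <- vapply(path, function(l) l$kind, character(1))
  seen_number <- FALSE
  for (i in seq_along(kinds)) {
    if (kinds[i] == "paralog_number") seen_number <- TRUE
    if (kinds[i] == "clade_letter" && seen_number) {
      add_finding(fb, "letter_after_number", "error",
                  "a clade letter may not follow a paralog number")
    }
  }
  splice_at <- which(kinds == "splice_number")
  if (length(splice_at) > 1) {
    add_finding(fb, "splice_not_terminal", "error",
                "at most one splice label is allowed")
  } else if (length(splice_at) == 1 && splice_at != length(kinds)) {
    add_finding(fb, "splice_not_terminal", "error",
                "a splice label must be terminal")
  }
  invisible(NULL)
}

## Core-name token -------------------------------------------------------------

try_parse_core <- function(token, mode, fb) {
  gamma <- FALSE
  if (grepl("^\u03b3", token)) {
    gamma <- TRUE
    token <- sub("^\u03b3", "", token)
  } else if (mode == "lenient" && grepl("^gamma", token, ignore.case = TRUE)) {
    probe <- sub("^(?i)gamma", "", token, perl = TRUE)
    if (grepl("(?i)H2A|H2B|H1|H3|H4", probe, perl = TRUE)) {
      gamma <- TRUE
      token <- probe
      add_finding(fb, "legacy_glyph", "warning",
                  "spelled-out 'gamma' normalized to the \u03b3 phospho-state marker")
    }
  }
  if (grepl("\u2202", token)) token <- gsub("\u2202", "\u03b4", token)
  if (grepl("\u00b0$", token)) {
    if (mode == "strict") return(NULL)
    token <- sub("\u00b0$", ".0", token)
    add_finding(fb, "legacy_glyph", "warning",
                "legacy '\u00b0' glyph read as paralog number 0")
  }
  if (grepl("[\u00b0\u03b4]", token)) return(NULL)  # registry's job (e.g. H1\u03b4)

  m <- regexpr("(?i)(H2A|H2B|H1|H3|H4)", token, perl = TRUE)
  if (m == -1) return(NULL)
  prefix_raw <- substr(token, 1, m - 1L)
  family <- toupper(substr(token, m, m + attr(m, "match.length") - 1L))
  rest <- substr(token, m + attr(m, "match.length"), nchar(token))
  if (!grepl("^[A-Za-z]*$", prefix_raw)) return(NULL)

  prefix <- NULL
  if (nzchar(prefix_raw)) {
    if (prefix_raw != tolower(prefix_raw)) {
      add_finding(fb, "prefix_case", "warning",
                  sprintf("prefix '%s' should be lowercase", prefix_raw))
    }
    prefix <- tolower(prefix_raw)
  }

  path <- list()
  mods <- empty_modifications()

  if (nzchar(rest)) {
    if (grepl("^[.-]", rest)) {
      if (grepl("-", rest, fixed = TRUE)) {
        add_finding(fb, "dash_separator",
                    if (mode == "strict") "error" else "warning",
                    "dash label separators are superseded; use a period")
      }
      parts <- strsplit(rest, "[.-]")[[1]]
      chunks <- parts[-1]
      if (length(chunks) == 0 || any(!nzchar(chunks)) || grepl("[.-]$", rest)) {
        add_finding(fb, "empty_label", "error", "empty label between separators")
        chunks <- chunks[nzchar(chunks)]
      }
      for (j in seq_along(chunks)) {
        chunk <- chunks[j]
        if (j == length(chunks)) {
          peeled <- peel_brno(chunk, fb)
          if (!is.null(peeled$mods)) {
            mods <- peeled$mods
            chunk <- peeled$label
            if (!nzchar(chunk)) {
              add_finding(fb, "mod_after_period",
                          if (mode == "strict") "error" else "warning",
                          "Brno modifications attach without punctuation; drop the period")
              next
            }
          }
        }
        labels <- parse_label(chunk, family, mode, fb)
        if (is.null(labels)) return(NULL)
        path <- c(path, labels)
      }
    } else {
      ## unpunctuated remainder must be a pure Brno suffix (H3K27me3)
      got <- parse_brno(rest, fb)
      if (is.null(got)) return(NULL)
      mods <- got
    }
  }

  check_path_grammar(path, mode, fb)
  new_histone_name(family = family, prefix = prefix, suffix_path = path,
                   modifications = mods, gamma = gamma)
}

## Public parser ---------------------------------------------------------------

#' Parse a histone variant name
#'
#' Parses a free-text histone variant name into its structured parts: optional
#' lowercase prefix (macro, cen, sub), one of the five family names (H1, H2A,
#' H2B, H3, H4), an ordered suffix path of branch labels in which every period
#' marks a phylogenetic branch point, detached descriptors, Brno modifications
#' and the \eqn{\gamma} phospho-state marker. Descriptors are the
#' whitespace-separated tokens preceding the rightmost token that parses as a
#' core name; surrounding parentheses are stripped. Case is not significant
#' for the name itself.
#'
#' Strict mode enforces the grammar: clade-letter labels are single uppercase
#' letters, no clade letter may follow a paralog number, and a splice label
#' (`s` + number) must be terminal and unique. Lenient mode additionally
#' accepts dash separators (`H2A.Z-1`), multi-letter clade labels
#' (`H2A.Bbd`), unpunctuated subtype numbers (`H2A.Z2K4ac`), and the legacy
#' glyphs `gamma` and `\u00b0`, each downgraded to a warning-level finding.
#'
#' @param text A single name string, e.g. `"H2A.Z.1"`, `"TS H3.4"`,
#'   `"macroH2A.1.s1"` or `"H2A.ZS138ph"`.
#' @param mode `"strict"` (default) or `"lenient"`.
#' @return A `histone_name` object. Parse findings (warnings, and errors in
#'   lenient mode) are attached as a tibble in attribute `"findings"`.
#' @seealso [format_histone_name()], [validate_name()], [normalize_name()]
#' @export
#' @examples
#' parse_histone_name("H2A.Z.1")
#' parse_histone_name("TS H3.4")
#' parse_histone_name("H2A.ZS138ph")$modifications
parse_histone_name <- function(text, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  stopifnot(is.character(text), length(text) == 1)
  raw <- trimws(text)
  if (!nzchar(raw)) stop_parse("empty name")
  tokens <- strsplit(raw, "\\s+")[[1]]

  fb <- new_findings()
  parsed <- NULL
  idx <- NA_integer_
  for (i in rev(seq_along(tokens))) {
    probe <- new_findings()
    p <- try_parse_core(tokens[i], mode, probe)
    if (!is.null(p)) {
      parsed <- p
      idx <- i
      fb$rows <- c(fb$rows, probe$rows)
      break
    }
  }
  if (is.null(parsed)) {
    stop_parse(sprintf("no token parses as a core histone name: '%s'",
                       tokens[length(tokens)]))
  }
  descriptors <- tokens[seq_len(idx - 1L)]
  descriptors <- gsub("^\\(|\\)$", "", descriptors)
  if (idx < length(tokens)) {
    add_finding(fb, "trailing_tokens",
                if (mode == "strict") "error" else "warning",
                sprintf("tokens after the name treated as descriptors: %s",
                        paste(tokens[(idx + 1L):length(tokens)], collapse = " ")))
    descriptors <- c(descriptors,
                     gsub("^\\(|\\)$", "", tokens[(idx + 1L):length(tokens)]))
  }
  parsed$descriptors <- descriptors

  findings <- findings_tbl(fb)
  if (mode == "strict" && any(findings$level == "error")) {
    bad <- findings[findings$level == "error", ]
    stop_parse(sprintf("invalid name '%s': %s", raw,
                       paste(unique(bad$message), collapse = "; ")),
               rule = bad$rule[1])
  }
  attr(parsed, "findings") <- findings
  parsed
}
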