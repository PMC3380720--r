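#' Validate a histone variant name against the nomenclature guidelines
#'
#' Checks a free-text name against the written guidelines and returns one
#' finding per violated rule rather than throwing. Warning-level findings
#' cover style points (uppercase prefix, multi-letter clade suffix, dash
#' separators, unknown modification types, paralog 0 outside H1, and any
#' other departure from canonical form); error-level findings cover grammar
#' violations (a clade letter after a paralog number, a non-terminal splice
#' label, empty labels, unparseable input).
#'
#' An empty report is equivalent to the name being strict-canonical:
#' re-formatting it changes nothing.
#'
#' @param text A single name string.
#' @return A tibble with columns `rule`, `level` (`"error"`/`"warning"`),
#'   `message`, `start`, `end`.
#' @export
#' @examples
#' validate_name("H2A.Z.1")    # empty: canonical
#' validate_name("MacroH2A")   # prefix-case warning
#' validate_name("H2A.Bbd")    # multi-letter clade warning
validate_name <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  parsed <- tryCatch(parse_histone_name(text, mode = "lenient"),
                     hv_parse_error = function(e) e)
  if (inherits(parsed, "hv_parse_error")) {
    return(tibble::tibble(rule = parsed$rule %||% "parse_error",
                          level = "error",
                          message = conditionMessage(parsed),
                          start = 1L, end = nchar(text)))
  }
  report <- attr(parsed, "findings")
  clean <- paste(strsplit(trimws(text), "\\s+")[[1]], collapse = " ")
  if (nrow(report) == 0 && format_histone_name(parsed) != clean) {
    report <- tibble::tibble(
      rule = "non_canonical_form", level = "warning",
      message = sprintf("'%s' is accepted but its canonical form is '%s'",
                        clean, format_histone_name(parsed)),
      start = 1L, end = nchar(text))
  }
  report
}

`%||%` <- function(x, y) if (is.null(x)) y else x
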