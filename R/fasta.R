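## FASTA in/out for protein records, on top of Biostrings.

#' Read protein sequences from FASTA
#'
#' Record ids are the first whitespace-delimited header token; sequences are
#' uppercased and must use the 20 standard one-letter codes plus X.
#' Duplicate ids and invalid characters are rejected with the offending
#' line number.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence`, `organism` (`NA` unless a
#'   header carries an `organism=` tag).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no FASTA file at '%s'", path))
  lines <- readLines(path, warn = FALSE)
  first_real <- which(nzchar(trimws(lines)))[1]
  if (is.na(first_real) || !startsWith(lines[first_real], ">")) {
    rlang::abort(sprintf("malformed FASTA at line %d: expected a '>' header",
                         if (is.na(first_real)) 1L else first_real),
                 class = "hv_fasta_error")
  }
  ## residue validation on the raw lines (Biostrings silently drops invalid
  ## codes), so errors can name the offending line
  allowed <- c(hv_aa20, "X")
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln) || startsWith(ln, ">")) next
    bad <- setdiff(unique(strsplit(toupper(ln), "")[[1]]), allowed)
    if (length(bad) > 0) {
      rlang::abort(sprintf("invalid residue '%s' at line %d", bad[1], k),
                   class = "hv_fasta_error")
    }
  }
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) {
                    rlang::abort(sprintf("malformed FASTA in '%s': %s", path,
                                         conditionMessage(e)),
                                 class = "hv_fasta_error")
                  })
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    rlang::abort(sprintf("duplicate FASTA id '%s'", dup), class = "hv_fasta_error")
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    rlang::abort(sprintf("empty sequence for id '%s'", ids[!nzchar(seqs)][1]),
                 class = "hv_fasta_error")
  }
  organism <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("organism=\\S+", h))
    if (length(m) == 0) NA_character_ else sub("^organism=", "", m)
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(id = ids, sequence = unname(seqs), organism = organism)
}

#' Write protein records to FASTA
#'
#' @param records A data frame with columns `id`, `sequence` (and optionally
#'   `organism`, written as an `organism=` header tag).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  headers <- records$id
  if ("organism" %in% names(records)) {
    tag <- ifelse(is.na(records$organism), "",
                  paste0(" organism=", records$organism))
    headers <- paste0(headers, tag)
  }
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
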