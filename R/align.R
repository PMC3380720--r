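## Global (Needleman-Wunsch) alignment with a deterministic traceback.
## Default scoring is the simplest auditable scheme: match +1, mismatch 0,
## linear gap -1; a substitution matrix may be supplied instead.

#' Alignment scoring scheme
#'
#' @param match,mismatch Scores used when no substitution matrix is given.
#' @param gap Linear per-residue gap penalty (a negative number).
#' @param substitution Optional square numeric matrix with residue dimnames;
#'   overrides `match`/`mismatch`.
#' @return A list of class `hv_scoring`.
#' @export
alignment_scoring <- function(match = 1, mismatch = 0, gap = -1,
                              substitution = NULL) {
  if (!is.null(substitution)) {
    stopifnot(is.matrix(substitution),
              !is.null(rownames(substitution)),
              identical(rownames(substitution), colnames(substitution)))
  }
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 substitution = substitution), class = "hv_scoring")
}

pair_score <- function(a, b, scoring) {
  if (!is.null(scoring$substitution)) return(scoring$substitution[a, b])
  if (a == b) scoring$match else scoring$mismatch
}

#' Optimal global alignment of two sequences
#'
#' Needleman-Wunsch with linear gap costs. The traceback is deterministic
#' with fixed operator preference diagonal > up (gap in `b`) > left (gap in
#' `a`), so identical inputs always yield the identical aligned pair.
#'
#' @param a,b Sequence strings (either may be empty).
#' @param scoring An [alignment_scoring()] scheme.
#' @return A list of class `hv_alignment`: `score`, `aligned` (character
#'   vector of the two gapped rows, `-` for gaps).
#' @export
#' @examples
#' global_align("AAIG", "SAVM")$score   # 1 under the default scheme
global_align <- function(a, b, scoring = alignment_scoring()) {
  a <- toupper(a); b <- toupper(b)
  av <- if (nzchar(a)) strsplit(a, "")[[1]] else character()
  bv <- if (nzchar(b)) strsplit(b, "")[[1]] else character()
  n <- length(av); m <- length(bv)
  gap <- scoring$gap

  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * 0:n
  S[1L, ] <- gap * 0:m
  if (n > 0 && m > 0) {
    for (i in seq_len(n)) {
      sub_row <- vapply(bv, pair_score, numeric(1), a = av[i], scoring = scoring)
      for (j in seq_len(m)) {
        S[i + 1L, j + 1L] <- max(S[i, j] + sub_row[j],
                                 S[i, j + 1L] + gap,
                                 S[i + 1L, j] + gap)
      }
    }
  }

  ## traceback, diagonal > up > left
  ra <- character(); rb <- character()
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1L, j + 1L] == S[i, j] + pair_score(av[i], bv[j], scoring)) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0 && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
    }
  }
  structure(list(score = S[n + 1L, m + 1L],
                 aligned = c(paste(ra, collapse = ""), paste(rb, collapse = ""))),
            class = "hv_alignment")
}

#' @export
print.hv_alignment <- function(x, ...) {
  cat("<alignment> score ", x$score, "\n  ", x$aligned[1], "\n  ",
      x$aligned[2], "\n", sep = "")
  invisible(x)
}

#' Proportion of differing sites between two aligned sequences
#'
#' The p-distance: mismatches divided by the number of columns in which
#' neither row carries a gap. Columns with a gap in either row are excluded.
#'
#' @param aligned_a,aligned_b Equal-length gapped strings.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' p_distance("AAIG", "SAVM")  # 0.75
p_distance <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b)) {
    rlang::abort("aligned sequences must have equal length", class = "hv_seq_error")
  }
  x <- strsplit(toupper(aligned_a), "")[[1]]
  y <- strsplit(toupper(aligned_b), "")[[1]]
  keep <- x != "-" & y != "-"
  if (!any(keep)) {
    rlang::abort("no comparable columns: p-distance undefined",
                 class = "hv_distance_error")
  }
  sum(x[keep] != y[keep]) / sum(keep)
}

#' Assign a histone family by nearest reference
#'
#' Aligns the query globally against every member of a family-tagged
#' reference panel and returns the family of the best-scoring reference.
#' Ties are broken toward the lexicographically smallest reference id, so
#' the result does not depend on panel order.
#'
#' @param seq A sequence string or record with a `sequence` field.
#' @param panel A data frame with columns `id`, `family`, `sequence`.
#' @param scoring An [alignment_scoring()] scheme.
#' @return A list of class `hv_family_call`: `family`, `best_id`, and
#'   `scores`, a tibble of all per-reference scores for audit.
#' @export
assign_family <- function(seq, panel, scoring = alignment_scoring()) {
  if (is.null(panel) || nrow(panel) == 0) {
    rlang::abort("reference panel is empty", class = "hv_panel_error")
  }
  stopifnot(all(c("id", "family", "sequence") %in% names(panel)))
  s <- extract_sequence(seq)
  scores <- vapply(panel$sequence, function(ref)
    global_align(s, ref, scoring)$score, numeric(1), USE.NAMES = FALSE)
  tab <- tibble::tibble(id = panel$id, family = panel$family, score = scores)
  tab <- tab[order(-tab$score, tab$id), ]
  structure(list(family = tab$family[1], best_id = tab$id[1], scores = tab),
            class = "hv_family_call")
}

#' @export
print.hv_family_call <- function(x, ...) {
  cat("<family_call> ", x$family, " (best reference: ", x$best_id, ", score ",
      x$scores$score[1], ")\n", sep = "")
  invisible(x)
}

#' Pairwise p-distance matrix for a set of sequences
#'
#' Aligns every pair globally and records the p-distance over the aligned
#' columns; a convenience feeding [build_nj_tree()].
#'
#' @param records A data frame with columns `id`, `sequence`.
#' @param scoring An [alignment_scoring()] scheme.
#' @return A symmetric labeled distance matrix with zero diagonal.
#' @export
distance_matrix <- function(records, scoring = alignment_scoring()) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  n <- nrow(records)
  D <- matrix(0, n, n, dimnames = list(records$id, records$id))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        al <- global_align(records$sequence[i], records$sequence[j], scoring)
        D[i, j] <- D[j, i] <- p_distance(al$aligned[1], al$aligned[2])
      }
    }
  }
  D
}
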