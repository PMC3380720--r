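# Independent oracles and small helpers shared across the suite.

# Exhaustive global-alignment score: plain recursion over all monotone
# alignments, no DP table or traceback, so it is independent of the
# implementation it checks. Exponential; only for short sequences.
enum_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  if (!nzchar(a) && !nzchar(b)) return(0)
  best <- -Inf
  if (nzchar(a) && nzchar(b)) {
    s <- if (substr(a, 1, 1) == substr(b, 1, 1)) match else mismatch
    best <- max(best, s + enum_align_score(substr(a, 2, nchar(a)),
                                           substr(b, 2, nchar(b)),
                                           match, mismatch, gap))
  }
  if (nzchar(a)) {
    best <- max(best, gap + enum_align_score(substr(a, 2, nchar(a)), b,
                                             match, mismatch, gap))
  }
  if (nzchar(b)) {
    best <- max(best, gap + enum_align_score(a, substr(b, 2, nchar(b)),
                                             match, mismatch, gap))
  }
  best
}

# Biostrings global alignment with the same linear-gap scheme, as a second
# independent route.
biostrings_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  alpha <- unique(strsplit(paste0(a, b, "A"), "")[[1]])
  mat <- matrix(mismatch, length(alpha), length(alpha),
                dimnames = list(alpha, alpha))
  diag(mat) <- match
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = -gap,
                                scoreOnly = TRUE)
}

all_strings <- function(alphabet, max_len) {
  out <- ""
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), l))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

expect_name_equal <- function(got, want) {
  attr(got, "findings") <- NULL
  attr(want, "findings") <- NULL
  expect_equal(got, want)
}

unified_of <- function(x) {
  if (is.null(x$unified)) NA_character_ else format_histone_name(x$unified)
}

random_aa_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
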