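## Neighbor joining with the Q-criterion, a fixed tie-break and clamping of
## negative branch lengths, so the same matrix always yields the same tree.

check_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    rlang::abort("distance input must be a square matrix", class = "hv_matrix_error")
  }
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) < 3) {
    rlang::abort("neighbor joining needs at least 3 taxa", class = "hv_matrix_error")
  }
  if (max(abs(d - t(d))) > 1e-8) {
    rlang::abort("distance matrix must be symmetric", class = "hv_matrix_error")
  }
  if (any(d < -1e-12)) {
    rlang::abort("distances must be non-negative", class = "hv_matrix_error")
  }
  if (any(abs(diag(d)) > 1e-12)) {
    rlang::abort("distance matrix must have a zero diagonal", class = "hv_matrix_error")
  }
  d
}

fmt_bl <- function(x) format(max(x, 0), digits = 10, scientific = FALSE, trim = TRUE)

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: at each step the pair minimizing the
#' Q-criterion \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j} is joined, with
#' branch lengths \eqn{b_i = d_{ij}/2 + (r_i - r_j)/(2(n-2))}. Ties on Q are
#' broken deterministically toward the candidate pair first in (row, column)
#' order of the current matrix; negative branch lengths are clamped to zero.
#' The final three lineages are joined at an unrooted trifurcation using the
#' three-taxon closed form, e.g. \eqn{b_A = (d_{AB} + d_{AC} - d_{BC})/2}.
#'
#' @param d A symmetric, labeled, non-negative distance matrix with zero
#'   diagonal and at least 3 taxa.
#' @return A list of class `hv_nj_tree` with `tree` (an [ape::read.tree]
#'   `phylo` object) and `newick` (the serialized string).
#' @export
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' build_nj_tree(d)$newick
build_nj_tree <- function(d) {
  d <- check_distance_matrix(d)
  labels <- rownames(d)
  ## each active node carries a newick fragment
  frag <- as.list(labels)
  names(frag) <- labels
  D <- d

  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    best <- NULL; best_q <- Inf
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        q <- (n - 2) * D[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) { best_q <- q; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[[i]], fmt_bl(bi),
                        frag[[j]], fmt_bl(bj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dk <- dk[-c(i, j)]
    keep <- setdiff(seq_len(n), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, dk), c(dk, 0))
    new_name <- paste0("node", length(frag))
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- new_name
    frag <- c(frag[keep], stats::setNames(list(new_frag), new_name))
  }

  bA <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  bB <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  bC <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[[1]], fmt_bl(bA), frag[[2]], fmt_bl(bB),
                    frag[[3]], fmt_bl(bC))
  structure(list(tree = ape::read.tree(text = newick), newick = newick),
            class = "hv_nj_tree")
}

#' @export
print.hv_nj_tree <- function(x, ...) {
  cat("<nj_tree> ", length(x$tree$tip.label), " tips\n", x$newick, "\n", sep = "")
  invisible(x)
}
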