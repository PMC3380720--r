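## Deterministic synthetic fixtures: protein scaffolds with planted diagnostic
## fragments, count-based clade simulation, and a random valid-name generator.
## No attempt is made to produce biologically realistic full-length histones;
## the scaffolds exist to carry planted truths for the typing layer.

with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic protein scaffold with planted fragments
#'
#' Draws a random amino-acid sequence from a composition (uniform over the
#' 20 standard residues by default) and overwrites it with the given
#' fragments at their anchors. A `"c_terminus"` anchor places the fragment
#' so it ends exactly at the last residue; an integer anchor is a 1-based
#' start position. Overlapping embeddings are an error. The same seed and
#' specification always produce byte-identical output.
#'
#' @param scaffold_length Total sequence length.
#' @param embeddings A list of `list(fragment =, anchor =)` entries, where
#'   `anchor` is `"c_terminus"` or an integer start position.
#' @param seed Integer seed.
#' @param composition Named numeric vector of residue frequencies; default
#'   uniform over the 20 standard residues.
#' @param id Record id.
#' @param truth_family,truth_motif,truth_h3_class,tree_clade Truth-table
#'   annotations carried alongside the record.
#' @return A list with `record` (tibble: `id`, `sequence`, `organism`) and
#'   `truth` (one-row tibble: `id`, `truth_family`, `truth_motif`,
#'   `truth_h3_class`, `tree_clade`).
#' @export
#' @examples
#' sc <- make_scaffold(60, list(list(fragment = "SQEY", anchor = "c_terminus")),
#'                     seed = 7)
#' substr(sc$record$sequence, 57, 60)  # "SQEY"
make_scaffold <- function(scaffold_length, embeddings = list(), seed = 1L,
                          composition = NULL, id = "scaffold",
                          truth_family = NA_character_,
                          truth_motif = NA_character_,
                          truth_h3_class = NA_character_,
                          tree_clade = NA_character_) {
  stopifnot(scaffold_length >= 1)
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1, 20), hv_aa20)
  }
  spans <- lapply(embeddings, function(e) {
    frag <- toupper(e$fragment)
    len <- nchar(frag)
    start <- if (identical(e$anchor, "c_terminus")) {
      scaffold_length - len + 1L
    } else {
      as.integer(e$anchor)
    }
    if (start < 1L || start + len - 1L > scaffold_length) {
      rlang::abort(sprintf("fragment '%s' does not fit in a scaffold of length %d",
                           frag, scaffold_length), class = "hv_fixture_error")
    }
    list(frag = frag, start = start, end = start + len - 1L)
  })
  if (length(spans) > 1) {
    ord <- order(vapply(spans, `[[`, integer(1), "start"))
    spans <- spans[ord]
    for (k in seq_len(length(spans) - 1)) {
      if (spans[[k + 1]]$start <= spans[[k]]$end) {
        rlang::abort("overlapping embeddings", class = "hv_fixture_error")
      }
    }
  }
  base <- with_preserved_seed(seed, {
    sample(names(composition), scaffold_length, replace = TRUE,
           prob = composition)
  })
  for (sp in spans) {
    base[sp$start:sp$end] <- strsplit(sp$frag, "")[[1]]
  }
  seq <- paste(base, collapse = "")
  list(record = tibble::tibble(id = id, sequence = seq,
                               organism = NA_character_),
       truth = tibble::tibble(id = id, truth_family = truth_family,
                              truth_motif = truth_motif,
                              truth_h3_class = truth_h3_class,
                              tree_clade = tree_clade))
}

#' Simulate sequences along a tree by counted substitutions
#'
#' Starting from the root sequence, applies exactly `counts[e]` random
#' substitutions along each edge `e` of the tree (positions drawn without
#' replacement within an edge; the replacement residue always differs from
#' the current one; no back-substitution bookkeeping across edges). Count-
#' based rather than rate-based mutation keeps the fixture exactly
#' reproducible for a given seed.
#'
#' @param tree An [ape] `phylo` tree.
#' @param root_seq Root amino-acid sequence.
#' @param seed Integer seed.
#' @param counts Integer substitution count per edge, in `tree$edge` order;
#'   default `round(tree$edge.length)`.
#' @return A tibble of leaf records (`id`, `sequence`, `organism = NA`).
#' @export
simulate_clades <- function(tree, root_seq, seed = 1L, counts = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(counts)) {
    if (is.null(tree$edge.length)) {
      rlang::abort("supply counts or a tree with edge lengths")
    }
    counts <- as.integer(round(tree$edge.length))
  }
  stopifnot(length(counts) == nrow(tree$edge))
  L <- nchar(root_seq)
  if (any(counts > L)) {
    rlang::abort("substitution counts cannot exceed the sequence length",
                 class = "hv_fixture_error")
  }
  root_vec <- strsplit(toupper(root_seq), "")[[1]]
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root_node]] <- root_vec

  with_preserved_seed(seed, {
    ## preorder traversal: parents of tree$edge rows come before children
    ord <- ape::reorder.phylo(tree, "cladewise")
    edge_order <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                        paste(tree$edge[, 1], tree$edge[, 2]))
    for (e in edge_order) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      s <- seqs[[parent]]
      k <- counts[e]
      if (k > 0) {
        pos <- sample.int(L, k)
        for (p in pos) {
          s[p] <- sample(setdiff(hv_aa20, s[p]), 1)
        }
      }
      seqs[[child]] <- s
    }
  })
  tibble::tibble(id = tree$tip.label,
                 sequence = vapply(seq_len(n_tip),
                                   function(i) paste(seqs[[i]], collapse = ""),
                                   character(1)),
                 organism = NA_character_)
}

#' Synthetic family reference panel
#'
#' A deterministic panel of random scaffolds tagged with the five family
#' names, for exercising [assign_family()] and [propose_name()] when no real
#' reference panel is supplied. The sequences are synthetic and carry no
#' homology to real histones.
#'
#' @param seed Integer seed.
#' @param length Sequence length per reference.
#' @return A tibble with columns `id`, `family`, `sequence`.
#' @export
reference_panel <- function(seed = 42L, length = 120L) {
  rows <- lapply(seq_along(hv_families), function(i) {
    fam <- hv_families[i]
    sc <- make_scaffold(length, seed = seed + i,
                        id = paste0("ref_", fam), truth_family = fam)
    tibble::tibble(id = sc$record$id, family = fam,
                   sequence = sc$record$sequence)
  })
  dplyr::bind_rows(rows)
}

#' Random strictly-valid histone names
#'
#' Generates structurally valid names under the strict grammar: optional
#' prefix, family, clade letters before paralog numbers, at most one
#' terminal splice label, optional descriptors, Brno modifications and
#' \eqn{\gamma} flag. Used for structural round-trip properties.
#'
#' @param n Number of names.
#' @param seed Integer seed.
#' @return A list of `histone_name` objects.
#' @export
random_histone_names <- function(n, seed = 1L) {
  with_preserved_seed(seed, {
    lapply(seq_len(n), function(i) {
      family <- sample(hv_families, 1)
      prefix <- sample(c(NA, "macro", "cen", "sub"), 1,
                       prob = c(0.7, 0.1, 0.1, 0.1))
      n_letters <- sample(0:2, 1, prob = c(0.5, 0.4, 0.1))
      n_numbers <- sample(0:2, 1, prob = c(0.35, 0.5, 0.15))
      path <- list()
      for (l in seq_len(n_letters)) {
        path <- c(path, list(new_branch_label("clade_letter", sample(LETTERS, 1))))
      }
      for (l in seq_len(n_numbers)) {
        val <- if (family == "H1" && stats::runif(1) < 0.1) 0L else
          sample.int(20L, 1)
        path <- c(path, list(new_branch_label("paralog_number", val)))
      }
      if (length(path) > 0 && stats::runif(1) < 0.2) {
        path <- c(path, list(new_branch_label("splice_number", sample.int(4L, 1))))
      }
      descriptors <- if (stats::runif(1) < 0.3) {
        sample(c("TS", "OO", "GC", "RC", "RI", "CS", "human", "bdelloid"),
               sample.int(2L, 1))
      } else character()
      mods <- empty_modifications()
      if (stats::runif(1) < 0.3) {
        k <- sample.int(2L, 1)
        mods <- tibble::tibble(
          residue = sample(hv_aa20, k, replace = TRUE),
          position = sample.int(300L, k),
          type = sample(hv_mod_seed, k, replace = TRUE),
          multiplicity = ifelse(stats::runif(k) < 0.4, sample.int(3L, k,
                                                                  replace = TRUE),
                                NA_integer_))
      }
      gamma <- stats::runif(1) < 0.1
      new_histone_name(family = family,
                       prefix = if (is.na(prefix)) NULL else prefix,
                       suffix_path = path, descriptors = descriptors,
                       modifications = mods, gamma = gamma)
    })
  })
}
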