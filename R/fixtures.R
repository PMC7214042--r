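# Seed-deterministic synthetic fixtures: a structural template family, a
# structureless negative control, a hand-sized parsimony example with its
# tree, and a degenerate invariant alignment. These are the package's test
# inputs; everything is generated in code, nothing is shipped as data.

#' A small nested helix structure
#'
#' `n_pairs` basepairs arranged in `n_helices` nested helices spread over
#' `L` columns.
#'
#' @param L alignment length.
#' @param n_pairs total basepairs.
#' @param n_helices number of helices (default 3).
#' @return an `rna_structure`.
#' @export
fixture_structure <- function(L = 60, n_pairs = 15, n_helices = 3) {
  per <- diff(round(seq(0, n_pairs, length.out = n_helices + 1)))
  span <- L %/% n_helices
  pi <- integer(0); pj <- integer(0)
  for (h in seq_len(n_helices)) {
    off <- (h - 1L) * span
    k <- per[h]
    if (2 * k + 2 > span) cp_stat_error("structure does not fit in L")
    pi <- c(pi, off + seq_len(k))
    pj <- c(pj, off + span - seq_len(k) + 1L)
  }
  secondary_structure(pi, pj)
}

random_root <- function(L, struct, model, seed) {
  set.seed(derive_seed(seed, 17L))
  codes <- sample_from_probs(cumsum(model$pi), L)
  impute_root({codes[c(struct$pairs)] <- 0L; codes}, struct, model)
}

#' Generate a synthetic structural template alignment
#'
#' Evolves a random root down a random tree (uniform branch lengths, scaled
#' to a given mean root-to-tip depth) under the default basepair-aware
#' model, yielding an annotated alignment with genuine covariation at the
#' paired columns.
#'
#' @param n_seq number of sequences.
#' @param L root length.
#' @param n_pairs basepairs in the annotated structure (0 for a
#'   structureless control).
#' @param depth mean root-to-tip path length in expected substitutions per
#'   site (controls diversity).
#' @param seed integer seed.
#' @return a `covaln` with `SS_cons` (when `n_pairs > 0`).
#' @export
fixture_template <- function(n_seq = 25, L = 60, n_pairs = 15, depth = 0.9,
                             seed = 7) {
  struct <- if (n_pairs > 0) fixture_structure(L, n_pairs) else NULL
  model <- default_model()
  tr <- local({
    set.seed(derive_seed(seed, 23L))
    ape::rtree(n_seq)
  })
  dep <- mean(ape::node.depth.edgelength(tr)[seq_len(n_seq)])
  tr <- rescale_branches(tr, depth / dep)
  root <- if (is.null(struct)) {
    local({set.seed(derive_seed(seed, 17L)); sample_from_probs(cumsum(model$pi), L)})
  } else {
    random_root(L, struct, model, seed)
  }
  evolve_down_tree(root, tr, model, struct, seed = derive_seed(seed, 31L))
}

#' An invariant (zero-variation) annotated alignment
#'
#' All rows identical: every column has one residue, all substitution
#' counts are 0, and alignment power is exactly 0.
#'
#' @param n_seq number of identical rows.
#' @param L length.
#' @param n_pairs annotated basepairs.
#' @param seed seed for the single random row.
#' @return a `covaln` with `SS_cons`.
#' @export
fixture_invariant <- function(n_seq = 10, L = 40, n_pairs = 8, seed = 7) {
  struct <- fixture_structure(L, n_pairs, n_helices = 2)
  model <- default_model()
  row <- paste(c("A", "C", "G", "U")[random_root(L, struct, model, seed)],
               collapse = "")
  new_alignment(paste0("seq", seq_len(n_seq)), rep(row, n_seq),
                ss_cons = wuss_from_pairs(struct, L))
}

#' Hand-sized parsimony fixture: alignment plus matching tree
#'
#' Six sequences, eight columns, with a fixed tree; per-column Fitch counts
#' were worked by hand once and are frozen in the test suite.
#'
#' @return list with `aln` (a `covaln`) and `tree` (ape `phylo`).
#' @export
fixture_fitch <- function() {
  newick <- "(((a:0.1,b:0.1):0.1,c:0.2):0.1,((d:0.1,e:0.1):0.1,f:0.2):0.1);"
  aln <- new_alignment(
    c("a", "b", "c", "d", "e", "f"),
    c("AAGGAC-U",
      "AAGGACGU",
      "AAGGUCGU",
      "ACGUACGA",
      "ACGUACGA",
      "ACGUGCGA"))
  list(aln = aln, tree = ape::read.tree(text = newick))
}
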