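# Fitch small parsimony: minimum number of substitutions per alignment
# column (and per proposed basepair, s_ij = s_i + s_j) on a tree. Branch
# lengths are ignored; gapped or ambiguous leaves carry the full residue
# alphabet and therefore never force a substitution. Implemented on bitmask
# state sets, vectorized across all columns at once.

RESIDUE_MASK <- c(15L, 1L, 2L, 4L, 8L, 15L)  # indexed by code+1: gap,A,C,G,U,N

prepare_fitch_tree <- function(tree) {
  as_rooted_binary(tree)
}

# masks: integer matrix (n_leaves x L), rownames = leaf labels
fitch_engine <- function(tree, masks) {
  tree <- prepare_fitch_tree(tree)
  tips <- tree$tip.label
  if (!setequal(rownames(masks), tips) || length(tips) != nrow(masks)) {
    cp_stat_error("tree/column leaf-set mismatch")
  }
  L <- ncol(masks)
  po <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tips)
  n_node <- n_tip + po$Nnode
  node_mask <- matrix(0L, n_node, L)
  node_mask[seq_len(n_tip), ] <- masks[tips, , drop = FALSE]
  counts <- numeric(L)
  seen <- logical(n_node)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]
    ch <- po$edge[e, 2L]
    cm <- node_mask[ch, ]
    if (!seen[par]) {
      node_mask[par, ] <- cm
      seen[par] <- TRUE
    } else {
      inter <- bitwAnd(node_mask[par, ], cm)
      z <- inter == 0L
      counts <- counts + z
      node_mask[par, ] <- ifelse(z, bitwOr(node_mask[par, ], cm), inter)
    }
  }
  counts
}

states_to_masks <- function(states) {
  # states: residue codes 0..5 or characters
  if (is.character(states)) {
    codes <- aln_matrix(new_alignment(names(states), states))[, 1]
  } else {
    codes <- as.integer(states)
  }
  m <- matrix(RESIDUE_MASK[codes + 1L], ncol = 1L)
  rownames(m) <- names(states)
  m
}

#' Minimum substitutions at one column (Fitch parsimony)
#'
#' @param tree an ape `phylo` tree whose tips match `names(column)`.
#' @param column named vector of leaf states: residue characters
#'   (`A/C/G/U/T`, gap, ambiguity) or integer codes 0..5.
#' @return the Fitch minimum number of substitutions (integer).
#' @export
fitch_column <- function(tree, column) {
  if (is.null(names(column))) cp_stat_error("column states must be named by leaf")
  as.integer(fitch_engine(tree, states_to_masks(column)))
}

#' Per-column and per-pair substitution counts for an alignment
#'
#' Applies Fitch parsimony to every column; the substitution count of a
#' proposed basepair (i, j) is the sum `s_i + s_j` of the independent
#' per-column counts.
#'
#' @param aln a `covaln` object.
#' @param tree an ape `phylo` tree with tips matching the sequence names.
#' @return an object of class `subs_counts`: list with `per_column`
#'   (integer vector of length L) and `n_leaves`.
#' @export
substitution_counts <- function(aln, tree) {
  m <- aln_matrix(aln)
  masks <- matrix(RESIDUE_MASK[m + 1L], nrow = nrow(m),
                  dimnames = list(rownames(m), NULL))
  s <- as.integer(fitch_engine(tree, masks))
  structure(list(per_column = s, n_leaves = nrow(m), L = ncol(m)),
            class = "subs_counts")
}

#' Substitutions for a column pair under column independence
#'
#' @param subs a `subs_counts` object.
#' @param i,j column indices (1-based).
#' @return `s_i + s_j`.
#' @export
pair_substitutions <- function(subs, i, j) {
  subs$per_column[i] + subs$per_column[j]
}

#' Joint pairwise substitutions on the 16-state basepair alphabet
#'
#' Optional, more expensive alternative to the independent-column count:
#' Fitch parsimony on ordered residue pairs, where a substitution is any
#' change of the joint pair state. A leaf with a gap on one side carries all
#' four residues on that side.
#'
#' @param tree an ape `phylo` tree.
#' @param col_i,col_j named leaf-state vectors as in [fitch_column()].
#' @return minimum number of joint pair-state changes; always
#'   `<= fitch_column(i) + fitch_column(j)`.
#' @export
joint_pair_substitutions <- function(tree, col_i, col_j) {
  mi <- states_to_masks(col_i)
  mj <- states_to_masks(col_j)
  if (!identical(rownames(mi), rownames(mj))) {
    cp_stat_error("the two columns label different leaf sets")
  }
  pair_mask <- function(ma, mb) {
    a_set <- which(bitwAnd(ma, 2L^(0:3)) > 0L)
    b_set <- which(bitwAnd(mb, 2L^(0:3)) > 0L)
    idx <- as.vector(outer(a_set - 1L, b_set, function(a, b) a * 4L + b))
    sum(2L^(idx - 1L))
  }
  m16 <- matrix(mapply(pair_mask, mi[, 1], mj[, 1]), ncol = 1L)
  rownames(m16) <- rownames(mi)
  as.integer(fitch_engine(tree, m16))
}
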