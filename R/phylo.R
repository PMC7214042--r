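# Phylogenetic tree handling: Newick IO, distance-based tree building,
# rescaling and taxon subsampling. Trees are ape "phylo" objects throughout;
# the downstream method (parsimony counts, null simulation) is agnostic to
# how the tree was produced, so a user-supplied tree from any ML program can
# replace the built-in neighbor-joining default.

#' Read a Newick tree
#'
#' @param path path to a Newick file (first tree is used).
#' @return an ape `phylo` object; missing branch lengths default to 0.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (is.null(tr) || !inherits(tr, "phylo")) {
    cp_format_error("cannot parse Newick file: ", path)
  }
  if (anyDuplicated(tr$tip.label)) {
    cp_format_error("duplicate leaf labels in tree: ",
                    paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0)) cp_format_error("negative branch length in ", path)
  tr
}

#' Write a Newick tree
#'
#' @param tree an ape `phylo` object.
#' @param path output path.
#' @return invisibly, `path`; round-trips topology, labels and lengths to 1e-9.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Pairwise fractional identity matrix of an alignment
#'
#' Identity of two rows is the fraction of matching residues over columns
#' where both rows carry an unambiguous residue; a pair with no mutually
#' ungapped column gets identity 0 (with a warning). Diagonal is 1.
#'
#' @param aln a `covaln` object (or an encoded integer matrix).
#' @return symmetric numeric matrix in \[0, 1\] with an `avg_identity`
#'   attribute (mean over off-diagonal pairs).
#' @export
pairwise_identity <- function(aln) {
  m <- if (inherits(aln, "covaln")) aln_matrix(aln) else aln
  if (nrow(m) < 2L) cp_stat_error("need at least 2 sequences")
  res <- (m >= 1L & m <= 4L) * 1
  shared <- tcrossprod(res)
  match <- matrix(0, nrow(m), nrow(m))
  for (v in 1:4) {
    iv <- (m == v) * 1
    match <- match + tcrossprod(iv)
  }
  if (any(shared[upper.tri(shared)] == 0)) {
    warning("sequence pair(s) with no mutually ungapped columns; identity set to 0")
  }
  id <- ifelse(shared > 0, match / shared, 0)
  diag(id) <- 1
  dimnames(id) <- list(rownames(m), rownames(m))
  attr(id, "avg_identity") <- mean(id[upper.tri(id)])
  id
}

#' Jukes-Cantor distances from an identity matrix
#'
#' `d = -(3/4) log(1 - (4/3) p)` with `p = 1 - identity`; saturated pairs
#' (log argument <= 0) are capped.
#'
#' @param id identity matrix with entries in \[0, 1\].
#' @param max_dist cap applied at saturation (default 10).
#' @return distance matrix of the same shape.
#' @export
identity_to_distance <- function(id, max_dist = 10) {
  p <- 1 - id
  arg <- 1 - 4 * p / 3
  d <- ifelse(arg > 0, -0.75 * log(pmax(arg, .Machine$double.xmin)), max_dist)
  d <- pmin(d, max_dist)
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape) with negative branch lengths
#' clamped to zero. Deterministic for a given matrix.
#'
#' @param d symmetric nonnegative distance matrix (zero diagonal), n >= 2.
#' @return an unrooted ape `phylo` tree (rooted two-leaf tree for n = 2).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) cp_stat_error("neighbor joining needs at least 2 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (n == 2L) {
    txt <- sprintf("(%s:%.10g,%s:%.10g);", rownames(d)[1], d[1, 2] / 2,
                   rownames(d)[2], d[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Build a rooted binary tree from an alignment
#'
#' Convenience pipeline: pairwise identity -> Jukes-Cantor distances ->
#' neighbor joining -> midpoint rooting -> arbitrary resolution of any
#' remaining multifurcation. This is the default tree used by the
#' covariation test and the simulator when no tree is supplied.
#'
#' @param aln a `covaln` object.
#' @param max_dist saturation cap for [identity_to_distance()].
#' @return a rooted, binary ape `phylo` tree.
#' @export
build_tree <- function(aln, max_dist = 10) {
  id <- suppressWarnings(pairwise_identity(aln))
  tr <- nj_tree(identity_to_distance(id, max_dist))
  as_rooted_binary(tr)
}

as_rooted_binary <- function(tree) {
  if (!ape::is.rooted(tree) && length(tree$tip.label) > 2L) {
    tree <- phangorn::midpoint(tree)
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  tree$edge.length[is.na(tree$edge.length) | tree$edge.length < 0] <- 0
  tree
}

#' Rescale all branch lengths by a constant factor
#'
#' @param tree an ape `phylo` tree.
#' @param factor positive multiplier.
#' @return the tree with every branch length multiplied by `factor`.
#' @export
rescale_branches <- function(tree, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    cp_stat_error("rescale factor must be a positive number")
  }
  tree$edge.length <- tree$edge.length * factor
  tree
}

#' Subsample a tree to n uniformly chosen taxa
#'
#' The induced subtree keeps patristic distances between retained leaves
#' exactly (degree-2 nodes are suppressed with their branch lengths summed).
#'
#' @param tree an ape `phylo` tree.
#' @param n number of leaves to keep, `2 <= n <= Ntip(tree)`.
#' @param seed integer seed controlling the uniform draw.
#' @return the induced subtree.
#' @export
subsample_taxa <- function(tree, n, seed) {
  nt <- length(tree$tip.label)
  if (n < 2L || n > nt) {
    cp_stat_error("subsample size ", n, " out of range [2, ", nt, "]")
  }
  if (n == nt) return(tree)
  keep <- local({
    set.seed(derive_seed(seed, 7L))
    sample(tree$tip.label, n)
  })
  ape::keep.tip(tree, keep)
}
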