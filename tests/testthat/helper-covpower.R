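# Shared generators and independent oracles for the test suite.
# All randomness is seeded per call; nothing is stored on disk.

random_alignment <- function(n_seq, L, seed, with_ss = FALSE, gap_frac = 0.1) {
  set.seed(seed)
  chars <- c("A", "C", "G", "U", "-")
  prob <- c(rep((1 - gap_frac) / 4, 4), gap_frac)
  rows <- replicate(n_seq, paste(sample(chars, L, replace = TRUE, prob = prob),
                                 collapse = ""))
  ss <- if (with_ss) wuss_from_pairs(fixture_structure(L, max(2L, L %/% 8L), 2),
                                     L) else NULL
  new_alignment(paste0("seq", seq_len(n_seq)), rows, ss_cons = ss)
}

random_structure <- function(L, B, seed, max_cross = 3) {
  # random pair set with a bounded number of mutually crossing families
  set.seed(seed)
  repeat {
    cols <- sample(L, 2 * B)
    idx <- matrix(cols, ncol = 2)
    idx <- t(apply(idx, 1, sort))
    st <- try(secondary_structure(idx[, 1], idx[, 2]), silent = TRUE)
    if (inherits(st, "rna_structure")) {
      w <- try(wuss_from_pairs(st, L), silent = TRUE)
      if (!inherits(w, "try-error")) {
        fams <- length(unique(gsub("[^A-Z<]", "", w)))
        if (fams <= max_cross + 1) return(st)
      }
    }
  }
}

# independent brute-force small-parsimony oracle: minimum substitutions over
# all internal-node labelings (4^Nnode enumeration); a leaf with a gap or
# ambiguity matches any parent state at no cost
brute_force_parsimony <- function(tree, states) {
  tree <- ape::multi2di(tree, random = FALSE)
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  }
  nt <- length(tree$tip.label)
  m <- tree$Nnode
  labs <- as.matrix(expand.grid(rep(list(1:4), m)))
  cost <- numeric(nrow(labs))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - nt
    ch <- tree$edge[e, 2]
    if (ch > nt) {
      cost <- cost + (labs[, p] != labs[, ch - nt])
    } else {
      st <- states[tree$tip.label[ch]]
      if (st %in% 1:4) cost <- cost + (labs[, p] != st)
    }
  }
  min(cost)
}

# 16-state joint version of the same oracle
brute_force_pair_parsimony <- function(tree, col_i, col_j) {
  tree <- ape::multi2di(tree, random = FALSE)
  if (!ape::is.rooted(tree)) {
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  }
  nt <- length(tree$tip.label)
  m <- tree$Nnode
  labs <- as.matrix(expand.grid(rep(list(1:16), m)))
  allowed <- function(a, b) {
    aa <- if (a %in% 1:4) a else 1:4
    bb <- if (b %in% 1:4) b else 1:4
    as.vector(outer(aa, bb, function(x, y) (x - 1) * 4 + y))
  }
  cost <- numeric(nrow(labs))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - nt
    ch <- tree$edge[e, 2]
    if (ch > nt) {
      cost <- cost + (labs[, p] != labs[, ch - nt])
    } else {
      ok <- allowed(col_i[tree$tip.label[ch]], col_j[tree$tip.label[ch]])
      cost <- cost + !(labs[, p] %in% ok)
    }
  }
  min(cost)
}

avg_identity <- function(aln) {
  attr(suppressWarnings(pairwise_identity(aln)), "avg_identity")
}
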