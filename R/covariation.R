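# Pairwise covariation statistics against a phylogeny-aware empirical null.
#
# The default statistic is the G-test on the 4x4 joint residue counts of two
# columns (rows gapped in either column excluded); G = 2*N*ln(2)*MI exactly.
# Significance is assessed against an empirical null built by re-evolving
# every column independently down the tree (preserving composition,
# per-column substitution counts and gap pattern, destroying pairwise
# correlation), pooled over many simulated alignments, with add-one-smoothed
# survival probabilities and a multiple-test correction to E-values.

#' Joint residue counts for a column pair
#'
#' @param aln a `covaln` object.
#' @param i,j distinct column indices (1-based).
#' @return list with `counts` (4x4 matrix over A,C,G,U; rows = column `i`)
#'   and `n` (number of rows with unambiguous residues in both columns).
#' @export
joint_counts <- function(aln, i, j) {
  m <- if (inherits(aln, "covaln")) aln_matrix(aln) else aln
  if (i == j) cp_stat_error("cannot pair a column with itself")
  if (i < 1 || j < 1 || i > ncol(m) || j > ncol(m)) {
    cp_stat_error("column index out of range")
  }
  a <- m[, i]; b <- m[, j]
  ok <- a >= 1L & a <= 4L & b >= 1L & b <= 4L
  counts <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                            c("A", "C", "G", "U")))
  if (any(ok)) {
    tab <- table(factor(a[ok], levels = 1:4), factor(b[ok], levels = 1:4))
    counts[] <- as.numeric(tab)
  }
  n <- sum(ok)
  if (n == 0L) warning("no mutually ungapped rows for columns ", i, ", ", j)
  list(counts = counts, n = n)
}

get_counts <- function(x) {
  if (is.list(x) && !is.null(x$counts)) x$counts else as.matrix(x)
}

#' Mutual information of a joint count table, in bits
#'
#' `MI = sum p_xy log2(p_xy / (p_x p_y))` with `0 log 0 = 0`; an empty table
#' gives 0.
#'
#' @param x 4x4 count table or the list returned by [joint_counts()].
#' @return nonnegative mutual information in bits.
#' @export
mutual_information <- function(x) {
  o <- get_counts(x)
  n <- sum(o)
  if (n == 0) return(0)
  p <- o / n
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  term <- ifelse(p > 0, p * log2(p / e), 0)
  sum(term)
}

#' G-test statistic of a joint count table
#'
#' `G = 2 sum O_xy ln(O_xy / E_xy)` with expected counts from the marginals;
#' identically `2 N ln(2) MI`.
#'
#' @param x 4x4 count table or the list returned by [joint_counts()].
#' @return nonnegative G statistic.
#' @export
g_test <- function(x) {
  o <- get_counts(x)
  n <- sum(o)
  if (n == 0) return(0)
  e <- outer(rowSums(o), colSums(o)) / n
  term <- ifelse(o > 0, o * log(o / e), 0)
  2 * sum(term)
}

#' Average-product correction of a pairwise score matrix
#'
#' `corrected(i,j) = stat(i,j) - mean_i * mean_j / mean_all`, with means over
#' off-diagonal entries. Offered for parity with common covariation scores;
#' not applied by default.
#'
#' @param stat_matrix symmetric score matrix.
#' @return corrected symmetric matrix (unchanged if all zero).
#' @export
apc_correct <- function(stat_matrix) {
  s <- as.matrix(stat_matrix)
  if (all(s == 0)) return(s)
  L <- nrow(s)
  diag(s) <- 0
  rowm <- rowSums(s) / (L - 1)
  allm <- sum(s) / (L * (L - 1))
  corr <- s - outer(rowm, rowm) / allm
  diag(corr) <- 0
  corr
}

# All-pairs G and MI matrices from an encoded alignment, via 16 residue
# cross-products; O(16 L^2) memory, fine for the alignment sizes in scope.
pair_statistics <- function(m) {
  ind <- lapply(1:4, function(v) (m == v) * 1)
  C <- vector("list", 16L)
  N <- 0
  for (x in 1:4) for (y in 1:4) {
    cxy <- crossprod(ind[[x]], ind[[y]])
    C[[(x - 1L) * 4L + y]] <- cxy
    N <- N + cxy
  }
  Rx <- lapply(1:4, function(x) Reduce(`+`, C[(x - 1L) * 4L + 1:4]))
  Cy <- lapply(1:4, function(y) Reduce(`+`, C[seq(y, 16L, by = 4L)]))
  G <- 0
  for (x in 1:4) for (y in 1:4) {
    O <- C[[(x - 1L) * 4L + y]]
    denom <- Rx[[x]] * Cy[[y]]
    term <- O * log(ifelse(O > 0, O * N / pmax(denom, .Machine$double.xmin), 1))
    term[O == 0] <- 0
    G <- G + term
  }
  G <- 2 * G
  G[N == 0] <- 0
  MI <- ifelse(N > 0, G / (2 * N * log(2)), 0)
  list(G = G, MI = MI, N = N)
}

# Null alignment generation: every column is re-evolved independently down
# the tree under an F81-type process whose stationary distribution is the
# column's observed residue composition. Rates start from matching the
# expected number of substitution events to the column's Fitch count s_i,
# then a short calibration loop inflates them globally so that the Fitch
# counts *inferred from the nulls* match the original s_i (parsimony
# undercounts multiple hits, so event-matching alone would make nulls less
# diverged than the input and break the identity/count preservation
# contract). Gap/ambiguity cells are copied from the input; columns with
# s_i = 0 are copied verbatim.
null_matrices <- function(m, tree, s, n, seed) {
  tree <- as_rooted_binary(tree)
  tips <- tree$tip.label
  m <- m[tips, , drop = FALSE]
  L <- ncol(m)
  n_tip <- nrow(m)
  total_len <- sum(tree$edge.length)
  freq <- vapply(seq_len(L), function(i) {
    v <- m[, i]
    tabulate(v[v >= 1L & v <= 4L], nbins = 4L)
  }, numeric(4))                      # 4 x L
  ## shrink the observed composition toward uniform: phylogenetically
  ## correlated leaves make the raw column frequencies a concentrated,
  ## biased estimate of the stationary composition, which would force the
  ## null to over-substitute (inflating parsimony counts) to reach the
  ## input's divergence
  shrink <- 0.3
  obs_comp <- sweep(freq, 2L, pmax(colSums(freq), 1), "/")
  comp <- (1 - shrink) * obs_comp + shrink * 0.25
  het <- 1 - colSums(comp^2)
  active <- s > 0 & colSums(freq > 0) > 1 & total_len > 0
  mu <- ifelse(active, s / (total_len * pmax(het, 1e-12)), 0)
  cum <- apply(comp, 2L, cumsum)      # 4 x L
  edges <- tree$edge                  # cladewise: parent before child
  elen <- tree$edge.length
  root <- n_tip + 1L
  draw_states <- function(cols) {
    u <- stats::runif(length(cols))
    1L + colSums(cum[, cols, drop = FALSE] < rep(u, each = 4L))
  }
  gap <- m == 0L | m == 5L
  simulate_one <- function(rate_factor) {
    node_states <- matrix(0L, n_tip + tree$Nnode, L)
    node_states[root, ] <- draw_states(seq_len(L))
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; ch <- edges[e, 2L]
      st <- node_states[par, ]
      p_change <- 1 - exp(-mu * rate_factor * elen[e])
      redraw <- which(stats::runif(L) < p_change & active)
      if (length(redraw)) st[redraw] <- draw_states(redraw)
      node_states[ch, ] <- st
    }
    sim <- node_states[seq_len(n_tip), , drop = FALSE]
    rownames(sim) <- tips
    if (any(!active)) sim[, !active] <- m[, !active]
    sim[gap] <- m[gap]
    sim
  }
  set.seed(derive_seed(seed, 13L))
  ## Fitch counts are minima and miss multiple hits, so running the process
  ## at the event-matched rate would leave the nulls less diverged than the
  ## input. Calibrate a global rate factor so the nulls reproduce the
  ## original average pairwise identity (the preservation contract); the
  ## per-column rate profile stays proportional to s_i throughout.
  avg_id <- function(x) attr(suppressWarnings(pairwise_identity(x)), "avg_identity")
  factor <- 1
  if (any(active)) {
    target <- avg_id(m)
    id_at <- function(f) mean(vapply(1:3, function(k) avg_id(simulate_one(f)),
                                     numeric(1)))
    ## secant search on log(factor) for identity(factor) = target
    f1 <- 1; y1 <- id_at(f1)
    if (abs(y1 - target) >= 0.01) {
      f2 <- min(max(f1 * ((1 - target) / max(1 - y1, 1e-3))^1.5, 0.05), 40)
      for (it in 1:6) {
        y2 <- id_at(f2)
        if (abs(y2 - target) < 0.01) break
        slope <- (y2 - y1) / (log(f2) - log(f1) + 1e-12)
        if (!is.finite(slope) || slope >= 0) {
          fn <- f2 * if (y2 > target) 2 else 0.5
        } else {
          fn <- exp(log(f2) + (target - y2) / slope)
        }
        f1 <- f2; y1 <- y2
        f2 <- min(max(fn, 0.05), 40)
      }
      factor <- f2
    }
  }
  lapply(seq_len(n), function(r) simulate_one(factor))
}

#' Phylogeny-preserving null alignments
#'
#' Simulates alignments with the same dimensions, gap pattern, per-column
#' composition and per-column substitution counts as the input, but with all
#' columns evolved independently (no pairwise correlation).
#'
#' @param aln a `covaln` object.
#' @param tree rooted tree with branch lengths matching the alignment
#'   (built with [build_tree()] if `NULL`).
#' @param subs optional `subs_counts` (computed if `NULL`).
#' @param n number of null alignments.
#' @param seed integer seed.
#' @return list of `covaln` objects.
#' @export
null_alignments <- function(aln, tree = NULL, subs = NULL, n = 20, seed = 42) {
  if (n < 1) cp_stat_error("need n >= 1 null alignments")
  if (is.null(tree)) tree <- build_tree(aln)
  tree <- as_rooted_binary(tree)
  if (is.null(subs)) subs <- substitution_counts(aln, tree)
  m <- aln_matrix(aln)
  sims <- null_matrices(m, tree, subs$per_column, n, seed)
  lapply(sims, function(x) {
    new_alignment(rownames(x), decode_matrix(x)[rownames(x)], aln$ss_cons)
  })
}

#' Empirical P-values and E-values against pooled null statistics
#'
#' Survival is the add-one-smoothed fraction of pooled null statistics at or
#' above each observed score; the E-value multiplies it by the number of
#' tests in the set, so it estimates the expected count of false positives
#' at that score.
#'
#' @param scores numeric vector of observed statistics.
#' @param null_samples pooled null statistic values (nonempty).
#' @param n_tests multiple-test correction factor (>= 1).
#' @param threshold E-value significance threshold (default 0.05).
#' @return data.frame with `stat`, `pvalue`, `evalue`, `significant`.
#' @export
assign_evalues <- function(scores, null_samples, n_tests, threshold = 0.05) {
  if (!length(null_samples)) cp_stat_error("empty null distribution")
  if (n_tests < 1) cp_stat_error("n_tests must be >= 1")
  srt <- sort(null_samples)
  M <- length(srt)
  cnt_lt <- findInterval(scores, srt, left.open = TRUE)
  cnt_ge <- M - cnt_lt
  pvalue <- (1 + cnt_ge) / (1 + M)
  evalue <- n_tests * pvalue
  data.frame(stat = scores, pvalue = pvalue, evalue = evalue,
             significant = evalue < threshold)
}

#' Phylogeny-aware covariation test of an alignment
#'
#' Computes the covariation statistic for every column pair, builds an
#' empirical null from tree-based simulations that destroy pairwise
#' correlation, and assigns E-values in one of two modes: `one_set` corrects
#' over all `L(L-1)/2` pairs; `two_set` (requires a proposed structure) runs
#' two independent tests, one on the `B` proposed basepairs and one on the
#' remaining pairs, each with its own correction factor, against the shared
#' null.
#'
#' @param aln a `covaln` object.
#' @param tree optional rooted tree (default: [build_tree()]).
#' @param structure optional `rna_structure`; defaults to the alignment's
#'   `SS_cons` when present. Mandatory for `two_set`.
#' @param mode `"one_set"` or `"two_set"`.
#' @param statistic `"GT"` (G-test, default) or `"MI"` (bits).
#' @param apc apply average-product correction to the score matrix.
#' @param n_null number of null alignments (raised automatically until at
#'   least `min_null_stats` pooled null pair statistics are available).
#' @param min_null_stats floor on the pooled null size (bounds E-value
#'   resolution).
#' @param evalue_threshold significance threshold (default 0.05).
#' @param min_ungapped pairs with fewer mutually ungapped rows are reported
#'   as untestable (stat 0, E-value = n_tests).
#' @param seed integer seed for the null simulations.
#' @return a data.frame of class `cov_results`, one row per tested pair:
#'   `left_pos`, `right_pos` (1-based), `in_structure`, `stat`, `pvalue`,
#'   `evalue`, `significant`, `s_ij`, `power` (NA until a power curve is
#'   applied), `untestable`, `n_tests`. Attributes record the mode, null
#'   size, tree and substitution counts.
#' @export
covariation_test <- function(aln, tree = NULL, structure = NULL,
                             mode = c("one_set", "two_set"),
                             statistic = c("GT", "MI"), apc = FALSE,
                             n_null = 20, min_null_stats = 1e5,
                             evalue_threshold = 0.05, min_ungapped = 3,
                             seed = 42) {
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  m <- aln_matrix(aln)
  L <- ncol(m)
  if (L < 2L) cp_stat_error("alignment has fewer than 2 columns")
  n_pairs <- L * (L - 1) / 2
  if (is.null(structure) && !is.null(aln$ss_cons)) {
    structure <- pairs_from_wuss(aln$ss_cons)
  }
  if (mode == "two_set" && (is.null(structure) || structure$B == 0L)) {
    cp_stat_error("two_set mode requires a proposed structure ",
                  "(SS_cons annotation or explicit structure)")
  }
  if (is.null(tree)) tree <- build_tree(aln)
  tree <- as_rooted_binary(tree)
  if (!setequal(tree$tip.label, aln$names)) {
    cp_stat_error("tree leaves do not match alignment sequence names")
  }
  subs <- substitution_counts(aln, tree)

  obs <- pair_statistics(m)
  S <- if (statistic == "GT") obs$G else obs$MI
  if (apc) S <- apc_correct(S)

  n_alns <- max(n_null, ceiling(min_null_stats / n_pairs))
  nulls <- null_matrices(m, tree, subs$per_column, n_alns, derive_seed(seed, 101L))
  ut <- upper.tri(S)
  pool <- unlist(lapply(nulls, function(x) {
    st <- pair_statistics(x)
    v <- if (statistic == "GT") st$G else st$MI
    if (apc) v <- apc_correct(v)
    v[ut & st$N >= min_ungapped]
  }), use.names = FALSE)
  if (!length(pool)) pool <- 0

  idx <- which(ut, arr.ind = TRUE)
  left <- idx[, 1L]; right <- idx[, 2L]
  stat <- S[ut]
  nshared <- obs$N[ut]
  untestable <- nshared < min_ungapped
  stat[untestable] <- 0

  in_structure <- rep(FALSE, length(left))
  if (!is.null(structure) && structure$B > 0L) {
    key <- paste(left, right)
    bkey <- paste(structure$pairs[, 1L], structure$pairs[, 2L])
    in_structure <- key %in% bkey
  }

  n_tests <- if (mode == "one_set") {
    rep(n_pairs, length(left))
  } else {
    B <- sum(in_structure)
    ifelse(in_structure, B, n_pairs - B)
  }

  res <- assign_evalues(stat, pool, n_tests = 1, threshold = 1)
  evalue <- pmin(res$pvalue * n_tests, n_tests)
  evalue[untestable] <- n_tests[untestable]
  significant <- evalue < evalue_threshold & !untestable

  out <- data.frame(left_pos = left, right_pos = right,
                    in_structure = in_structure, stat = stat,
                    pvalue = res$pvalue, evalue = evalue,
                    significant = significant,
                    s_ij = subs$per_column[left] + subs$per_column[right],
                    power = NA_real_, untestable = untestable,
                    n_tests = n_tests)
  out <- out[order(out$left_pos, out$right_pos), ]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "statistic") <- statistic
  attr(out, "n_null_alignments") <- n_alns
  attr(out, "n_null_stats") <- length(pool)
  attr(out, "evalue_threshold") <- evalue_threshold
  attr(out, "tree") <- tree
  attr(out, "subs") <- subs
  attr(out, "seed") <- seed
  class(out) <- c("cov_results", "data.frame")
  out
}
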