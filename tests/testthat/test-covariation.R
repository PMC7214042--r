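test_that("joint_counts tabulates residue pairs and excludes gapped rows", {
  aln <- new_alignment(paste0("s", 1:8), c(rep("AU", 4), rep("GC", 4)))
  jc <- joint_counts(aln, 1, 2)
  expect_equal(jc$n, 8)
  expect_equal(jc$counts["A", "U"], 4)
  expect_equal(jc$counts["G", "C"], 4)
  expect_equal(sum(jc$counts), 8)
  expect_error(joint_counts(aln, 2, 2), class = "covpower_stat_error")
  gappy <- new_alignment(c("a", "b", "c"), c("AU", "-U", "GN"))
  jc2 <- joint_counts(gappy, 1, 2)
  expect_equal(jc2$n, 1)                      # only the fully observed row
  expect_equal(jc2$counts["A", "U"], 1)
})

test_that("mutual information and G-test match hand values and identity", {
  half <- joint_counts(new_alignment(paste0("s", 1:8),
                                     c(rep("AU", 4), rep("GC", 4))), 1, 2)
  expect_identical(mutual_information(half), 1)
  expect_equal(g_test(half), 2 * 8 * log(2))  # G = 2 N ln2 MI with MI = 1
  indep <- joint_counts(new_alignment(paste0("s", 1:8),
                                      rep(c("AU", "AC", "GU", "GC"), 2)), 1, 2)
  expect_identical(mutual_information(indep), 0)
  expect_equal(g_test(indep), 0)
  invar <- joint_counts(new_alignment(paste0("s", 1:6), rep("AU", 6)), 1, 2)
  expect_identical(mutual_information(invar), 0)
  # exactly independent table built from outer product margins
  o <- outer(c(1, 3, 2, 2), c(2, 2, 3, 1))
  expect_equal(g_test(o), 0, tolerance = 1e-12)
  # identity and entropy bound on random tables
  set.seed(8)
  for (rep in 1:25) {
    o <- matrix(rpois(16, 3), 4, 4)
    if (sum(o) == 0) next
    mi <- mutual_information(o)
    expect_gte(mi, -1e-12)
    expect_equal(g_test(o), 2 * sum(o) * log(2) * mi, tolerance = 1e-9)
    h <- function(p) { p <- p[p > 0] / sum(p); -sum(p * log2(p)) }
    expect_lte(mi, min(h(rowSums(o)), h(colSums(o))) + 1e-9)
  }
})

test_that("average-product correction behaves as documented", {
  expect_equal(apc_correct(matrix(0, 4, 4)), matrix(0, 4, 4))
  const <- matrix(3, 5, 5); diag(const) <- 0
  expect_equal(max(abs(apc_correct(const))), 0, tolerance = 1e-12)
  set.seed(3)
  s <- matrix(rexp(36), 6, 6); s <- s + t(s); diag(s) <- 0
  corr <- apc_correct(s)
  expect_equal(corr, t(corr))
  # one dominant pair in a weak background stays the maximum
  s2 <- matrix(0.01, 6, 6); diag(s2) <- 0
  s2[2, 5] <- s2[5, 2] <- 10
  c2 <- apc_correct(s2)
  top <- which(c2 == max(c2), arr.ind = TRUE)
  expect_true(all(sort(top[1, ]) == c(2, 5)))
})

test_that("pair_statistics agrees with the single-pair functions", {
  aln <- random_alignment(12, 15, seed = 5)
  m <- aln_matrix(aln)
  st <- covpower:::pair_statistics(m)
  set.seed(6)
  for (rep in 1:10) {
    ij <- sort(sample(15, 2))
    jc <- joint_counts(aln, ij[1], ij[2])
    expect_equal(st$G[ij[1], ij[2]], g_test(jc), tolerance = 1e-9)
    expect_equal(st$MI[ij[1], ij[2]], mutual_information(jc), tolerance = 1e-9)
    expect_equal(st$N[ij[1], ij[2]], jc$n)
  }
})

test_that("null alignments preserve dimensions, gaps, invariant columns,
           identity and substitution counts", {
  tmpl <- fixture_template(n_seq = 40, L = 60, n_pairs = 15, depth = 0.3,
                           seed = 11)
  tree <- build_tree(tmpl)
  subs <- substitution_counts(tmpl, tree)
  nulls <- null_alignments(tmpl, tree, subs, n = 50, seed = 9)
  m <- aln_matrix(tmpl)
  n0 <- aln_matrix(nulls[[1]])[rownames(m), ]
  expect_equal(dim(n0), dim(m))
  expect_equal(n0 == 0, m == 0)               # gap pattern copied
  inv <- which(subs$per_column == 0)
  expect_equal(n0[, inv], m[, inv])           # s_i = 0 columns verbatim
  # identity preservation: within 3 percentage points
  idn <- mean(vapply(nulls[1:20], avg_identity, numeric(1)))
  expect_lt(abs(idn - avg_identity(tmpl)), 0.03)
  # per-column Fitch counts: mean over 50 nulls within 25% for s_i >= 5
  ncounts <- vapply(nulls, function(a) {
    substitution_counts(a, tree)$per_column
  }, numeric(tmpl$L))
  hi <- which(subs$per_column >= 5)
  expect_gt(length(hi), 5)
  ratio <- rowMeans(ncounts)[hi] / subs$per_column[hi]
  expect_true(all(abs(ratio - 1) <= 0.25))
})

test_that("empirical E-values: smoothing bounds and monotonicity", {
  null <- c(0.5, 1, 2, 3, 10)
  ev <- assign_evalues(c(0.1, 2.5, 99), null, n_tests = 45)
  expect_equal(ev$evalue[1], 45 * 1, tolerance = 1e-9)      # below all nulls
  expect_equal(ev$evalue[3], 45 / (1 + 5))                  # above all nulls
  expect_true(all(diff(ev$evalue) <= 0))                    # monotone in score
  expect_true(ev$evalue[3] <= 45 / (1 + length(null)))
  expect_error(assign_evalues(1, numeric(0), 10), class = "covpower_stat_error")
})

test_that("covariation_test modes, test counts and error contracts", {
  aln <- random_alignment(8, 10, seed = 21, gap_frac = 0)
  res1 <- covariation_test(aln, mode = "one_set", n_null = 5,
                           min_null_stats = 500, seed = 1)
  expect_equal(nrow(res1), 45L)                # L(L-1)/2
  expect_true(all(res1$n_tests == 45))
  st <- secondary_structure(c(1, 2, 3, 4), c(10, 9, 8, 7))
  res2 <- covariation_test(aln, structure = st, mode = "two_set", n_null = 5,
                           min_null_stats = 500, seed = 1)
  expect_equal(sum(res2$in_structure), 4L)
  expect_equal(unique(res2$n_tests[res2$in_structure]), 4)
  expect_equal(unique(res2$n_tests[!res2$in_structure]), 41)
  # two-set basepair E-values <= one-set E-values at the same scores
  key <- paste(res1$left_pos, res1$right_pos)
  k2 <- paste(res2$left_pos, res2$right_pos)
  bp <- res2$in_structure
  expect_true(all(res2$evalue[bp] <= res1$evalue[match(k2[bp], key)] + 1e-12))
  expect_error(covariation_test(aln, mode = "two_set", n_null = 2, seed = 1),
               "structure", class = "covpower_stat_error")
})

test_that("structural alignments yield significant basepairs, controls do not", {
  tmpl <- fixture_template(n_seq = 25, L = 60, n_pairs = 15, depth = 0.9,
                           seed = 7)
  res <- covariation_test(tmpl, mode = "two_set", n_null = 15,
                          min_null_stats = 2e4, seed = 5)
  bp <- res[res$in_structure, ]
  expect_gt(sum(bp$significant), 7)            # strong covariation recovered
  # structureless control: false positives bounded by the E-value budget
  ctrl <- fixture_template(n_seq = 25, L = 60, n_pairs = 0, depth = 0.9,
                           seed = 8)
  resc <- covariation_test(ctrl, mode = "one_set", n_null = 15,
                           min_null_stats = 2e4, seed = 5)
  expect_lte(sum(resc$significant), 2)
})

test_that("covariation results are deterministic given the seed", {
  aln <- fixture_template(n_seq = 12, L = 40, n_pairs = 8, depth = 0.5,
                          seed = 3)
  r1 <- covariation_test(aln, mode = "two_set", n_null = 5,
                         min_null_stats = 1e3, seed = 77)
  r2 <- covariation_test(aln, mode = "two_set", n_null = 5,
                         min_null_stats = 1e3, seed = 77)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})
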