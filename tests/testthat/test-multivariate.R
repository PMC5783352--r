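# Mutual information, PCA and Ward dendrograms.

test_that("spearman MI reproduces closed-form values and rank invariance", {
  # permutation of 1..5 with Spearman rho exactly 0.5
  x <- 1:5
  y <- c(2, 4, 1, 3, 5)
  expect_equal(cor(x, y, method = "spearman"), 0.5)
  expect_equal(spearman_mi(x, y, normalized = FALSE), 0.143841,
               tolerance = 1e-5)
  expect_equal(spearman_mi(x, y), 0.25, tolerance = 1e-9)
  # perfectly dependent profiles saturate at 1 (clipped, not infinite)
  expect_equal(spearman_mi(1:10, (1:10)^3), 1, tolerance = 1e-9)
  # monotone transforms leave the value unchanged
  set.seed(71)
  a <- rnorm(50); b <- a + rnorm(50)
  expect_equal(spearman_mi(a, b), spearman_mi(exp(a), b^3 + 10 * b))
  # independent long profiles sit near zero
  expect_lt(spearman_mi(rnorm(1000), rnorm(1000)), 0.02)
  expect_error(spearman_mi(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_mi(1:2, 2:1), "3 observations")
})

test_that("MI matrices are symmetric with unit diagonal and [0,1] entries", {
  set.seed(72)
  mat <- matrix(rnbinom(40 * 6, mu = 100, size = 5), 40, 6,
                dimnames = list(NULL, paste0("s", 1:6)))
  mat <- log2(mat + 1)
  mi <- mi_matrix(mat)
  expect_true(isSymmetric(unclass(mi)))
  expect_equal(unname(diag(mi)), rep(1, 6))
  expect_true(all(mi >= 0 & mi <= 1))
  # oracle recomputation from rank correlations
  for (i in 1:5) for (j in (i + 1):6) {
    rho <- cor(mat[, i], mat[, j], method = "spearman")
    expect_lt(abs(mi[i, j] - rho^2), 1e-12)
  }
  # identical and monotone-copied samples reach 1
  dup <- cbind(a = mat[, 1], b = mat[, 1], c = sqrt(mat[, 1]) + 2)
  mid <- mi_matrix(dup)
  expect_equal(unname(mid["a", "b"]), 1)
  expect_equal(unname(mid["a", "c"]), 1)
})

test_that("PCA separates mirror profiles, reproduces duplicates and
           reconstructs the centered matrix", {
  prof <- c(3, -1, 4, 0, -2, 5)
  two <- cbind(s1 = prof, s2 = -prof)
  p2 <- pca_scores(two)
  expect_equal(p2$scores["s1", 1], -p2$scores["s2", 1])
  expect_gt(abs(p2$scores["s1", 1]), 0)
  expect_equal(p2$explained_var[2], 0, tolerance = 1e-12)

  set.seed(73)
  mat <- matrix(rnorm(30 * 5), 30, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
  mat <- cbind(mat, s6 = mat[, 3])  # duplicated sample
  p <- pca_scores(mat, n_components = 5)
  expect_equal(p$scores["s3", ], p$scores["s6", ], tolerance = 1e-9)
  expect_true(all(diff(p$explained_var) <= 1e-12))
  expect_lte(sum(p$explained_var), 1 + 1e-12)
  # loading-sum sign convention
  expect_true(all(colSums(p$loadings) >= -1e-9))
  # full reconstruction of the centered matrix
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, t(mat - rowMeans(mat)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_scores(mat[1:3, ], n_components = 5), "components")
})

test_that("Ward trees follow the Lance-Williams oracle and export Newick", {
  set.seed(74)
  x <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(paste0("L", 1:6), NULL))
  tree <- ward_tree(t(x), axis = "samples")  # columns = the 6 leaves
  oracle <- ward_lw_oracle(x)
  expect_equal(tree$hclust$height, oracle$heights, tolerance = 1e-9)
  got_sets <- hclust_merge_sets(tree$hclust)
  for (s in seq_along(oracle$merges)) {
    expect_setequal(unlist(got_sets[[s]]), unlist(oracle$merges[[s]]))
  }
  expect_true(all(diff(tree$hclust$height) >= -1e-12))

  # two identical leaves merge first at height zero
  y <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  t3 <- ward_tree(t(y), axis = "samples")
  expect_equal(min(t3$hclust$height), 0)
  expect_setequal(unlist(hclust_merge_sets(t3$hclust)[[1]]), c(1, 2))

  # Newick round trip preserves topology and heights
  nwk <- as_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, paste0("L", 1:6))
  back_coph <- ape::cophenetic.phylo(phy)[paste0("L", 1:6), paste0("L", 1:6)]
  coph <- as.matrix(cophenetic(tree$hclust))[paste0("L", 1:6),
                                             paste0("L", 1:6)]
  expect_equal(back_coph, coph, tolerance = 1e-6)
})

test_that("tree comparison is exact on clones and spots a flipped leaf", {
  set.seed(75)
  x <- matrix(rnorm(8 * 5), 5, 8,
              dimnames = list(NULL, paste0("t", 1:8)))
  a <- ward_tree(x, axis = "samples")
  expect_equal(compare_trees(a, a)$cophenetic_cor, 1)
  # permuting the input columns leaves the comparison at 1
  b <- ward_tree(x[, sample(8)], axis = "samples")
  cmp <- compare_trees(a, b)
  expect_equal(cmp$cophenetic_cor, 1, tolerance = 1e-9)
  expect_true(all(cmp$agreement$agreement == 1))
  # a leaf that changes cluster membership degrades the agreement: two
  # tight clusters, with t1 jumping from the first to the second
  base <- cbind(t1 = c(0, 0), t2 = c(0.2, 0), t3 = c(0, 0.2),
                t4 = c(0.2, 0.2), t5 = c(10, 10), t6 = c(10.2, 10),
                t7 = c(10, 10.2), t8 = c(10.2, 10.2))
  moved <- base
  moved[, "t1"] <- c(10.1, 10.1)
  ta <- ward_tree(base, axis = "samples")
  tb <- ward_tree(moved, axis = "samples")
  cmp2 <- compare_trees(ta, tb)
  expect_lt(cmp2$cophenetic_cor, 1)
  # at k = 2, every (t1, other) pair flips co-membership: 7 of 28 pairs
  expect_equal(cmp2$agreement$agreement[cmp2$agreement$k == 2], 21 / 28)
  expect_error(compare_trees(a, ward_tree(x[, 1:5], axis = "samples")),
               "leaf sets")
})
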