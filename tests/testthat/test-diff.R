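# Expression filtering, Fisher contrasts, sex-bias classification, sweep.

test_that("expressed filter applies the strict >100-in->=3-samples rule", {
  mat <- rbind(
    kept = c(150, 120, 101, 5),
    dropped = c(101, 99, 150, 2),   # only two samples above 100
    zero = c(0, 0, 0, 0)
  )
  colnames(mat) <- paste0("s", 1:4)
  cm <- counts_fixture(mat)
  fe <- filter_expressed(cm)
  expect_equal(rownames(fe$counts), "kept")
  # idempotent
  expect_equal(filter_expressed(fe)$counts, fe$counts)
  # all-zero matrix empties out
  expect_equal(nrow(filter_expressed(counts_fixture(mat[3, , drop = FALSE],
                                                    lib = rep(1, 4)))$counts),
               0L)
})

test_that("fisher_pair matches hypergeometric enumeration and is symmetric", {
  expect_equal(fisher_pair(3, 4, 1, 4), fisher_enum_oracle(3, 1, 1, 3),
               tolerance = 1e-9)
  expect_equal(fisher_pair(3, 4, 1, 4), 0.4857143, tolerance = 1e-6)
  expect_equal(fisher_pair(10, 100, 10, 100), 1)
  expect_equal(fisher_pair(0, 100, 0, 100), 1)
  # symmetry under swapping the groups
  expect_equal(fisher_pair(17, 400, 5, 350), fisher_pair(5, 350, 17, 400))
  # p decreases monotonically with imbalance at fixed margins
  p <- vapply(5:9, function(a) fisher_pair(a, 10, 10 - a, 10), 0)
  expect_true(all(diff(p) < 1e-12))
  # enumeration agreement across a grid of small tables
  for (a in 0:4) for (c in 0:4) {
    expect_equal(fisher_pair(a, 6, c, 7), fisher_enum_oracle(a, 6 - a, c, 7 - c),
                 tolerance = 1e-9, info = paste(a, c))
  }
  expect_error(fisher_pair(1, 0, 1, 5), "library")
  expect_error(fisher_pair(6, 5, 1, 5), "library size")
})

test_that("pairwise contrasts pool counts, adjust with BH and gate the
           direction label", {
  set.seed(51)
  mat <- matrix(rnbinom(20 * 6, mu = 300, size = 50), 20, 6,
                dimnames = list(paste0("g", 1:20, ":3-Pre"),
                                c(paste0("a", 1:3), paste0("b", 1:3))))
  mat[1:4, 1:3] <- mat[1:4, 1:3] * 5L
  cm <- counts_fixture(mat, lib = colSums(mat) + 500)
  res <- pairwise_contrast(cm, paste0("a", 1:3), paste0("b", 1:3))
  expect_equal(res$count_a, unname(rowSums(mat[, 1:3])))
  expect_equal(res$q_value, bh_oracle(res$p_value), tolerance = 1e-12)
  expect_true(all(res$direction[1:4] == "up_in_a"))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(res$direction[res$p_value >= 0.05] == "unchanged"))
  expect_equal(res$region_label, rep("3-Pre", 20))

  # identical pooled fractions: p = 1, unchanged, log2fc = 0
  flat <- counts_fixture(matrix(c(50, 50, 50, 50), 1, 4,
                                dimnames = list("x:5tRF", paste0("s", 1:4))),
                         lib = rep(1000, 4))
  r1 <- pairwise_contrast(flat, c("s1", "s2"), c("s3", "s4"),
                          use_tmm = FALSE)
  expect_equal(r1$p_value, 1)
  expect_equal(r1$log2fc, 0)
  expect_equal(r1$direction, "unchanged")
  expect_equal(r1$q_value, r1$p_value)  # BH identity at m = 1

  expect_error(pairwise_contrast(flat, "s1", "s1"), "overlap")
  expect_error(pairwise_contrast(flat, "s1", character(0)), "non-empty")
  expect_error(pairwise_contrast(flat, "s1", "nope"), "unknown")
})

test_that("sex-bias labels need strict consistency across every strain", {
  fx <- sex_bias_fixture()
  sb <- classify_sex_bias(fx$counts, fx$strain, fx$sex)
  expect_equal(sb$bias, fx$expected$bias)
  expect_equal(sb$mean_female, fx$expected$mean_female, tolerance = 1e-12)
  expect_equal(sb$mean_male, fx$expected$mean_male, tolerance = 1e-12)

  # a single tied strain breaks the label
  tied <- fx$counts
  tied["AAEL016015:3-Pre", "Lvp_M"] <- tied["AAEL016015:3-Pre", "Lvp_F"]
  sb2 <- classify_sex_bias(tied, fx$strain, fx$sex)
  expect_equal(sb2$bias[sb2$bin_id == "AAEL016015:3-Pre"], "inconsistent")

  # per-strain rescaling applied to both sexes leaves labels unchanged
  scale_by_strain <- rep(c(2, 0.5, 1, 7, 0.1), 2)
  sb3 <- classify_sex_bias(sweep(fx$counts, 2, scale_by_strain, "*"),
                           fx$strain, fx$sex)
  expect_equal(sb3$bias, sb$bias)

  expect_error(classify_sex_bias(fx$counts[, -1], fx$strain[-1], fx$sex[-1]),
               "exactly one female")
})

test_that("window sweep finds 15 nt bins best for 15 nt fragments and
           handles degenerate inputs", {
  plan <- data.frame(gene = 1:4,
                     region_label = c("3-Pre", "5tRF", "D-loop", "T-loop"),
                     mean_A = c(400, 300, 250, 250),
                     mean_B = c(400, 60, 50, 250))
  fx <- make_sim_fixture(n_genes = 6, seed = 61, source_plan = plan,
                         groups = data.frame(label = c("A", "B"),
                                             n = c(3L, 3L)),
                         read_length_range = c(15L, 15L))
  rs <- simulate_reads(fx$design, fx$sim, fx$bins)
  sources <- lapply(rs$reads, exact_match_map, reference = fx$sim$genome)
  sw <- window_sweep(sources, fx$retained, fx$sim$structures,
                     group_a = paste0("A_r", 1:3),
                     group_b = paste0("B_r", 1:3),
                     contig_lengths = fx$sim$genome,
                     sizes = c(15L, 25L, 35L))
  expect_equal(sw$best_window, 15L)
  expect_equal(sw$table$window, c(15L, 25L, 35L))
  expect_true(all(diff(sw$table$n_expressed) <= 0))

  # single size gives a one-row table
  sw1 <- window_sweep(sources, fx$retained, fx$sim$structures,
                      group_a = paste0("A_r", 1:3),
                      group_b = paste0("B_r", 1:3),
                      contig_lengths = fx$sim$genome, sizes = 15L)
  expect_equal(nrow(sw1$table), 1L)

  # zero reads: all-zero table, smallest size reported with a warning
  none <- lapply(sources, function(a) a[0, ])
  expect_warning(
    sw0 <- window_sweep(none, fx$retained, fx$sim$structures,
                        group_a = paste0("A_r", 1:3),
                        group_b = paste0("B_r", 1:3),
                        contig_lengths = fx$sim$genome,
                        sizes = c(15L, 20L)),
    "no expressed")
  expect_equal(sw0$best_window, 15L)
  expect_true(all(sw0$table$n_significant == 0))
})
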