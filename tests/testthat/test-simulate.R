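# The synthetic-data generator and its truth bookkeeping.

test_that("gene simulation is deterministic and respects the design", {
  d <- sim_design(n_genes = 10, n_excluded = 3, seed = 5)
  s1 <- simulate_genes(d)
  s2 <- simulate_genes(d)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$genes, s2$genes)
  expect_equal(nrow(s1$genes), 10L)
  expect_equal(sum(s1$genes$is_pseudo | s1$genes$is_selenocysteine |
                     s1$genes$n_introns > 0), 3L)
  # a different seed changes the sequences
  s3 <- simulate_genes(sim_design(n_genes = 10, n_excluded = 3, seed = 6))
  expect_false(identical(as.character(s1$genome), as.character(s3$genome)))
  # empty design gives empty outputs
  s0 <- simulate_genes(sim_design(n_genes = 0, seed = 1))
  expect_equal(nrow(s0$genes), 0L)
  expect_equal(length(s0$genome), 0L)
})

test_that("mature sequences carry the anticodon at the canonical site and
           every read-length k-mer is unique genome-wide", {
  fx <- make_sim_fixture(n_genes = 12, seed = 15)
  expect_true(all(substr(fx$sim$mature, 34, 36) == fx$sim$genes$anticodon))
  # structure strings validate against the fallback geometry
  expect_equal(unname(nchar(fx$sim$ss)), unname(nchar(fx$sim$mature)))
  # k-mer uniqueness: any planted read must map to exactly one locus
  genome_chr <- as.character(fx$sim$genome)
  kmers <- unlist(lapply(genome_chr, function(s) {
    substring(s, 1:(nchar(s) - 14), 15:nchar(s))
  }))
  kmers <- kmers[!grepl("N", kmers)]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  expect_false(any(duplicated(c(kmers, rc))))
})

test_that("truth drawn counts equal the reads actually emitted", {
  plan <- data.frame(gene = 1:2, region_label = c("3-Pre", "A-loop"),
                     mean_A = c(100, 60), mean_B = c(100, 60))
  fx <- make_sim_fixture(n_genes = 5, seed = 23, source_plan = plan,
                         groups = data.frame(label = "A", n = 1L))
  rs <- simulate_reads(fx$design, fx$sim, fx$bins)
  emitted <- table(sub("^[^:]+:(.+):[0-9]+$", "\\1", names(rs$reads[[1]])))
  for (i in seq_len(nrow(rs$truth))) {
    b <- rs$truth$bin_id[i]
    n_emitted <- if (b %in% names(emitted)) emitted[[b]] else 0L
    expect_equal(n_emitted, rs$truth$drawn_count[i], info = b)
  }
  # a plan pointing at a bin that does not exist is refused
  bad <- fx$design
  bad$source_plan$region_label[1] <- "5-Pre"
  bins_no_pre <- fx$bins[fx$bins$region_label != "5-Pre", ]
  expect_error(simulate_reads(bad, fx$sim, bins_no_pre), "plan error")
  # empty plan and zero background give empty read sets
  d0 <- sim_design(n_genes = 3, seed = 2,
                   groups = data.frame(label = "A", n = 1L))
  s0 <- simulate_genes(d0)
  b0 <- build_bins(filter_trnas(s0$genes), s0$structures,
                   contig_lengths = s0$genome)
  r0 <- simulate_reads(d0, s0, b0)
  expect_equal(length(r0$reads[[1]]), 0L)
})

test_that("counting the simulated reads reproduces the truth exactly at
           zero background", {
  plan <- data.frame(gene = 1:4,
                     region_label = c("3-Pre", "5tRF", "T-loop", "D-loop"),
                     mean_A = c(200, 150, 120, 80),
                     mean_B = c(50, 150, 120, 300))
  fx <- make_sim_fixture(n_genes = 8, seed = 29, source_plan = plan,
                         groups = data.frame(label = c("A", "B"),
                                             n = c(2L, 2L)))
  rs <- simulate_reads(fx$design, fx$sim, fx$bins)
  sources <- lapply(rs$reads, exact_match_map, reference = fx$sim$genome)
  expect_equal(sum(vapply(sources, attr, 0L, "n_multihit")), 0L)
  cm <- build_count_matrix(sources, fx$bins)
  tm <- truth_matrix(rs$truth)
  expect_equal(cm$counts[rownames(tm), colnames(tm)], tm,
               ignore_attr = TRUE)
  # bins outside the plan stay at zero
  other <- setdiff(rownames(cm$counts), rownames(tm))
  expect_true(all(cm$counts[other, ] == 0))
  # FASTQ writing round-trips the sequences
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rs$reads[[1]], f)
  back <- Biostrings::readDNAStringSet(f, format = "fastq")
  expect_equal(as.character(back), rs$reads[[1]])
})

test_that("a 4-fold female excess is labelled female-biased in nearly all
           seeds", {
  plan <- data.frame(bin_id = "gX:3-Pre", mean_F = 2000, mean_M = 500)
  groups <- data.frame(label = c("F", "M"), n = c(5L, 5L))
  hits <- 0L
  for (seed in 1:100) {
    sc <- simulate_counts(plan, groups, seed = seed)
    counts <- sc$counts$counts
    strain <- rep(paste0("st", 1:5), 2)
    sex <- rep(c("F", "M"), each = 5)
    lab <- classify_sex_bias(counts, strain, sex)$bias
    if (lab == "Female biased") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("count-level simulation is deterministic and bookkeeps truth", {
  plan <- data.frame(bin_id = paste0("b", 1:6),
                     mean_A = c(500, 500, 100, 100, 2000, 0),
                     mean_B = c(125, 500, 100, 400, 2000, 0))
  groups <- data.frame(label = c("A", "B"), n = c(3L, 3L))
  s1 <- simulate_counts(plan, groups, seed = 11)
  s2 <- simulate_counts(plan, groups, seed = 11)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_equal(s1$truth$is_differential, c(TRUE, FALSE, FALSE, TRUE, FALSE,
                                           FALSE))
  expect_equal(s1$truth$direction, c("A", "none", "none", "B", "none",
                                     "none"))
  expect_equal(s1$counts$samples$lib_size,
               unname(colSums(s1$counts$counts)))
})
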