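# Read-to-bin assignment and count-matrix assembly.

two_bins <- data.frame(
  bin_id = c("g1:5tRF", "g1:D-loop"),
  gene_id = "g1", region_label = c("5tRF", "D-loop"),
  seq_id = "c1", start = c(100, 115), end = c(115, 130),
  strand = "+", width = 15L, stringsAsFactors = FALSE
)

aln_row <- function(id, start, end, strand = "+", unmapped = FALSE,
                    secondary = FALSE) {
  data.frame(read_id = id, seq_id = if (unmapped) NA else "c1",
             start = if (unmapped) NA else start,
             end = if (unmapped) NA else end,
             strand = if (unmapped) NA else strand, mapq = 60L,
             is_unmapped = unmapped, is_secondary = secondary,
             stringsAsFactors = FALSE)
}

test_that("maximal-overlap assignment with the 10 nt floor and 5' tie-break", {
  aln <- rbind(
    aln_row("exact", 100, 115),        # coincident with g1:5tRF
    aln_row("mostly_a", 103, 122),     # 12 nt on 5tRF, 7 nt on D-loop
    aln_row("tie", 103, 127),          # 12 nt on both -> smaller start wins
    aln_row("short", 110, 121),        # 5 and 6 nt, below the floor
    aln_row("anti", 100, 115, strand = "-"),
    aln_row("un", 0, 0, unmapped = TRUE),
    aln_row("sec", 100, 115, secondary = TRUE)
  )
  got <- assign_reads(aln, two_bins)
  expect_equal(got, c("g1:5tRF", "g1:5tRF", "g1:5tRF", NA, NA, NA, NA))
  # unstranded mode admits the antisense read
  expect_equal(assign_reads(aln, two_bins, stranded = FALSE)[5], "g1:5tRF")
})

test_that("assignment agrees with a brute-force overlap scan", {
  fx <- make_sim_fixture(n_genes = 6, seed = 13, check_unique = FALSE)
  set.seed(99)
  n <- 300
  contigs <- unique(fx$bins$seq_id)
  clen <- stats::setNames(Biostrings::width(fx$sim$genome),
                          names(fx$sim$genome))
  start <- floor(runif(n, 0, clen[sample(contigs, n, TRUE)] - 25))
  aln <- data.frame(
    read_id = paste0("r", seq_len(n)),
    seq_id = sample(contigs, n, TRUE),
    start = start, end = start + sample(15:21, n, TRUE),
    strand = sample(c("+", "-"), n, TRUE), mapq = 60L,
    is_unmapped = FALSE, is_secondary = FALSE, stringsAsFactors = FALSE
  )
  expect_equal(assign_reads(aln, fx$bins), assign_brute(aln, fx$bins))
  expect_equal(assign_reads(aln, fx$bins, stranded = FALSE),
               assign_brute(aln, fx$bins, stranded = FALSE))
})

test_that("count matrices tally assigned primary reads per sample", {
  aln1 <- do.call(rbind, replicate(100, aln_row("r", 100, 115),
                                   simplify = FALSE))
  aln1$read_id <- paste0("r", 1:100)
  empty <- aln_row("x", 0, 0, unmapped = TRUE)[0, ]
  cm <- build_count_matrix(list(s1 = aln1, s2 = empty), two_bins)
  expect_equal(unname(cm$counts["g1:5tRF", ]), c(100, 0))
  expect_equal(sum(cm$counts[, "s2"]), 0)
  expect_equal(cm$samples$lib_size, c(100, 0))
  # column sums never exceed mapped primary reads
  expect_true(all(colSums(cm$counts) <= cm$samples$lib_size))
  # read order does not matter
  cm_rev <- build_count_matrix(list(s1 = aln1[100:1, ], s2 = empty),
                               two_bins)
  expect_equal(cm_rev$counts, cm$counts)
  expect_error(build_count_matrix(list(aln1, empty), two_bins), "named")
  expect_error(
    build_count_matrix(stats::setNames(list(aln1, empty), c("a", "a")),
                       two_bins), "duplicate")
})

test_that("antisense simulated reads contribute nothing under stranded
           counting", {
  fx <- make_sim_fixture(n_genes = 4, seed = 17,
                         source_plan = data.frame(
                           gene = 1, region_label = "5tRF",
                           mean_A = 50, mean_B = 50))
  rs <- simulate_reads(fx$design, fx$sim, fx$bins)
  aln <- exact_match_map(rs$reads[[1]], fx$sim$genome)
  flipped <- aln
  flipped$strand <- ifelse(aln$strand == "+", "-", "+")
  cm <- build_count_matrix(list(s = flipped), fx$bins)
  expect_equal(sum(cm$counts), 0)
  cm_ok <- build_count_matrix(list(s = aln), fx$bins)
  expect_gt(sum(cm_ok$counts), 0)
})

test_that("counts and sample sheets survive the TSV round trip", {
  set.seed(5)
  mat <- matrix(rpois(20, 30), 5, 4,
                dimnames = list(paste0("b", 1:5), paste0("s", 1:4)))
  cm <- counts_fixture(mat, lib = colSums(mat) + 10,
                       meta = data.frame(sex = c("F", "F", "M", "M")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cm, f)
  back <- read_counts(f)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$samples$lib_size, cm$samples$lib_size)
  expect_equal(back$samples$sex, cm$samples$sex)
})
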