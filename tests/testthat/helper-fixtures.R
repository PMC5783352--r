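# Shared fixture builders (all synthetic, generated at test time).

# a small simulated gene set with bins; memoised per parameter set within
# a test file run
make_sim_fixture <- function(n_genes = 8, n_excluded = 0, seed = 101,
                             source_plan = NULL,
                             groups = data.frame(label = c("A", "B"),
                                                 n = c(3L, 3L)),
                             ...) {
  design <- sim_design(n_genes = n_genes, n_excluded = n_excluded,
                       groups = groups, source_plan = source_plan,
                       seed = seed, ...)
  sim <- simulate_genes(design)
  retained <- filter_trnas(sim$genes)
  bins <- build_bins(retained, sim$structures, contig_lengths = sim$genome,
                     window = design$fragment_window, flank = design$flank)
  list(design = design, sim = sim, retained = retained, bins = bins)
}

# hand-written one-gene reference: 30 nt flanks around a 72 nt mature
# sequence on the plus strand of a 200 nt contig
make_manual_gene <- function() {
  set.seed(9)
  flank5 <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  flank3 <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  mature <- paste(sample(c("A", "C", "G", "T"), 72, TRUE), collapse = "")
  mature <- paste0(substr(mature, 1, 33), "GCC", substr(mature, 37, 72))
  pad <- paste(sample(c("A", "C", "G", "T"), 200 - 132, TRUE), collapse = "")
  contig <- paste0(flank5, mature, flank3, pad)
  genes <- data.frame(gene_id = "chrT.trna1", seq_id = "chrT", start = 30,
                      end = 102, strand = "+", isotype = "Gly",
                      anticodon = "GCC", score = 70, is_pseudo = FALSE,
                      is_selenocysteine = FALSE, stringsAsFactors = FALSE)
  genes$introns <- list(NULL)
  genes$n_introns <- 0L
  genome <- Biostrings::DNAStringSet(c(chrT = contig))
  list(genes = genes, genome = genome, mature = mature,
       structure = locate_structure(mature, anticodon = "GCC"))
}

# trf_counts straight from a matrix
counts_fixture <- function(mat, lib = NULL, meta = NULL) {
  samples <- data.frame(sample_id = colnames(mat),
                        lib_size = lib %||% colSums(mat),
                        stringsAsFactors = FALSE)
  if (!is.null(meta)) samples <- cbind(samples, meta)
  trf_counts(mat, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the shipped cross-strain sex-bias mean table, as classifier input
sex_bias_fixture <- function() {
  tbl <- read.delim(system.file("extdata", "sex_bias_means.tsv",
                                package = "trfbin"))
  means <- data.frame(bin_id = paste0(tbl$gene_id, ":", tbl$trf_class),
                      mean_female = tbl$mean_female,
                      mean_male = tbl$mean_male,
                      bias = tbl$bias, stringsAsFactors = FALSE)
  c(sex_bias_matrix(means), list(expected = means))
}
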