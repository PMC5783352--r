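# Synthetic reference, annotation and read-set generator with truth tables.

# isotype -> anticodon pairs used when drawing genes
SIM_ISOTYPES <- c(Gly = "GCC", Asp = "GTC", Ala = "AGC", Lys = "TTT",
                  Thr = "TGT", Pro = "CGG", Trp = "CCA", Glu = "CTC",
                  Gln = "CTG", Phe = "GAA", Ser = "GCT", Arg = "TCT",
                  Val = "TAC", His = "GTG")

#' Describe a simulation
#'
#' Collects every knob of the synthetic-data generator into one validated
#' design object.  The defaults emulate the study conditions the pipeline
#' is meant for: 15--21 nt fragments cut from specific structural regions
#' of specific tRNA genes, precursor-flank fragments, negative-binomial
#' counts with dispersion 0.1 (the standard overdispersion level for
#' RNA-seq-like data), and optional uniform background reads.
#'
#' @param n_genes Number of tRNA genes to simulate.
#' @param n_excluded How many of them carry an exclusion flag (cycled over
#'   pseudogene, selenocysteine and intron-containing).
#' @param groups `data.frame` with columns `label` and `n` (replicates per
#'   group); samples are named `<label>_r<i>`.
#' @param source_plan `data.frame` describing the expressed tRFs: `gene`
#'   (ordinal into the retained genes) or `gene_id`, `region_label`, one
#'   `mean_<label>` column per group, and optionally `dispersion` per row.
#' @param dispersion Negative-binomial dispersion used where the plan has
#'   none (default 0.1; variance = mu + dispersion * mu^2).
#' @param background_rate Poisson mean of random-position reads per sample
#'   (default 0).
#' @param read_length_range Read length interval in nt (default 15--21).
#' @param fragment_window Bin width the fragments are cut for (default 15).
#' @param mature_length_range Mature tRNA lengths, drawn uniformly
#'   (default 72--76 nt; the canonical clover-leaf layout with fixed
#'   landmark offsets needs at least 72).
#' @param flank Precursor flank simulated on each side (default 30 nt).
#' @param near_edge_n Number of genes placed at a contig start with only
#'   `near_edge_flank` nt of 5' flank, so their 5-Pre bin drops.
#' @param near_edge_flank Truncated flank for those genes (default 10 nt).
#' @param genes_per_contig Genes packed per contig (default 50).
#' @param spacer Length of the `N` spacer between gene cassettes (default
#'   20 nt); `N` runs keep cassette k-mers from bleeding into each other.
#' @param check_unique Redraw genes until every genome k-mer of the
#'   minimum read length is unique on both strands, so the exact-match
#'   fixture mapper is unambiguous (default `TRUE`).
#' @param seed Integer seed; all generator output is a deterministic
#'   function of the design including the seed.
#' @return A validated list of class `sim_design`.
#' @export
sim_design <- function(n_genes, n_excluded = 0L,
                       groups = data.frame(label = c("A", "B"), n = c(3L, 3L)),
                       source_plan = NULL, dispersion = 0.1,
                       background_rate = 0, read_length_range = c(15L, 21L),
                       fragment_window = 15L,
                       mature_length_range = c(72L, 76L), flank = 30L,
                       near_edge_n = 0L, near_edge_flank = 10L,
                       genes_per_contig = 50L, spacer = 20L,
                       check_unique = TRUE, seed = 1L) {
  if (n_excluded > n_genes) stop_validation("n_excluded exceeds n_genes")
  if (dispersion <= 0) stop_validation("dispersion must be positive")
  if (background_rate < 0) stop_validation("background_rate must be >= 0")
  if (mature_length_range[1] < 72L) {
    stop_validation("mature lengths below 72 nt cannot hold the canonical ",
                    "landmark layout")
  }
  if (fragment_window > read_length_range[2]) {
    stop_validation("fragment_window outside the reach of read_length_range")
  }
  if (!is.null(source_plan)) {
    mean_cols <- paste0("mean_", groups$label)
    missing <- setdiff(mean_cols, names(source_plan))
    if (length(missing)) {
      stop_validation("source_plan lacks columns: ",
                      paste(missing, collapse = ", "))
    }
    if (any(as.matrix(source_plan[, mean_cols]) < 0)) {
      stop_validation("plan means must be >= 0")
    }
  }
  structure(list(
    n_genes = as.integer(n_genes), n_excluded = as.integer(n_excluded),
    groups = groups, source_plan = source_plan, dispersion = dispersion,
    background_rate = background_rate,
    read_length_range = as.integer(read_length_range),
    fragment_window = as.integer(fragment_window),
    mature_length_range = as.integer(mature_length_range),
    flank = as.integer(flank), near_edge_n = as.integer(near_edge_n),
    near_edge_flank = as.integer(near_edge_flank),
    genes_per_contig = as.integer(genes_per_contig),
    spacer = as.integer(spacer), check_unique = isTRUE(check_unique),
    seed = as.integer(seed)
  ), class = "sim_design")
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sampling helpers immune to R's length-1 sample() surprise
sample_one <- function(x) x[sample.int(length(x), 1L)]
sample_n <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# canonical clover-leaf structure string for a mature length >= 72
canonical_ss <- function(len) {
  core <- paste0(strrep(">", 7), "..", strrep(">", 4), strrep(".", 8),
                 strrep("<", 4), "..", strrep(">", 5), strrep(".", 7),
                 strrep("<", 5), strrep(".", 4), strrep(">", 5),
                 strrep(".", 7), strrep("<", 5), strrep("<", 7))
  paste0(core, strrep(".", len - 72L))
}

# one random mature sequence with the anticodon at 1-based 34-36
random_mature <- function(len, anticodon) {
  s <- random_bases(len)
  paste0(substr(s, 1, 33), anticodon, substr(s, 37, len))
}

#' Simulate tRNA genes, reference and structures
#'
#' Draws `n_genes` tRNA genes with random mature sequences of 72--76 nt in
#' canonical clover-leaf geometry (the [locate_structure()] fallback holds
#' exactly, and matching structure strings are emitted), places each gene
#' with its precursor flanks on a contig on a random strand, flags
#' `n_excluded` genes as pseudogene / selenocysteine / intron-containing,
#' and (by default) redraws genes until every k-mer of the minimum read
#' length is unique genome-wide on both strands.
#'
#' @param design A [sim_design()] object.
#' @return List of class `trf_sim`: `genome`
#'   ([Biostrings::DNAStringSet]), `genes` (the [read_trnascan()] table
#'   layout), `mature` (named character, transcription orientation), `ss`
#'   (named structure strings), `structures` ([trna_structures()] output)
#'   and `design`.
#' @export
simulate_genes <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  n <- design$n_genes
  if (n == 0L) {
    return(structure(list(genome = Biostrings::DNAStringSet(),
                          genes = empty_gene_table(), mature = character(),
                          ss = character(),
                          structures = list(), design = design),
                     class = "trf_sim"))
  }
  flank <- design$flank

  iso_idx <- sample(length(SIM_ISOTYPES), n, replace = TRUE)
  isotype <- names(SIM_ISOTYPES)[iso_idx]
  anticodon <- unname(SIM_ISOTYPES[iso_idx])
  mlen <- sample_n(seq(design$mature_length_range[1],
                      design$mature_length_range[2]), n)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  near_edge <- rep(FALSE, n)
  if (design$near_edge_n > 0L) {
    near_edge[seq_len(min(design$near_edge_n, n))] <- TRUE
    strand[near_edge] <- "+"  # truncated flank is the transcriptional 5'
  }
  f5 <- ifelse(near_edge, design$near_edge_flank, flank)
  f3 <- rep(flank, n)

  # exclusion flags, cycled pseudo / SeC / intron over a random draw
  is_pseudo <- is_sec <- has_intron <- rep(FALSE, n)
  if (design$n_excluded > 0L) {
    flagged <- sample(which(!near_edge))[seq_len(design$n_excluded)]
    kind <- rep_len(c("pseudo", "sec", "intron"), design$n_excluded)
    is_pseudo[flagged[kind == "pseudo"]] <- TRUE
    is_sec[flagged[kind == "sec"]] <- TRUE
    has_intron[flagged[kind == "intron"]] <- TRUE
    isotype[is_sec] <- "SeC"
    anticodon[is_sec] <- "TCA"
  }

  # contig layout: near-edge genes open their own contigs
  contig_of <- integer(n)
  if (any(near_edge)) {
    contig_of[near_edge] <- seq_len(sum(near_edge))
  }
  normal <- which(!near_edge)
  if (length(normal)) {
    contig_of[normal] <- sum(near_edge) +
      ((seq_along(normal) - 1L) %/% design$genes_per_contig) + 1L
  }
  # near-edge contigs hold a single gene each, normal contigs up to
  # genes_per_contig; a near-edge gene must be first on its contig
  n_contigs <- max(contig_of)
  contig_names <- paste0("ctg", seq_len(n_contigs))

  mature <- vapply(seq_len(n), function(i) random_mature(mlen[i], anticodon[i]),
                   "")
  flank5_seq <- vapply(f5, random_bases, "")
  flank3_seq <- vapply(f3, random_bases, "")

  assemble <- function() {
    cassette <- vapply(seq_len(n), function(i) {
      tx <- paste0(flank5_seq[i], mature[i], flank3_seq[i])
      if (strand[i] == "+") tx else revcomp_chr(tx)
    }, "")
    spacer_seq <- strrep("N", design$spacer)
    gstart <- gend <- numeric(n)
    cass_start <- cass_end <- numeric(n)
    contig_seqs <- character(n_contigs)
    for (ci in seq_len(n_contigs)) {
      idx <- which(contig_of == ci)
      idx <- idx[order(near_edge[idx], decreasing = TRUE)]  # near-edge first
      off <- 0
      parts <- character(0)
      for (i in idx) {
        left_pad <- if (strand[i] == "+") f5[i] else f3[i]
        gstart[i] <- off + left_pad
        gend[i] <- gstart[i] + mlen[i]
        cass_start[i] <- off
        cass_end[i] <- off + nchar(cassette[i])
        parts <- c(parts, cassette[i], spacer_seq)
        off <- off + nchar(cassette[i]) + design$spacer
      }
      contig_seqs[ci] <- paste(parts, collapse = "")
    }
    list(contig_seqs = contig_seqs, gstart = gstart, gend = gend,
         cass_start = cass_start, cass_end = cass_end)
  }

  asm <- assemble()
  if (design$check_unique) {
    k <- design$read_length_range[1]
    for (round in seq_len(50L)) {
      bad <- duplicate_kmer_genes(asm, contig_of, k)
      if (length(bad) == 0L) break
      for (i in bad) {
        mature[i] <- random_mature(mlen[i], anticodon[i])
        flank5_seq[i] <- random_bases(f5[i])
        flank3_seq[i] <- random_bases(f3[i])
      }
      asm <- assemble()
    }
    if (length(duplicate_kmer_genes(asm, contig_of, k))) {
      warning("duplicate ", k, "-mers remain after 50 redraw rounds; ",
              "the exact-match mapper may discard some reads as multi-hit")
    }
  }

  genome <- Biostrings::DNAStringSet(asm$contig_seqs)
  names(genome) <- contig_names
  seq_id <- contig_names[contig_of]
  trna_num <- stats::ave(seq_len(n), contig_of, FUN = seq_along)
  gene_id <- paste0(seq_id, ".trna", trna_num)

  introns <- vector("list", n)
  for (i in which(has_intron)) {
    introns[[i]] <- cbind(start = asm$gstart[i] + 30, end = asm$gstart[i] + 40)
  }
  genes <- data.frame(
    gene_id = gene_id, seq_id = seq_id, start = asm$gstart, end = asm$gend,
    strand = strand, isotype = isotype, anticodon = anticodon,
    score = round(runif(n, 40, 90), 1), is_pseudo = is_pseudo,
    is_selenocysteine = is_sec, stringsAsFactors = FALSE
  )
  genes$introns <- introns
  genes$n_introns <- vapply(introns, function(x) if (is.null(x)) 0L else 1L, 0L)

  names(mature) <- gene_id
  ss <- vapply(mlen, canonical_ss, "")
  names(ss) <- gene_id
  structures <- lapply(seq_len(n), function(i) {
    locate_structure(mature[i], anticodon = anticodon[i], ss = ss[[i]])
  })
  names(structures) <- gene_id

  structure(list(genome = genome, genes = genes, mature = mature, ss = ss,
                 structures = structures, design = design),
            class = "trf_sim")
}

# indices of genes whose cassette contains a k-mer duplicated genome-wide
# (either strand); N-containing k-mers (spacers) never collide with reads
duplicate_kmer_genes <- function(asm, contig_of, k) {
  kmers <- list(); pos <- list(); contig <- list(); m <- 0L
  for (ci in seq_along(asm$contig_seqs)) {
    s <- asm$contig_seqs[ci]
    L <- nchar(s)
    if (L < k) next
    km <- substring(s, 1:(L - k + 1L), k:L)
    keep <- !grepl("N", km, fixed = TRUE)
    m <- m + 1L
    kmers[[m]] <- km[keep]
    pos[[m]] <- which(keep)
    contig[[m]] <- rep(ci, sum(keep))
  }
  if (m == 0L) return(integer(0))
  fwd <- unlist(kmers); fwd_pos <- unlist(pos); fwd_ctg <- unlist(contig)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(fwd)))
  all_k <- c(fwd, rc)
  dup_val <- unique(all_k[duplicated(all_k)])
  if (length(dup_val) == 0L) return(integer(0))
  hit <- fwd %in% dup_val | rc %in% dup_val
  if (!any(hit)) return(integer(0))
  bad <- logical(length(contig_of))
  hp <- fwd_pos[hit]; hc <- fwd_ctg[hit]
  for (i in seq_along(contig_of)) {
    ci <- contig_of[i]
    inside <- hc == ci & hp + k - 1L > asm$cass_start[i] &
      hp <= asm$cass_end[i]
    if (any(inside)) bad[i] <- TRUE
  }
  which(bad)
}

sim_samples <- function(design) {
  g <- design$groups
  data.frame(
    sample_id = unlist(lapply(seq_len(nrow(g)), function(i) {
      paste0(g$label[i], "_r", seq_len(g$n[i]))
    })),
    group = rep(g$label, g$n),
    replicate = unlist(lapply(g$n, seq_len)),
    stringsAsFactors = FALSE
  )
}

#' Simulate small-RNA read sets with a truth table
#'
#' For every sample and every planned tRF, draws a negative-binomial count
#' and emits that many reads: exact genomic subsequences on the gene
#' strand whose 5' end is uniform within +-2 nt of the bin's 5' end and
#' whose length is uniform in the design's read-length range.  The 3' end
#' is truncated (never below the minimum read length) when a longer read
#' would overlap a neighbouring bin of the same gene more than its source
#' bin, so emitted reads always count toward the bin they were drawn for.
#' Background reads (Poisson per sample) are placed uniformly at random.
#'
#' @param design The [sim_design()] object (its `seed + 1` seeds the read
#'   stream so gene and read draws are independent).
#' @param sim Output of [simulate_genes()] for the same design.
#' @param bins Bin table built from the simulated genes ([build_bins()]).
#' @return List: `reads` (per-sample named character vectors), `truth`
#'   (`data.frame`: `bin_id`, `sample_id`, `group`, `replicate`,
#'   `true_mean`, `drawn_count`, `is_differential`, `direction`), and
#'   `samples`.
#' @export
simulate_reads <- function(design, sim, bins) {
  stopifnot(inherits(design, "sim_design"), inherits(sim, "trf_sim"))
  set.seed(design$seed + 1L)
  samples <- sim_samples(design)
  plan <- resolve_plan(design, sim, bins)
  lmin <- design$read_length_range[1]
  lmax <- design$read_length_range[2]
  genome_chr <- stats::setNames(as.character(sim$genome), names(sim$genome))

  reads <- vector("list", nrow(samples))
  names(reads) <- samples$sample_id
  truth <- vector("list", nrow(samples) * max(1L, nrow(plan)))
  t_i <- 0L
  for (s in seq_len(nrow(samples))) {
    sample_reads <- character(0)
    for (p in seq_len(nrow(plan))) {
      mu <- plan[[paste0("mean_", samples$group[s])]][p]
      disp <- plan$dispersion[p]
      cnt <- stats::rnbinom(1L, mu = mu, size = 1 / disp)
      if (cnt > 0) {
        seqs <- emit_bin_reads(cnt, plan[p, ], bins, genome_chr, lmin, lmax)
        names(seqs) <- paste0(samples$sample_id[s], ":", plan$bin_id[p],
                              ":", seq_along(seqs))
        sample_reads <- c(sample_reads, seqs)
      }
      t_i <- t_i + 1L
      truth[[t_i]] <- data.frame(
        bin_id = plan$bin_id[p], sample_id = samples$sample_id[s],
        group = samples$group[s], replicate = samples$replicate[s],
        true_mean = mu, drawn_count = as.integer(cnt),
        is_differential = plan$is_differential[p],
        direction = plan$direction[p], stringsAsFactors = FALSE
      )
    }
    if (design$background_rate > 0) {
      nb <- stats::rpois(1L, design$background_rate)
      if (nb > 0) {
        bg <- vapply(seq_len(nb), function(i) {
          ctg <- sample_one(names(genome_chr))
          len <- sample_one(lmin:lmax)
          clen <- nchar(genome_chr[[ctg]])
          if (clen < len) return(random_bases(len))
          st <- sample_one(seq_len(clen - len + 1L))
          sq <- substr(genome_chr[[ctg]], st, st + len - 1L)
          if (sample_one(c(TRUE, FALSE))) sq else revcomp_chr(sq)
        }, "")
        names(bg) <- paste0(samples$sample_id[s], ":bg:", seq_len(nb))
        sample_reads <- c(sample_reads, bg)
      }
    }
    reads[[s]] <- sample_reads
  }
  truth <- do.call(rbind, truth[seq_len(t_i)])
  list(reads = reads, truth = truth, samples = samples)
}

# attach bin ids, dispersions and differential labels to the source plan
resolve_plan <- function(design, sim, bins) {
  plan <- design$source_plan
  if (is.null(plan) || nrow(plan) == 0L) {
    return(data.frame(bin_id = character(), gene_id = character(),
                      region_label = character(), dispersion = numeric(),
                      is_differential = logical(), direction = character()))
  }
  plan <- as.data.frame(plan)
  if (is.null(plan$gene_id)) {
    retained <- filter_trnas(sim$genes)
    if (any(plan$gene > nrow(retained))) {
      stop_validation("plan refers to gene ordinals beyond the retained set")
    }
    plan$gene_id <- retained$gene_id[plan$gene]
  }
  plan$bin_id <- paste0(plan$gene_id, ":", plan$region_label)
  missing <- setdiff(plan$bin_id, bins$bin_id)
  if (length(missing)) {
    stop_validation("plan error: no bin for ",
                    paste(missing, collapse = ", "))
  }
  if (is.null(plan$dispersion)) plan$dispersion <- design$dispersion
  plan$dispersion[is.na(plan$dispersion)] <- design$dispersion
  mean_cols <- paste0("mean_", design$groups$label)
  mm <- as.matrix(plan[, mean_cols, drop = FALSE])
  plan$is_differential <- apply(mm, 1, function(r) max(r) > min(r))
  plan$direction <- ifelse(plan$is_differential,
                           design$groups$label[apply(mm, 1, which.max)],
                           "none")
  plan
}

# emit `cnt` reads for one planned tRF
emit_bin_reads <- function(cnt, plan_row, bins, genome_chr, lmin, lmax) {
  b <- bins[bins$bin_id == plan_row$bin_id, ]
  gene_bins <- bins[bins$gene_id == plan_row$gene_id, ]
  clen <- nchar(genome_chr[[b$seq_id]])
  vapply(seq_len(cnt), function(i) {
    jit <- sample_one(-2:2)
    len <- sample_one(lmin:lmax)
    repeat {
      iv <- read_interval(b, jit, len, clen)
      if (!is.null(iv) &&
          isTRUE(best_bin_overlap(iv, gene_bins) == plan_row$bin_id)) break
      if (len > lmin) {
        len <- len - 1L
      } else if (jit != 0L) {
        jit <- 0L; len <- lmin
      } else {
        iv <- read_interval(b, 0L, lmin, clen)
        if (is.null(iv)) {  # bin flush against a contig edge
          rs <- max(0, min(b$start, clen - lmin))
          iv <- c(rs, rs + lmin)
        }
        break  # keep the minimal read even if assignment is off
      }
    }
    sq <- substr(genome_chr[[b$seq_id]], iv[1] + 1L, iv[2])
    if (b$strand == "-") revcomp_chr(sq) else sq
  }, "")
}

read_interval <- function(b, jit, len, clen) {
  if (b$strand == "+") {
    rs <- b$start + jit; re <- rs + len
  } else {
    re <- b$end - jit; rs <- re - len
  }
  if (rs < 0 || re > clen) return(NULL)
  c(rs, re)
}

best_bin_overlap <- function(iv, gene_bins) {
  ov <- pmin(iv[2], gene_bins$end) - pmax(iv[1], gene_bins$start)
  ok <- ov >= 10
  if (!any(ok)) return(NA_character_)
  cand <- gene_bins[ok, ]
  ov <- ov[ok]
  cand <- cand[order(-ov, cand$start, cand$bin_id), ]
  cand$bin_id[1]
}

#' Simulate a count matrix directly from a plan
#'
#' Count-level shortcut past read emission: draws the negative-binomial
#' counts of [simulate_reads()] straight into a `trf_counts` object, for
#' tests and power studies that do not need sequences.
#'
#' @param plan `data.frame` with `bin_id`, one `mean_<label>` column per
#'   group and optionally `dispersion`.
#' @param groups `data.frame` with `label` and `n` (replicates).
#' @param dispersion Fallback dispersion (default 0.1).
#' @param lib_extra Reads added to every library size on top of the
#'   column sums, emulating mapped reads outside the plan (default 0).
#' @param seed Seed for the draw.
#' @return List with `counts` (a `trf_counts`) and `truth`.
#' @export
simulate_counts <- function(plan, groups, dispersion = 0.1, lib_extra = 0,
                            seed = 1L) {
  set.seed(seed)
  samples <- sim_samples(list(groups = groups))
  if (is.null(plan$dispersion)) plan$dispersion <- dispersion
  counts <- matrix(0, nrow = nrow(plan), ncol = nrow(samples),
                   dimnames = list(plan$bin_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    mu <- plan[[paste0("mean_", samples$group[s])]]
    counts[, s] <- stats::rnbinom(nrow(plan), mu = mu,
                                  size = 1 / plan$dispersion)
  }
  mean_cols <- paste0("mean_", groups$label)
  mm <- as.matrix(plan[, mean_cols, drop = FALSE])
  truth <- data.frame(
    bin_id = plan$bin_id,
    is_differential = apply(mm, 1, function(r) max(r) > min(r)),
    direction = ifelse(apply(mm, 1, function(r) max(r) > min(r)),
                       groups$label[apply(mm, 1, which.max)], "none"),
    stringsAsFactors = FALSE
  )
  samples$lib_size <- colSums(counts) + lib_extra
  list(counts = trf_counts(counts, samples), truth = truth)
}

#' Write per-sample reads as FASTQ
#'
#' @param reads Named character vector of read sequences (one sample), as
#'   produced by [simulate_reads()].
#' @param file Output FASTQ path.
#' @return Invisibly, `file`.
#' @export
write_fastq <- function(reads, file) {
  dss <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(dss)))
  Biostrings::writeXStringSet(dss, file, format = "fastq", qualities = quals)
  invisible(file)
}
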