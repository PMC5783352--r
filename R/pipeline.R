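# Pipeline front-end: config handling, stage commands, run manifests.
# The exec/trfbin script is a thin dispatcher over these functions.

#' Load and validate a run configuration
#'
#' @param config A YAML path or a named list.
#' @param required Config keys that must name existing files.
#' @return The config list.
#' @export
load_config <- function(config, required = character()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_validation("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_validation("config must be a list or YAML path")
  for (key in required) {
    path <- config[[key]]
    if (!is_nonempty_string(path)) {
      stop_validation("config key '", key, "' is required")
    }
    if (!file.exists(path)) {
      stop_validation("config key '", key, "': file not found: ", path)
    }
  }
  config
}

out_path <- function(config, ...) {
  dir <- config$output_dir %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file.path(dir, ...)
}

write_manifest <- function(config, stage, extra = list()) {
  manifest <- list(
    stage = stage,
    package = "trfbin",
    version = as.character(utils::packageVersion("trfbin")),
    seed = config$seed %||% NA,
    parameters = config[setdiff(names(config), "output_dir")]
  )
  manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, out_path(config, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a sample sheet
#'
#' TSV with at least `sample_id`; typically also `path` (alignment or
#' FASTQ file per library) and metadata columns (`strain`, `sex`, `stage`,
#' `treatment`, `replicate`).
#'
#' @param file TSV path.
#' @return `data.frame`.
#' @export
read_sample_sheet <- function(file) {
  sheet <- read_tsv(file)
  if (!"sample_id" %in% names(sheet)) {
    stop_validation("sample sheet needs a sample_id column")
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop_validation("duplicate sample_id in sample sheet")
  }
  sheet
}

#' Aggregate read totals over sample groups
#'
#' Sums per-group read counts of a sequencing summary table and reports
#' the grand total and, when the number of libraries is given, the mean
#' reads per library.
#'
#' @param x TSV path or `data.frame` with columns `sample_group` and
#'   `n_reads` (a `description` column is carried through when present).
#' @param n_libraries Optional library count used for the per-library
#'   mean.
#' @return Object of class `trf_sample_summary`: list with `groups`,
#'   `grand_total`, `n_libraries`, `mean_per_library`.
#' @export
summarize_samples <- function(x, n_libraries = NULL) {
  if (is.character(x)) x <- read_tsv(x)
  if (!all(c("sample_group", "n_reads") %in% names(x))) {
    stop_validation("need columns sample_group and n_reads")
  }
  if (any(is.na(x$n_reads)) || any(x$n_reads < 0)) {
    stop_validation("n_reads must be non-negative")
  }
  grand <- sum(as.numeric(x$n_reads))
  structure(list(
    groups = x,
    grand_total = grand,
    n_libraries = n_libraries,
    mean_per_library = if (!is.null(n_libraries)) grand / n_libraries else NULL
  ), class = "trf_sample_summary")
}

#' @export
print.trf_sample_summary <- function(x, ...) {
  cat(nrow(x$groups), "sample groups\n")
  cat("grand total reads:", format(x$grand_total, big.mark = ","), "\n")
  if (!is.null(x$mean_per_library)) {
    cat("mean reads per library (n =", x$n_libraries, "):",
        format(round(x$mean_per_library, 1), big.mark = ","), "\n")
  }
  invisible(x)
}

#' Pipeline stage: simulate a synthetic dataset
#'
#' Generates reference, annotation, structure strings, per-sample FASTQ
#' reads, truth table and sample sheet from the `simulate` block of the
#' config, writing everything under `output_dir`.
#'
#' @param config Config list or YAML path; `config$simulate` holds the
#'   [sim_design()] fields (`groups` and `source_plan` may be lists of
#'   rows as YAML naturally produces).
#' @return Invisibly, a list with the output paths and the `trf_sim`.
#' @export
run_simulate <- function(config) {
  config <- load_config(config)
  sc <- config$simulate
  if (is.null(sc)) stop_validation("config needs a 'simulate' block")
  groups <- as.data.frame(do.call(rbind, lapply(sc$groups, as.data.frame)))
  if (is.null(groups) || nrow(groups) == 0L || any(groups$n < 1L)) {
    stop_validation("simulate.groups must define at least one sample")
  }
  plan <- if (!is.null(sc$source_plan)) {
    as.data.frame(do.call(rbind, lapply(sc$source_plan, as.data.frame)))
  } else NULL
  design <- sim_design(
    n_genes = sc$n_genes, n_excluded = sc$n_excluded %||% 0L,
    groups = groups, source_plan = plan,
    dispersion = sc$dispersion %||% 0.1,
    background_rate = sc$background_rate %||% 0,
    read_length_range = unlist(sc$read_length_range %||% c(15L, 21L)),
    fragment_window = sc$fragment_window %||% config$window %||% 15L,
    flank = sc$flank %||% config$flank %||% 30L,
    near_edge_n = sc$near_edge_n %||% 0L,
    seed = config$seed %||% sc$seed %||% 1L
  )
  sim <- simulate_genes(design)
  paths <- list(
    reference = out_path(config, "genome.fa"),
    annotation = out_path(config, "trnascan.txt"),
    structures = out_path(config, "structures.tsv"),
    sample_sheet = out_path(config, "samples.tsv"),
    truth = out_path(config, "truth.tsv")
  )
  Biostrings::writeXStringSet(sim$genome, paths$reference)
  write_trnascan(sim$genes, paths$annotation)
  write_tsv(data.frame(gene_id = names(sim$ss), mature = unname(sim$mature),
                       ss = unname(sim$ss), stringsAsFactors = FALSE),
            paths$structures)
  retained <- filter_trnas(sim$genes)
  bins <- build_bins(retained, sim$structures, contig_lengths = sim$genome,
                     window = design$fragment_window, flank = design$flank)
  rs <- simulate_reads(design, sim, bins)
  read_dir <- out_path(config, "reads")
  if (!dir.exists(read_dir)) dir.create(read_dir)
  fq <- vapply(names(rs$reads), function(s) {
    f <- file.path(read_dir, paste0(s, ".fastq"))
    write_fastq(rs$reads[[s]], f)
    f
  }, "")
  sheet <- rs$samples
  sheet$path <- unname(fq)
  write_tsv(sheet, paths$sample_sheet)
  write_tsv(rs$truth, paths$truth)
  write_manifest(config, "simulate",
                 list(n_genes = nrow(sim$genes),
                      n_excluded = sum(!sim$genes$gene_id %in% retained$gene_id),
                      n_samples = nrow(sheet)))
  invisible(c(paths, list(sim = sim, fastq = fq)))
}

#' Pipeline stage: build bins and export GTF
#'
#' Parses the annotation, applies the exclusion filter, locates clover-leaf
#' landmarks (structure strings when provided, canonical geometry
#' otherwise) and writes the structure-anchored bins as GTF together with
#' a summary.
#'
#' @param config Config list or YAML path with keys `annotation`,
#'   `reference`, optional `structures`, `window`, `flank`, `output_dir`.
#' @return Invisibly, the summary list (`genes_total`, `genes_excluded`,
#'   `genes_retained`, `n_bins`, `bins_per_label`, `gtf`).
#' @export
run_bins <- function(config) {
  config <- load_config(config, required = c("annotation", "reference"))
  genes <- read_trnascan(config$annotation)
  retained <- filter_trnas(genes)
  genome <- as_genome(config$reference)
  ss <- NULL
  if (is_nonempty_string(config$structures)) {
    st <- read_tsv(config$structures)
    ss <- stats::setNames(st$ss, st$gene_id)
  }
  structures <- trna_structures(retained, genome, ss = ss)
  bins <- build_bins(retained, structures, contig_lengths = genome,
                     window = config$window %||% 15L,
                     flank = config$flank %||% 30L)
  gtf <- out_path(config, "bins.gtf")
  write_gtf(bins, gtf)
  summary <- list(
    genes_total = nrow(genes),
    genes_excluded = nrow(genes) - nrow(retained),
    genes_retained = nrow(retained),
    n_bins = nrow(bins),
    bins_per_label = as.list(table(bins$region_label)),
    gtf = gtf
  )
  write_manifest(config, "bins", summary[names(summary) != "gtf"])
  invisible(summary)
}

#' Pipeline stage: count reads into bins
#'
#' Consumes SAM/BAM alignments per sample (or FASTQ mapped through the
#' exact-match fixture mapper when `mapper: exact`), assigns reads to the
#' GTF bins and writes the count matrix with its library-size sidecar and
#' an assignment log.
#'
#' @param config Config with `bins` (GTF), `sample_sheet` (needs `path`
#'   per sample), optional `reference` (required for `mapper: exact`),
#'   `min_overlap`, `stranded`.
#' @return Invisibly, the `trf_counts` object.
#' @export
run_count <- function(config) {
  config <- load_config(config, required = c("bins", "sample_sheet"))
  bins <- read_gtf(config$bins)
  if (nrow(bins) == 0L) stop_validation("bin file is empty: ", config$bins)
  sheet <- read_sample_sheet(config$sample_sheet)
  if (!"path" %in% names(sheet)) {
    stop_validation("sample sheet needs a path column")
  }
  missing <- sheet$sample_id[!file.exists(sheet$path)]
  if (length(missing)) {
    stop_validation("alignment/read files missing for samples: ",
                    paste(missing, collapse = ", "))
  }
  mapper <- config$mapper %||% "sam"
  if (mapper == "exact") {
    config <- load_config(config, required = "reference")
    ref <- as_genome(config$reference)
  }
  n_multi <- stats::setNames(rep(NA_integer_, nrow(sheet)), sheet$sample_id)
  sources <- lapply(seq_len(nrow(sheet)), function(i) {
    if (mapper == "exact") {
      aln <- exact_match_map(sheet$path[i], ref)
      n_multi[[i]] <<- attr(aln, "n_multihit")
      aln
    } else {
      read_alignments(sheet$path[i])
    }
  })
  names(sources) <- sheet$sample_id
  meta_cols <- setdiff(names(sheet), "path")
  cm <- build_count_matrix(sources, bins,
                           sample_meta = sheet[, meta_cols, drop = FALSE],
                           min_overlap = config$min_overlap %||% 10L,
                           stranded = config$stranded %||% TRUE)
  write_counts(cm, out_path(config, "counts.tsv"))
  log_df <- data.frame(sample_id = cm$samples$sample_id,
                       mapped = cm$samples$lib_size,
                       assigned = cm$samples$n_assigned,
                       unassigned = cm$samples$lib_size -
                         cm$samples$n_assigned,
                       multihit_discarded = unname(n_multi))
  write_tsv(log_df, out_path(config, "counting_log.tsv"))
  write_manifest(config, "count",
                 list(n_bins = nrow(bins), n_samples = nrow(sheet)))
  invisible(cm)
}

#' Pipeline stage: expression analysis
#'
#' Runs expressed-tRF filtering, TMM normalization, the configured Fisher
#' exact contrasts, sex-bias classification (when `sex` and `strain`
#' metadata are present), the mutual-information matrix, PCA scores and
#' Ward dendrograms, writing each product as TSV/Newick under
#' `output_dir`.
#'
#' @param config Config with `counts` (TSV from [run_count()]),
#'   `contrasts` (list of `name`/`group_a`/`group_b`), filter and test
#'   parameters.
#' @return Invisibly, a list with the computed objects.
#' @export
run_analyze <- function(config) {
  config <- load_config(config, required = "counts")
  cm <- read_counts(config$counts)
  fe <- filter_expressed(cm, min_count = config$min_count %||% 100L,
                         min_samples = config$min_samples %||% 3L)
  if (nrow(fe$counts) == 0L) {
    stop_runtime("no expressed bins after filtering")
  }
  use_tmm <- config$use_tmm %||% TRUE
  factors <- if (use_tmm && ncol(fe$counts) >= 2L) tmm_factors(fe) else NULL
  if (!is.null(factors)) {
    write_tsv(data.frame(sample_id = factors$sample_ids,
                         factor = unname(factors$factors),
                         reference = factors$reference_sample),
              out_path(config, "tmm_factors.tsv"))
  }
  norm <- normalized_counts(fe, factors)
  logn <- log2(norm + 1)

  results <- list(expressed = fe, factors = factors)
  for (ct in config$contrasts %||% list()) {
    res <- pairwise_contrast(fe, unlist(ct$group_a), unlist(ct$group_b),
                             factors = factors,
                             alpha = config$alpha %||% 0.05,
                             use_tmm = use_tmm && !is.null(factors))
    write_tsv(res, out_path(config, paste0("contrast_", ct$name, ".tsv")))
    results$contrasts[[ct$name]] <- res
  }

  meta <- fe$samples
  has_sex <- all(c("sex", "strain") %in% names(meta)) &&
    !anyNA(meta$sex) && !anyNA(meta$strain)
  if (has_sex) {
    sb <- classify_sex_bias(norm, strain = meta$strain, sex = meta$sex)
    write_tsv(sb, out_path(config, "sex_bias.tsv"))
    results$sex_bias <- sb
  }

  if (ncol(fe$counts) >= 2L && nrow(logn) >= 3L) {
    mi <- mi_matrix(logn)
    write_tsv(data.frame(sample_id = rownames(mi), unclass(mi),
                         check.names = FALSE), out_path(config, "mi_matrix.tsv"))
    results$mi <- mi
    if (nrow(logn) >= 2L) {
      pca <- pca_scores(logn, n_components = min(2L, ncol(logn)))
      write_tsv(data.frame(sample_id = rownames(pca$scores), pca$scores,
                           check.names = FALSE),
                out_path(config, "pca_scores.tsv"))
      results$pca <- pca
    }
    tree <- ward_tree(logn, axis = "samples")
    as_newick(tree, out_path(config, "samples_tree.nwk"))
    results$sample_tree <- tree
    if (has_sex && nrow(logn) >= 2L) {
      sexes <- toupper(substr(meta$sex, 1, 1))
      male <- ward_tree(logn[, sexes == "M", drop = FALSE], axis = "trfs")
      female <- ward_tree(logn[, sexes == "F", drop = FALSE], axis = "trfs")
      as_newick(male, out_path(config, "trf_tree_male.nwk"))
      as_newick(female, out_path(config, "trf_tree_female.nwk"))
      cmp <- compare_trees(male, female)
      jsonlite::write_json(cmp, out_path(config, "tree_comparison.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "columns")
      results$tree_comparison <- cmp
    }
  }
  write_manifest(config, "analyze",
                 list(n_expressed = nrow(fe$counts),
                      n_samples = ncol(fe$counts),
                      contrasts = vapply(config$contrasts %||% list(),
                                         function(ct) ct$name, "")))
  invisible(results)
}

#' Pipeline stage: bin-size sweep
#'
#' Re-runs binning, counting, filtering and one contrast for each bin
#' width in `sweep_sizes` and writes the per-width table.
#'
#' @param config Config with `annotation`, `reference`, `sample_sheet`,
#'   a single contrast under `contrasts`, and `sweep_sizes`.
#' @return Invisibly, the [window_sweep()] result.
#' @export
run_sweep <- function(config) {
  config <- load_config(config,
                        required = c("annotation", "reference", "sample_sheet"))
  genes <- filter_trnas(read_trnascan(config$annotation))
  genome <- as_genome(config$reference)
  structures <- trna_structures(genes, genome)
  sheet <- read_sample_sheet(config$sample_sheet)
  mapper <- config$mapper %||% "sam"
  sources <- lapply(seq_len(nrow(sheet)), function(i) {
    if (mapper == "exact") exact_match_map(sheet$path[i], genome)
    else read_alignments(sheet$path[i])
  })
  names(sources) <- sheet$sample_id
  ct <- config$contrasts[[1]]
  if (is.null(ct)) stop_validation("sweep needs one contrast in the config")
  sw <- window_sweep(sources, genes, structures,
                     group_a = unlist(ct$group_a),
                     group_b = unlist(ct$group_b),
                     contig_lengths = genome,
                     sizes = unlist(config$sweep_sizes %||%
                                      c(15L, 20L, 25L, 30L, 35L)),
                     flank = config$flank %||% 30L,
                     min_overlap = config$min_overlap %||% 10L,
                     min_count = config$min_count %||% 100L,
                     min_samples = config$min_samples %||% 3L,
                     alpha = config$alpha %||% 0.05)
  write_tsv(sw$table, out_path(config, "window_sweep.tsv"))
  write_manifest(config, "sweep", list(best_window = sw$best_window))
  invisible(sw)
}
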