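# Read-to-bin assignment and the bins x samples count container.

#' Assign aligned reads to tRF bins
#'
#' Each mapped primary read is assigned to at most one bin: the bin with
#' the largest overlap with the aligned span, provided that overlap is at
#' least `min_overlap` nt.  With `stranded = TRUE` only same-strand bins
#' are eligible.  Ties are broken toward the bin with the smaller genomic
#' start, then the lexicographically smaller `bin_id`.
#'
#' @param aln Alignment `data.frame` ([read_alignments()] layout); only
#'   mapped, non-secondary rows are considered.
#' @param bins Bin table ([build_bins()]).
#' @param min_overlap Minimum read/bin overlap in nt (default 10).
#' @param stranded Require read and bin on the same strand (default `TRUE`).
#' @return Character vector along `aln` rows: the assigned `bin_id`, or
#'   `NA` when no bin qualifies (or the record is unmapped/secondary).
#' @export
assign_reads <- function(aln, bins, min_overlap = 10L, stranded = TRUE) {
  out <- rep(NA_character_, nrow(aln))
  if (nrow(aln) == 0L || nrow(bins) == 0L) return(out)
  eligible <- which(!aln$is_unmapped & !aln$is_secondary)
  if (length(eligible) == 0L) return(out)

  reads_gr <- GenomicRanges::GRanges(
    seqnames = aln$seq_id[eligible],
    ranges = IRanges::IRanges(start = aln$start[eligible] + 1,
                              end = aln$end[eligible]),
    strand = aln$strand[eligible]
  )
  bins_gr <- GenomicRanges::GRanges(
    seqnames = bins$seq_id,
    ranges = IRanges::IRanges(start = bins$start + 1, end = bins$end),
    strand = bins$strand
  )
  ov <- GenomicRanges::findOverlaps(reads_gr, bins_gr,
                                    minoverlap = as.integer(min_overlap),
                                    ignore.strand = !stranded)
  if (length(ov) == 0L) return(out)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  width_ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(reads_gr)[q], IRanges::ranges(bins_gr)[s]))
  # best per read: widest overlap, then smaller bin start, then bin_id
  ord <- order(q, -width_ov, bins$start[s], bins$bin_id[s], method = "radix")
  first <- ord[!duplicated(q[ord])]
  out[eligible[q[first]]] <- bins$bin_id[s[first]]
  out
}

#' Assemble a bins x samples count matrix
#'
#' Counts, for every sample, the mapped primary reads assigned to each bin
#' by [assign_reads()].  Library sizes record the number of mapped primary
#' reads per sample (the denominator used by the Fisher contrasts), with
#' assigned-read totals kept alongside.
#'
#' @param sources Named list, one entry per sample: an alignment
#'   `data.frame` or a SAM/BAM path.  Names are the sample ids.
#' @param bins Bin table ([build_bins()]).
#' @param sample_meta Optional `data.frame` with a `sample_id` column plus
#'   attributes such as `strain`, `sex`, `stage`, `treatment`, `replicate`.
#' @inheritParams assign_reads
#' @return A `trf_counts` object: list with `counts` (integer matrix, bins
#'   x samples), `samples` (`sample_id`, `lib_size`, `n_assigned`, merged
#'   metadata) and `bins`.
#' @export
build_count_matrix <- function(sources, bins, sample_meta = NULL,
                               min_overlap = 10L, stranded = TRUE) {
  if (length(sources) == 0L) stop_validation("at least one sample required")
  if (nrow(bins) == 0L) stop_validation("bin table is empty")
  ids <- names(sources)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop_validation("sources must be a named list (names = sample ids)")
  }
  if (anyDuplicated(ids)) stop_validation("duplicate sample ids in sources")

  counts <- matrix(0L, nrow = nrow(bins), ncol = length(sources),
                   dimnames = list(bins$bin_id, ids))
  lib_size <- n_assigned <- stats::setNames(integer(length(sources)), ids)
  for (j in seq_along(sources)) {
    aln <- sources[[j]]
    if (is.character(aln)) aln <- read_alignments(aln)
    primary <- !aln$is_unmapped & !aln$is_secondary
    lib_size[j] <- sum(primary)
    hit <- assign_reads(aln, bins, min_overlap = min_overlap,
                        stranded = stranded)
    tab <- table(factor(hit[primary], levels = bins$bin_id))
    counts[, j] <- as.integer(tab)
    n_assigned[j] <- sum(tab)
  }
  samples <- data.frame(sample_id = ids, lib_size = as.numeric(lib_size),
                        n_assigned = as.integer(n_assigned),
                        stringsAsFactors = FALSE)
  if (!is.null(sample_meta)) {
    if (!"sample_id" %in% names(sample_meta)) {
      stop_validation("sample_meta needs a sample_id column")
    }
    samples <- merge(samples, sample_meta, by = "sample_id", all.x = TRUE,
                     sort = FALSE)
    samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  }
  trf_counts(counts, samples, bins)
}

#' Construct a tRF count container
#'
#' @param counts Integer matrix, bins x samples, with dimnames.
#' @param samples `data.frame` with `sample_id` and `lib_size` columns (one
#'   row per matrix column, same order).
#' @param bins Optional bin table matching the matrix rows.
#' @return Object of class `trf_counts`.
#' @export
trf_counts <- function(counts, samples, bins = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0)) stop_validation("counts must be non-negative")
  if (is.null(samples$sample_id)) stop_validation("samples needs sample_id")
  if (nrow(samples) != ncol(counts)) {
    stop_validation("samples rows must match count columns")
  }
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (is.null(samples$lib_size)) samples$lib_size <- colSums(counts)
  if (any(samples$lib_size < colSums(counts))) {
    stop_validation("library sizes below column sums")
  }
  if (!is.null(bins) && nrow(bins) != nrow(counts)) {
    stop_validation("bin table rows must match count rows")
  }
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples, bins = bins),
            class = "trf_counts")
}

#' @export
print.trf_counts <- function(x, ...) {
  cat("trf_counts: ", nrow(x$counts), " bins x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("library sizes: ", paste(format(x$samples$lib_size), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.trf_counts <- function(x) dim(x$counts)

#' Write / read a count matrix as TSV
#'
#' The matrix is written with `bin_id` as the first column; sample
#' metadata and library sizes go to a sidecar `<file>.samples.tsv`.
#'
#' @param x A `trf_counts` object.
#' @param file Output TSV path.
#' @return Invisibly, `file`.
#' @export
write_counts <- function(x, file) {
  df <- data.frame(bin_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, file)
  write_tsv(x$samples, paste0(file, ".samples.tsv"))
  invisible(file)
}

#' @rdname write_counts
#' @export
read_counts <- function(file) {
  df <- read_tsv(file)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$bin_id
  samples <- read_tsv(paste0(file, ".samples.tsv"))
  trf_counts(counts, samples)
}
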