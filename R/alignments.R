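# Alignment input (SAM/BAM) and the exact-match fixture mapper.

#' Read alignment records from SAM or BAM
#'
#' Returns records in file order with unmapped and secondary alignments
#' flagged rather than dropped, so callers can count mapped primary reads
#' for library sizes.  SAM input is converted through
#' [Rsamtools::asBam()]; aligned spans come from the CIGAR reference
#' width.
#'
#' @param file Path to a `.sam` or `.bam` file.
#' @return `data.frame` with `read_id`, `seq_id`, `start`, `end` (0-based
#'   half-open; `NA` for unmapped records), `strand`, `mapq`,
#'   `is_unmapped`, `is_secondary`.
#' @export
read_alignments <- function(file) {
  if (!file.exists(file)) stop_validation("alignment file not found: ", file)
  ext <- tolower(tools::file_ext(file))
  bam <- file
  if (ext != "bam") {
    bam <- tryCatch(
      Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop_validation("not a readable SAM/BAM file: ",
                                          file, " (", conditionMessage(e), ")")
    )
  }
  res <- tryCatch(
    Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar")
    ))[[1]],
    error = function(e) stop_validation("not a readable SAM/BAM file: ",
                                        file, " (", conditionMessage(e), ")")
  )
  n <- length(res$qname)
  unmapped <- bitwAnd(res$flag, 4L) > 0L
  secondary <- bitwAnd(res$flag, 256L) > 0L
  revstrand <- bitwAnd(res$flag, 16L) > 0L
  ref_width <- rep(NA_integer_, n)
  has_cigar <- !unmapped & !is.na(res$cigar)
  if (any(has_cigar)) {
    ref_width[has_cigar] <-
      GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[has_cigar])
  }
  start0 <- ifelse(unmapped, NA_real_, as.numeric(res$pos) - 1)
  data.frame(
    read_id = res$qname,
    seq_id = ifelse(unmapped, NA_character_, as.character(res$rname)),
    start = start0,
    end = start0 + ref_width,
    strand = ifelse(unmapped, NA_character_, ifelse(revstrand, "-", "+")),
    mapq = as.integer(res$mapq),
    is_unmapped = unmapped,
    is_secondary = secondary,
    stringsAsFactors = FALSE
  )
}

#' Exact-substring mapper for fixture reads
#'
#' A deliberately simple mapper used so synthetic read sets need no
#' external aligner: every read is searched as an exact substring on both
#' strands of the reference.  A unique hit produces one mapped record;
#' reads with zero hits are returned unmapped, and reads hitting more than
#' one locus are discarded as unmapped with the multi-hit count recorded
#' (ambiguous reads must never be double-counted across near-identical
#' isoacceptor copies).
#'
#' @param reads A named character vector / [Biostrings::DNAStringSet] of
#'   read sequences, or a FASTQ path.
#' @param reference Reference contigs ([Biostrings::DNAStringSet] or FASTA
#'   path).
#' @return Alignment `data.frame` in the [read_alignments()] layout, with
#'   attribute `n_multihit` giving the number of discarded multi-hit reads.
#' @export
exact_match_map <- function(reads, reference) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  reference <- as_genome(reference)
  widths <- Biostrings::width(reads)
  if (length(reads) && (min(widths) < 10L || max(widths) > 50L)) {
    stop_validation("read lengths must be within 10-50 nt")
  }

  hits <- vector("list", length(reads))  # per-read list of (seq, start0, strand)
  # reads with ambiguity codes cannot exact-match and stay unmapped
  clean <- Biostrings::alphabetFrequency(reads, baseOnly = TRUE)[, "other",
                                                                 drop = TRUE] == 0
  for (w in unique(widths[clean])) {
    idx <- which(widths == w & clean)
    pd <- Biostrings::PDict(reads[idx])
    for (ci in seq_along(reference)) {
      contig <- reference[[ci]]
      clen <- length(contig)
      fwd <- Biostrings::matchPDict(pd, contig)
      rev <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(contig))
      for (k in seq_along(idx)) {
        r <- idx[k]
        fs <- BiocGenerics::start(fwd[[k]])
        rs <- BiocGenerics::start(rev[[k]])
        if (length(fs)) {
          hits[[r]] <- c(hits[[r]], lapply(fs, function(s) {
            list(seq = names(reference)[ci], start = s - 1L, strand = "+")
          }))
        }
        if (length(rs)) {
          hits[[r]] <- c(hits[[r]], lapply(rs, function(s) {
            list(seq = names(reference)[ci], start = clen - (s - 1L) - w,
                 strand = "-")
          }))
        }
      }
    }
  }

  n <- length(reads)
  nhit <- lengths(hits)
  out <- data.frame(
    read_id = names(reads),
    seq_id = NA_character_, start = NA_real_, end = NA_real_,
    strand = NA_character_, mapq = ifelse(nhit == 1L, 60L, 0L),
    is_unmapped = nhit != 1L, is_secondary = FALSE,
    stringsAsFactors = FALSE
  )
  uniq <- which(nhit == 1L)
  if (length(uniq)) {
    out$seq_id[uniq] <- vapply(hits[uniq], function(h) h[[1]]$seq, "")
    out$start[uniq] <- vapply(hits[uniq], function(h) h[[1]]$start, 0L)
    out$end[uniq] <- out$start[uniq] + widths[uniq]
    out$strand[uniq] <- vapply(hits[uniq], function(h) h[[1]]$strand, "")
  }
  attr(out, "n_multihit") <- sum(nhit > 1L)
  out
}

#' Write alignment records as SAM
#'
#' Minimal single-end SAM writer used by the pipeline to persist fixture
#' mappings; sequences are emitted as `*` unless supplied.
#'
#' @param aln Alignment `data.frame` ([read_alignments()] layout).
#' @param contig_lengths Named vector of contig lengths for the `@SQ`
#'   header.
#' @param file Output path.
#' @param seqs Optional named character vector of read sequences.
#' @return Invisibly, `file`.
#' @export
write_sam <- function(aln, contig_lengths, file, seqs = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  flag <- ifelse(aln$is_unmapped, 4L, ifelse(aln$strand == "-", 16L, 0L)) +
    ifelse(aln$is_secondary, 256L, 0L)
  seq_field <- if (is.null(seqs)) rep("*", nrow(aln)) else
    unname(seqs[aln$read_id])
  width <- ifelse(aln$is_unmapped, NA, aln$end - aln$start)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  aln$read_id, flag,
                  ifelse(aln$is_unmapped, "*", aln$seq_id),
                  ifelse(aln$is_unmapped, 0L, as.integer(aln$start + 1)),
                  ifelse(aln$is_unmapped, 0L, aln$mapq),
                  ifelse(aln$is_unmapped, "*",
                         paste0(as.integer(width), "M")),
                  seq_field)
  writeLines(c(hdr, body), file)
  invisible(file)
}
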