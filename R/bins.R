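# Structure-anchored bin construction and GTF serialization.

#' Build the structure-anchored bins of one tRNA gene
#'
#' Anchors up to seven fixed-width bins on a gene's clover-leaf landmarks:
#' `5-Pre` ends at the mature 5' boundary, `5tRF` starts at it, the
#' `D-loop`, `A-loop` and `T-loop` bins are centered on the loop midpoints
#' (ties broken toward 5'), `3tRF` ends at the mature 3' boundary and
#' `3-Pre` starts immediately after it.  A bin is emitted only when it fits
#' entirely in available sequence: precursor bins need at least `window` nt
#' of flank, loop bins must not extend beyond the mature span.  All
#' positions are strand-aware -- "5'" is the gene's transcriptional 5' end.
#'
#' @param gene One-row gene table (see [read_trnascan()]).
#' @param structure Structure annotation from [locate_structure()].
#' @param window Bin width in nt (default 15).
#' @param flank Precursor flank searched on each side, nt (default 30).
#' @param available_flank_5,available_flank_3 Flank actually available in
#'   the reference upstream/downstream of the mature span (transcription
#'   orientation), capped at `flank`; defaults assume unconstrained flanks.
#' @return A `data.frame` of bins: `bin_id` (`<gene_id>:<region_label>`),
#'   `gene_id`, `region_label`, `seq_id`, `start`, `end` (0-based
#'   half-open), `strand`, `width`.
#' @export
make_bins <- function(gene, structure, window = 15L, flank = 30L,
                      available_flank_5 = flank, available_flank_3 = flank) {
  if (window < 1L) stop_validation("window must be >= 1")
  len <- structure$mature_length
  avail5 <- min(available_flank_5, flank)
  avail3 <- min(available_flank_3, flank)

  # candidate bins in mature coordinates (0 = mature 5' end)
  cand <- list()
  if (avail5 >= window) cand[["5-Pre"]] <- c(-window, 0L)
  if (window <= len) {
    cand[["5tRF"]] <- c(0L, window)
    for (lab in c("D-loop", "A-loop", "T-loop")) {
      lp <- structure[[c(`D-loop` = "d_loop", `A-loop` = "a_loop",
                         `T-loop` = "t_loop")[[lab]]]]
      loop_len <- lp[2] - lp[1]
      s <- lp[1] - ceiling((window - loop_len) / 2)  # 5'-ward on odd excess
      if (s >= 0L && s + window <= len) cand[[lab]] <- c(s, s + window)
    }
    cand[["3tRF"]] <- c(len - window, len)
  } else {
    warning("window ", window, " exceeds mature length ", len, " of ",
            gene$gene_id, ": no mature bins emitted")
  }
  if (avail3 >= window) cand[["3-Pre"]] <- c(len, len + window)
  if (length(cand) == 0L) return(empty_bin_table())

  labs <- names(cand)
  m <- do.call(rbind, cand)
  # mature -> genomic: plus strand counts up from gene start, minus strand
  # counts down from gene end.
  if (gene$strand == "+") {
    gstart <- gene$start + m[, 1]
    gend <- gene$start + m[, 2]
  } else {
    gstart <- gene$end - m[, 2]
    gend <- gene$end - m[, 1]
  }
  data.frame(
    bin_id = paste0(gene$gene_id, ":", labs),
    gene_id = gene$gene_id,
    region_label = labs,
    seq_id = gene$seq_id,
    start = as.numeric(gstart),
    end = as.numeric(gend),
    strand = gene$strand,
    width = as.integer(window),
    stringsAsFactors = FALSE
  )
}

empty_bin_table <- function() {
  data.frame(bin_id = character(), gene_id = character(),
             region_label = character(), seq_id = character(),
             start = numeric(), end = numeric(), strand = character(),
             width = integer(), stringsAsFactors = FALSE)
}

#' Build bins for a whole gene table
#'
#' Applies [make_bins()] to every gene, deriving the available flank on
#' each side from the contig bounds (a gene close to a contig edge loses
#' the corresponding precursor bin when less than `window` nt remain).
#'
#' @param genes Gene table (already filtered; see [filter_trnas()]).
#' @param structures Named list from [trna_structures()].
#' @param contig_lengths Named numeric vector of contig lengths, or a
#'   genome ([Biostrings::DNAStringSet]/FASTA path) they are taken from.
#'   `NULL` treats flanks as unconstrained.
#' @inheritParams make_bins
#' @return Combined bin `data.frame` (see [make_bins()]).
#' @export
build_bins <- function(genes, structures, contig_lengths = NULL,
                       window = 15L, flank = 30L) {
  if (!is.null(contig_lengths) && !is.numeric(contig_lengths)) {
    g <- as_genome(contig_lengths)
    contig_lengths <- stats::setNames(Biostrings::width(g), names(g))
  }
  pieces <- lapply(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, ]
    if (is.null(contig_lengths)) {
      up <- flank; down <- flank
    } else {
      clen <- contig_lengths[[gene$seq_id]]
      if (gene$strand == "+") {
        up <- gene$start; down <- clen - gene$end
      } else {
        up <- clen - gene$end; down <- gene$start
      }
    }
    make_bins(gene, structures[[gene$gene_id]], window = window,
              flank = flank, available_flank_5 = up, available_flank_3 = down)
  })
  out <- do.call(rbind, c(pieces, list(empty_bin_table())))
  rownames(out) <- NULL
  out
}

#' Write bins as GTF
#'
#' One line per bin with feature `tRF_bin`, 1-based inclusive coordinates,
#' and attributes `gene_id`, `bin_id` and `region_label`; lines are sorted
#' by (`seq_id`, `start`, `bin_id`) so reruns are byte-identical.
#'
#' @param bins Bin table from [build_bins()].
#' @param file Output path or connection.
#' @return Invisibly, `file`.
#' @export
write_gtf <- function(bins, file) {
  ord <- order(bins$seq_id, bins$start, bins$bin_id, method = "radix")
  bins <- bins[ord, , drop = FALSE]
  lines <- sprintf(
    '%s\ttrfbin\ttRF_bin\t%d\t%d\t.\t%s\t.\tgene_id "%s"; bin_id "%s"; region_label "%s";',
    bins$seq_id, as.integer(bins$start + 1), as.integer(bins$end),
    bins$strand, bins$gene_id, bins$bin_id, bins$region_label
  )
  writeLines(lines, file)
  invisible(file)
}

#' Read bins back from a GTF written by [write_gtf()]
#'
#' @param file GTF path.
#' @return Bin table in the [make_bins()] layout.
#' @export
read_gtf <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_bin_table())
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) {
    stop_validation("malformed GTF line ", bad[1])
  }
  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, ' "([^"]*)"'), a))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  attrs <- vapply(f, `[[`, "", 9L)
  start1 <- as.numeric(vapply(f, `[[`, "", 4L))
  end1 <- as.numeric(vapply(f, `[[`, "", 5L))
  data.frame(
    bin_id = attr_get(attrs, "bin_id"),
    gene_id = attr_get(attrs, "gene_id"),
    region_label = attr_get(attrs, "region_label"),
    seq_id = vapply(f, `[[`, "", 1L),
    start = start1 - 1,
    end = end1,
    strand = vapply(f, `[[`, "", 7L),
    width = as.integer(end1 - start1 + 1),
    stringsAsFactors = FALSE
  )
}
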