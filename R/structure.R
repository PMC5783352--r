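# Clover-leaf landmark location within the mature tRNA sequence.

# Canonical fallback geometry, 0-based half-open offsets within the mature
# sequence (1-based: D-loop 14-21, A-loop 33-39, T-loop 54-60).
CANONICAL_D_LOOP <- c(13L, 21L)
CANONICAL_A_LOOP <- c(32L, 39L)
CANONICAL_T_LOOP <- c(53L, 60L)

#' Locate clover-leaf loops within a mature tRNA sequence
#'
#' Finds the D-, anticodon- (A-) and T-loop intervals of a mature tRNA,
#' either from a secondary-structure string or, when none is supplied, from
#' canonical clover-leaf geometry (acceptor stem 7 bp; D-loop at 1-based
#' positions 14--21; the 7-nt anticodon loop at 33--39 containing the
#' anticodon triplet 34--36; T-loop at 54--60).
#'
#' With a structure string (tRNAscan `><` notation or dot-bracket), loops
#' are the unpaired runs enclosed by a hairpin -- an opening pair character
#' on the 5' side and a closing one on the 3' side -- taken in 5' to 3'
#' order as D, anticodon and T.
#'
#' @param mature_seq Mature tRNA sequence (character, 60--100 nt).
#' @param anticodon Optional anticodon triplet; when given, the inferred
#'   anticodon loop must contain it (consistency check).
#' @param ss Optional secondary-structure string of the same length as
#'   `mature_seq`.
#' @return A list with `mature_length`, and 0-based half-open offset pairs
#'   `d_loop`, `a_loop`, `t_loop` relative to the mature 5' end.
#' @examples
#' locate_structure(paste(rep("ACGT", 18), collapse = ""))
#' @export
locate_structure <- function(mature_seq, anticodon = NULL, ss = NULL) {
  mature_seq <- toupper(chartr("U", "T", as.character(mature_seq)))
  len <- nchar(mature_seq)
  if (len < 60L || len > 100L) {
    stop_validation("mature sequence length ", len, " outside 60-100 nt")
  }
  if (is.null(ss)) {
    loops <- list(d_loop = CANONICAL_D_LOOP, a_loop = CANONICAL_A_LOOP,
                  t_loop = CANONICAL_T_LOOP)
  } else {
    ss <- as.character(ss)
    if (nchar(ss) != len) {
      stop_validation("structure string length ", nchar(ss),
                      " does not match mature length ", len)
    }
    loops <- hairpin_loops(ss)
    if (length(loops) < 3L) {
      stop_runtime("structure error: fewer than three loops resolvable ",
                   "from the structure string")
    }
    loops <- list(d_loop = loops[[1]], a_loop = loops[[2]], t_loop = loops[[3]])
  }
  for (lp in loops) {
    if (lp[1] < 0L || lp[2] > len) {
      stop_runtime("structure error: loop [", lp[1], ",", lp[2],
                   ") outside the mature sequence")
    }
  }
  if (!is.null(anticodon)) {
    anticodon <- toupper(chartr("U", "T", anticodon))
    a_region <- substr(mature_seq, loops$a_loop[1] + 1L, loops$a_loop[2])
    if (!grepl(anticodon, a_region, fixed = TRUE)) {
      stop_runtime("consistency error: anticodon ", anticodon,
                   " not found inside the inferred anticodon loop")
    }
  }
  c(list(mature_length = len), loops)
}

# Unpaired runs enclosed by a hairpin: previous character opens a pair,
# next character closes one.  Returns 0-based half-open intervals.
hairpin_loops <- function(ss) {
  chars <- strsplit(ss, "")[[1]]
  unpaired <- chars %in% c(".", ",", "-", ":", "_")
  open <- chars %in% c(">", "(")
  close <- chars %in% c("<", ")")
  runs <- rle(unpaired)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    s <- starts[k]; e <- ends[k]
    if (s > 1L && e < length(chars) && open[s - 1L] && close[e + 1L]) {
      out[[length(out) + 1L]] <- c(s - 1L, e)  # to 0-based half-open
    }
  }
  out
}

#' Extract mature sequences for a gene table
#'
#' Pulls the annotated (mature) span of each gene from the reference and
#' reverse-complements minus-strand genes so the returned sequences read
#' 5' to 3' in transcription orientation.
#'
#' @param genes Gene table ([read_trnascan()]).
#' @param genome A [Biostrings::DNAStringSet] of reference contigs (or a
#'   FASTA path).
#' @return A named [Biostrings::DNAStringSet], one entry per gene.
#' @export
gene_sequences <- function(genes, genome) {
  genome <- as_genome(genome)
  missing <- setdiff(unique(genes$seq_id), names(genome))
  if (length(missing)) {
    stop_validation("contigs absent from reference: ",
                    paste(missing, collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(genes)), function(i) {
    s <- Biostrings::subseq(genome[[genes$seq_id[i]]],
                            start = genes$start[i] + 1L, end = genes$end[i])
    if (genes$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, ""))
  names(seqs) <- genes$gene_id
  seqs
}

as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet")) {
    stop_validation("reference must be a DNAStringSet or FASTA path")
  }
  genome
}

#' Locate structures for every gene in a table
#'
#' @param genes Gene table.
#' @param genome Reference ([Biostrings::DNAStringSet] or FASTA path) used
#'   to extract mature sequences.
#' @param ss Optional named character vector of structure strings keyed by
#'   `gene_id`; genes without an entry fall back to canonical geometry.
#' @param check_anticodon Verify that the anticodon lies inside the
#'   inferred anticodon loop (default `TRUE`).
#' @return Named list of structure annotations ([locate_structure()]).
#' @export
trna_structures <- function(genes, genome, ss = NULL, check_anticodon = TRUE) {
  seqs <- gene_sequences(genes, genome)
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]
    locate_structure(
      as.character(seqs[[i]]),
      anticodon = if (check_anticodon) genes$anticodon[i] else NULL,
      ss = if (!is.null(ss) && gid %in% names(ss)) ss[[gid]] else NULL
    )
  })
  names(out) <- genes$gene_id
  out
}
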