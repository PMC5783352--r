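#' Parse a tRNAscan-SE tabular annotation
#'
#' Reads the classic tRNAscan-SE tabular output (three header lines followed
#' by one row per tRNA) into a gene table.  Both the 9-column form and the
#' note-extended 10-column form are accepted; the pseudogene flag is read
#' from the note column when present.  Coordinates are converted to the
#' package-internal 0-based half-open convention on the plus strand: a
#' source row with begin greater than end encodes a minus-strand gene.
#'
#' @param file Path to a tRNAscan-SE tabular file, or a character vector of
#'   lines (used by the simulator round-trips).
#' @return A `data.frame` with one row per tRNA: `gene_id` (synthesized as
#'   `<seq_id>.trna<N>`), `seq_id`, `start`, `end` (0-based half-open),
#'   `strand`, `isotype`, `anticodon`, `score`, the exclusion flags
#'   `is_pseudo` and `is_selenocysteine`, `n_introns`, and a list column
#'   `introns` of two-column matrices of 0-based half-open genomic intron
#'   spans (`NULL` when intron-free).
#' @seealso [filter_trnas()], [write_trnascan()]
#' @export
read_trnascan <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file)
  } else {
    as.character(file)
  }
  rows <- vector("list", length(lines))
  n_out <- 0L
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    f <- strsplit(trimws(line), "[ \t]+")[[1]]
    # header lines: column banner, label row, dash ruler
    if (f[1] %in% c("Sequence", "Name") || grepl("^-+$", f[1])) next
    if (length(f) < 9L) {
      stop_validation("malformed tRNAscan row at line ", i,
                      ": expected at least 9 fields, got ", length(f))
    }
    num <- suppressWarnings(as.numeric(f[c(2, 3, 4, 7, 8, 9)]))
    if (anyNA(num)) {
      stop_validation("malformed tRNAscan row at line ", i,
                      ": non-numeric coordinate or score field")
    }
    begin <- num[2]; end <- num[3]
    if (begin == end) {
      stop_validation("invalid tRNAscan record at line ", i,
                      ": begin == end (", begin, ")")
    }
    strand <- if (begin < end) "+" else "-"
    start0 <- min(begin, end) - 1
    end0 <- max(begin, end)
    anticodon <- toupper(f[6])
    if (anticodon == "???") anticodon <- "NNN"
    anticodon <- chartr("U", "T", anticodon)
    if (nchar(anticodon) != 3L || grepl("[^ACGTN]", anticodon)) {
      stop_validation("invalid anticodon '", f[6], "' at line ", i)
    }
    note <- if (length(f) >= 10L) paste(f[10:length(f)], collapse = " ") else ""
    ib <- num[4]; ie <- num[5]
    introns <- NULL
    if (ib > 0 && ie > 0) {
      is0 <- min(ib, ie) - 1
      ie0 <- max(ib, ie)
      if (is0 <= start0 || ie0 >= end0) {
        stop_validation("invalid tRNAscan record at line ", i,
                        ": intron span not strictly inside the gene")
      }
      introns <- cbind(start = is0, end = ie0)
    }
    n_out <- n_out + 1L
    rows[[n_out]] <- list(
      gene_id = paste0(f[1], ".trna", f[2]),
      seq_id = f[1], start = start0, end = end0, strand = strand,
      isotype = f[5], anticodon = anticodon, score = num[6],
      is_pseudo = grepl("pseudo", note, ignore.case = TRUE),
      is_selenocysteine = grepl("^sec", tolower(f[5])),
      introns = list(introns)
    )
  }
  rows <- rows[seq_len(n_out)]
  if (n_out == 0L) {
    return(empty_gene_table())
  }
  out <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    seq_id = vapply(rows, `[[`, "", "seq_id"),
    start = vapply(rows, `[[`, 0, "start"),
    end = vapply(rows, `[[`, 0, "end"),
    strand = vapply(rows, `[[`, "", "strand"),
    isotype = vapply(rows, `[[`, "", "isotype"),
    anticodon = vapply(rows, `[[`, "", "anticodon"),
    score = vapply(rows, `[[`, 0, "score"),
    is_pseudo = vapply(rows, `[[`, TRUE, "is_pseudo"),
    is_selenocysteine = vapply(rows, `[[`, TRUE, "is_selenocysteine"),
    stringsAsFactors = FALSE
  )
  out$introns <- lapply(rows, function(r) r$introns[[1]])
  out$n_introns <- vapply(out$introns, function(x) if (is.null(x)) 0L else nrow(x), 0L)
  out
}

empty_gene_table <- function() {
  out <- data.frame(
    gene_id = character(), seq_id = character(), start = numeric(),
    end = numeric(), strand = character(), isotype = character(),
    anticodon = character(), score = numeric(), is_pseudo = logical(),
    is_selenocysteine = logical(), stringsAsFactors = FALSE
  )
  out$introns <- list()
  out$n_introns <- integer()
  out
}

#' Exclude pseudogene, selenocysteine and intron-containing tRNAs
#'
#' Pseudogene tRNAs, tRNAs for the non-standard amino acid selenocysteine,
#' and tRNAs whose precursors carry introns are removed before binning;
#' relative order of the remaining genes is preserved.
#'
#' @param genes Gene table from [read_trnascan()] or [simulate_genes()].
#' @return The retained subset of `genes`.
#' @export
filter_trnas <- function(genes) {
  if (nrow(genes) == 0L) return(genes)
  keep <- !genes$is_pseudo & !genes$is_selenocysteine & genes$n_introns == 0L
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a gene table back out in tRNAscan-SE tabular form
#'
#' Inverse of [read_trnascan()]: emits the three header lines and one row
#' per gene, using begin > end to encode the minus strand and the note
#' column to carry the pseudogene flag.
#'
#' @param genes Gene table as returned by [read_trnascan()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_trnascan <- function(genes, file) {
  hdr <- c(
    paste("Sequence", "tRNA", "Bounds", "tRNA", "Anti", "Intron", "Bounds",
          "Cove", sep = "\t"),
    paste("Name", "tRNA #", "Begin", "End", "Type", "Codon", "Begin", "End",
          "Score", "Note", sep = "\t"),
    paste(rep("--------", 10), collapse = "\t")
  )
  fmt_row <- function(i) {
    g <- genes[i, ]
    if (g$strand == "+") {
      b <- g$start + 1; e <- g$end
    } else {
      b <- g$end; e <- g$start + 1
    }
    intr <- genes$introns[[i]]
    if (is.null(intr)) {
      ib <- 0; ie <- 0
    } else if (g$strand == "+") {
      ib <- intr[1, "start"] + 1; ie <- intr[1, "end"]
    } else {
      ib <- intr[1, "end"]; ie <- intr[1, "start"] + 1
    }
    trna_num <- sub(".*\\.trna", "", g$gene_id)
    note <- if (g$is_pseudo) "pseudo" else ""
    paste(g$seq_id, trna_num, b, e, g$isotype, g$anticodon, ib, ie,
          formatC(g$score, format = "f", digits = 1), note, sep = "\t")
  }
  body <- vapply(seq_len(nrow(genes)), fmt_row, "")
  writeLines(c(hdr, body), file)
  invisible(file)
}
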