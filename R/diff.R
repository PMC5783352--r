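# Expressed-tRF filtering, Fisher exact contrasts, sex-bias classification
# and the bin-size sweep.

#' Keep expressed tRFs
#'
#' A bin counts as expressed when strictly more than `min_count` reads map
#' to it in at least `min_samples` samples (the default, more than 100
#' reads in at least 3 samples, is the expression rule used for tRF
#' discovery).  Idempotent; bin order is preserved.
#'
#' @param x `trf_counts` object.
#' @param min_count Read-count threshold (strict inequality; default 100).
#' @param min_samples Number of samples that must exceed it (default 3).
#' @return Filtered `trf_counts`.
#' @export
filter_expressed <- function(x, min_count = 100L, min_samples = 3L) {
  keep <- rowSums(x$counts > min_count) >= min_samples
  bins <- if (!is.null(x$bins)) x$bins[keep, , drop = FALSE] else NULL
  trf_counts(x$counts[keep, , drop = FALSE], x$samples, bins)
}

#' Two-sided Fisher exact test for one pooled contrast
#'
#' Tests the 2x2 table `[[count_a, lib_a - count_a], [count_b, lib_b -
#' count_b]]`; the two-sided p-value sums hypergeometric probabilities no
#' larger than that of the observed table (ties at 1e-7 relative
#' tolerance).
#'
#' @param count_a,count_b Pooled read counts in each group.
#' @param lib_a,lib_b Pooled library sizes.
#' @return The p-value.
#' @examples
#' fisher_pair(3, 4, 1, 4)  # 0.4857
#' @export
fisher_pair <- function(count_a, lib_a, count_b, lib_b) {
  if (lib_a <= 0 || lib_b <= 0) stop_validation("zero library size")
  if (count_a < 0 || count_b < 0 || count_a > lib_a || count_b > lib_b) {
    stop_validation("counts must lie in [0, library size]")
  }
  tab <- matrix(c(count_a, lib_a - count_a, count_b, lib_b - count_b),
                nrow = 2, byrow = TRUE)
  stats::fisher.test(round(tab))$p.value
}

#' Pairwise group contrast by pooled Fisher exact tests
#'
#' Counts are pooled within each group; library sizes are pooled after
#' scaling by the TMM factors (rounded to the nearest integer); each bin
#' gets a two-sided Fisher exact p-value, Benjamini-Hochberg q-values are
#' computed across the tested bins, and the log2 fold change comes from
#' pooled normalized count fractions with a +0.5 continuity offset.  A bin
#' is labelled `up_in_a`/`up_in_b` only when p < `alpha`.
#'
#' @param x `trf_counts` object (typically after [filter_expressed()]).
#' @param group_a,group_b Disjoint, non-empty character vectors of sample
#'   ids.
#' @param factors Optional `tmm_factors`; when `NULL` and `use_tmm` is
#'   `TRUE` they are computed from `x`.
#' @param alpha Significance gate for the direction label (default 0.05).
#' @param use_tmm Scale pooled library sizes by TMM factors (default
#'   `TRUE`); `FALSE` uses raw library sizes.
#' @return `data.frame` with one row per bin: `bin_id`, `region_label`,
#'   `group_a`, `group_b`, `count_a`, `count_b`, `lib_a`, `lib_b`,
#'   `log2fc`, `p_value`, `q_value`, `direction`.
#' @export
pairwise_contrast <- function(x, group_a, group_b, factors = NULL,
                              alpha = 0.05, use_tmm = TRUE) {
  ids <- colnames(x$counts)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_validation("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b))) {
    stop_validation("groups overlap: ",
                    paste(intersect(group_a, group_b), collapse = ", "))
  }
  unknown <- setdiff(c(group_a, group_b), ids)
  if (length(unknown)) {
    stop_validation("unknown samples in contrast: ",
                    paste(unknown, collapse = ", "))
  }
  eff <- stats::setNames(x$samples$lib_size, ids)
  if (use_tmm) {
    if (is.null(factors)) factors <- tmm_factors(x)
    eff <- eff * factors$factors[ids]
  }
  la <- round(sum(eff[group_a])); lb <- round(sum(eff[group_b]))
  ca <- rowSums(x$counts[, group_a, drop = FALSE])
  cb <- rowSums(x$counts[, group_b, drop = FALSE])
  p <- vapply(seq_along(ca), function(i) fisher_pair(ca[i], la, cb[i], lb), 0)
  q <- stats::p.adjust(p, method = "BH")
  log2fc <- log2(((ca + 0.5) / la) / ((cb + 0.5) / lb))
  direction <- rep("unchanged", length(p))
  direction[p < alpha & log2fc > 0] <- "up_in_a"
  direction[p < alpha & log2fc < 0] <- "up_in_b"
  region <- if (!is.null(x$bins)) x$bins$region_label else
    sub("^.*:", "", rownames(x$counts))
  data.frame(
    bin_id = rownames(x$counts), region_label = region,
    group_a = paste(group_a, collapse = ","),
    group_b = paste(group_b, collapse = ","),
    count_a = unname(ca), count_b = unname(cb),
    lib_a = la, lib_b = lb,
    log2fc = unname(log2fc), p_value = unname(p), q_value = unname(q),
    direction = direction, stringsAsFactors = FALSE
  )
}

#' Classify sex-biased tRFs across strains
#'
#' Given normalized counts for paired female/male samples of several
#' strains (exactly one sample per sex per strain), a tRF is "Female
#' biased" when its female count strictly exceeds the male count in every
#' strain, "Male biased" in the mirror case, and "inconsistent" otherwise.
#' Cross-strain mean counts per sex are reported alongside.
#'
#' @param x Numeric matrix of normalized counts (bins x samples) or a
#'   `trf_counts` object.
#' @param strain,sex Character vectors along the samples (columns); `sex`
#'   values must be `"F"`/`"female"` or `"M"`/`"male"` (case-insensitive).
#'   For a `trf_counts` input they default to the metadata columns of the
#'   same names.
#' @return `data.frame`: `bin_id`, `mean_female`, `mean_male`, `bias` (one
#'   of `"Female biased"`, `"Male biased"`, `"inconsistent"`).
#' @export
classify_sex_bias <- function(x, strain = NULL, sex = NULL) {
  if (inherits(x, "trf_counts")) {
    strain <- strain %||% x$samples$strain
    sex <- sex %||% x$samples$sex
    x <- x$counts
  }
  x <- as.matrix(x)
  if (is.null(strain) || is.null(sex) ||
      length(strain) != ncol(x) || length(sex) != ncol(x)) {
    stop_validation("strain and sex must be given for every sample")
  }
  sex <- toupper(substr(sex, 1, 1))
  if (!all(sex %in% c("F", "M"))) {
    stop_validation("sex must be female/male")
  }
  strains <- unique(strain)
  fcol <- mcol <- integer(length(strains))
  for (k in seq_along(strains)) {
    f <- which(strain == strains[k] & sex == "F")
    m <- which(strain == strains[k] & sex == "M")
    if (length(f) != 1L || length(m) != 1L) {
      stop_validation("strain ", strains[k],
                      " must contribute exactly one female and one male sample")
    }
    fcol[k] <- f; mcol[k] <- m
  }
  fm <- x[, fcol, drop = FALSE]
  mm <- x[, mcol, drop = FALSE]
  all_f <- rowSums(fm > mm) == length(strains)
  all_m <- rowSums(mm > fm) == length(strains)
  bias <- rep("inconsistent", nrow(x))
  bias[all_f] <- "Female biased"
  bias[all_m] <- "Male biased"
  data.frame(bin_id = rownames(x) %||% paste0("bin", seq_len(nrow(x))),
             mean_female = unname(rowMeans(fm)),
             mean_male = unname(rowMeans(mm)),
             bias = bias, stringsAsFactors = FALSE)
}

#' Expand cross-strain sex means into a per-strain count matrix
#'
#' Builds a fixture matrix of per-strain female/male counts whose
#' cross-strain means equal given target means and whose per-strain
#' orderings follow the sign of the mean difference: each strain's value
#' is the target mean times a strain weight, and the weights average
#' exactly 1.
#'
#' @param means `data.frame` with columns `bin_id`, `mean_female`,
#'   `mean_male`.
#' @param strains Strain labels (default five laboratory strains).
#' @param weights Positive strain weights with mean 1 (default
#'   `c(0.6, 0.8, 1, 1.2, 1.4)`).
#' @return List with `counts` (bins x samples matrix), `strain` and `sex`
#'   vectors along the columns.
#' @export
sex_bias_matrix <- function(means,
                            strains = c("Lvp", "Rock", "MoyoS", "MoyoR",
                                        "Trini"),
                            weights = c(0.6, 0.8, 1, 1.2, 1.4)) {
  stopifnot(length(weights) == length(strains), all(weights > 0))
  if (abs(mean(weights) - 1) > 1e-12) {
    stop_validation("strain weights must average 1")
  }
  counts <- cbind(outer(means$mean_female, weights),
                  outer(means$mean_male, weights))
  rownames(counts) <- means$bin_id
  strain <- rep(strains, 2)
  sex <- rep(c("F", "M"), each = length(strains))
  colnames(counts) <- paste0(strain, "_", sex)
  list(counts = counts, strain = strain, sex = sex)
}

#' Sweep bin sizes and count significant tRFs
#'
#' Re-bins, re-counts, re-filters and re-tests one contrast for each bin
#' width, reporting per width the number of expressed bins and the number
#' significant at `alpha`; the best width maximizes the significant count,
#' ties going to the smallest width.
#'
#' @param sources Named per-sample alignment sources
#'   ([build_count_matrix()]).
#' @param genes Filtered gene table.
#' @param structures Structures from [trna_structures()].
#' @param group_a,group_b Contrast sample ids.
#' @param contig_lengths Passed to [build_bins()].
#' @param sizes Bin widths to try (default 15, 20, 25, 30, 35 nt).
#' @param flank,min_overlap,stranded,min_count,min_samples,alpha,use_tmm
#'   Stage parameters, as in the individual operations.
#' @return List with `table` (`window`, `n_expressed`, `n_significant`)
#'   and `best_window`.
#' @export
window_sweep <- function(sources, genes, structures, group_a, group_b,
                         contig_lengths = NULL,
                         sizes = c(15L, 20L, 25L, 30L, 35L),
                         flank = 30L, min_overlap = 10L, stranded = TRUE,
                         min_count = 100L, min_samples = 3L, alpha = 0.05,
                         use_tmm = TRUE) {
  if (length(sizes) == 0L) stop_validation("sizes must be non-empty")
  sizes <- sort(unique(as.integer(sizes)))
  # read alignment files once; re-counting per window reuses the records
  sources <- lapply(sources, function(s) {
    if (is.character(s)) read_alignments(s) else s
  })
  n_expressed <- n_significant <- integer(length(sizes))
  for (k in seq_along(sizes)) {
    bins <- build_bins(genes, structures, contig_lengths = contig_lengths,
                       window = sizes[k], flank = flank)
    if (nrow(bins) == 0L) next
    cm <- build_count_matrix(sources, bins, min_overlap = min_overlap,
                             stranded = stranded)
    fe <- filter_expressed(cm, min_count = min_count,
                           min_samples = min_samples)
    n_expressed[k] <- nrow(fe$counts)
    if (nrow(fe$counts) == 0L) next
    can_tmm <- use_tmm && all(fe$samples$lib_size > 0)
    res <- pairwise_contrast(fe, group_a, group_b, alpha = alpha,
                             use_tmm = can_tmm)
    n_significant[k] <- sum(res$p_value < alpha)
  }
  tab <- data.frame(window = sizes, n_expressed = n_expressed,
                    n_significant = n_significant)
  if (all(n_significant == 0L) && all(n_expressed == 0L)) {
    warning("no expressed bins at any window size; reporting smallest size")
  }
  best <- sizes[which.max(n_significant)]  # which.max takes first = smallest
  list(table = tab, best_window = best)
}
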