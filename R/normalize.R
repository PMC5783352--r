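# Trimmed mean of M-values (TMM) library normalization.

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors for a count matrix.
#' The reference sample is the one whose upper-quartile count fraction is
#' closest to the mean of those fractions.  For each sample, bins with a
#' zero count in either the sample or the reference are excluded; M is the
#' log2 ratio of count fractions and A the mean log2 count fraction; the
#' top and bottom `trim_m` of M values and `trim_a` of A values are
#' discarded; the factor is 2 to the precision-weighted mean of the
#' remaining M values, weights being the inverse asymptotic binomial
#' variance.  Factors are rescaled to geometric mean 1.
#'
#' @param x A `trf_counts` object or a counts matrix (bins x samples).
#' @param lib_sizes Library sizes per sample; defaults to those stored in
#'   `x` (or column sums for a bare matrix).
#' @param trim_m,trim_a Two-sided trim fractions for M and A (defaults
#'   0.30 and 0.05, the standard TMM constants).
#' @return Object of class `tmm_factors`: list with `sample_ids`,
#'   `factors` (named, geometric mean 1) and `reference_sample`.
#' @export
tmm_factors <- function(x, lib_sizes = NULL, trim_m = 0.30, trim_a = 0.05) {
  counts <- if (inherits(x, "trf_counts")) x$counts else as.matrix(x)
  if (is.null(lib_sizes)) {
    lib_sizes <- if (inherits(x, "trf_counts")) x$samples$lib_size else
      colSums(counts)
  }
  if (ncol(counts) < 2L) stop_validation("TMM needs at least 2 samples")
  if (any(lib_sizes <= 0)) stop_validation("all library sizes must be positive")
  ids <- colnames(counts) %||% paste0("S", seq_len(ncol(counts)))

  f75 <- vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j], 0.75, names = FALSE) / lib_sizes[j]
  }, 0)
  ref <- which.min(abs(f75 - mean(f75)))

  factors <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], lib_sizes[j], counts[, ref], lib_sizes[ref],
             trim_m, trim_a)
  }, 0)
  factors <- factors / geometric_mean(factors)
  structure(list(sample_ids = ids,
                 factors = stats::setNames(factors, ids),
                 reference_sample = ids[ref]),
            class = "tmm_factors")
}

# One sample against the reference.
tmm_pair <- function(obs, n_obs, ref, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    stop_runtime("degenerate sample: no bins with nonzero counts shared ",
                 "with the reference")
  }
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(sel) || all(w[sel] == 0)) return(1)
  f <- sum(M[sel] / w[sel]) / sum(1 / w[sel])
  if (!is.finite(f)) return(1)
  2^f
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("TMM factors (reference: ", x$reference_sample, ")\n", sep = "")
  print(round(x$factors, 4))
  invisible(x)
}

#' Normalized counts
#'
#' Scales counts to a common effective library size: counts divided by
#' `lib_size * factor` and multiplied by the mean effective library size
#' (so values stay on the count scale), or by 1e6 for CPM.
#'
#' @param x `trf_counts` object.
#' @param factors `tmm_factors` object, or `NULL` for library-size-only
#'   scaling.
#' @param per_million Return counts per million instead of mean-library
#'   scale.
#' @return Numeric matrix, same shape as the counts.
#' @export
normalized_counts <- function(x, factors = NULL, per_million = FALSE) {
  counts <- x$counts
  eff <- x$samples$lib_size
  if (!is.null(factors)) {
    f <- factors$factors[colnames(counts)]
    if (anyNA(f)) stop_validation("factors missing for some samples")
    eff <- eff * f
  }
  scale_to <- if (per_million) 1e6 else mean(eff)
  sweep(counts, 2, eff, "/") * scale_to
}
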