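# Sample-level analyses: mutual information, PCA, Ward dendrograms.

#' Normalized mutual information of two expression profiles
#'
#' Mutual information estimated from the Spearman rank correlation under a
#' bivariate-normal copula: with `rho` the Spearman correlation
#' (average-rank ties), the raw MI is `-0.5 * ln(1 - rho^2)` (|rho|
#' clipped at 1 - 1e-12) and the normalized MI is `1 - exp(-2 * MI)` =
#' `rho^2`, which lies in [0, 1] and is invariant under strictly monotone
#' transforms of either profile.
#'
#' @param x,y Numeric profiles of equal length (>= 3 shared observations).
#' @param normalized Return the [0,1]-normalized value (default) or the
#'   raw MI in nats.
#' @return A single number.
#' @examples
#' spearman_mi(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
spearman_mi <- function(x, y, normalized = TRUE) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_validation("profiles must share at least 3 observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_runtime("undefined correlation: constant profile")
  }
  rho <- stats::cor(x, y, method = "spearman")
  rho <- sign(rho) * min(abs(rho), 1 - 1e-12)
  raw <- -0.5 * log(1 - rho^2)
  if (normalized) 1 - exp(-2 * raw) else raw
}

#' Pairwise mutual-information matrix over samples
#'
#' @param mat Numeric matrix of normalized expression, bins x samples;
#'   every pair of columns is compared with [spearman_mi()].
#' @return Object of class `mi_matrix`: symmetric matrix with unit
#'   diagonal, entries in [0, 1], dimnames = sample ids.
#' @export
mi_matrix <- function(mat) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  if (n < 2L) stop_validation("need at least 2 samples")
  ids <- colnames(mat) %||% paste0("S", seq_len(n))
  out <- diag(1, n)
  dimnames(out) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      out[i, j] <- out[j, i] <- spearman_mi(mat[, i], mat[, j])
    }
  }
  class(out) <- c("mi_matrix", class(out))
  out
}

#' Principal component scores of samples
#'
#' Centers each bin across samples and decomposes the centered matrix by
#' SVD.  The sign of each component is fixed so its loading vector has a
#' non-negative sum, making scores reproducible across platforms.
#'
#' @param mat Numeric matrix of log-scale normalized counts, bins x
#'   samples.
#' @param n_components Number of components to return (default 2).
#' @return List with `scores` (samples x components), `explained_var`
#'   (fractions, non-increasing, summing to <= 1), `loadings` (bins x
#'   components), `center` (per-bin means) and `sdev`.
#' @export
pca_scores <- function(mat, n_components = 2L) {
  mat <- as.matrix(mat)
  if (nrow(mat) < n_components) {
    stop_validation("fewer bins (", nrow(mat), ") than components (",
                    n_components, ")")
  }
  if (ncol(mat) < 2L) stop_validation("need at least 2 samples")
  center <- rowMeans(mat)
  xc <- t(mat - center)  # samples x bins, bin-centered
  sv <- svd(xc)
  total <- sum(sv$d^2)
  k <- min(n_components, length(sv$d))
  flip <- ifelse(colSums(sv$v[, seq_len(k), drop = FALSE]) < 0, -1, 1)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, "*")
  loadings <- sweep(sv$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  rownames(scores) <- colnames(mat)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(loadings) <- rownames(mat)
  colnames(loadings) <- colnames(scores)
  list(scores = scores,
       explained_var = if (total > 0) sv$d[seq_len(k)]^2 / total else
         rep(0, k),
       loadings = loadings, center = center, sdev = sv$d / sqrt(max(1, nrow(xc) - 1)))
}

#' Ward hierarchical clustering with Newick export
#'
#' Agglomerative clustering of samples (columns) or tRFs (rows) using
#' Euclidean distance on the supplied (log-scale normalized) profiles and
#' Ward linkage (`ward.D2`, the Lance-Williams update on squared
#' distances).
#'
#' @param mat Numeric matrix, bins x samples.
#' @param axis Cluster `"samples"` (columns) or `"trfs"` (rows).
#' @return Object of class `trf_dendro` wrapping the `hclust` result.
#' @export
ward_tree <- function(mat, axis = c("samples", "trfs")) {
  axis <- match.arg(axis)
  items <- if (axis == "samples") t(as.matrix(mat)) else as.matrix(mat)
  if (nrow(items) < 2L) stop_validation("need at least 2 leaves")
  if (is.null(rownames(items))) {
    rownames(items) <- paste0("leaf", seq_len(nrow(items)))
  }
  hc <- stats::hclust(stats::dist(items, method = "euclidean"),
                      method = "ward.D2")
  structure(list(hclust = hc, axis = axis, leaf_ids = hc$labels),
            class = "trf_dendro")
}

#' @export
print.trf_dendro <- function(x, ...) {
  cat("Ward dendrogram of ", length(x$leaf_ids), " ", x$axis,
      " (heights ", round(min(x$hclust$height), 3), "..",
      round(max(x$hclust$height), 3), ")\n", sep = "")
  invisible(x)
}

#' Serialize a dendrogram to Newick
#'
#' @param tree A `trf_dendro` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `file`).
#' @export
as_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Compare two dendrograms over the same leaves
#'
#' Reports the Pearson correlation of the two cophenetic distance
#' matrices and, for cuts into k = 2..4 clusters, the fraction of leaf
#' pairs whose co-membership agrees between the trees (the numerical
#' content of a tanglegram).
#'
#' @param a,b `trf_dendro` objects with identical leaf sets.
#' @param k Cluster counts for the co-membership comparison (default 2:4).
#' @return List with `cophenetic_cor` and `agreement` (`data.frame` of `k`
#'   and the concordant leaf-pair fraction).
#' @export
compare_trees <- function(a, b, k = 2:4) {
  la <- a$leaf_ids
  if (!setequal(la, b$leaf_ids) || length(la) != length(b$leaf_ids)) {
    stop_validation("leaf sets differ between the trees")
  }
  ca <- as.matrix(stats::cophenetic(a$hclust))[la, la]
  cb <- as.matrix(stats::cophenetic(b$hclust))[la, la]
  lower <- lower.tri(ca)
  cc <- stats::cor(ca[lower], cb[lower])
  k <- k[k >= 2 & k <= length(la)]
  agreement <- vapply(k, function(kk) {
    ga <- stats::cutree(a$hclust, k = kk)[la]
    gb <- stats::cutree(b$hclust, k = kk)[la]
    same_a <- outer(ga, ga, "==")[lower]
    same_b <- outer(gb, gb, "==")[lower]
    mean(same_a == same_b)
  }, 0)
  list(cophenetic_cor = cc,
       agreement = data.frame(k = k, agreement = agreement))
}
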