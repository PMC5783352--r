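# Independent oracle implementations used to cross-check the package.
# These deliberately use different algorithms (enumeration, direct
# formulas, naive loops) than the implementation paths they verify.

# Two-sided Fisher exact p for a 2x2 table [[a, b], [c, d]] by full
# enumeration of the hypergeometric support with choose().
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  prob <- vapply(lo:hi, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, 0)
  obs <- prob[a - lo + 1]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg q-values: sort, scale by m/rank, cumulative minimum
# from the largest p down.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Direct-formula TMM factor of sample j against reference r (no rescaling):
# trims by sorting rather than ranks, so it is only valid on tie-free data.
tmm_pair_oracle <- function(yj, nj, yr, nr, trim_m = 0.30, trim_a = 0.05) {
  keep <- yj > 0 & yr > 0
  yj <- yj[keep]; yr <- yr[keep]
  M <- log2((yj / nj) / (yr / nr))
  A <- 0.5 * (log2(yj / nj) + log2(yr / nr))
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep_m <- order(M)[lo_m:hi_m]
  keep_a <- order(A)[lo_a:hi_a]
  sel <- intersect(keep_m, keep_a)
  v <- (nj - yj[sel]) / (nj * yj[sel]) + (nr - yr[sel]) / (nr * yr[sel])
  2^(sum(M[sel] / v) / sum(1 / v))
}

tmm_oracle <- function(counts, libs, trim_m = 0.30, trim_a = 0.05) {
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75, names = FALSE)) / libs
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair_oracle(counts[, j], libs[j], counts[, ref], libs[ref],
                    trim_m, trim_a)
  }, 0)
  f / exp(mean(log(f)))
}

# Ward (ward.D2) agglomeration by the Lance-Williams update on squared
# Euclidean distances, run as an explicit O(n^3) loop.  Returns the merge
# heights and, per merge, the sorted pair of leaf sets.
ward_lw_oracle <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_val <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (d2[i, j] < best_val) { best_val <- d2[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(best_val)
    merges[[step]] <- list(sort(members[[i]]), sort(members[[j]]))
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

# leaf sets merged at each step of an hclust tree, for comparison with the
# oracle above
hclust_merge_sets <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1)
  expand <- function(idx) {
    if (idx < 0) return(-idx)
    sort(unlist(sets_members[[idx]]))
  }
  sets_members <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    a <- expand(hc$merge[s, 1])
    b <- expand(hc$merge[s, 2])
    sets_members[[s]] <- c(a, b)
    sets[[s]] <- list(sort(a), sort(b))
  }
  sets
}

# brute-force read-to-bin assignment: scan every bin, no interval index
assign_brute <- function(aln, bins, min_overlap = 10, stranded = TRUE) {
  vapply(seq_len(nrow(aln)), function(i) {
    if (aln$is_unmapped[i] || aln$is_secondary[i]) return(NA_character_)
    best_id <- NA_character_; best_ov <- -Inf
    best_start <- Inf
    for (b in seq_len(nrow(bins))) {
      if (bins$seq_id[b] != aln$seq_id[i]) next
      if (stranded && bins$strand[b] != aln$strand[i]) next
      ov <- min(aln$end[i], bins$end[b]) - max(aln$start[i], bins$start[b])
      if (ov < min_overlap) next
      better <- ov > best_ov ||
        (ov == best_ov && (bins$start[b] < best_start ||
                           (bins$start[b] == best_start &&
                            bins$bin_id[b] < best_id)))
      if (better) {
        best_id <- bins$bin_id[b]; best_ov <- ov; best_start <- bins$start[b]
      }
    }
    best_id
  }, "")
}

# pivot a simulate_reads truth table into a bins x samples matrix
truth_matrix <- function(truth) {
  tapply(truth$drawn_count, list(truth$bin_id, truth$sample_id), sum)
}
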