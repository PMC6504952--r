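# Independent brute-force oracles; deliberately naive, sharing no code with
# the package implementations they check.

# Wilcoxon signed-rank two-sided p by enumerating all 2^n sign assignments.
wsr_enum_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# BH step-up by the textbook recipe.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- prev
  }
  adj
}

# Two-sided Fisher exact p by enumerating all tables with the fixed margins.
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# All maximal clusters of flagged positions: every window of the flagged
# list is checked explicitly for the gap rule, minimum size, and maximality.
cluster_enum_oracle <- function(pos, flagged, min_cpgs, max_gap) {
  idx <- which(flagged)
  p <- pos[idx]
  m <- length(idx)
  out <- list()
  for (i in seq_len(m)) {
    for (j in i:m) {
      if (j - i + 1 < min_cpgs) next
      if (j > i && any(diff(p[i:j]) > max_gap)) next
      left_max <- i == 1 || p[i] - p[i - 1] > max_gap
      right_max <- j == m || p[j + 1] - p[j] > max_gap
      if (left_max && right_max) {
        out[[length(out) + 1L]] <- c(start = p[i], end = p[j], n = j - i + 1)
      }
    }
  }
  if (!length(out)) return(data.frame(start = numeric(), end = numeric(),
                                      n = numeric()))
  as.data.frame(do.call(rbind, out))
}

# Exhaustive within-pair region oracle: per pair, candidate probes by
# effect size, clusters by window enumeration, outlier rule re-checked
# per member from the raw matrix.
wp_dmr_enum_oracle <- function(beta, sheet, manifest, delta_threshold = 0.2,
                               min_cpgs = 3, max_gap = 1000, sd_mult = 3) {
  res <- list()
  cm <- rowMeans(beta)
  cs <- apply(beta, 1, sd)
  for (pid in unique(sheet$pair_id)) {
    a <- sheet$sample_id[sheet$pair_id == pid & sheet$role == "affected"]
    u <- sheet$sample_id[sheet$pair_id == pid & sheet$role == "non_affected"]
    delta <- beta[, a] - beta[, u]
    for (ch in unique(manifest$chrom)) {
      sel <- manifest$probe_id[manifest$chrom == ch]
      sel <- sel[order(manifest$pos[match(sel, manifest$probe_id)])]
      pos <- manifest$pos[match(sel, manifest$probe_id)]
      cand <- abs(delta[sel]) > delta_threshold & !is.na(delta[sel])
      cl <- cluster_enum_oracle(pos, cand, min_cpgs, max_gap)
      for (r in seq_len(nrow(cl))) {
        members <- sel[cand & pos >= cl$start[r] & pos <= cl$end[r]]
        outlier <- abs(beta[members, a] - cm[members]) > sd_mult * cs[members] |
          abs(beta[members, u] - cm[members]) > sd_mult * cs[members]
        if (all(outlier)) {
          res[[length(res) + 1L]] <- data.frame(
            pair_id = pid, chrom = ch, start = cl$start[r], end = cl$end[r],
            n = cl$n[r], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res)) return(data.frame(pair_id = character(), chrom = character(),
                                      start = numeric(), end = numeric(),
                                      n = numeric()))
  out <- do.call(rbind, res)
  out[order(out$pair_id, out$chrom, out$start), , drop = FALSE]
}
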