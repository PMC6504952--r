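#' @importFrom stats pnorm pt qt pchisq var sd complete.cases rnorm rbinom
#'   rnbinom runif p.adjust fisher.test bartlett.test t.test cor.test
#'   lm.fit rgeom quantile
NULL

# ---- result container ------------------------------------------------------

new_test_result <- function(statistic, p_value, method, note = NULL) {
  stopifnot(method %in% c("exact", "normal_approx"))
  res <- list(statistic = statistic, p_value = p_value, method = method,
              note = note)
  class(res) <- "twinmeth_test"
  res
}

#' @export
print.twinmeth_test <- function(x, ...) {
  cat("statistic =", format(x$statistic), " p =", format(x$p_value),
      " [", x$method, "]\n", sep = "")
  if (!is.null(x$note)) cat("note: ", x$note, "\n", sep = "")
  invisible(x)
}

# ---- Wilcoxon signed-rank --------------------------------------------------

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' The workhorse test of the paired EWAS scans. Zero differences are dropped
#' before ranking (the classic Wilcoxon convention); ties in the absolute
#' differences receive midranks. The exact p-value is computed by dynamic
#' programming over the signed-rank distribution (valid with midranks, unlike
#' the no-ties closed form), the asymptotic one by the normal approximation
#' with tie-corrected variance and a 0.5 continuity correction.
#'
#' @param diffs numeric vector of paired differences; NAs removed.
#' @param mode `"auto"` (exact for at most 25 nonzero differences, normal
#'   otherwise), `"exact"`, or `"normal"`.
#' @return a `twinmeth_test` with the signed-rank statistic W (sum of ranks of
#'   positive differences), the two-sided p-value, and the method used. A
#'   vector with no nonzero differences yields p = 1 with a note.
#' @export
wilcoxon_signed_rank <- function(diffs, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(diffs) == 0L) stop("empty difference vector")
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) == 0L) stop("no non-missing differences")
  d <- diffs[diffs != 0]
  if (length(d) == 0L) {
    warning("all differences are zero; no signal to test")
    return(new_test_result(0, 1, "exact", note = "all_zero"))
  }
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (mode == "auto") mode <- if (n <= 25L) "exact" else "normal"
  if (mode == "exact") {
    p <- .wsr_exact_p(r, w)
    new_test_result(w, p, "exact")
  } else {
    p <- .wsr_normal_p(r, w)
    new_test_result(w, p, "normal_approx")
  }
}

# Exact two-sided p for the signed-rank statistic with midranks: convolve the
# distribution of 2*W over all 2^n sign assignments (doubled midranks are
# integers), then double the smaller tail.
.wsr_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)   # f[k+1] = #assignments with 2W = k
  f[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
    f <- f + shifted
  }
  f <- f / 2^length(r2)
  w2 <- as.integer(round(2 * w))
  lo <- sum(f[seq_len(w2 + 1L)])
  hi <- sum(f[seq.int(w2 + 1L, total + 1L)])
  min(1, 2 * min(lo, hi))
}

# Normal approximation with tie correction and continuity correction,
# matching the standard large-sample treatment.
.wsr_normal_p <- function(ranks, w) {
  n <- length(ranks)
  mu <- n * (n + 1) / 4
  ties <- table(ranks)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(1)
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sig2)
  min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
}

# Vectorised row-wise p-values for a delta matrix (probes x pairs). Rows with
# fewer than 2 usable values give NA. Used by the scan functions.
.wsr_p_by_row <- function(mat, mode = "auto") {
  apply(mat, 1L, function(d) {
    d <- d[!is.na(d)]
    if (length(d) < 2L) return(NA_real_)
    dd <- d[d != 0]
    if (length(dd) == 0L) return(1)
    r <- rank(abs(dd))
    w <- sum(r[dd > 0])
    m <- if (mode == "auto") (if (length(dd) <= 25L) "exact" else "normal") else mode
    if (m == "exact") .wsr_exact_p(r, w) else .wsr_normal_p(r, w)
  })
}

# ---- multiple testing ------------------------------------------------------

#' Benjamini-Hochberg adjustment preserving input order
#'
#' Thin validated wrapper around [stats::p.adjust()] with `method = "BH"`.
#' Missing values propagate as missing; the adjustment is computed over the
#' non-missing entries.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals)) stop("p-values must be numeric")
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

# ---- Fisher exact ----------------------------------------------------------

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conventional minimum-likelihood two-sided test: the p-value sums the
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one. The table is
#' \code{rbind(c(a, b), c(c, d))}.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return a `twinmeth_test`; the statistic is the hypergeometric probability
#'   of the observed table.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all margins are zero")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  ft <- fisher.test(tab, alternative = "two.sided")
  obs_p <- stats::dhyper(a, a + b, c + d, a + c)
  new_test_result(obs_p, ft$p.value, "exact")
}

# ---- Bartlett --------------------------------------------------------------

#' Bartlett's test of equal variances for two samples
#'
#' The k = 2 Bartlett statistic with the standard small-sample correction
#' factor, referred to a chi-square distribution with one degree of freedom.
#' This is the variance criterion of the differential-variability scan.
#'
#' @param x,y numeric vectors, each of length at least 2.
#' @return a `twinmeth_test` with the corrected Bartlett statistic.
#' @export
bartlett_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations")
  }
  if (var(x) == 0 && var(y) == 0) stop("both sample variances are zero")
  bt <- bartlett.test(list(x, y))
  new_test_result(unname(bt$statistic), bt$p.value, "normal_approx")
}

# ---- t tests ---------------------------------------------------------------

#' Two-sample t-test (paired or unpaired pooled-variance)
#'
#' The unpaired form uses the pooled-variance (equal-variance) statistic, the
#' form the differential-variability scan inherits from iEVORA; Welch's
#' unequal-variance form is available via `welch = TRUE`. The paired form is
#' the one-sample t-test on the differences. A zero-variance paired
#' difference vector is degenerate: p is 1 when the mean difference is also
#' zero, and missing (with a note) otherwise.
#'
#' @param x,y numeric vectors; equal lengths required when `paired`.
#' @param paired logical.
#' @param welch logical; unpaired only.
#' @return a `twinmeth_test`.
#' @export
t_two_sample <- function(x, y, paired = FALSE, welch = FALSE) {
  if (paired) {
    if (length(x) != length(y)) stop("paired test requires equal lengths")
    d <- x - y
    d <- d[!is.na(d)]
    if (length(d) < 2L) stop("need at least 2 complete pairs")
    if (sd(d) == 0) {
      if (mean(d) == 0) {
        return(new_test_result(0, 1, "exact", note = "zero_variance"))
      }
      return(new_test_result(NA_real_, NA_real_, "exact",
                             note = "zero_variance"))
    }
    tt <- t.test(d)
  } else {
    tt <- t.test(x, y, var.equal = !welch)
  }
  new_test_result(unname(tt$statistic), tt$p.value, "normal_approx")
}

# ---- power -----------------------------------------------------------------

#' Power of the two-sided paired t-test
#'
#' Power to detect a mean within-pair difference `delta` with `n_pairs` pairs
#' at two-sided level `alpha`, given standard deviation `sd` of the pair
#' differences. Computed from the noncentral t distribution with
#' `n_pairs - 1` degrees of freedom and noncentrality
#' `delta * sqrt(n_pairs) / sd`. The paired t-test is the closest parametric
#' equivalent of the Wilcoxon signed-rank scan and is the standard desk
#' calculation for sizing a paired EWAS.
#'
#' @param n_pairs number of twin pairs (>= 2).
#' @param delta mean within-pair beta-value difference to detect.
#' @param sd standard deviation of the pair differences (> 0).
#' @param alpha two-sided significance level in (0, 1).
#' @return the power, in \[0, 1\]; equals `alpha` when `delta = 0`.
#' @examples
#' paired_t_power(45, 0.05, 0.0266, 1e-7)
#' @export
paired_t_power <- function(n_pairs, delta, sd, alpha = 0.05) {
  if (sd <= 0) stop("sd must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_pairs < 2 || n_pairs != round(n_pairs)) {
    stop("n_pairs must be an integer >= 2")
  }
  df <- n_pairs - 1
  ncp <- delta * sqrt(n_pairs) / sd
  tcrit <- qt(1 - alpha / 2, df)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) + pt(-tcrit, df, ncp = ncp)
}

# ---- amplicon coverage arithmetic -----------------------------------------

#' Fraction of a repetitive element family interrogated by an amplicon assay
#'
#' For a repeat family amplified with generic primers, the fraction of genomic
#' copies sampled at a given read depth is simply reads / copies (each read
#' originates from one copy). Returned as a percentage; e.g. 2000 reads
#' against ~1,000,000 genomic Alu copies interrogates 0.2% of the family.
#'
#' @param reads minimum sequencing coverage (reads per sample).
#' @param genomic_copies copies of the element per genome.
#' @return percentage of copies interrogated.
#' @export
fraction_of_copies_interrogated <- function(reads, genomic_copies) {
  if (reads < 0 || genomic_copies <= 0) stop("invalid counts")
  100 * min(1, reads / genomic_copies)
}
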