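# Cohort-level DMR calling on paired WGBS counts.
#
# Per-CpG methylation fractions (strand-aggregated counts) are compared
# between co-twins with a paired t-test across pairs; significant sites are
# then clustered into regions by a pairwise-gap rule. Sex chromosomes are
# retained: X-linked regions are legitimate calls in a sex-matched
# twin design.

#' Filter WGBS sites on per-sample coverage
#'
#' Keeps sites where every sample reaches `min_cov` total reads, the standard
#' guard before site-level testing. Counts retained/removed are reported via
#' `message()`.
#'
#' @param counts a `wgbs_counts` object (see [read_wgbs_counts()]).
#' @param min_cov minimum total reads per sample (default 10).
#' @return filtered `wgbs_counts`.
#' @export
coverage_filter <- function(counts, min_cov = 10L) {
  keep <- rowSums(counts$total >= min_cov) == ncol(counts$total)
  message("coverage_filter: ", sum(keep), " of ", length(keep),
          " sites at coverage >= ", min_cov, " in all samples")
  new_wgbs_counts(counts$sites[keep, , drop = FALSE],
                  counts$meth[keep, , drop = FALSE],
                  counts$total[keep, , drop = FALSE])
}

#' Per-site paired t-tests on methylation fractions
#'
#' Methylation fraction = methylated / total reads per sample; per site, a
#' two-sided paired t-test across twin pairs on (affected - non-affected)
#' fractions. Sites whose pair differences have zero variance get a missing
#' p (logged); their mean difference is still reported.
#'
#' @param counts a `wgbs_counts` object (coverage-filtered).
#' @param sheet validated twin sheet covering the count samples.
#' @return data frame sorted by (chrom, pos): chrom, pos, mean_diff
#'   (affected minus non-affected), p.
#' @export
site_paired_tests <- function(counts, sheet) {
  sheet <- validate_twin_sheet(sheet)
  frac <- counts$meth / counts$total
  missing_samples <- setdiff(sheet$sample_id, colnames(frac))
  if (length(missing_samples)) {
    stop("sample absent from counts: ", missing_samples[1])
  }
  pairs <- unique(sheet$pair_id)
  if (length(pairs) < 2L) stop("need at least 2 pairs")
  aff <- vapply(pairs, function(p)
    sheet$sample_id[sheet$pair_id == p & sheet$role == "affected"], character(1))
  non <- vapply(pairs, function(p)
    sheet$sample_id[sheet$pair_id == p & sheet$role == "non_affected"], character(1))
  d <- frac[, aff, drop = FALSE] - frac[, non, drop = FALSE]
  mean_diff <- rowMeans(d)
  sdd <- apply(d, 1L, sd)
  n <- ncol(d)
  tstat <- mean_diff / (sdd / sqrt(n))
  p <- 2 * pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  degenerate <- sdd == 0
  p[degenerate] <- NA_real_
  if (any(degenerate)) {
    message(sum(degenerate), " site(s) with zero-variance differences: p set missing")
  }
  out <- data.frame(chrom = counts$sites$chrom, pos = counts$sites$pos,
                    mean_diff = mean_diff, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Cluster significant WGBS sites into regions
#'
#' Cohort-level region rule: a region is at least `min_cpgs` significant
#' CpGs — each with p < `p_threshold` (default 0.05) and
#' |mean difference| > `diff_threshold` (default 0.2) — with at most
#' `max_gap` bp (default 500) between neighbouring significant CpGs.
#' Mixed-direction regions are permitted; the `consistent` flag (all member
#' differences of one sign) lets a direction-consistency filter be applied
#' downstream.
#'
#' @param site_table output of [site_paired_tests()], sorted by (chrom, pos).
#' @param p_threshold site significance level.
#' @param diff_threshold minimum absolute mean methylation difference.
#' @param min_cpgs minimum significant CpGs per region.
#' @param max_gap maximum distance in bp between consecutive significant CpGs.
#' @return region call data frame: chrom, start_pos, end_pos, n_cpgs, probes
#'   (member positions, comma-joined as chrom:pos), pair_id = "cohort",
#'   mean_delta (mean of member mean differences), consistent.
#' @export
cluster_significant_sites <- function(site_table, p_threshold = 0.05,
                                      diff_threshold = 0.2, min_cpgs = 3L,
                                      max_gap = 500L) {
  ord <- order(site_table$chrom, site_table$pos)
  if (!identical(ord, seq_len(nrow(site_table)))) {
    stop("site table must be sorted by (chrom, pos)")
  }
  sig <- which(!is.na(site_table$p) & site_table$p < p_threshold &
                 abs(site_table$mean_diff) > diff_threshold)
  calls <- list()
  for (ch in unique(site_table$chrom[sig])) {
    si <- sig[site_table$chrom[sig] == ch]
    breaks <- which(diff(site_table$pos[si]) > max_gap)
    grp <- cumsum(c(1L, seq_along(si)[-1] %in% (breaks + 1L)))
    for (g in split(si, grp)) {
      if (length(g) < min_cpgs) next
      diffs <- site_table$mean_diff[g]
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch,
        start_pos = min(site_table$pos[g]),
        end_pos = max(site_table$pos[g]),
        n_cpgs = length(g),
        probes = paste(ch, site_table$pos[g], sep = ":", collapse = ","),
        pair_id = "cohort",
        mean_delta = mean(diffs),
        consistent = all(diffs > 0) || all(diffs < 0),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(calls) == 0L) {
    out <- empty_region_calls()
    out$aberrant_role <- NULL
    out$consistent <- logical()
    return(out)
  }
  out <- do.call(rbind, calls)
  out[order(out$chrom, out$start_pos), , drop = FALSE]
}
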