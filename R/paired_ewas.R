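# Pair-wise differential methylation scans.
#
# The unit of analysis is the within-pair difference: for each probe and twin
# pair, delta = beta(affected co-twin) - beta(non-affected co-twin). Genetic
# background and shared environment cancel in this difference, which is what
# makes the discordant-MZ-twin design informative.

#' Compute per-probe within-pair beta differences
#'
#' @param beta probes x samples matrix (unadjusted or composition-adjusted).
#' @param sheet validated twin sheet covering the samples.
#' @return probes x pairs matrix of deltas (affected minus non-affected);
#'   NA where either co-twin's value is missing.
#' @export
compute_pair_deltas <- function(beta, sheet) {
  sheet <- validate_twin_sheet(sheet)
  missing_samples <- setdiff(sheet$sample_id, colnames(beta))
  if (length(missing_samples)) {
    stop("sample absent from matrix: ", missing_samples[1])
  }
  pairs <- unique(sheet$pair_id)
  aff <- vapply(pairs, function(p)
    sheet$sample_id[sheet$pair_id == p & sheet$role == "affected"], character(1))
  non <- vapply(pairs, function(p)
    sheet$sample_id[sheet$pair_id == p & sheet$role == "non_affected"], character(1))
  deltas <- beta[, aff, drop = FALSE] - beta[, non, drop = FALSE]
  colnames(deltas) <- pairs
  deltas
}

#' Epigenome-wide scan for differentially methylated positions
#'
#' Per probe: mean within-pair delta, its t-based normal-theory 95% CI, a
#' two-sided Wilcoxon signed-rank p-value on the pair deltas, and
#' Benjamini-Hochberg FDR across all scanned probes in one batch. Probes
#' with fewer than 2 usable pairs are skipped (reported with NA statistics).
#' Significance flags: `suggestive` for p below `suggestive_alpha`
#' (default 5e-6), `genomewide` for FDR below `fdr_threshold` (default 0.05).
#'
#' @param deltas probes x pairs delta matrix from [compute_pair_deltas()].
#' @param manifest optional manifest; when given, chrom/pos are attached.
#' @param suggestive_alpha suggestive significance level on the raw p.
#' @param fdr_threshold genome-wide significance level on the FDR.
#' @param mode Wilcoxon p-value mode passed through (`"auto"` default).
#' @return data frame, one row per probe in input order: probe, (chrom, pos,)
#'   n_pairs_used, mean_delta, ci_low, ci_high, p, fdr, suggestive, genomewide.
#' @export
dmp_scan <- function(deltas, manifest = NULL, suggestive_alpha = 5e-6,
                     fdr_threshold = 0.05, mode = "auto") {
  if (is.null(dim(deltas)) || nrow(deltas) == 0L || ncol(deltas) == 0L) {
    stop("empty delta matrix")
  }
  n_used <- rowSums(!is.na(deltas))
  mean_delta <- rowMeans(deltas, na.rm = TRUE)
  sds <- apply(deltas, 1L, sd, na.rm = TRUE)
  se <- sds / sqrt(n_used)
  tq <- qt(0.975, df = pmax(n_used - 1L, 1L))
  p <- .wsr_p_by_row(deltas, mode = mode)
  skipped <- n_used < 2L
  if (any(skipped)) {
    message(sum(skipped), " probe(s) skipped: fewer than 2 usable pairs")
    mean_delta[skipped] <- NA_real_
    se[skipped] <- NA_real_
  }
  out <- data.frame(
    probe = rownames(deltas),
    n_pairs_used = n_used,
    mean_delta = mean_delta,
    ci_low = mean_delta - tq * se,
    ci_high = mean_delta + tq * se,
    p = p,
    fdr = bh_adjust(p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$suggestive <- !is.na(out$p) & out$p < suggestive_alpha
  out$genomewide <- !is.na(out$fdr) & out$fdr < fdr_threshold
  if (!is.null(manifest)) {
    manifest <- validate_manifest(manifest)
    idx <- match(out$probe, manifest$probe_id)
    out <- cbind(out[1L], chrom = manifest$chrom[idx], pos = manifest$pos[idx],
                 out[-1L])
  }
  out
}

#' Treatment-subset effect scan
#'
#' Re-runs the pair-wise scan within a subset of pairs (e.g. the pairs whose
#' affected co-twin is on interferon-beta at blood draw) and reports probes
#' passing both an effect-size and a significance cutoff, the filter used for
#' treatment-associated DMPs: |mean delta| > `effect_threshold` (default
#' 0.05) and Wilcoxon p < `p_threshold` (default 0.001).
#'
#' @param deltas probes x pairs delta matrix.
#' @param pair_subset character vector of pair ids to scan.
#' @param effect_threshold minimum absolute mean delta.
#' @param p_threshold maximum Wilcoxon p.
#' @return data frame of passing probes: probe, n_pairs_used, mean_delta,
#'   p, direction ("hyper" / "hypo" in the affected co-twin).
#' @export
subset_effect_scan <- function(deltas, pair_subset, effect_threshold = 0.05,
                               p_threshold = 0.001) {
  if (length(pair_subset) == 0L) stop("empty pair subset")
  unknown <- setdiff(pair_subset, colnames(deltas))
  if (length(unknown)) stop("unknown pair id: ", unknown[1])
  if (length(pair_subset) < 5L) {
    warning("subset has fewer than 5 pairs; exact Wilcoxon p-values used")
  }
  sub <- deltas[, pair_subset, drop = FALSE]
  n_used <- rowSums(!is.na(sub))
  mean_delta <- rowMeans(sub, na.rm = TRUE)
  p <- .wsr_p_by_row(sub, mode = "auto")
  hit <- !is.na(p) & !is.na(mean_delta) &
    abs(mean_delta) > effect_threshold & p < p_threshold
  data.frame(
    probe = rownames(sub)[hit],
    n_pairs_used = n_used[hit],
    mean_delta = mean_delta[hit],
    p = p[hit],
    direction = ifelse(mean_delta[hit] > 0, "hyper", "hypo"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Array-wide hypermethylation summary
#'
#' Quantifies the overall tilt of the scan: the fraction of probes whose mean
#' within-pair delta is positive (hypermethylated in the affected co-twins),
#' the per-pair count of positive-delta probes, and the Pearson correlation
#' of those counts against a focal probe's per-pair deltas (with two-sided
#' p), used to relate global tilt to a single treatment-marker CpG.
#'
#' @param deltas probes x pairs delta matrix.
#' @param focal_probe probe id present in `deltas`.
#' @return list: `fraction_positive`, `per_pair_positive_counts` (named),
#'   `pearson_r_vs_focal`, `p`.
#' @export
hypermethylation_summary <- function(deltas, focal_probe) {
  if (!focal_probe %in% rownames(deltas)) {
    stop("focal probe not in delta matrix: ", focal_probe)
  }
  means <- rowMeans(deltas, na.rm = TRUE)
  means <- means[!is.nan(means)]
  if (length(means) == 0L) stop("all deltas missing")
  counts <- colSums(deltas > 0, na.rm = TRUE)
  focal <- deltas[focal_probe, ]
  ct <- cor.test(counts, focal, method = "pearson")
  list(
    fraction_positive = mean(means > 0),
    per_pair_positive_counts = counts,
    pearson_r_vs_focal = unname(ct$estimate),
    p = ct$p.value
  )
}
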