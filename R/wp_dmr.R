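# Within-pair differentially methylated region (WP-DMR) calling.
#
# A WP-DMR is a contiguous run of CpGs with a large within-pair methylation
# difference private to a single twin pair. Three rules define a call:
#   1. effect:  >= min_cpgs member CpGs, each |delta| > delta_threshold;
#   2. gap:     consecutive member CpGs at most max_gap bp apart;
#   3. outlier: at each member CpG, at least one co-twin lies more than
#      sd_mult cohort standard deviations from the cohort mean, excluding
#      regions that are simply variable across everyone.
# The SD band is computed per probe over all cohort samples (including the
# tested pair; sample SD, denominator n - 1), which is conservative and
# deterministic.

#' Call within-pair differentially methylated regions
#'
#' Per pair and chromosome, candidate CpGs (|delta| above `delta_threshold`
#' after composition adjustment) are clustered greedily left to right,
#' breaking whenever the gap between consecutive candidates exceeds
#' `max_gap`; clusters with at least `min_cpgs` candidates are kept, and a
#' kept cluster is reported only if every member CpG passes the cohort
#' outlier rule (some co-twin beyond `sd_mult` SDs from the cohort mean).
#' The aberrant co-twin is assigned by majority vote over member CpGs
#' (`"ambiguous"` on a tie). Probes named in `excluded_probes` (e.g. known
#' treatment-associated CpGs) are removed before scanning.
#'
#' @param adjusted probes x samples composition-adjusted beta matrix.
#' @param sheet validated twin sheet.
#' @param manifest manifest with positions for all scanned probes.
#' @param excluded_probes character vector of probe ids to drop first.
#' @param delta_threshold minimum |delta| per member CpG (default 0.2).
#' @param min_cpgs minimum member CpGs per region (default 3).
#' @param max_gap maximum distance in bp between consecutive member CpGs
#'   (default 1000).
#' @param sd_mult outlier band width in cohort SDs (default 3).
#' @return region call data frame: chrom, start_pos, end_pos (1-based
#'   inclusive), n_cpgs, probes (comma-joined), pair_id, mean_delta (signed
#'   mean over members), mean_abs_delta, aberrant_role.
#' @export
call_wp_dmrs <- function(adjusted, sheet, manifest,
                         excluded_probes = character(),
                         delta_threshold = 0.2, min_cpgs = 3L,
                         max_gap = 1000L, sd_mult = 3) {
  sheet <- validate_twin_sheet(sheet)
  manifest <- validate_manifest(manifest)
  keep <- setdiff(rownames(adjusted), excluded_probes)
  adjusted <- adjusted[keep, , drop = FALSE]
  idx <- match(rownames(adjusted), manifest$probe_id)
  if (anyNA(idx)) {
    stop("manifest lacks position for probe: ",
         rownames(adjusted)[which(is.na(idx))[1]])
  }
  chrom <- manifest$chrom[idx]
  pos <- manifest$pos[idx]
  cohort_mean <- rowMeans(adjusted, na.rm = TRUE)
  cohort_sd <- apply(adjusted, 1L, sd, na.rm = TRUE)
  deltas <- compute_pair_deltas(adjusted, sheet)

  calls <- list()
  for (pid in colnames(deltas)) {
    aff <- sheet$sample_id[sheet$pair_id == pid & sheet$role == "affected"]
    non <- sheet$sample_id[sheet$pair_id == pid & sheet$role == "non_affected"]
    cand <- which(!is.na(deltas[, pid]) & abs(deltas[, pid]) > delta_threshold)
    if (length(cand) < min_cpgs) next
    for (ch in unique(chrom[cand])) {
      ci <- cand[chrom[cand] == ch]
      ci <- ci[order(pos[ci])]
      breaks <- which(diff(pos[ci]) > max_gap)
      grp <- cumsum(c(1L, seq_along(ci)[-1] %in% (breaks + 1L)))
      for (g in split(ci, grp)) {
        if (length(g) < min_cpgs) next
        lo <- cohort_mean[g] - sd_mult * cohort_sd[g]
        hi <- cohort_mean[g] + sd_mult * cohort_sd[g]
        aff_out <- adjusted[g, aff] < lo | adjusted[g, aff] > hi
        non_out <- adjusted[g, non] < lo | adjusted[g, non] > hi
        if (!all(aff_out | non_out)) next
        votes_aff <- sum(aff_out & !non_out)
        votes_non <- sum(non_out & !aff_out)
        role <- if (votes_aff > votes_non) "affected"
                else if (votes_non > votes_aff) "non_affected"
                else "ambiguous"
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = ch,
          start_pos = min(pos[g]),
          end_pos = max(pos[g]),
          n_cpgs = length(g),
          probes = paste(rownames(adjusted)[g], collapse = ","),
          pair_id = pid,
          mean_delta = mean(deltas[g, pid]),
          mean_abs_delta = mean(abs(deltas[g, pid])),
          aberrant_role = role,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(calls) == 0L) {
    out <- empty_region_calls()
    out$mean_abs_delta <- numeric()
    return(out)
  }
  out <- do.call(rbind, calls)
  out[order(out$pair_id, out$chrom, out$start_pos), , drop = FALSE]
}

#' Post-hoc verifier for within-pair region calls
#'
#' Independently re-checks every reported region against the three defining
#' rules (effect size per member, pairwise gap, cohort-outlier band) and
#' returns the ids of violating regions (empty when all calls are valid).
#' Intended as a guard in pipelines and tests; it shares no code with the
#' caller's clustering logic.
#'
#' @inheritParams call_wp_dmrs
#' @param calls output of [call_wp_dmrs()].
#' @return integer vector of offending row indices (empty if none).
#' @export
verify_wp_dmrs <- function(calls, adjusted, sheet, manifest,
                           delta_threshold = 0.2, min_cpgs = 3L,
                           max_gap = 1000L, sd_mult = 3) {
  sheet <- validate_twin_sheet(sheet)
  manifest <- validate_manifest(manifest)
  bad <- integer()
  for (i in seq_len(nrow(calls))) {
    probes <- strsplit(calls$probes[i], ",", fixed = TRUE)[[1]]
    pid <- calls$pair_id[i]
    aff <- sheet$sample_id[sheet$pair_id == pid & sheet$role == "affected"]
    non <- sheet$sample_id[sheet$pair_id == pid & sheet$role == "non_affected"]
    d <- adjusted[probes, aff] - adjusted[probes, non]
    ppos <- manifest$pos[match(probes, manifest$probe_id)]
    m <- rowMeans(adjusted[probes, , drop = FALSE], na.rm = TRUE)
    s <- apply(adjusted[probes, , drop = FALSE], 1L, sd, na.rm = TRUE)
    outlier <- abs(adjusted[probes, aff] - m) > sd_mult * s |
               abs(adjusted[probes, non] - m) > sd_mult * s
    ok <- length(probes) >= min_cpgs &&
      all(abs(d) > delta_threshold) &&
      all(diff(sort(ppos)) <= max_gap) &&
      all(outlier)
    if (!ok) bad <- c(bad, i)
  }
  bad
}

#' Group overlapping within-pair regions across pairs
#'
#' Regions discovered in different pairs that overlap by at least 1 bp on the
#' same chromosome are grouped (transitively), flagging recurrently aberrant
#' loci; typically run on calls produced at a relaxed effect threshold.
#'
#' @param calls region call data frame (any threshold).
#' @return the input with a `group` integer column plus per-group annotation
#'   columns `group_size` (number of distinct pairs in the group) and
#'   `role_concordant` (all members share one aberrant role).
#' @export
recurrent_wp_dmrs <- function(calls) {
  if (nrow(calls) == 0L) {
    calls$group <- integer()
    calls$group_size <- integer()
    calls$role_concordant <- logical()
    return(calls)
  }
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start_pos, calls$end_pos))
  merged <- GenomicRanges::reduce(gr)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  group <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  calls$group <- group
  calls$group_size <- ave(calls$pair_id, group,
                          FUN = function(p) length(unique(p)))
  calls$group_size <- as.integer(calls$group_size)
  calls$role_concordant <- as.logical(ave(calls$aberrant_role, group,
                                          FUN = function(r) length(unique(r)) == 1L))
  calls[order(calls$group, calls$pair_id), , drop = FALSE]
}
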