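# Differential variability scan (iEVORA-style).
#
# Some disease signatures show up as a change in methylation variance rather
# than mean. The scan follows the two-criterion iEVORA recipe: a Bartlett
# variance test per probe with FDR correction, combined with a raw unpaired
# t-test filter on the means, ranked by the t-test p-value. Co-twins are
# treated as independent group members here because that is how the source
# algorithm is defined; a paired t variant is available for sensitivity
# analysis.

#' Pre-filter probes for the differential-variability scan
#'
#' Removes probes with a SNP within five bases of the interrogated CpG,
#' probes on the sex chromosomes, and probes with any missing value; the
#' Bartlett test is sensitive to all three. Counts removed per reason are
#' reported via `message()`.
#'
#' @param beta probes x samples matrix.
#' @param manifest validated manifest with `snp_within_5bp` and `sex_chrom`.
#' @return filtered beta matrix.
#' @export
dvp_prefilter <- function(beta, manifest) {
  manifest <- validate_manifest(manifest)
  idx <- match(rownames(beta), manifest$probe_id)
  if (anyNA(idx)) {
    stop("probe absent from manifest: ", rownames(beta)[which(is.na(idx))[1]])
  }
  snp <- manifest$snp_within_5bp[idx]
  sex <- manifest$sex_chrom[idx]
  has_na <- rowSums(is.na(beta)) > 0L
  message("dvp_prefilter: removed ", sum(snp), " SNP-proximal, ",
          sum(sex & !snp), " sex-chromosome, ",
          sum(has_na & !snp & !sex), " incomplete probe(s)")
  beta[!(snp | sex | has_na), , drop = FALSE]
}

#' iEVORA-style differential-variability scan
#'
#' Per probe: Bartlett p for unequal variance between the two groups, BH FDR
#' across probes on the Bartlett p, and an unpaired pooled-variance t-test p
#' on the means. A probe is flagged as differentially variable (DVP) when
#' `bartlett_fdr < bartlett_fdr_threshold` (default 0.001) and
#' `t_p < t_p_threshold` (default 0.05). Flagged probes are ranked by the
#' t-test p (the iEVORA ranking). `hypervariable_role` names the group with
#' the larger variance.
#'
#' @param beta filtered probes x samples matrix (see [dvp_prefilter()]).
#' @param groups named character/factor of group labels per sample (two
#'   levels), names matching `colnames(beta)`; for a twin cohort pass the
#'   sheet's role per sample.
#' @param bartlett_fdr_threshold FDR cutoff on the Bartlett test.
#' @param t_p_threshold raw p cutoff on the t-test.
#' @param paired use a paired t-test instead of the unpaired pooled form
#'   (sensitivity analysis; requires samples ordered consistently by pair).
#' @return data frame sorted with flagged probes first by `t_p`: probe,
#'   bartlett_p, bartlett_fdr, t_p, var_<group1>, var_<group2>,
#'   hypervariable_role, dvp.
#' @export
ievora_scan <- function(beta, groups, bartlett_fdr_threshold = 0.001,
                        t_p_threshold = 0.05, paired = FALSE) {
  groups <- groups[colnames(beta)]
  lv <- unique(as.character(groups))
  if (length(lv) != 2L) stop("exactly two groups required")
  g1 <- which(groups == lv[1]); g2 <- which(groups == lv[2])
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("each group needs at least 2 samples")
  }
  x1 <- beta[, g1, drop = FALSE]
  x2 <- beta[, g2, drop = FALSE]
  v1 <- apply(x1, 1L, var)
  v2 <- apply(x2, 1L, var)
  bart_p <- vapply(seq_len(nrow(beta)), function(i) {
    if (v1[i] == 0 && v2[i] == 0) return(NA_real_)
    bartlett_two_sample(x1[i, ], x2[i, ])$p_value
  }, numeric(1))
  t_p <- vapply(seq_len(nrow(beta)), function(i) {
    res <- if (paired) t_two_sample(x1[i, ], x2[i, ], paired = TRUE)
           else t_two_sample(x1[i, ], x2[i, ])
    res$p_value
  }, numeric(1))
  out <- data.frame(
    probe = rownames(beta),
    bartlett_p = bart_p,
    bartlett_fdr = bh_adjust(bart_p),
    t_p = t_p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[[paste0("var_", lv[1])]] <- v1
  out[[paste0("var_", lv[2])]] <- v2
  out$hypervariable_role <- ifelse(v1 > v2, lv[1], lv[2])
  out$dvp <- !is.na(out$bartlett_fdr) & !is.na(out$t_p) &
    out$bartlett_fdr < bartlett_fdr_threshold & out$t_p < t_p_threshold
  out[order(!out$dvp, out$t_p), , drop = FALSE]
}
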