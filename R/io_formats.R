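#' @importFrom utils read.delim write.table head
NULL

# ---- manifest --------------------------------------------------------------

#' Validate a probe manifest
#'
#' A manifest is a data frame with columns `probe_id`, `chrom`, `pos`
#' (1-based), `sex_chrom` and `snp_within_5bp` (logical flags). Internal
#' coordinates are 1-based throughout; only BED export converts.
#'
#' @param manifest data frame.
#' @return the validated manifest (flags coerced to logical), invisibly usable.
#' @export
validate_manifest <- function(manifest) {
  need <- c("probe_id", "chrom", "pos", "sex_chrom", "snp_within_5bp")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$probe_id)) {
    stop("duplicate probe ids in manifest: ",
         manifest$probe_id[duplicated(manifest$probe_id)][1])
  }
  if (any(is.na(manifest$pos)) || any(manifest$pos < 1)) {
    stop("manifest positions must be 1-based integers >= 1")
  }
  if (any(!nzchar(as.character(manifest$chrom)))) stop("empty chromosome name")
  manifest$sex_chrom <- as.logical(manifest$sex_chrom)
  manifest$snp_within_5bp <- as.logical(manifest$snp_within_5bp)
  manifest
}

#' Read a probe manifest TSV
#' @param path TSV with columns probe_id, chrom, pos, sex_chrom, snp_within_5bp.
#' @return validated manifest data frame.
#' @export
read_manifest <- function(path) {
  validate_manifest(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_manifest
#' @param manifest manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  write.table(validate_manifest(manifest), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- beta matrix -----------------------------------------------------------

#' Read a beta-value matrix
#'
#' TSV with a header row of sample ids and the probe id in the first column.
#' Values must be in \[0, 1\] or NA; every probe must appear in the manifest.
#'
#' @param path file path.
#' @param manifest validated manifest (probes are checked against it).
#' @return numeric matrix, probes in rows (rownames), samples in columns,
#'   input row order preserved.
#' @export
read_beta_matrix <- function(path, manifest) {
  manifest <- validate_manifest(manifest)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("beta matrix needs a probe column and >= 1 sample")
  probes <- as.character(df[[1L]])
  if (anyDuplicated(probes)) {
    stop("duplicate probe in beta matrix: ", probes[duplicated(probes)][1])
  }
  unknown <- setdiff(probes, manifest$probe_id)
  if (length(unknown)) {
    stop("probe absent from manifest: ", unknown[1])
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  for (j in seq_len(ncol(mat))) {
    col <- suppressWarnings(as.numeric(mat[, j]))
    bad <- which(is.na(col) & !(mat[, j] %in% c("NA", NA, "")))
    if (length(bad)) {
      stop("non-numeric value at probe ", probes[bad[1]],
           ", sample ", colnames(mat)[j])
    }
    mat[, j] <- col
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- probes
  validate_beta_matrix(mat)
}

#' @rdname read_beta_matrix
#' @param beta numeric probes x samples matrix.
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) stop("beta must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta matrix needs probe rownames and sample colnames")
  }
  out <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(out)) {
    stop("beta value outside [0, 1] at probe ", rownames(beta)[out[1, 1]],
         ", sample ", colnames(beta)[out[1, 2]])
  }
  beta
}

#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta),
                   format(beta, digits = 6, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- twin sample sheet -----------------------------------------------------

#' Read and validate a twin sample sheet
#'
#' Columns: `sample_id`, `pair_id`, `role` (affected / non_affected), and
#' logical covariates `ifn_current` (interferon-beta at blood draw),
#' `gc_recent_3to12m` (glucocorticoids 3-12 months before draw), `smoking`.
#' Every pair must contribute exactly one affected and one non-affected
#' sample.
#'
#' @param path TSV file.
#' @return validated data frame.
#' @export
read_twin_sheet <- function(path) {
  validate_twin_sheet(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_twin_sheet
#' @param sheet data frame.
#' @export
validate_twin_sheet <- function(sheet) {
  need <- c("sample_id", "pair_id", "role")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("twin sheet lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicated sample_id: ", sheet$sample_id[duplicated(sheet$sample_id)][1])
  }
  bad_role <- setdiff(unique(sheet$role), c("affected", "non_affected"))
  if (length(bad_role)) stop("unknown role: ", bad_role[1])
  for (pid in unique(sheet$pair_id)) {
    roles <- sort(sheet$role[sheet$pair_id == pid])
    if (!identical(roles, c("affected", "non_affected"))) {
      stop("pair ", pid, " must have exactly one affected and one ",
           "non_affected sample")
    }
  }
  for (cov in intersect(c("ifn_current", "gc_recent_3to12m", "smoking"),
                        names(sheet))) {
    sheet[[cov]] <- as.logical(sheet[[cov]])
  }
  sheet
}

#' @rdname read_twin_sheet
#' @export
write_twin_sheet <- function(sheet, path) {
  write.table(validate_twin_sheet(sheet), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Restrict a sheet to samples present in a matrix, preserving the pairing
# invariant (errors if a co-twin is lost).
sheet_for_samples <- function(sheet, sample_ids) {
  sub <- sheet[sheet$sample_id %in% sample_ids, , drop = FALSE]
  validate_twin_sheet(sub)
}

# ---- region calls ----------------------------------------------------------

# A region call set is a data frame with columns chrom, start_pos, end_pos
# (1-based inclusive outermost CpG coordinates), n_cpgs, probes (comma-joined
# member ids), pair_id ("cohort" for cohort-level calls), mean_delta, and
# optional aberrant_role / consistent columns.

empty_region_calls <- function() {
  data.frame(chrom = character(), start_pos = integer(), end_pos = integer(),
             n_cpgs = integer(), probes = character(), pair_id = character(),
             mean_delta = numeric(), aberrant_role = character(),
             stringsAsFactors = FALSE)
}

#' Write region calls as BED
#'
#' Converts the 1-based inclusive CpG extent to BED 0-based half-open
#' coordinates: start = leftmost CpG position - 1, end = rightmost CpG
#' position. The name field carries the provenance (pair id, or "cohort"),
#' the score field the mean methylation difference times 1000, rounded.
#' Output is sorted by (chrom, start); an empty call set yields a file with
#' only the header comment.
#'
#' @param regions region call data frame (see [call_wp_dmrs()]).
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  header <- "# chrom\tstart\tend\tname\tscore"
  if (nrow(regions) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  start0 <- regions$start_pos - 1L
  end0 <- regions$end_pos
  if (any(end0 <= start0)) stop("region with end <= start after conversion")
  bed <- data.frame(chrom = regions$chrom, start = start0, end = end0,
                    name = regions$pair_id,
                    score = round(regions$mean_delta * 1000),
                    stringsAsFactors = FALSE)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a region call table as TSV
#' @param regions region call data frame.
#' @param path output path.
#' @export
write_regions_tsv <- function(regions, path) {
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- WGBS count tables -----------------------------------------------------

#' Read a per-CpG bisulfite count table
#'
#' TSV with columns `chrom`, `pos`, then a `<sample>.meth` / `<sample>.total`
#' column pair per sample (strand-aggregated counts).
#'
#' @param path file path.
#' @return a `wgbs_counts` object: list with `sites` (chrom, pos data frame)
#'   and integer matrices `meth` and `total` (sites x samples).
#' @export
read_wgbs_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meth_cols <- grep("\\.meth$", names(df), value = TRUE)
  samples <- sub("\\.meth$", "", meth_cols)
  total_cols <- paste0(samples, ".total")
  if (!all(total_cols %in% names(df))) stop("missing .total column(s)")
  meth <- as.matrix(df[meth_cols]); colnames(meth) <- samples
  total <- as.matrix(df[total_cols]); colnames(total) <- samples
  new_wgbs_counts(df[c("chrom", "pos")], meth, total)
}

new_wgbs_counts <- function(sites, meth, total) {
  if (any(total <= 0)) stop("total read counts must be positive")
  if (any(meth < 0) || any(meth > total)) {
    stop("methylated counts must lie in [0, total]")
  }
  obj <- list(sites = sites, meth = meth, total = total)
  class(obj) <- "wgbs_counts"
  obj
}

#' @rdname read_wgbs_counts
#' @param counts a `wgbs_counts` object.
#' @export
write_wgbs_counts <- function(counts, path) {
  samples <- colnames(counts$meth)
  out <- counts$sites
  for (s in samples) {
    out[[paste0(s, ".meth")]] <- counts$meth[, s]
    out[[paste0(s, ".total")]] <- counts$total[, s]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- configuration ---------------------------------------------------------

#' Default analysis configuration
#'
#' All pipeline thresholds in one list, each at its standard default:
#' suggestive and genome-wide DMP thresholds, treatment-subset effect and p
#' cutoffs, within-pair DMR rules, differential-variability cutoffs, WGBS
#' region rules, and the power-calculation settings. The list round-trips
#' through YAML via [write_config()] / [read_config()].
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    dmp = list(suggestive_alpha = 5e-6, fdr_threshold = 0.05),
    subset_scan = list(effect_threshold = 0.05, p_threshold = 0.001),
    wp_dmr = list(delta_threshold = 0.2, relaxed_delta = 0.15,
                  min_cpgs = 3L, max_gap = 1000L, sd_mult = 3),
    dvp = list(bartlett_fdr_threshold = 0.001, t_p_threshold = 0.05),
    wgbs = list(min_cov = 10L, p_threshold = 0.05, diff_threshold = 0.2,
                relaxed_diff = 0.15, min_cpgs = 3L, max_gap = 500L),
    power = list(n_pairs = 45L, delta = 0.05, sd = 0.0266, alpha = 1e-7)
  )
}

#' @rdname default_config
#' @param config configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}
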