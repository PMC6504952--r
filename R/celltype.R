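# Reference-based cell-type deconvolution and composition adjustment.
#
# PBMC methylomes are mixtures of cell-type methylomes weighted by cell
# proportions; between-twin composition differences confound a paired EWAS.
# Proportions are estimated per sample by constrained projection of the
# observed beta profile onto cell-type reference profiles, and beta values
# are then adjusted by regressing each probe on the proportions and keeping
# residual + probe mean, so adjusted values stay on an interpretable scale.

#' Validate a cell-type reference profile
#'
#' @param ref numeric matrix, reference probes x cell types, mean beta in
#'   \[0, 1\], with probe rownames and cell-type colnames.
#' @return the validated matrix.
#' @export
validate_reference <- function(ref) {
  if (!is.matrix(ref) || !is.numeric(ref)) stop("reference must be numeric matrix")
  if (ncol(ref) < 2L) stop("reference needs at least 2 cell types")
  if (is.null(rownames(ref)) || is.null(colnames(ref))) {
    stop("reference needs probe rownames and cell-type colnames")
  }
  if (any(is.na(ref)) || any(ref < 0 | ref > 1)) {
    stop("reference values must be in [0, 1] with no missing entries")
  }
  ref
}

#' Read / write a reference profile TSV (probes in rows, cell types in columns)
#' @param path file path.
#' @export
read_reference <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1L]])
  validate_reference(mat)
}

#' @rdname read_reference
#' @param ref reference matrix.
#' @export
write_reference <- function(ref, path) {
  df <- data.frame(probe_id = rownames(ref), ref, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate cell-type proportions by constrained projection
#'
#' Houseman-style reference-based deconvolution: for each sample, the beta
#' values at the reference probes are projected onto the cell-type reference
#' profiles by least squares under non-negativity, and the weights are then
#' normalised to sum to one. The non-negative fit uses the Lawson-Hanson
#' algorithm ([pracma::lsqnonneg()]).
#'
#' Reference probes with a missing beta in any sample are dropped (with a
#' warning); at least as many probes as cell types must remain and the
#' reference must have full column rank.
#'
#' @param beta probes x samples beta matrix (must cover the reference probes).
#' @param ref reference profile matrix, probes x cell types.
#' @return samples x cell types proportion matrix; rows sum to 1.
#' @export
estimate_proportions <- function(beta, ref) {
  ref <- validate_reference(ref)
  common <- intersect(rownames(ref), rownames(beta))
  if (length(common) < ncol(ref)) {
    stop("fewer usable reference probes than cell types")
  }
  b <- beta[common, , drop = FALSE]
  keep <- rowSums(is.na(b)) == 0L
  if (!all(keep)) {
    warning(sum(!keep), " reference probe(s) dropped for missing values")
    b <- b[keep, , drop = FALSE]
    common <- common[keep]
  }
  A <- ref[common, , drop = FALSE]
  if (nrow(A) < ncol(A)) stop("fewer usable reference probes than cell types")
  if (qr(A)$rank < ncol(A)) stop("reference matrix is rank-deficient")
  props <- t(vapply(seq_len(ncol(b)), function(j) {
    w <- pracma::lsqnonneg(A, b[, j])$x
    s <- sum(w)
    if (s <= 0) stop("degenerate fit for sample ", colnames(b)[j])
    w / s
  }, numeric(ncol(A))))
  dimnames(props) <- list(colnames(b), colnames(ref))
  props
}

#' Adjust beta values for cell-type composition
#'
#' Per probe, ordinary least squares of beta on the proportion covariates
#' across samples; the adjusted value is the residual plus the unadjusted
#' probe mean, which keeps adjusted values on the beta scale (the per-probe
#' mean is preserved exactly). One cell-type column is dropped to break the
#' sum-to-one collinearity, and constant covariate columns are dropped, so a
#' cohort with identical composition everywhere is returned unchanged.
#' Adjusted values may fall slightly outside \[0, 1\]; they are deliberately
#' not clipped, so the mean-preservation property holds for inference.
#'
#' @param beta probes x samples beta matrix (NA allowed; probes with missing
#'   values are fitted on complete cases, missing cells stay missing).
#' @param props samples x cell types proportion matrix from
#'   [estimate_proportions()].
#' @param extra_covariates optional numeric matrix/data frame of additional
#'   per-sample covariates (e.g. smoking) appended to the design.
#' @return adjusted matrix, same dimensions and dimnames as `beta`.
#' @export
adjust_for_composition <- function(beta, props, extra_covariates = NULL) {
  if (!setequal(colnames(beta), rownames(props))) {
    stop("sample sets of beta matrix and proportion matrix differ")
  }
  X <- props[colnames(beta), -ncol(props), drop = FALSE]
  if (!is.null(extra_covariates)) {
    ec <- as.matrix(extra_covariates)
    if (nrow(ec) != ncol(beta)) stop("covariate rows must match samples")
    X <- cbind(X, ec)
  }
  keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0L) return(beta)
  if (ncol(beta) < ncol(X) + 2L) {
    stop("need more samples than covariates + 1")
  }
  design <- cbind(`(Intercept)` = 1, X)
  adjusted <- beta
  complete_rows <- rowSums(is.na(beta)) == 0L
  if (any(complete_rows)) {
    B <- t(beta[complete_rows, , drop = FALSE])
    fit <- lm.fit(design, B)
    res <- t(as.matrix(fit$residuals))
    adjusted[complete_rows, ] <- res + rowMeans(beta[complete_rows, , drop = FALSE])
  }
  for (i in which(!complete_rows)) {
    y <- beta[i, ]
    ok <- !is.na(y)
    if (sum(ok) < ncol(design) + 1L) next   # too few samples: left unadjusted
    f <- lm.fit(design[ok, , drop = FALSE], y[ok])
    adjusted[i, ok] <- f$residuals + mean(y[ok])
  }
  adjusted
}

#' Mean within-pair Pearson correlation across probes
#'
#' Quality metric for the composition adjustment: correlating co-twins across
#' probes before and after adjustment shows whether removing composition
#' signal makes co-twin methylomes more similar.
#'
#' @param beta probes x samples matrix.
#' @param sheet validated twin sheet.
#' @return named numeric vector of per-pair correlations.
#' @export
within_pair_correlations <- function(beta, sheet) {
  sheet <- validate_twin_sheet(sheet)
  pairs <- unique(sheet$pair_id)
  out <- vapply(pairs, function(pid) {
    a <- sheet$sample_id[sheet$pair_id == pid & sheet$role == "affected"]
    u <- sheet$sample_id[sheet$pair_id == pid & sheet$role == "non_affected"]
    stats::cor(beta[, a], beta[, u], use = "complete.obs")
  }, numeric(1))
  names(out) <- pairs
  out
}
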