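# Small in-code fixtures shared across test files.

# A minimal twin sheet of n pairs.
make_sheet <- function(n_pairs, prefix = "p") {
  pid <- paste0(prefix, seq_len(n_pairs))
  data.frame(
    sample_id = as.vector(rbind(paste0(pid, "_A"), paste0(pid, "_U"))),
    pair_id = rep(pid, each = 2),
    role = rep(c("affected", "non_affected"), n_pairs),
    stringsAsFactors = FALSE
  )
}

# Flat-background beta matrix for region-calling fixtures: tight cohort
# around `center` so the SD-outlier band is narrow and an injected aberration
# clears it.
make_flat_beta <- function(probes, sheet, center = 0.4, noise = 0.005,
                           seed = 1) {
  set.seed(seed)
  m <- matrix(center + rnorm(length(probes) * nrow(sheet), 0, noise),
              length(probes), nrow(sheet),
              dimnames = list(probes, sheet$sample_id))
  m
}

make_manifest <- function(probes, chrom = "chr1", pos = NULL) {
  if (is.null(pos)) pos <- seq(100, by = 400, length.out = length(probes))
  data.frame(probe_id = probes, chrom = chrom, pos = pos,
             sex_chrom = FALSE, snp_within_5bp = FALSE,
             stringsAsFactors = FALSE)
}

# Random small WP-DMR instance for oracle-equivalence tests: a flat cohort
# with spiked runs of consecutive probes in random pairs.
random_wp_instance <- function(seed, n_probes = 40, n_pairs = 12) {
  set.seed(seed)
  probes <- sprintf("cg%03d", seq_len(n_probes))
  sheet <- make_sheet(n_pairs)
  manifest <- make_manifest(probes,
                            pos = cumsum(sample(c(200, 400, 800, 1200),
                                                n_probes, replace = TRUE)))
  beta <- matrix(0.4 + rnorm(n_probes * 2 * n_pairs, 0, 0.01),
                 n_probes, 2 * n_pairs,
                 dimnames = list(probes, sheet$sample_id))
  for (k in seq_len(sample(1:4, 1))) {
    len <- sample(2:4, 1)
    start <- sample(seq_len(n_probes - len + 1), 1)
    pid <- sample(unique(sheet$pair_id), 1)
    who <- sample(c("_A", "_U"), 1)
    beta[start:(start + len - 1), paste0(pid, who)] <-
      beta[start:(start + len - 1), paste0(pid, who)] +
      sample(c(-1, 1), 1) * runif(1, 0.25, 0.45)
  }
  list(beta = pmin(pmax(beta, 0), 1), sheet = sheet, manifest = manifest)
}
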