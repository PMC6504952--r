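make_counts <- function(frac_aff, frac_non, pos, coverage = 100L) {
  n_pairs <- ncol(frac_aff)
  sheet <- make_sheet(n_pairs, prefix = "w")
  total <- matrix(coverage, length(pos), 2L * n_pairs,
                  dimnames = list(NULL, sheet$sample_id))
  meth <- total
  for (i in seq_len(n_pairs)) {
    meth[, paste0("w", i, "_A")] <- round(frac_aff[, i] * coverage)
    meth[, paste0("w", i, "_U")] <- round(frac_non[, i] * coverage)
  }
  list(counts = new_wgbs_counts(data.frame(chrom = "chr1", pos = pos),
                                meth, total),
       sheet = sheet)
}

test_that("coverage filter keeps only sites covered in every sample", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L))
  total <- matrix(c(9L, 10L, 30L, 12L, 10L, 30L), 3, 2,
                  dimnames = list(NULL, c("a", "b")))
  meth <- matrix(0L, 3, 2, dimnames = list(NULL, c("a", "b")))
  meth[] <- 1L
  counts <- new_wgbs_counts(sites, meth, total)
  expect_message(kept <- coverage_filter(counts, 10), "2 of 3")
  expect_equal(kept$sites$pos, c(20L, 30L))
  ident <- suppressMessages(coverage_filter(counts, 0))
  expect_equal(ident$sites, counts$sites)
})

test_that("site-level paired t matches stats::t.test; degenerate sites flagged", {
  diffs <- c(0.3, 0.25, 0.28, 0.27)
  fa <- matrix(rep(0.5 + diffs, each = 2), 2, 4)
  fn <- matrix(0.5, 2, 4)
  fn[2, ] <- fa[2, ]                       # identical co-twins at site 2
  fix <- make_counts(fa, fn, pos = c(100L, 200L))
  expect_message(site_paired_tests(fix$counts, fix$sheet), "zero-variance")
  st <- suppressMessages(site_paired_tests(fix$counts, fix$sheet))
  expect_equal(st$mean_diff[1], mean(diffs))
  expect_equal(st$p[1], t.test(diffs)$p.value, tolerance = 1e-12)
  expect_equal(st$mean_diff[2], 0)
  expect_true(is.na(st$p[2]))
  # negating differences flips the mean and keeps the p
  rev <- make_counts(fn[1, , drop = FALSE], fa[1, , drop = FALSE], pos = 100L)
  str <- site_paired_tests(rev$counts, rev$sheet)
  expect_equal(str$mean_diff, -st$mean_diff[1])
  expect_equal(str$p, st$p[1])
})

test_that("significant-site clustering applies the pairwise-gap rule", {
  base <- data.frame(chrom = "chr1", pos = c(100L, 350L, 820L),
                     mean_diff = 0.3, p = 0.01, stringsAsFactors = FALSE)
  calls <- cluster_significant_sites(base)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start_pos, 100L)
  expect_equal(calls$end_pos, 820L)
  expect_equal(calls$n_cpgs, 3L)
  expect_equal(calls$pair_id, "cohort")
  expect_true(calls$consistent)

  spread <- base; spread$pos <- c(100L, 700L, 1300L)
  expect_equal(nrow(cluster_significant_sites(spread)), 0L)

  mixed <- base; mixed$mean_diff <- c(0.3, -0.3, 0.3)
  expect_false(cluster_significant_sites(mixed)$consistent)

  unsorted <- base[c(2, 1, 3), ]
  expect_error(cluster_significant_sites(unsorted), "sorted")
})

test_that("relaxing the difference threshold only adds regions", {
  set.seed(17)
  n <- 400
  st <- data.frame(chrom = "chr1", pos = sort(sample(1:40000, n)),
                   mean_diff = rnorm(n, 0, 0.2),
                   p = runif(n)^2, stringsAsFactors = FALSE)
  strict <- cluster_significant_sites(st, diff_threshold = 0.2)
  relaxed <- cluster_significant_sites(st, diff_threshold = 0.15)
  for (i in seq_len(nrow(strict))) {
    expect_true(any(relaxed$start_pos <= strict$start_pos[i] &
                      relaxed$end_pos >= strict$end_pos[i]))
  }
  expect_gte(nrow(relaxed), nrow(strict))
})

test_that("clustering agrees with the window-enumeration oracle", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(50:200, 1)
    st <- data.frame(chrom = "chr1", pos = sort(sample(1:25000, n)),
                     mean_diff = rnorm(n, 0, 0.25),
                     p = runif(n)^3, stringsAsFactors = FALSE)
    calls <- cluster_significant_sites(st)
    flagged <- !is.na(st$p) & st$p < 0.05 & abs(st$mean_diff) > 0.2
    oracle <- cluster_enum_oracle(st$pos, flagged, 3, 500)
    expect_equal(nrow(calls), nrow(oracle), info = paste("seed", seed))
    if (nrow(calls)) {
      expect_equal(calls$start_pos, oracle$start, info = paste("seed", seed))
      expect_equal(calls$end_pos, oracle$end, info = paste("seed", seed))
      expect_equal(calls$n_cpgs, as.integer(oracle$n),
                   info = paste("seed", seed))
    }
  }
})

test_that("spiked regions are recovered in >=90% of 50 seeded cohorts", {
  hits <- 0L; nreg <- 0L
  for (s in 1:50) {
    cfg <- sim_config(n_probes = 100, seed = s,
                      wgbs = list(n_pairs = 4, n_sites = 1500,
                                  coverage_mean = 30,
                                  true_dmr = list(count = 2, n_cpgs = 5,
                                                  delta = 0.3, span_bp = 400)))
    w <- generate_wgbs_pairs(cfg)
    st <- suppressMessages(
      site_paired_tests(suppressMessages(coverage_filter(w$counts, 10)),
                        w$sheet))
    calls <- cluster_significant_sites(st)
    for (i in seq_len(nrow(w$truth))) {
      nreg <- nreg + 1L
      hits <- hits + any(calls$start_pos <= w$truth$end_pos[i] &
                           calls$end_pos >= w$truth$start_pos[i])
    }
  }
  expect_gte(hits / nreg, 0.9)
})

test_that("end-to-end recovery of spiked regions from simulated counts", {
  cfg <- sim_config(n_probes = 100, seed = 5,
                    wgbs = list(n_pairs = 4, n_sites = 1200, coverage_mean = 30,
                                true_dmr = list(count = 2, n_cpgs = 5,
                                                delta = 0.3, span_bp = 400)))
  w <- generate_wgbs_pairs(cfg)
  filt <- suppressMessages(coverage_filter(w$counts, 10))
  st <- suppressMessages(site_paired_tests(filt, w$sheet))
  calls <- cluster_significant_sites(st)
  for (i in seq_len(nrow(w$truth))) {
    expect_true(any(calls$start_pos <= w$truth$end_pos[i] &
                      calls$end_pos >= w$truth$start_pos[i]))
  }
})
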