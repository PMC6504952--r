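test_that("cohort generation is deterministic and leaves the RNG alone", {
  cfg <- sim_config(n_pairs = 8, n_probes = 300,
                    dmp = list(count = 5, delta = 0.05), seed = 101)
  set.seed(77); before <- rnorm(3)
  s1 <- generate_twin_cohort(cfg)
  s2 <- generate_twin_cohort(cfg)
  expect_identical(s1$beta, s2$beta)
  expect_identical(s1$sheet, s2$sheet)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$truth$dmp, s2$truth$dmp)
  set.seed(77)
  expect_identical(rnorm(3), before)   # generator restored the RNG state

  w1 <- generate_wgbs_pairs(cfg)
  w2 <- generate_wgbs_pairs(cfg)
  expect_identical(w1$counts$meth, w2$counts$meth)

  cfg2 <- sim_config(n_pairs = 8, n_probes = 300,
                     dmp = list(count = 5, delta = 0.05), seed = 102)
  expect_false(identical(generate_twin_cohort(cfg2)$beta, s1$beta))
})

test_that("emitted artifacts satisfy the package's own validators", {
  cfg <- sim_config(n_pairs = 10, n_probes = 400,
                    dmp = list(count = 5, delta = 0.05),
                    mqtl = list(count = 10, modes = c(0.1, 0.5, 0.9)),
                    seed = 13)
  sim <- generate_twin_cohort(cfg)
  expect_silent(validate_beta_matrix(sim$beta))
  expect_silent(validate_manifest(sim$manifest))
  expect_equal(nrow(validate_twin_sheet(sim$sheet)), 20L)
  expect_true(all(rowSums(sim$proportions) - 1 < 1e-9))
  expect_silent(validate_reference(sim$reference))
  # TSV round trip of the full fixture set
  dir <- withr::local_tempdir()
  write_beta_matrix(sim$beta, file.path(dir, "beta.tsv"))
  write_manifest(sim$manifest, file.path(dir, "manifest.tsv"))
  write_twin_sheet(sim$sheet, file.path(dir, "sheet.tsv"))
  write_sim_truth(sim$truth, file.path(dir, "truth.json"))
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  b <- read_beta_matrix(file.path(dir, "beta.tsv"), man)
  expect_equal(b, sim$beta, tolerance = 1e-6)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$dmp$probe, sim$truth$dmp$probe)
})

test_that("pair-difference noise is calibrated to the target median SD", {
  cfg <- sim_config(n_pairs = 45, n_probes = 4000, seed = 7)
  sim <- generate_twin_cohort(cfg)
  d <- compute_pair_deltas(sim$beta, sim$sheet)
  med <- median(apply(d, 1, sd))
  expect_lt(abs(med - 0.0266) / 0.0266, 0.20)
})

test_that("a zero-spike cohort is null: empty truth, chance-level hits", {
  cfg <- sim_config(n_pairs = 45, n_probes = 3000, seed = 29)
  sim <- generate_twin_cohort(cfg)
  expect_equal(nrow(sim$truth$dmp), 0L)
  expect_equal(nrow(sim$truth$wp_dmr), 0L)
  tab <- dmp_scan(compute_pair_deltas(sim$beta, sim$sheet))
  expect_equal(sum(tab$suggestive), 0L)
  frac <- mean(tab$p < 0.001)
  ci <- 1.96 * sqrt(0.001 * 0.999 / nrow(tab))
  expect_lt(abs(frac - 0.001), ci)
})

test_that("reference profiles have discriminating probes separated by 0.3", {
  cfg <- sim_config(n_pairs = 5, n_probes = 500, n_cell_types = 2, seed = 3)
  ref <- generate_reference(cfg)
  expect_equal(dim(ref), c(500L, 2L))
  expect_true(all(ref >= 0 & ref <= 1))
  expect_identical(ref, generate_reference(cfg))
  disc <- attr(ref, "discriminating")
  ranges <- apply(ref[disc, , drop = FALSE], 1, function(x) diff(range(x)))
  expect_true(all(ranges >= 0.3))
  # non-marker probes are identical across cell types
  other <- setdiff(rownames(ref), disc)
  expect_true(all(ref[other, 1] == ref[other, 2]))
})

test_that("spike categories are disjoint and mQTL probes are pair-concordant", {
  cfg <- sim_config(n_pairs = 20, n_probes = 2000,
                    dmp = list(count = 30, delta = 0.05),
                    dvp = list(count = 30, var_inflation = 8, mean_shift = 0.01),
                    mqtl = list(count = 30, modes = c(0.1, 0.5, 0.9)),
                    treatment = list(subset_size = 6, count = 30, delta = -0.1),
                    wp_dmr = list(count = 2, n_cpgs = 3, delta = 0.3,
                                  max_span_bp = 1000, target_role = "affected"),
                    seed = 17)
  sim <- generate_twin_cohort(cfg)
  tr <- sim$truth
  sets <- list(tr$dmp$probe, tr$dvp$probe, tr$mqtl$probes,
               tr$treatment$probes,
               unlist(strsplit(tr$wp_dmr$probes, ",")))
  all_spiked <- unlist(sets)
  expect_equal(anyDuplicated(all_spiked), 0L)
  # mQTL probes: co-twins share the mode, and betas sit near the modes
  for (j in seq_len(ncol(tr$mqtl$modes))) {
    pid <- colnames(tr$mqtl$modes)[j]
    a <- sim$beta[tr$mqtl$probes, paste0(pid, "_A")]
    u <- sim$beta[tr$mqtl$probes, paste0(pid, "_U")]
    expect_lt(max(abs(a - tr$mqtl$modes[, j])), 0.25)
    expect_lt(max(abs(a - u)), 0.2)
  }
  # treatment deltas appear only in the labelled subset
  d <- compute_pair_deltas(sim$beta, sim$sheet)
  in_sub <- colMeans(d[tr$treatment$probes, tr$treatment$pairs, drop = FALSE])
  out_sub <- colMeans(d[tr$treatment$probes,
                        setdiff(colnames(d), tr$treatment$pairs),
                        drop = FALSE])
  expect_lt(max(in_sub), -0.05)
  expect_lt(max(abs(out_sub)), 0.05)
})

test_that("WGBS generator: coverage, counts, and truth geometry", {
  cfg <- sim_config(n_probes = 100, seed = 41,
                    wgbs = list(n_pairs = 4, n_sites = 3000, coverage_mean = 30,
                                true_dmr = list(count = 2, n_cpgs = 5,
                                                delta = 0.3, span_bp = 400)))
  w <- generate_wgbs_pairs(cfg)
  expect_true(all(w$counts$total >= 1))
  expect_true(all(w$counts$meth <= w$counts$total))
  expect_lt(abs(mean(w$counts$total) - 30) / 30, 0.10)
  expect_equal(nrow(w$truth), 2L)
  expect_true(all(w$truth$end_pos - w$truth$start_pos <= 400))
  expect_equal(nrow(validate_twin_sheet(w$sheet)), 8L)
})
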