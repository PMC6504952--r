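# Synthetic twin-cohort generator.
#
# Emulates the statistical structure the paired analyses assume: bimodal
# beta baselines, twin-correlated cell-type composition, technical noise
# calibrated so the per-probe SD of within-pair differences matches a target
# (default 0.0266, a realistic array median), plus spike-in ground truth for
# every pipeline stage: mean-shift DMPs, pair-private contiguous WP-DMRs,
# group-wise variance-inflated DVPs, trimodal mQTL-like probes,
# treatment-subset effects, and binomially sampled WGBS counts. Every run is
# fully determined by the seed and accompanied by a truth ledger.

# Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults mirror the cohort design the pipeline targets: 45 twin pairs, a
#' per-probe technical SD of pair differences of 0.0266, a 12-pair treatment
#' subset, DMP spikes of 0.05 (the effect size the power calculation is
#' anchored to), within-pair region spikes of 0.3 over 3 CpGs within 1 kb,
#' 8-fold variance inflation for differential-variability spikes, and a
#' four-pair WGBS design at mean coverage 30 with 0.3 regions over 5 CpGs
#' within 400 bp. Spike counts may be set to 0 for null cohorts. `seed` is
#' mandatory.
#'
#' @param n_pairs,n_probes,n_cell_types cohort dimensions.
#' @param noise_sd target per-probe SD of within-pair beta differences.
#' @param dirichlet_concentration concentration of the per-pair Dirichlet
#'   draw of cell proportions (larger = less between-pair variation).
#' @param within_pair_proportion_sd SD of the multiplicative log-normal
#'   perturbation separating co-twins' proportions.
#' @param n_discriminating reference probes at which cell types differ.
#' @param dmp,wp_dmr,dvp,mqtl,treatment,wgbs spike-block lists; see defaults.
#' @param seed integer RNG seed (required).
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_pairs = 45L, n_probes = 20000L, n_cell_types = 6L,
                       noise_sd = 0.0266, dirichlet_concentration = 50,
                       within_pair_proportion_sd = 0.05,
                       n_discriminating = 200L,
                       dmp = list(count = 0L, delta = 0.05),
                       wp_dmr = list(count = 0L, n_cpgs = 3L, delta = 0.3,
                                     max_span_bp = 1000L,
                                     target_role = "affected"),
                       dvp = list(count = 0L, var_inflation = 8,
                                  mean_shift = 0.01),
                       mqtl = list(count = 0L, modes = c(0.1, 0.5, 0.9)),
                       treatment = list(subset_size = 12L, count = 0L,
                                        delta = -0.10),
                       wgbs = list(n_pairs = 4L, n_sites = 5000L,
                                   coverage_mean = 30,
                                   true_dmr = list(count = 0L, n_cpgs = 5L,
                                                   delta = 0.3,
                                                   span_bp = 400L)),
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- list(n_pairs = as.integer(n_pairs), n_probes = as.integer(n_probes),
              n_cell_types = as.integer(n_cell_types), noise_sd = noise_sd,
              dirichlet_concentration = dirichlet_concentration,
              within_pair_proportion_sd = within_pair_proportion_sd,
              n_discriminating = as.integer(n_discriminating),
              dmp = dmp, wp_dmr = wp_dmr, dvp = dvp, mqtl = mqtl,
              treatment = treatment, wgbs = wgbs, seed = as.integer(seed))
  spikes <- cfg$dmp$count + cfg$wp_dmr$count * cfg$wp_dmr$n_cpgs +
    cfg$dvp$count + cfg$mqtl$count + cfg$treatment$count
  if (spikes > cfg$n_probes / 2) stop("spike counts exceed half the probes")
  for (d in c(cfg$dmp$delta, abs(cfg$wp_dmr$delta), abs(cfg$treatment$delta))) {
    if (d <= 0 || d >= 1) stop("spike deltas must lie in (0, 1)")
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$treatment$subset_size > cfg$n_pairs) {
    if (cfg$treatment$count > 0) stop("treatment subset too large")
    cfg$treatment$subset_size <- cfg$n_pairs   # unused label set: shrink
  }
  class(cfg) <- "sim_config"
  cfg
}

# Bimodal baseline beta values: components near 0, near 1, and intermediate,
# clamped away from saturation so logit-scale noise stays well behaved.
.baseline_beta <- function(n) {
  comp <- sample.int(3L, n, replace = TRUE, prob = c(0.35, 0.35, 0.30))
  b <- numeric(n)
  b[comp == 1L] <- stats::rbeta(sum(comp == 1L), 2, 14)
  b[comp == 2L] <- stats::rbeta(sum(comp == 2L), 14, 2)
  b[comp == 3L] <- stats::rbeta(sum(comp == 3L), 5, 5)
  pmin(pmax(b, 0.05), 0.95)
}

#' Generate a cell-type reference profile
#'
#' Probes x cell-types matrix of mean beta values. Most probes are identical
#' across cell types (a shared bimodal baseline); a designated subset of
#' discriminating probes (attribute `"discriminating"`) separates the cell
#' types by at least 0.3, mimicking the marker CpGs a blood reference panel
#' provides for deconvolution.
#'
#' @param config a [sim_config()] (fields n_probes, n_cell_types,
#'   n_discriminating, seed are used).
#' @param seed optional override of `config$seed`.
#' @return reference matrix with attributes `"discriminating"` (probe ids)
#'   and `"baseline"` (shared baseline vector).
#' @export
generate_reference <- function(config, seed = config$seed) {
  stopifnot(config$n_cell_types >= 2L)
  .with_seed(seed, {
    np <- config$n_probes; k <- config$n_cell_types
    probes <- sprintf("cg%07d", seq_len(np))
    base <- .baseline_beta(np)
    ref <- matrix(base, nrow = np, ncol = k,
                  dimnames = list(probes, paste0("CT", seq_len(k))))
    disc <- sort(sample.int(np, config$n_discriminating))
    for (i in disc) {
      lo <- runif(1, 0.05, 0.30)
      hi <- lo + runif(1, 0.35, 0.60)
      lab <- sample(rep_len(c(0L, 1L), k))   # both levels always present
      ref[i, ] <- pmin(ifelse(lab == 1L, hi, lo) + runif(k, 0, 0.05), 0.98)
    }
    attr(ref, "discriminating") <- probes[disc]
    attr(ref, "baseline") <- base
    ref
  })
}

# Dirichlet draw via gamma variates.
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

# Manifest with realistic CpG spacing: probes assigned to chromosomes in
# blocks, positions accumulated with geometric gaps (median about 300 bp).
.make_manifest <- function(probes) {
  np <- length(probes)
  n_chrom <- min(22L, max(1L, np %/% 50L))
  chrom_idx <- sort(rep_len(seq_len(n_chrom), np))
  chrom <- paste0("chr", chrom_idx)
  pos <- integer(np)
  for (ci in seq_len(n_chrom)) {
    sel <- which(chrom_idx == ci)
    gaps <- 1L + stats::rgeom(length(sel), 1 / 433)
    pos[sel] <- 10000L + cumsum(gaps)
  }
  data.frame(probe_id = probes, chrom = chrom, pos = pos,
             sex_chrom = FALSE, snp_within_5bp = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic discordant twin cohort
#'
#' Produces a beta matrix, twin sheet, manifest, reference profile, true
#' proportions, and a truth ledger. Per pair, a shared cell-proportion vector
#' is drawn from a Dirichlet and perturbed per co-twin (log-normal,
#' renormalised); expected beta is proportions times the reference. Technical
#' noise is added on the logit scale with a per-probe scale calibrated (delta
#' method) so the SD of within-pair differences approximates `noise_sd`;
#' spikes are then applied on the beta scale and values clipped to
#' \[0.001, 0.999\]. Spiked probe sets are disjoint and drawn from mid-range
#' baseline probes so the configured effect size is realised unclipped.
#'
#' @param config a [sim_config()].
#' @return list with `beta`, `sheet`, `manifest`, `reference`, `proportions`
#'   (samples x cell types), and `truth` (see [write_sim_truth()]).
#' @export
generate_twin_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ref <- generate_reference(config)
  .with_seed(config$seed + 1L, {
    np <- config$n_probes; npair <- config$n_pairs
    k <- config$n_cell_types
    probes <- rownames(ref)
    base <- attr(ref, "baseline")
    disc <- attr(ref, "discriminating")
    manifest <- .make_manifest(probes)

    pair_ids <- sprintf("pair%03d", seq_len(npair))
    aff_ids <- paste0(pair_ids, "_A")
    non_ids <- paste0(pair_ids, "_U")
    samples <- as.vector(rbind(aff_ids, non_ids))
    sheet <- data.frame(
      sample_id = samples,
      pair_id = rep(pair_ids, each = 2L),
      role = rep(c("affected", "non_affected"), npair),
      ifn_current = FALSE, gc_recent_3to12m = FALSE,
      smoking = as.logical(stats::rbinom(2L * npair, 1L, 0.29)),
      stringsAsFactors = FALSE
    )
    ifn_pairs <- sort(sample(pair_ids, config$treatment$subset_size))
    sheet$ifn_current <- sheet$pair_id %in% ifn_pairs & sheet$role == "affected"
    gc_pairs <- sort(sample(setdiff(pair_ids, ifn_pairs),
                            min(14L, npair - length(ifn_pairs))))
    sheet$gc_recent_3to12m <- sheet$pair_id %in% gc_pairs &
      sheet$role == "affected"

    # twin-correlated cell proportions
    alpha <- config$dirichlet_concentration * rev(seq_len(k)) / sum(seq_len(k))
    pair_props <- .rdirichlet(npair, alpha)
    props <- matrix(NA_real_, 2L * npair, k,
                    dimnames = list(samples, colnames(ref)))
    for (i in seq_len(npair)) {
      for (s in c(aff_ids[i], non_ids[i])) {
        w <- pair_props[i, ] *
          exp(stats::rnorm(k, 0, config$within_pair_proportion_sd))
        props[s, ] <- w / sum(w)
      }
    }
    mu <- ref %*% t(props)       # probes x samples expected beta

    # disjoint spike probes from mid-range baselines, away from reference
    # marker probes, so configured deltas are realised unclipped
    pool <- setdiff(probes[base >= 0.15 & base <= 0.80], disc)
    take <- function(n) {
      picked <- sample(pool, n)
      pool <<- setdiff(pool, picked)
      picked
    }
    dmp_probes <- if (config$dmp$count > 0) take(config$dmp$count) else character()
    dvp_probes <- if (config$dvp$count > 0) take(config$dvp$count) else character()
    treat_probes <- if (config$treatment$count > 0)
      take(config$treatment$count) else character()
    mqtl_probes <- if (config$mqtl$count > 0) take(config$mqtl$count) else character()

    # mQTL-like probes: pair-shared trimodal mode, identical in co-twins
    mqtl_modes <- NULL
    if (length(mqtl_probes)) {
      mode_prob <- if (length(config$mqtl$modes) == 3L) c(0.25, 0.5, 0.25)
                   else rep(1, length(config$mqtl$modes))
      mqtl_modes <- matrix(
        sample(config$mqtl$modes, length(mqtl_probes) * npair, replace = TRUE,
               prob = mode_prob),
        nrow = length(mqtl_probes), dimnames = list(mqtl_probes, pair_ids))
      for (i in seq_len(npair)) {
        mu[mqtl_probes, c(aff_ids[i], non_ids[i])] <- mqtl_modes[, i]
      }
    }

    # technical noise on the logit scale, delta-method calibrated so the
    # per-probe SD of pair differences is ~ noise_sd
    mu_c <- pmin(pmax(mu, 0.02), 0.98)
    s_logit <- (config$noise_sd / sqrt(2)) / (mu_c * (1 - mu_c))
    if (config$dvp$count > 0) {
      s_logit[dvp_probes, aff_ids] <-
        s_logit[dvp_probes, aff_ids] * sqrt(config$dvp$var_inflation)
    }
    beta <- stats::plogis(stats::qlogis(mu_c) +
                            stats::rnorm(length(mu_c)) * s_logit)

    # beta-scale spikes
    if (config$dvp$count > 0 && config$dvp$mean_shift != 0) {
      beta[dvp_probes, aff_ids] <- beta[dvp_probes, aff_ids] +
        config$dvp$mean_shift
    }
    if (length(dmp_probes)) {
      beta[dmp_probes, aff_ids] <- beta[dmp_probes, aff_ids] + config$dmp$delta
    }
    if (length(treat_probes)) {
      treat_aff <- paste0(ifn_pairs, "_A")
      beta[treat_probes, treat_aff] <- beta[treat_probes, treat_aff] +
        config$treatment$delta
    }

    # pair-private contiguous WP-DMR spikes
    wp_truth <- list()
    if (config$wp_dmr$count > 0) {
      runs <- .find_spike_runs(manifest, probes[base <= 0.6 & base >= 0.1],
                               pool, config$wp_dmr$n_cpgs,
                               config$wp_dmr$max_span_bp,
                               config$wp_dmr$count)
      wp_pairs <- sample(pair_ids, length(runs), replace = FALSE)
      for (j in seq_along(runs)) {
        run <- runs[[j]]
        pool <- setdiff(pool, run)
        target <- if (identical(config$wp_dmr$target_role, "affected"))
          paste0(wp_pairs[j], "_A") else paste0(wp_pairs[j], "_U")
        beta[run, target] <- beta[run, target] + config$wp_dmr$delta
        ridx <- match(run, manifest$probe_id)
        wp_truth[[j]] <- data.frame(
          pair_id = wp_pairs[j], chrom = manifest$chrom[ridx[1]],
          start_pos = min(manifest$pos[ridx]),
          end_pos = max(manifest$pos[ridx]),
          probes = paste(run, collapse = ","),
          delta = config$wp_dmr$delta,
          target_role = config$wp_dmr$target_role,
          stringsAsFactors = FALSE)
      }
    }
    beta <- pmin(pmax(beta, 0.001), 0.999)

    truth <- list(
      proportions = props,
      dmp = data.frame(probe = dmp_probes,
                       delta = rep(config$dmp$delta, length(dmp_probes)),
                       stringsAsFactors = FALSE),
      dvp = data.frame(probe = dvp_probes,
                       var_inflation = rep(config$dvp$var_inflation,
                                           length(dvp_probes)),
                       mean_shift = rep(config$dvp$mean_shift,
                                        length(dvp_probes)),
                       stringsAsFactors = FALSE),
      treatment = list(pairs = ifn_pairs,
                       probes = treat_probes,
                       delta = config$treatment$delta),
      mqtl = list(probes = mqtl_probes, modes = mqtl_modes),
      wp_dmr = if (length(wp_truth)) do.call(rbind, wp_truth) else
        data.frame(),
      discriminating = disc
    )
    list(beta = beta, sheet = sheet, manifest = manifest, reference = ref,
         proportions = props, truth = truth)
  })
}

# Find `count` disjoint runs of `n_cpgs` consecutive manifest probes, all in
# the eligible/pool sets, spanning at most `max_span_bp` on one chromosome.
.find_spike_runs <- function(manifest, eligible, pool, n_cpgs, max_span_bp,
                             count) {
  ok <- manifest$probe_id %in% intersect(eligible, pool)
  runs <- list()
  used <- logical(nrow(manifest))
  starts <- sample(seq_len(nrow(manifest) - n_cpgs + 1L))
  for (s in starts) {
    idx <- s:(s + n_cpgs - 1L)
    if (any(used[idx]) || !all(ok[idx])) next
    if (length(unique(manifest$chrom[idx])) != 1L) next
    if (max(manifest$pos[idx]) - min(manifest$pos[idx]) > max_span_bp) next
    if (any(diff(manifest$pos[idx]) > 1000L)) next
    runs[[length(runs) + 1L]] <- manifest$probe_id[idx]
    used[idx] <- TRUE
    if (length(runs) == count) break
  }
  if (length(runs) < count) stop("could not place all region spikes")
  runs
}

#' Generate paired WGBS-like count data
#'
#' Per site, a twin-correlated true methylation fraction (pair-shared bimodal
#' baseline, small per-individual logit perturbation); per sample-site, total
#' reads are 1 + negative-binomial with mean `coverage_mean`, and methylated
#' reads are binomial in the true fraction. True regions add `delta` to the
#' affected co-twins' fractions over contiguous sites within `span_bp`.
#'
#' @param config a [sim_config()]; the `wgbs` block drives this generator.
#' @return list with `counts` (a `wgbs_counts`), `sheet`, and `truth`
#'   (data frame of true region intervals, possibly empty).
#' @export
generate_wgbs_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  w <- config$wgbs
  .with_seed(config$seed + 2L, {
    ns <- w$n_sites; npair <- w$n_pairs
    pair_ids <- sprintf("wpair%02d", seq_len(npair))
    aff_ids <- paste0(pair_ids, "_A")
    non_ids <- paste0(pair_ids, "_U")
    samples <- as.vector(rbind(aff_ids, non_ids))
    sheet <- data.frame(sample_id = samples,
                        pair_id = rep(pair_ids, each = 2L),
                        role = rep(c("affected", "non_affected"), npair),
                        stringsAsFactors = FALSE)
    gaps <- 1L + stats::rgeom(ns, 1 / 120)
    pos <- 10000L + cumsum(gaps)
    sites <- data.frame(chrom = "chr1", pos = pos, stringsAsFactors = FALSE)
    base <- .baseline_beta(ns)

    # place true regions on runs of sites; force mid-low baselines so +delta
    # stays in range
    truth <- data.frame()
    spiked <- logical(ns)
    if (w$true_dmr$count > 0) {
      placed <- 0L
      for (s in sample(seq_len(ns - w$true_dmr$n_cpgs + 1L))) {
        idx <- s:(s + w$true_dmr$n_cpgs - 1L)
        if (any(spiked[idx])) next
        if (pos[idx[length(idx)]] - pos[idx[1]] > w$true_dmr$span_bp) next
        base[idx] <- runif(length(idx), 0.25, 0.45)
        spiked[idx] <- TRUE
        truth <- rbind(truth, data.frame(
          chrom = "chr1", start_pos = pos[idx[1]],
          end_pos = pos[idx[length(idx)]], n_cpgs = length(idx),
          delta = w$true_dmr$delta, stringsAsFactors = FALSE))
        placed <- placed + 1L
        if (placed == w$true_dmr$count) break
      }
      if (placed < w$true_dmr$count) stop("could not place all WGBS regions")
    }

    # pair-shared fraction with small individual deviation
    frac <- matrix(NA_real_, ns, 2L * npair,
                   dimnames = list(NULL, samples))
    for (i in seq_len(npair)) {
      pair_f <- stats::plogis(stats::qlogis(pmin(pmax(base, 0.02), 0.98)) +
                                stats::rnorm(ns, 0, 0.25))
      for (s in c(aff_ids[i], non_ids[i])) {
        frac[, s] <- stats::plogis(stats::qlogis(pmin(pmax(pair_f, 0.02),
                                                      0.98)) +
                                     stats::rnorm(ns, 0, 0.10))
      }
    }
    if (any(spiked)) {
      frac[spiked, aff_ids] <- pmin(frac[spiked, aff_ids] + w$true_dmr$delta,
                                    0.99)
    }
    total <- matrix(1L + stats::rnbinom(ns * 2L * npair, mu = w$coverage_mean - 1,
                                        size = 8),
                    ns, 2L * npair, dimnames = list(NULL, samples))
    meth <- matrix(stats::rbinom(ns * 2L * npair, as.vector(total),
                                 as.vector(frac)),
                   ns, 2L * npair, dimnames = list(NULL, samples))
    list(counts = new_wgbs_counts(sites, meth, total), sheet = sheet,
         truth = truth)
  })
}

#' Write the simulation truth ledger as JSON
#'
#' @param truth the `truth` element of [generate_twin_cohort()] output.
#' @param path output JSON path.
#' @export
write_sim_truth <- function(truth, path) {
  out <- truth
  out$proportions <- as.data.frame(out$proportions)
  out$mqtl$modes <- if (is.null(out$mqtl$modes)) NULL else
    as.data.frame(out$mqtl$modes)
  jsonlite::write_json(out, path, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  invisible(path)
}
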