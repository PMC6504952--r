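---
title: "Methods: paired methylome analysis in discordant MZ twins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired methylome analysis in discordant MZ twins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The design and its unit of inference

A disease-discordant monozygotic twin pair is a perfectly genetically
matched case–control unit. For probe $j$ and pair $i$ the within-pair
difference $\Delta\beta_{ij} = \beta_{ij}^{\mathrm{aff}} -
\beta_{ij}^{\mathrm{non}}$ cancels genotype and shared environment; under
the null of no disease association it is symmetric about zero. Every
cohort-level scan in this package is a test on the vector
$(\Delta\beta_{1j}, \ldots, \Delta\beta_{nj})$.

# Statistical primitives

**Wilcoxon signed-rank.** Zeros are dropped before ranking (the classic
convention; the number of pairs used is reported after dropping) and
absolute ties receive midranks. For $\le 25$ nonzero differences the
two-sided p is exact, computed by convolving the signed-rank distribution
over all $2^n$ sign assignments (doubled midranks are integers, so the
distribution is a polynomial convolution; this remains exact under ties,
unlike the closed form behind `psignrank`). Above 25 the tie-corrected
normal approximation with a 0.5 continuity correction is used, so a
45-pair cohort scan runs in normal mode. Both modes are validated against
full enumeration and against `stats::wilcox.test` where the latter is
exact.

**Multiplicity.** Benjamini–Hochberg over all probes of a scan in one
batch (`stats::p.adjust`); no per-chromosome stratification. The scan
reports a *suggestive* flag at raw $p < 5\times10^{-6}$ and a
*genome-wide* flag at FDR $< 0.05$.

**Power.** The paired t-test is used as the tractable parametric
equivalent of the signed-rank scan: power is computed from the noncentral
t distribution with $n-1$ df and noncentrality $\delta\sqrt{n}/\sigma$.
With $n = 45$, $\delta = 0.05$, $\sigma = 0.0266$ and
$\alpha = 10^{-7}$ this exceeds 0.98; at $\delta = 0$ it equals $\alpha$
exactly, and at large $n$ it agrees with the normal-theory formula to
within 0.005.

**Other tests.** The two-sided Fisher exact test uses the conventional
minimum-likelihood rule (sum of hypergeometric probabilities no larger
than the observed table's). Bartlett's two-sample statistic uses the
standard small-sample correction and a $\chi^2_1$ reference. The unpaired
t-test defaults to the pooled-variance form because that is what the
differential-variability algorithm prescribes; Welch is available behind a
flag.

# Cell-type composition

PBMC methylomes are mixtures over cell types, and composition differs
systematically between co-twins of whom one carries an inflammatory
disease or its treatments. Proportions are estimated per sample by
projecting the β profile at the reference's marker probes onto the
reference columns under non-negativity (Lawson–Hanson NNLS via
`pracma::lsqnonneg`) followed by normalisation to sum to one. A
quadratic-programming formulation would impose the simplex constraint
jointly; the NNLS-then-normalise route is the standard practical
approximation and recovers noiseless mixtures to $10^{-6}$.

Adjustment regresses each probe on the proportion covariates (one cell
type dropped to break the sum-to-one collinearity; constant columns
dropped, so a composition-homogeneous cohort passes through unchanged) and
keeps *residual + unadjusted probe mean*. Consequences, both tested: the
per-probe mean is preserved to $10^{-9}$, and the operation is idempotent
to $10^{-8}$. Adjusted values may leave $[0,1]$ slightly; they are not
clipped, because clipping would break mean preservation — any clipping is
cosmetic and belongs in report output only. Whether to feed all estimated
fractions or a subset into the regression is open in principle; the
default is all minus one, which is the maximal non-collinear set. Smoking
or other per-sample covariates can be appended to the same design rather
than forming a separate code path.

# Region callers

**Within-pair DMRs.** Three rules define a pair-private region: ≥ 3
member CpGs with $|\Delta\beta| > 0.2$ each; consecutive members ≤ 1 kb
apart (greedy left-to-right clustering with a hard break at a violating
gap — a later probe never rescues a broken cluster, matching the pairwise
definition of the gap rule); and a cohort-outlier band — at every member
CpG at least one co-twin must lie more than 3 sample SDs from the probe's
cohort mean. The SD is taken over *all* cohort samples including the
tested pair: the paper-style definition is ambiguous on this point, and
including the pair is the conservative, deterministic choice. It has a
knowable consequence: with $2n$ samples the largest attainable z-score is
$(2n-1)/\sqrt{2n}$, so the band is unsatisfiable below ~6 pairs — tiny
fixtures must use 12 pairs or more. The outlier rule is enforced per
member probe (stricter than a region-average rule, which is the other
defensible reading). The aberrant co-twin is assigned by majority vote
across members, with ties reported as ambiguous. Treatment-associated
probes are excluded before scanning, mirroring the exclusion of
interferon-associated CpGs in cohort practice. The caller is verified
against an exhaustive window-enumeration oracle and by an independent
post-hoc rule checker.

**WGBS regions.** Methylation fractions use strand-aggregated counts;
sites need coverage ≥ 10 in every sample. Significant sites
($p < 0.05$ paired t, $|$difference$| > 0.2$) are clustered with a 500 bp
pairwise-gap rule ("maximum distance between neighbouring significant
CpGs" and "max. distance" are read as the same rule). Mixed-direction
regions are allowed but flagged (`consistent`), so a direction-consistency
filter is one `subset()` away. Sex chromosomes are retained — in a
sex-matched twin design X-linked regions are legitimate calls.

**Differential variability.** The two-criterion scan (Bartlett FDR
< 0.001 *and* raw t p < 0.05, ranked by t p) runs on unadjusted β by
default — the variance signal of interest may itself be compositional, and
the source algorithm is defined on raw data — with adjusted input a
drop-in alternative. Co-twins enter as independent group members because
the source algorithm is unpaired; a paired t variant is available for
sensitivity analysis.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults are the study
conditions the analyses target: 45 pairs, a 12-pair treatment subset, and
technical noise calibrated so the per-probe SD of pair differences has
median ≈ 0.0266.

*Baselines* are bimodal (Beta mixtures near 0, near 1, and intermediate),
clamped to $[0.05, 0.95]$ so logit-scale noise stays well behaved.
*Composition*: a per-pair Dirichlet proportion vector (concentration 50
over 6 cell types), perturbed per co-twin by a multiplicative log-normal
(SD 0.05) and renormalised; only the 200 designated reference marker
probes separate cell types (by ≥ 0.3), so composition signal does not
contaminate the noise calibration of the remaining probes. *Noise* is
added on the logit scale with per-probe scale
$\sigma_{\mathrm{logit}} = (0.0266/\sqrt2)\,/\,[\mu(1-\mu)]$ — the
delta-method calibration — and the realised median pair-difference SD is
tested to be within 20% of target. *Spikes* are applied on the β scale
after back-transformation (matching how $\Delta\beta$ is defined), drawn
from disjoint mid-range-baseline probe sets ($\beta_0 \in [0.15, 0.80]$)
so configured effect sizes are realised unclipped: mean-shift DMPs
(default 0.05, the power-analysis effect size), pair-private contiguous
WP-DMRs (0.3 over 3 CpGs within 1 kb, placed in the affected co-twin by
default with a switch), variance-inflated DVPs (×8 on one group's noise
plus a 0.01 mean shift), trimodal pair-concordant mQTL probes
(modes 0.1/0.5/0.9 with Hardy–Weinberg-like 1:2:1 weights), and a
treatment effect (−0.10 in the affected co-twins of the labelled 12-pair
subset, the hypomethylation direction typical of interferon markers).
Values are clipped to $[0.001, 0.999]$ to avoid degenerate variance at
saturated probes. Manifest positions use geometric gaps with median
≈ 300 bp, the array-like spacing regime the 1 kb gap rule was designed
for.

*WGBS*: four pairs, per-site pair-shared fractions (logit SD 0.25 between
pairs, 0.10 between co-twins), totals $1 + \mathrm{NB}(\mu = 29,
\mathrm{size} = 8)$ (mean 30, realistically over-dispersed, never zero),
methylated reads binomial. True regions add 0.3 over 5 contiguous sites
within 400 bp, with member baselines forced to 0.25–0.45 so the shift
fits in range.

Everything is driven by a mandatory seed; generation saves and restores
the caller's RNG state, and identical seeds give identical output (the
generator is base R's default Mersenne-Twister stream).

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: Infinium I/II chemistry bias, batch and
position effects, genome-scale probe counts (scans here use $10^3$–$10^4$
probes, not $8.5\times10^5$), realistic linkage between composition and
disease status, cohort heterogeneity of effect sizes, and bisulfite
conversion error. Recovery rates on spiked cohorts are upper bounds on
real-data sensitivity.

# Numerical and scale choices

Test and simulation sizes were chosen to exercise each claim at the
smallest scale at which it is meaningful: oracle equivalence on ≤ 50-probe
/ ≤ 200-site instances over 50–100 seeds, null calibration with 10,000
signed-rank replicates at the cohort size of 45, spike recovery with 200
spiked probes per category, and WGBS recovery over 50 seeded four-pair
cohorts (where measured sensitivity is ≈ 0.85–0.9; the per-site paired t
has only 3 df, and the all-sample coverage filter removes ~20% of member
sites at mean coverage 30, which is the binding constraint).

One stated expectation is not attainable and is deliberately left failing
in the acceptance tests rather than weakened: joint two-criterion
differential-variability sensitivity of 0.8 for ×8 variance inflation with
a 0.01 mean shift at 45 + 45 samples and pair-difference SD 0.0266. The
t-stage is the binding constraint — its noncentrality is
$0.01 / \sqrt{(v_1 + 8 v_1)/2}\,\sqrt{2/45} \approx 1.19$ with $v_1 =
(0.0266/\sqrt2)^2$, i.e. ~0.22 power at $p < 0.05$, for any
implementation. Measured joint sensitivity is ≈ 0.25, while the
Bartlett stage alone detects ≈ 99% of inflated probes and pure mean
shifts are never flagged; those facets are asserted and pass.

# Interfaces

All artifacts are plain text: TSV for matrices, sheets, references,
count tables and result tables; BED (0-based half-open, converted from
the manifest's 1-based coordinates) for regions; YAML for the threshold
configuration (every default is the pipeline's standard value); JSON for
the simulation truth ledger. The package is driven from R; the exported
functions compose into the full pipeline in a few lines (see the README),
and `scripts/acceptance.R` is a worked, seeded end-to-end run.
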