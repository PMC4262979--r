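---
title: "Methods: models, parameters and design choices in methdev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in methdev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdev)
```

`methdev` is a case-control EWAS pipeline for 450K-style methylation
matrices together with a synthetic-data generator that plants every
effect it later asks the pipeline to find. This vignette explains the
statistical models, the parameters that matter, what the generator does
and does not emulate, and the numerical and design decisions a
maintainer would want spelled out.

## The measurement model

A 450K-style array reports, per CpG probe and sample, methylated and
unmethylated intensities `M` and `U`; the methylation proportion is
`β = M/(M + U + α)` with the conventional stabilizing offset `α = 100`.
Betas are bounded, trimodally distributed (most CpGs are nearly
unmethylated or nearly methylated) and heteroscedastic near the bounds,
so inference happens on M-values, `logit2(β) = log2(β/(1−β))`, which
are unbounded and closer to homoscedastic in the mid-range. Before the
transform betas are clipped to `[ε, 1−ε]` with `ε = 0.001` so M-values
stay finite; effect sizes are nevertheless reported on the beta scale
(`Δβ`, case mean minus control mean), because beta differences are what
a reader can interpret as percentage methylation.

## Quality control

Two matrix-level filters, in order, with deliberately asymmetric
boundary conventions:

- **Samples**: removed when *strictly more than* 1% of probes have
  detection p > 0.05. A sample at exactly 1% survives.
- **Probes**: removed when the fraction of samples with detection
  p > 0.05 is *at least* 1%, or the fraction with beadcount < 3 is *at
  least* 5%. A beadcount of exactly 3 is adequate.

The strict/inclusive split mirrors how these rules are conventionally
phrased ("more than 1% of probes" versus "in at least 1% of samples"),
and the tests pin the boundaries exactly. Probes with a SNP near the
extension site and all sex-chromosome probes are then dropped; the
predicted-versus-reported sex check (2-means split of mean X-chromosome
beta, females higher because X-inactivation leaves intermediate
methylation) is advisory — mismatches are flagged for follow-up, never
auto-removed, since a mismatch can indicate a sample swap or a
karyotype anomaly that deserves different handling.

`dasen_like_normalize()` approximates dasen-style normalization: per
sample, type I intensities are shifted so their median matches that
sample's type II median (a background equalization across the two
Infinium chemistries), then each of the four stratum matrices
(methylated/unmethylated × type I/II) is quantile normalized between
samples (via `limma::normalizeQuantiles`), and betas are recomputed.
The genuine article interpolates a fitted background offset rather
than shifting medians; the median shift preserves the essential
structure (type-stratified between-sample quantile normalization) and
is exactly testable by hand. Single-sample input degrades to the
identity with a warning.

## Probe-wise inference

Each probe is fit by OLS of M on `intercept + diagnosis + covariates`
(age and sex by default), sharing one design matrix across probes so
the whole matrix is fit with two matrix products. The diagnosis
coefficient gets a two-sided t-test. With `moderation = TRUE` (the
default, and the mode intended for analysis) residual variances are
shrunk toward a common prior: `s̃² = (d₀s₀² + d·s²)/(d₀+d)`, with
hyperparameters estimated by moment matching on log-variances using a
Newton inversion of the trigamma function. The moderated t uses
`d + d₀` degrees of freedom. This is the standard empirical-Bayes
scheme; the test suite checks it against `limma::eBayes` to numerical
precision on a heteroscedastic instance, and the unmoderated mode
against the closed-form two-group t-test. Zero-residual probes
(constant within groups) get NA statistics with a logged message rather
than infinite t's; singular designs fail naming the collinear columns.

`bh_adjust()` implements BH step-up with an explicit total test count
`N ≥ length(p)`, so a printed head of a longer ranked list can be
adjusted as the `k` smallest of `N` tests — `stats::p.adjust` cannot
express this. Ties keep stable original order. A brute-force step-up
oracle validates it on random vectors.

## Cellular composition

Bulk brain is a neuron/glia mixture, and case-control shifts in
neuronal proportion create spurious probe-level differences at any CpG
where the two cell types differ. Over a marker-probe panel with known
neuron and glia reference profiles, the mixing weight solving the
least-squares projection has the closed form
`w = Σ d(β − β_glia) / Σ d²` with `d = β_neuron − β_glia`, clipped to
`[0,1]`. `refit_with_composition()` repeats the probe-wise model with
`w` appended as a covariate: a planted effect that is *purely* a
composition confound loses significance after adjustment, while a
genuine effect barely moves — both behaviours are exercised in the
tests. A constant `w` (collinear with the intercept) is dropped with a
warning, making the refit identical to the unadjusted fit. The
two-class model is intentional: it captures the mechanism of
reference-based deconvolution without importing an external reference
panel; multi-cell-type extensions are out of scope.

## Regions and runs

Regions are gene × feature-category groups plus CpG islands (maximal
runs of consecutive Island-annotated probes on one chromosome); a probe
may serve several regions, and regions need at least two members. The
region summary is the unweighted mean M-value of members — the simplest
defensible choice, and the one a mean-based oracle can check — tested
with the same linear model and BH across regions. Aggregation trades
probe-level resolution for power: a coordinated shift of −0.02 beta
across eight adjacent probes is individually sub-threshold but
region-significant in most simulation replicates, which the tests
demonstrate. `find_runs()` separately reports maximal runs of
genomically consecutive, nominally significant, same-direction probes;
runs are descriptive (they inherit the owning region's FDR) rather than
an independent inferential procedure. BED export converts the 1-based
inclusive annotation to 0-based half-open intervals with
`score = −10·log10(q)` capped at 1000.

## Co-methylation networks

The network pipeline is unsigned WGCNA-style: Pearson correlation →
adjacency `|r|^power` (default power 6, the conventional choice for
unsigned networks) → topological overlap
`TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)` →
average-linkage clustering of `1 − TOM` → static cut → small clusters
to grey → eigengene-based merging of near-duplicate modules
(`cor(ME) > 1 − merge_height`, default 0.25) → size-ranked color
labels. Blocks of at most `block_size` (default 20,000) probes are
pre-clustered by k-means when the matrix exceeds one block.

Two deliberate departures from the WGCNA defaults:

- **Static cut at height 0.9** instead of the dynamic hybrid tree cut.
  The dynamic cut's parameters interact opaquely; a static cut is
  auditable, and its height can be reasoned about: coherent modules
  (pairwise |r| ≥ 0.7) merge below `1 − TOM ≈ 0.88`, while background
  probes whose chance correlation with a module factor reaches
  |r| ≈ 0.3–0.45 attach only above ≈ 0.9. Cutting at 0.9 therefore
  keeps modules down to coherence ~0.7 intact without accreting
  background. Heights of 0.95 and above measurably pollute planted
  modules with background probes; the recovery tests (adjusted Rand
  index > 0.9 on planted instances, ≥95% grey on pure noise) pin the
  behaviour.
- **Simplified module preservation.** Full preservation aggregates
  many statistics; here each discovery module gets two — the absolute
  correlation between discovery and test-cohort kME over the members,
  and the mean absolute intra-module correlation (density) in the test
  cohort — each converted to a permutation Z against random same-size
  probe sets drawn in the test cohort by the *identical* code path,
  composited as the median. kME correlation is taken in absolute value
  because an eigengene's sign is arbitrary for modules holding both
  positively and negatively loaded probes, and a cohort-to-cohort sign
  flip would otherwise report a perfectly preserved module as
  anti-preserved. When test data duplicate the discovery data the kME
  statistic is degenerately 1 for every probe set; its Z is then
  defined as 0 (observed equals the null mean) so the composite falls
  back to the density Z and stays finite.

Module-trait association defaults to marginal Pearson correlation of
each eigengene with each trait (diagnosis coded CTL=0/SZ=1, sex
M=0/F=1; p from the t distribution on n−2 df), with a
covariate-adjusted regression variant available — both are provided
because either convention is common and they answer slightly different
questions. Probe significance versus module membership uses |kME|, for
the same sign-arbitrariness reason as above.

## Replication and developmental enrichment

Replication takes the top-k discovery probes by p (default 100),
recomputes beta-scale group differences at matched probes in the
replication cohort, and reports Pearson r, its two-sided p and sign
concordance; missing probes are dropped and counted. Beta-scale
differences (not M-scale coefficients) are the default effect measure
because cross-cohort comparability of raw methylation differences is
the point; the coefficient variant sits behind a flag.

Developmental enrichment asks whether a target probe set tracks fetal
age more often than chance: per-probe Pearson correlation with days
post-conception, BH *within the probe set* (set-local FDR, so a random
98-probe draw and the observed 98-probe target face the same
procedure — the same counting function literally runs for both), and an
empirical one-tailed p over `n_perm` random same-size draws from the
universe, `p = (1 + #{null ≥ observed})/(1 + n_perm)`. The `+1`
correction avoids reporting p = 0 and costs at most one permutation
count relative to the uncorrected convention; the tail is inclusive
(`≥`) because ties in null counts are common with small sets. The
universe defaults to all probes in the fetal matrix; passing the
post-QC autosomal set is recommended and is what the pipeline does.

## What the generator emulates — and what it does not

`sim_config()` defaults describe the emulated study: 20/23 SZ/CTL
discovery PFC samples (21/23 cerebellum, 18/15 replication), 179 fetal
samples aged 23–184 days post-conception, trimodal baselines (mixture
of Beta(2,20), Beta(5,5), Beta(20,2)), planted DMP effects of
`delta_beta = 0.05` (the 0.02–0.09 range typical of brain case-control
differences), modules of 100 probes from shared latent factors with
loadings 0.08–0.14 (half of them shifted one factor-SD by diagnosis),
neuron/glia reference profiles separated by ≥0.2 beta at 10% marker
probes, neuronal proportions uniform on 0.25–0.65, beta-scale Gaussian
noise with `noise_sd = 0.03`, detection-p/beadcount failures injected
at 5%/1%, and a replication cohort whose disease effects (probe-level
and module-level) are attenuated by 0.5. Intensities are drawn so that
`M/(M+U+100)` reproduces the target beta exactly (total intensity
lognormal around 5000, inflated where needed to keep `U ≥ 0`), and
noise is added on the beta scale then clipped to `[0.001, 0.999]` —
heteroscedasticity near the bounds then arises naturally after the
M-transform.

Injected QC failures avoid planted DMP, module and marker probes, so
quality control cannot silently delete the planted truth a test is
about to look for; the injections are themselves recorded in `truth`
and the QC tests verify they are caught.

Deliberately **not** emulated: batch and chip-position effects, probe
cross-reactivity beyond the SNP flag, genotype structure, IDAT-level
signal artifacts, nonlinear developmental trajectories, and spatial
correlation between neighbouring probes outside planted modules.
Passing tests therefore certify the pipeline's statistical machinery —
calibration under the null, recovery of known effects, exact rule
boundaries — not robustness to the technical artifacts of real arrays.
On real data the QC and normalization stages face distributional
violations the generator never produces.

## Numerical choices and degenerate inputs

- Beta clipping `ε = 0.001` before the logit; inverse transform used
  for group means when no beta matrix is supplied.
- Residual variances below 1e-12 are treated as degenerate (NA
  statistics, logged); the trigamma-inverse Newton iteration runs to a
  relative tolerance of 1e-8.
- `bh_adjust` breaks p-value ties by stable original order; q-values
  cap at 1.
- The 2-means sex check initializes centers at the observed extremes,
  making it deterministic.
- Eigengenes are unit-variance and sign-oriented so the mean member
  correlation is positive; zero-variance probes are excluded with a
  warning, and a module reduced below two variable probes is an error.
- Permutation p has floor `1/(n_perm + 1)`; fewer than 100 permutations
  warns.
- All generator streams derive child seeds from the master seed by a
  fixed integer recurrence (kept below 2³¹), so discovery, replication
  and fetal cohorts share planted structure while drawing independent
  noise, and every run is byte-reproducible from the config.

## Problem sizes

The test suite and acceptance script run at sizes chosen to make every
statistical claim measurable in seconds to a couple of minutes: null
calibration on 5,000 probes × 40 samples, module recovery on 1,000
probes × 43 samples, permutation-uniformity over 200 repetitions at 500
permutations, power and replication checks over 15–20 replicates at
600–1,500 probes, and the full-pipeline acceptance run at 4,000 probes
with 100 planted DMPs, four modules and 10,000 enrichment permutations.
These sizes are scaled-down but structurally faithful versions of a
450K analysis; nothing in the implementation assumes them, and
`block_size` exists precisely so full-array matrices decompose.

## Known limitations

- The dasen approximation's median-shift background step is cruder
  than a fitted background offset; on real intensity distributions the
  two can differ near the background floor.
- The static tree cut trades the dynamic cut's adaptivity for
  auditability; highly heterogeneous module coherence within one
  dataset may favour the dynamic cut.
- Preservation Z-scores from 100 permutations have coarse resolution;
  raise `n_perm` for publication-grade preservation claims.
- The two-class composition model cannot represent more than two cell
  populations; estimates are projections onto the neuron/glia axis.
- Enrichment assumes exchangeability of probes within the universe;
  restricting the universe (for example to autosomal post-QC probes
  matched on variance) is the user's responsibility where
  exchangeability is doubtful.
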