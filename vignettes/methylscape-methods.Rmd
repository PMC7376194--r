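---
title: "methylscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscape)
```

# Scope and data model

`methylscape` analyses paired tumor/normal whole-genome bisulfite
sequencing at single-CpG resolution. The central object is a
`methylome_matrix`: CpG loci (rows, sorted by chromosome and position)
by samples (columns), holding methylation ratios in [0, 1] and optional
read coverages, with a two-level cohort label per sample. All genomic
coordinates in the package are 0-based half-open (BED-native); a CpG
locus is identified by the position of the C on the + strand, and the
strand column is carried but not used by any statistic, since CpG
dinucleotides are measured symmetrically. Missing measurements are
explicit `NA`s, never zeros — a 0 is a real, fully unmethylated
observation.

# Differential methylation

**Filtering.** `filter_matrix()` retains exactly the loci where every
sample has a present ratio and (when coverages exist) at least
`min_cov = 5` reads. The threshold is inclusive and the completeness
requirement is strict: a single missing sample drops the locus. This
mirrors the standard practice of testing only "confident" CpGs and makes
every downstream test a complete-case test.

**Per-CpG test.** `call_dmcs()` applies a classical one-way fixed-effects
ANOVA per locus (for two cohorts, F is exactly the squared pooled
two-sample t statistic — a property the test suite asserts on random
instances). P-values are Benjamini–Hochberg adjusted over all tested
loci — the post-filter universe is the multiplicity family — and loci
with q < `alpha_q` (default 0.05) are reported with direction `hyper`
(tumor mean above normal mean) or `hypo`. A locus with Δ = 0 cannot be
significant, since Δ = 0 between two cohorts forces F = 0 and p = 1; this
is documented rather than special-cased. The equal-variance assumption of
the pooled ANOVA is knowingly violated when tumor noise is larger; with
balanced cohorts the test is robust to this, which the null-calibration
test verifies empirically (the q < 0.05 call rate on a zero-effect study
stays within binomial slack of the nominal level).

**Heterogeneity.** Two per-CpG dispersion measures are computed per
cohort: the unbiased sample variance, and Shannon entropy of the
methylation-level histogram over ten equal bins on [0, 1] (last bin
right-closed, so 1.0 is counted). Entropy is reported in nats — the
convention of the numerical libraries this analysis style descends
from — and is bounded by ln 10 ≈ 2.303. Entropy is invariant to
perturbations that do not cross a bin edge; with ten samples per cohort
it is a coarse but robust spread measure.

**TSS metaprofile.** Each CpG is assigned a strand-aware signed distance
to the nearest TSS (upstream negative) and binned into 200-bp windows
across ±15 kb. Per-bin cohort means are z-normalized across bins; the
package uses the z-score because only the profile *shape* is
interpretable after per-cohort normalization, and a flat profile then
reads as all-zero.

# DMR construction

DMRs are built from the sorted DMC list by a single sweep: extend the
open region while the next DMC is on the same chromosome, within
`max_gap = 150` bp of the previous member (inclusive), and has the same
direction; close otherwise; emit regions with at least two members. The
150-bp gap is the minimal CpG-island size; requiring two members means
singleton DMCs are never regions. The region interval is
`[first, last + 1)` and CpG density is members/span.

A two-member region at the maximal gap has density 2/151 ≈ 0.0132, which
is the quantity `scripts/acceptance.R` recomputes and is above the 0.01
floor usually quoted for such constructions. The general per-region
bound is k/((k−1)·150 + 1) for k members — *decreasing* in k toward
1/150 ≈ 0.0066 — so the 0.01 floor is a property of short chains, not of
every region; the property tests assert the exact per-k bound.

**Region significance.** The member ANOVA p-values within a region all
concern shifts of the same sign, so the default aggregation treats them
as direction-aligned one-sided evidence and combines them by Stouffer's
method, z = Σ qnorm(1 − pᵢ)/√k; the alternative `min_q` rule takes the
best member q Bonferroni-scaled by k. Region p-values are BH-adjusted
across regions. Stouffer is the default because it uses all members
rather than the extreme one; both are exposed since neither is canonical
for this construction.

# Enrichment statistics

- `annotate_sites()` labels each site with the first containing track in
  a fixed precedence order (promoter > exon > intron > enhancer > CGI by
  convention, configurable) — a site is counted once, so composition
  fractions sum to 1.
- `tfbs_enrichment_ratio()` is a composition ratio: each factor's share
  of TFBS-overlapping DMC sites over its share of total TFBS base pairs.
  The observed side is site-count weighted and the background is
  bp-weighted; this choice (over bp-weighting both sides) is documented
  because the convention is genuinely ambiguous in the field.
- `permutation_overlap_test()` relocates query elements uniformly and
  independently (lengths preserved, chromosome chosen
  length-proportionally) and reports z = (obs − mean)/sd and the
  add-one empirical p, which can never be below 1/(n_perm + 1). No
  gap/masking model is applied.
- `fisher_region_enrichment()` tiles the universe into 1-kb bins (the
  contingency population), tests each region set one-sided via the
  hypergeometric upper tail, computes OR = ad/bc with a Haldane 0.5
  correction on zero cells, and filters at p < 0.05 and OR > 2.
- `hypergeom_geneset()` is the textbook upper-tail over-representation
  test with Bonferroni scaling by the number of sets — Bonferroni, not
  BH, because gene-set families in this analysis style are traditionally
  reported that way, while the interval-enrichment families use BH.

# Methylome–transcriptome integration

Promoters are strand-aware −4500/+500 windows around the TSS, clipped at
zero. DEGs are called per gene by a Wilcoxon rank-sum test on
log2(TPM + 1) — exact when tie-free, normal approximation otherwise —
with BH adjustment and the conventional thresholds |log2FC| ≥ 1,
q < 0.05. The rank-sum test replaces a count-model fit deliberately: the
data model is TPM-level (no raw counts), and a distribution-free test is
self-contained and robust at n = 10 per cohort. The fold change uses a
pseudocount of 1 on mean TPM.

A gene is classified when a significant promoter DMR
(q_region ≤ `dmr_q_max`) and an up/down DEG call coincide. Of the two
region-significance thresholds in circulation for this style of
analysis (0.001 and 0.01) the package defaults to the laxer 0.01 and
leaves it configurable. When several DMRs overlap one promoter the
direction comes from the smallest q_region, ties broken by larger
|mean Δ|, then leftmost — a deterministic rule, since ties do occur in
discrete data. The quadrants are C1 = (hyper, down), C2 = (hypo, up)
(the canonical repression/activation pairs), and the non-canonical
C3 = (hyper, up), C4 = (hypo, down).

Survival stratification splits patients at the median of a
methylation-variance covariate (the median patient falls in the *low*
group, so the split is deterministic for odd n). The covariate is the
patient's mean squared deviation from the per-CpG cohort mean, averaged
over loci — one reasonable formalization of "variance of methylation
level per patient", chosen and documented because the quantity is
usually left under-specified. The Cox model (Efron ties) adjusts for
age, sex and alcohol and reports the Wald test and 95% CI on the
high-vs-low coefficient; all-censored inputs and separation are rejected
with clear errors rather than returning unstable estimates.

# The Ornstein–Uhlenbeck methylation model

Per-CpG methylation is modelled as dM = θ(μ − M)dt + σ dW with
equilibrium μ, restoring force θ (1/time) and noise σ = 0.04 — "4%" in
methylation-fraction units per √time. `simulate_ou()` integrates by
Euler–Maruyama, clipping to [0, 1] after each step; clipping is the
simplest boundary scheme for a fraction-valued process, and all variance
checks are restricted to regimes where μ ± 4·σ/√(2θ) lies inside the
unit interval so truncation is negligible. The integrator refuses
θ·dt ≥ 2 (explicit-Euler instability). Defaults dt = 0.01 and
n_steps = 10⁴ are declared, not derived — the source analysis style
does not fix them — as are θ_normal = 2 ("high", tight regulation) and
θ_tumor = 0.2 ("low", post-carcinogenic drift), giving stationary
standard deviations of 0.02 and 0.063.

`estimate_ou_params()` is the recovery oracle: an AR(1) least-squares
fit mapped back through θ = (1 − a)/dt, μ = b/(1 − a),
σ = sd(ε)/√dt. It is biased near the boundaries where clipping breaks
linearity; the acceptance checks therefore recover parameters only in
interior regimes (θ within ±20% at 10⁵ steps).

# The synthetic study and what it does (not) show

`sim_config()` defines the generated study conditions:

| parameter | default | role |
|---|---|---|
| chrom_length | 2 Mb | one synthetic chromosome |
| n_islands × island_length | 80 × 600 bp | CpG islands, rate 0.08 CpG/bp |
| background_cpg_rate | 0.006 CpG/bp | sparse background CpGs |
| n_genes | 160 | half with island TSSs |
| n_normal, n_tumor | 10, 10 | the paired-cohort scale |
| mu_island, mu_background | 0.1, 0.8 | bimodal baseline methylome |
| delta_hypo, delta_hyper | 0.3 | planted mean shifts |
| frac_hypo | 0.5 | background CpGs shifted down in tumor |
| frac_c1..c4 | 0.05/0.1875/0.075/0.1 | planted quadrant classes (8/30/12/16 genes) |
| theta_normal, theta_tumor, sigma | 2, 0.2, 0.04 | OU noise regimes |
| cov_mean, cov_dispersion | 30, 0.3 | negative-binomial coverage |
| lfc_mean | 2 | planted expression shift (log2) |
| n_patients, hr_true | 200, 1/0.36 | survival cohort and planted hazard ratio |

Sample values are drawn directly from the OU *stationary* law
N(μ, σ²/2θ) clipped to [0, 1] — marginally equivalent to integrating a
long trace per CpG and orders of magnitude faster; full traces are
exercised in the OU module's own tests. Coverage is negative binomial
with mean 30: with dispersion 0.3 this puts ~98.5% of per-sample
coverages at ≥ 5 reads, so the all-sample completeness filter retains
roughly three quarters of loci, matching the retention regime a real
deep-coverage WGBS study reports; a mean of 15 with the same dispersion
would let the 20-sample completeness requirement discard most of the
genome, which is a property of the filter, not of real data.

Hypermethylation is planted at C1/C3 promoter islands (0.1 → 0.4) and
hypomethylation at C2/C4 promoter islands; the latter are given a
*methylated* baseline (0.8 → 0.5) because an unmethylated island cannot
lose 0.3 of methylation — biologically these are the methylated,
silenced promoters that reactivate. Class genes are drawn from the
island-TSS half of the genes for the same reason. Expression is log2
TPM ~ N(baseline, 0.25²) with tumor means shifted ±2 by class; TFBS
tracks place one site per promoter with class-dependent probability
(0.9 in C3 for the PRC2-like and CTCF-like factors, 0.5 in C1, 0.2
elsewhere) plus a uniformly placed neutral factor. Survival patients
carry a small CpG panel whose noise level is set by a per-patient θ;
the realized panel variance is the stratification covariate and the
planted hazard multiplier is `hr_true` = 1/0.36 ≈ 2.78 for the
high-variance half, with exponential event times and uniform censoring
on (0, 2000) days.

The preset `sim_config_hypo_share()` re-balances these knobs
(frac_hypo = 0.95, two hyper-class and six hypo-class genes among 120)
so that the *expected* share of hypomethylated CpGs among all
differential CpGs is 97.3% — solved from the expected CpG counts of each
compartment before generation, emulating the canonical
majority-hypomethylation split. `sim_config_null()` zeroes every effect,
making the cohorts exchangeable.

What passing tests on this generator show: the pipeline recovers planted
mean shifts, directions, classes and hazard ratios at realistic effect
sizes and cohort sizes, and stays calibrated when nothing is planted.
What they do not show: robustness to read-level artifacts (bisulfite
conversion failure, mapping bias), coverage–methylation coupling,
between-patient heterogeneity of effect, copy-number confounding, or a
real genome's annotation geometry — none of which the generator
emulates.

# Numerical and engineering choices

- Interval overlap is delegated to IRanges behind the package's 0-based
  half-open data model; BH to `p.adjust`; hypergeometric tails to
  `phyper`; Cox fits to `survival::coxph`. Each of these sits behind the
  package's own function surface and is cross-checked in the tests
  against an independent brute-force oracle (all-pairs overlap, literal
  step-up enumeration, exact 2×2 enumeration, grid-search partial
  likelihood).
- Stouffer aggregation caps member p-values into [1e-300, 1 − 1e-16]
  to keep the normal quantile finite.
- All generators take explicit seeds and restore the caller's RNG
  state; stage seeds in the study generator are fixed offsets of the
  master seed, so every artifact is reproducible independently.
- Problem sizes in the shipped tests are desk-scale by design: ~15k CpGs
  for the default study, ~50k for the null-calibration run, 10⁵ steps
  for OU recovery; the full suite runs in well under a minute.

# Known limitations

- The ANOVA is unweighted by coverage; a beta-binomial or smoothing
  model would use the reads more efficiently but is out of scope.
- The AR(1) OU estimator is biased near the [0, 1] boundaries.
- The Fisher universe is an unmasked 1-kb tiling; assembly gaps or
  mappability are not modelled.
- The DMR sweep is a fixed-gap rule, not an HMM/changepoint caller, and
  density counts member DMCs, not all genomic CpGs in the span.
- `coexpression_null()` pools permutation correlations across genes,
  which assumes approximately exchangeable gene-wise null
  distributions.
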