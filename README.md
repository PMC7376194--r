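# methylscape

Differential methylation, methylation heterogeneity and
methylome–transcriptome integration for paired tumor/normal WGBS cohorts.

Whole-genome bisulfite sequencing of tumor and adjacent normal tissue yields
a matrix of per-CpG methylation ratios. Squamous tumors typically lose
methylation genome-wide while gaining it focally at CpG-island promoters,
and they do so with markedly increased cell-to-cell stochasticity.
`methylscape` packages the analysis chain that turns such a matrix, plus a
matched expression matrix and genome annotation, into interpretable calls:

- **DMCs** — per-CpG one-way ANOVA between cohorts
  (F with df (k−1, N−k)), Benjamini–Hochberg adjustment, loci with
  q < 0.05 called hyper- or hypomethylated from the sign of
  Δ = mean(tumor) − mean(normal), after a 5×-coverage/completeness filter.
- **DMRs** — maximal runs of same-direction DMCs with successive gaps
  ≤ 150 bp (the minimal CpG-island size), ≥ 2 members; density =
  members / span. Region-level significance by a direction-aligned
  Stouffer combination (or a Bonferroni-scaled min-q), BH across regions.
- **Heterogeneity** — per-CpG sample variance and Shannon entropy over a
  10-bin histogram of methylation levels (nats, bounded by ln 10), with
  cohort comparisons; per-patient variance covariates for survival.
- **OU model** — per-CpG methylation dynamics as a bounded
  Ornstein–Uhlenbeck process dM = θ(μ − M)dt + σdW, integrated by
  Euler–Maruyama and clipped to [0,1]; stationary law N(μ, σ²/2θ); a high
  restoring force θ models tight normal-tissue regulation, a low θ the
  noisier tumor state. An AR(1) fit recovers (θ, μ, σ) from traces.
- **Enrichment** — annotation composition by precedence, TFBS
  proportion-ratio enrichment, permutation Z-scores for interval overlap,
  Fisher's exact region-set tests over a 1-kb binned universe
  (filter p < 0.05 and OR > 2), promoter binding-site counting per gene
  cluster, hypergeometric gene-set tests with Bonferroni correction.
- **Integration** — promoters as strand-aware −4500/+500 TSS windows;
  DEGs by Wilcoxon rank-sum on log2(TPM+1) with |log2FC| ≥ 1 and q < 0.05;
  genes with a significant promoter DMR *and* a DEG call are classified
  into quadrants C1 (hyper, down), C2 (hypo, up), C3 (hyper, up),
  C4 (hypo, down); Cox proportional-hazards survival analysis after a
  median split on methylation variance.
- **Synthetic cohorts** — a seeded generator producing a full study
  (genome, methylomes via the OU stationary law, coupled expression, TFBS
  tracks, survival) with a ground-truth manifest, so every stage is
  testable without external data.

## Worked example

```r
library(methylscape)

cfg   <- sim_config(seed = 7)          # the default synthetic study
study <- simulate_study(cfg)

m    <- filter_matrix(study$methylome, min_cov = 5)
dmcs <- call_dmcs(m, alpha_q = 0.05)
dmrs <- aggregate_dmr_significance(build_dmrs(dmcs, max_gap = 150), dmcs)

genes <- study$genome$genes[, 1:6]
quad  <- classify_quadrants(dmrs, promoter_windows(genes),
                            call_degs(study$expression))

sv  <- stratify_by_variance(setNames(study$survival$survival$variance,
                                     study$survival$survival$patient_id),
                            study$survival$survival)
fit <- fit_cox(sv, covariates = c("age", "sex", "alcohol"))
```

Output:

```
methylome_matrix: 15464 CpG loci x 20 samples (10 normal, 10 tumor)
# after filter_matrix: 11379 CpG loci x 20 samples
6229 DMCs: 86.7% hypo, 13.3% hyper
824 DMRs; median span 92 bp; median density 0.028
quadrants: C1 8, C2 30, C3 12, C4 16
high- vs low-variance HR = 2.70 (95% CI 1.90-3.85), Wald p = 3.2e-08
```

Reading the numbers: the filter keeps the ~74% of CpGs covered ≥ 5× in
every sample; the DMC direction split reflects the generator's
majority-hypomethylation design; the 66 quadrant genes recover the planted
C1–C4 classes (8/30/12/16); and the Cox fit recovers the planted
high-variance hazard ratio (truth 2.78, the generator's default) with a
confidence interval that covers it.

The whole pipeline also runs as one call writing TSV/BED/JSON artifacts:

```r
run_pipeline(list(sim = list(), seed = 1), outdir = "out")
```

A thin command-line wrapper lives at `inst/scripts/methylscape.R`
(`run`, `simulate`, `simulate-ou` subcommands).

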