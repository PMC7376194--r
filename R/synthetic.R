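#' Configuration for the synthetic tumor/normal methylome study
#'
#' Defines the study conditions emulated by the generator: a single
#' synthetic chromosome carrying CpG islands (dense CpGs, unmethylated
#' baseline) over a methylated background; two cohorts of per-CpG
#' methylation ratios drawn from the stationary law of the bounded OU
#' process (high restoring force in normal tissue, low in tumor, so tumor
#' noise is larger); a majority-hypomethylated plus minority
#' focal-hypermethylated tumor mean shift; expression coupled to promoter
#' methylation through four quadrant classes (C1 hyper/down, C2 hypo/up,
#' C3 hyper/up, C4 hypo/down); TFBS tracks enriched at hypermethylated
#' promoters; and survival times linked to methylation variance.
#'
#' C1/C3 genes carry promoter islands at the unmethylated island baseline
#' that gain `delta_hyper` in the tumor; C2/C4 genes carry methylated
#' promoter islands (background baseline) that lose `delta_hypo`. Class
#' fractions are taken relative to `n_genes` but drawn from the island-TSS
#' half of the genes, since the shifts act on promoter island CpGs.
#'
#' @param chrom_length synthetic chromosome length in bp.
#' @param n_islands,island_length,island_cpg_rate CpG island count, width
#'   (bp) and within-island CpG rate (CpGs/bp).
#' @param background_cpg_rate background CpG rate (CpGs/bp).
#' @param n_genes total genes; half get island TSSs.
#' @param gene_length gene span in bp.
#' @param n_normal,n_tumor cohort sizes (>= 2).
#' @param frac_hypo fraction of eligible background CpGs mean-shifted down
#'   in tumor.
#' @param delta_hypo,delta_hyper methylation mean shifts (fractions).
#' @param frac_c1,frac_c2,frac_c3,frac_c4 quadrant class fractions of
#'   `n_genes`.
#' @param lfc_mean expression log2 fold-change magnitude for class genes.
#' @param theta_normal,theta_tumor,sigma OU parameters: restoring forces
#'   and noise level (stationary sd is `sigma / sqrt(2 theta)`).
#' @param mu_island,mu_background baseline equilibrium methylation of
#'   island and background CpGs.
#' @param cov_mean,cov_dispersion negative-binomial read coverage mean and
#'   dispersion (variance `= mu + dispersion mu^2`).
#' @param expr_baseline_mean,expr_baseline_sd,expr_noise_sd log2-TPM
#'   baseline distribution and per-sample noise.
#' @param tfbs_probs named list: per factor, a named vector of per-cluster
#'   site-placement probabilities (`other` = unclassed genes).
#' @param tfbs_width binding-site width in bp.
#' @param n_neutral_sites sites for the uniformly placed neutral factor.
#' @param n_enhancers,enhancer_length enhancer track geometry.
#' @param n_patients,hr_true,baseline_hazard,censor_horizon,n_survival_cpgs
#'   survival generator: cohort size, hazard ratio of the high-variance
#'   group, baseline exponential rate (1/days), censoring horizon (days),
#'   CpG panel size for the realized variance covariate.
#' @param seed master seed; stage seeds are derived from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chrom_length = 2e6,
                       n_islands = 80, island_length = 600,
                       island_cpg_rate = 0.08, background_cpg_rate = 0.006,
                       n_genes = 160, gene_length = 8000,
                       n_normal = 10, n_tumor = 10,
                       frac_hypo = 0.5, delta_hypo = 0.3, delta_hyper = 0.3,
                       frac_c1 = 0.05, frac_c2 = 0.1875,
                       frac_c3 = 0.075, frac_c4 = 0.1,
                       lfc_mean = 2,
                       theta_normal = 2, theta_tumor = 0.2, sigma = 0.04,
                       mu_island = 0.1, mu_background = 0.8,
                       cov_mean = 30, cov_dispersion = 0.3,
                       expr_baseline_mean = 5, expr_baseline_sd = 1,
                       expr_noise_sd = 0.25,
                       tfbs_probs = list(
                         EZH2 = c(C1 = 0.5, C2 = 0.2, C3 = 0.9, C4 = 0.2,
                                  other = 0.2),
                         SUZ12 = c(C1 = 0.5, C2 = 0.2, C3 = 0.9, C4 = 0.2,
                                   other = 0.2),
                         CTCF = c(C1 = 0.2, C2 = 0.2, C3 = 0.9, C4 = 0.2,
                                  other = 0.2)),
                       tfbs_width = 200, n_neutral_sites = 50,
                       n_enhancers = 30, enhancer_length = 1000,
                       n_patients = 200, hr_true = 1 / 0.36,
                       baseline_hazard = 1 / 1000, censor_horizon = 2000,
                       n_survival_cpgs = 500,
                       seed = 1) {
  cfg <- as.list(environment())
  fr <- c(frac_hypo, frac_c1, frac_c2, frac_c3, frac_c4)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0,1]")
  if (frac_c1 + frac_c2 + frac_c3 + frac_c4 > 1)
    stopf("class fractions must sum to at most 1")
  if (island_cpg_rate <= 0 || background_cpg_rate < 0)
    stopf("CpG rates must be positive")
  if (n_normal < 2 || n_tumor < 2) stopf("cohort sizes must be >= 2")
  if (theta_normal <= 0 || theta_tumor <= 0) stopf("theta must be > 0")
  structure(cfg, class = "sim_config")
}

#' Study conditions reproducing a 97.3% hypomethylated differential split
#'
#' Preset deriving from [sim_config()]: nearly all background CpGs are
#' mean-shifted down while only a handful of hypermethylated promoter
#' islands are planted, so the expected share of hypomethylated CpGs among
#' all differential CpGs is 97.3% (solved from the expected CpG counts of
#' each compartment before generation).
#'
#' @param ... overrides forwarded to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_hypo_share <- function(...) {
  sim_config(n_islands = 60, n_genes = 120,
             frac_hypo = 0.95,
             frac_c1 = 3 / 120, frac_c2 = 4 / 120,
             frac_c3 = 4 / 120, frac_c4 = 2 / 120, ...)
}

#' Null study conditions (no differential signal)
#'
#' All effect knobs at zero and equal restoring force in both cohorts: the
#' two cohorts are exchangeable. Used for calibration studies.
#'
#' @param ... overrides forwarded to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_null <- function(...) {
  args <- list(frac_hypo = 0, delta_hypo = 0, delta_hyper = 0,
               frac_c1 = 0, frac_c2 = 0, frac_c3 = 0, frac_c4 = 0,
               lfc_mean = 0, theta_tumor = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Generate the synthetic genome annotation
#'
#' CpG positions are placed by two Poisson processes: a background rate
#' over the whole chromosome and a higher rate within `n_islands`
#' non-overlapping island intervals. Half of the genes get their TSS at an
#' island centre (alternating strand), the rest are placed away from
#' islands. The promoter track is the -4500/+500 strand-aware TSS window;
#' CGI and enhancer tracks are emitted alongside. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return list with `cpgs` (`chrom`, `pos`, `strand`, `is_island`),
#'   `genes` (gene table plus `island_tss`), `tracks` (named interval
#'   list: `cgi`, `promoter`, `enhancer`), `chrom_length`, `config`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  exp_cpgs <- cfg$background_cpg_rate * cfg$chrom_length +
    cfg$island_cpg_rate * cfg$n_islands * cfg$island_length
  if (exp_cpgs > cfg$chrom_length)
    stopf("CpG rates imply more CpGs (%.0f) than base pairs", exp_cpgs)
  with_seed(cfg$seed, {
    chrom <- "chrS"
    # non-overlapping islands: one per equal slot, margin at both ends
    islands <- NULL
    if (cfg$n_islands > 0) {
      slot <- cfg$chrom_length / cfg$n_islands
      lo <- 0.2 * slot
      hi <- 0.8 * slot - cfg$island_length
      if (hi <= lo) stopf("islands do not fit the chromosome")
      starts <- (seq_len(cfg$n_islands) - 1) * slot +
        floor(runif(cfg$n_islands, lo, hi))
      islands <- intervals(chrom, starts, starts + cfg$island_length,
                           name = paste0("cgi", seq_len(cfg$n_islands)))
    }
    in_island <- function(pos) {
      if (is.null(islands)) return(rep(FALSE, length(pos)))
      hit <- rep(FALSE, length(pos))
      for (i in seq_len(nrow(islands)))
        hit <- hit | (pos >= islands$start[i] & pos < islands$end[i])
      hit
    }
    island_cpgs <- numeric(0)
    if (cfg$n_islands > 0) {
      counts <- rpois(cfg$n_islands, cfg$island_cpg_rate * cfg$island_length)
      island_cpgs <- unlist(lapply(seq_len(cfg$n_islands), function(i)
        islands$start[i] +
          sort(sample.int(cfg$island_length, min(counts[i], cfg$island_length)) - 1)))
    }
    n_bg <- rpois(1, cfg$background_cpg_rate * cfg$chrom_length)
    bg <- sort(sample.int(cfg$chrom_length, min(n_bg, cfg$chrom_length)) - 1)
    bg <- bg[!in_island(bg)]
    bg <- setdiff(bg, island_cpgs)
    cpgs <- data.frame(chrom = chrom,
                       pos = c(island_cpgs, bg), strand = "+",
                       is_island = c(rep(TRUE, length(island_cpgs)),
                                     rep(FALSE, length(bg))))
    cpgs <- cpgs[order(cpgs$pos), , drop = FALSE]
    rownames(cpgs) <- NULL
    # genes: island TSSs first (alternating strand), then background TSSs
    n_isl_genes <- min(cfg$n_genes %/% 2, cfg$n_islands)
    n_bg_genes <- cfg$n_genes - n_isl_genes
    tss_isl <- if (n_isl_genes > 0)
      floor((islands$start + islands$end)[seq_len(n_isl_genes)] / 2) else numeric(0)
    # background TSSs at least 5.5 kb away from any island so their
    # promoters contain no island CpGs
    margin <- 5500
    forbidden <- if (!is.null(islands))
      cbind(islands$start - margin, islands$end + margin) else NULL
    ok_tss <- function(p) {
      if (is.null(forbidden)) return(rep(TRUE, length(p)))
      ok <- rep(TRUE, length(p))
      for (i in seq_len(nrow(forbidden)))
        ok <- ok & !(p >= forbidden[i, 1] & p < forbidden[i, 2])
      ok
    }
    cand <- floor(runif(n_bg_genes * 10, cfg$gene_length + 1,
                        cfg$chrom_length - cfg$gene_length - 1))
    cand <- cand[ok_tss(cand)]
    if (length(cand) < n_bg_genes)
      stopf("could not place %d background genes", n_bg_genes)
    tss_bg <- sort(cand[seq_len(n_bg_genes)])
    tss <- c(tss_isl, tss_bg)
    island_tss <- c(rep(TRUE, n_isl_genes), rep(FALSE, n_bg_genes))
    strand <- rep(c("+", "-"), length.out = cfg$n_genes)
    genes <- data.frame(
      gene_id = sprintf("g%03d", seq_len(cfg$n_genes)),
      chrom = chrom, strand = strand, tss = tss,
      body_start = ifelse(strand == "+", tss,
                          pmax(tss - cfg$gene_length, 0)),
      body_end = ifelse(strand == "+",
                        pmin(tss + cfg$gene_length, cfg$chrom_length), tss),
      island_tss = island_tss, stringsAsFactors = FALSE)
    enh_start <- floor(runif(cfg$n_enhancers, 0,
                             cfg$chrom_length - cfg$enhancer_length))
    tracks <- list(
      cgi = if (!is.null(islands)) islands else
        intervals(character(0), numeric(0), numeric(0)),
      promoter = promoter_windows(genes[, setdiff(names(genes), "island_tss")]),
      enhancer = intervals(chrom, enh_start,
                           enh_start + cfg$enhancer_length,
                           name = paste0("enh", seq_len(cfg$n_enhancers))))
    list(cpgs = cpgs, genes = genes, tracks = tracks,
         chrom_length = stats::setNames(cfg$chrom_length, chrom),
         config = cfg)
  })
}

#' Generate the tumor/normal methylome cohorts with a truth manifest
#'
#' Baseline equilibrium methylation is `mu_island` for island CpGs and
#' `mu_background` otherwise, except that C2/C4 promoter islands start at
#' the methylated background baseline (so a hypomethylation shift is
#' representable). Normal samples draw from the OU stationary law with
#' `theta_normal`; tumor samples use `theta_tumor` and shifted means: a
#' `frac_hypo` subset of eligible background CpGs loses `delta_hypo`,
#' C1/C3 promoter island CpGs gain `delta_hyper`, C2/C4 promoter island
#' CpGs lose `delta_hypo`. Coverages are negative binomial. The manifest
#' records every planted shift with its direction and the per-gene class
#' assignment.
#'
#' @param genome output of [make_genome()].
#' @param config the same [sim_config()].
#' @return list with `methylome` (a `methylome_matrix`) and `manifest`
#'   (list: `cpg` truth table, `genes` class table, `n_clipped`).
#' @export
make_methylome_cohort <- function(genome, config) {
  cfg <- config
  cp <- genome$cpgs
  genes <- genome$genes
  with_seed(cfg$seed + 101L, {
    n_cls <- round(cfg$n_genes *
                     c(C1 = cfg$frac_c1, C2 = cfg$frac_c2,
                       C3 = cfg$frac_c3, C4 = cfg$frac_c4))
    isl_genes <- genes$gene_id[genes$island_tss]
    if (sum(n_cls) > length(isl_genes))
      stopf("class fractions require %d island-TSS genes but only %d exist",
            sum(n_cls), length(isl_genes))
    picked <- sample(isl_genes, sum(n_cls))
    cls <- rep(names(n_cls), n_cls)
    gene_class <- stats::setNames(rep("null", cfg$n_genes), genes$gene_id)
    gene_class[picked] <- cls
    prom <- promoter_windows(genes[, setdiff(names(genes), "island_tss")])
    siv <- sites_as_intervals(cp)
    hits <- overlap(siv, prom)
    cls_of_prom <- gene_class[prom$name]
    # per CpG: class of containing class-gene promoter (if any)
    cpg_class <- rep(NA_character_, nrow(cp))
    for (cl in c("C1", "C2", "C3", "C4")) {
      h <- hits[cls_of_prom[hits$subject] == cl, , drop = FALSE]
      cpg_class[h$query] <- cl
    }
    in_class_prom <- !is.na(cpg_class)
    mu_n <- ifelse(cp$is_island, cfg$mu_island, cfg$mu_background)
    # methylated promoter islands for the hypo classes
    hypo_cls <- in_class_prom & cpg_class %in% c("C2", "C4") & cp$is_island
    mu_n[hypo_cls] <- cfg$mu_background
    hyper_cls <- in_class_prom & cpg_class %in% c("C1", "C3") & cp$is_island
    mu_t <- mu_n
    mu_t[hyper_cls] <- mu_t[hyper_cls] + cfg$delta_hyper
    mu_t[hypo_cls] <- mu_t[hypo_cls] - cfg$delta_hypo
    eligible_bg <- which(!cp$is_island & !in_class_prom)
    n_shift <- round(cfg$frac_hypo * length(eligible_bg))
    bg_hypo <- if (n_shift > 0) sample(eligible_bg, n_shift) else integer(0)
    mu_t[bg_hypo] <- mu_t[bg_hypo] - cfg$delta_hypo
    n_clipped <- sum(mu_t < 0 | mu_t > 1)
    if (n_clipped > 0)
      warning(n_clipped, " tumor equilibrium values clipped into [0,1]")
    mu_t <- pmin(pmax(mu_t, 0), 1)
    n <- nrow(cp)
    ratios <- matrix(NA_real_, n, cfg$n_normal + cfg$n_tumor)
    for (j in seq_len(cfg$n_normal))
      ratios[, j] <- rstationary_ou(n, mu_n, cfg$theta_normal, cfg$sigma)
    for (j in seq_len(cfg$n_tumor))
      ratios[, cfg$n_normal + j] <-
        rstationary_ou(n, mu_t, cfg$theta_tumor, cfg$sigma)
    coverages <- matrix(rnbinom(n * ncol(ratios), mu = cfg$cov_mean,
                                size = 1 / cfg$cov_dispersion),
                        n, ncol(ratios))
    samples <- data.frame(
      sample_id = c(sprintf("N%02d", seq_len(cfg$n_normal)),
                    sprintf("T%02d", seq_len(cfg$n_tumor))),
      cohort = rep(c("normal", "tumor"), c(cfg$n_normal, cfg$n_tumor)))
    delta_mu <- mu_t - mu_n
    manifest <- list(
      cpg = data.frame(chrom = cp$chrom, pos = cp$pos,
                       is_island = cp$is_island,
                       differential = delta_mu != 0,
                       direction = ifelse(delta_mu > 0, "hyper",
                                          ifelse(delta_mu < 0, "hypo", "none")),
                       mu_normal = mu_n, mu_tumor = mu_t,
                       stringsAsFactors = FALSE),
      genes = data.frame(gene_id = genes$gene_id,
                         class = unname(gene_class),
                         true_lfc = ifelse(gene_class %in% c("C2", "C3"),
                                           cfg$lfc_mean,
                                           ifelse(gene_class %in% c("C1", "C4"),
                                                  -cfg$lfc_mean, 0)),
                         stringsAsFactors = FALSE),
      n_clipped = n_clipped)
    list(methylome = methylome_matrix(cp[, c("chrom", "pos", "strand")],
                                      ratios, coverages, samples),
         manifest = manifest)
  })
}

#' Generate the coupled expression matrix
#'
#' Per gene, log2 TPM is drawn as a gene baseline plus per-sample normal
#' noise; tumor samples of class genes are mean-shifted by the manifest's
#' true log2 fold change (+`lfc_mean` for C2/C3, -`lfc_mean` for C1/C4).
#'
#' @param genome output of [make_genome()].
#' @param manifest manifest from [make_methylome_cohort()].
#' @param config the same [sim_config()].
#' @return an `expression_matrix` with the methylome's sample sheet.
#' @export
make_expression <- function(genome, manifest, config) {
  cfg <- config
  genes <- genome$genes
  with_seed(cfg$seed + 202L, {
    nN <- cfg$n_normal; nT <- cfg$n_tumor
    base <- rnorm(nrow(genes), cfg$expr_baseline_mean, cfg$expr_baseline_sd)
    lfc <- manifest$genes$true_lfc[match(genes$gene_id,
                                         manifest$genes$gene_id)]
    lx <- matrix(rnorm(nrow(genes) * (nN + nT), 0, cfg$expr_noise_sd),
                 nrow(genes)) + base
    lx[, (nN + 1):(nN + nT)] <- lx[, (nN + 1):(nN + nT)] + lfc
    samples <- data.frame(
      sample_id = c(sprintf("N%02d", seq_len(nN)),
                    sprintf("T%02d", seq_len(nT))),
      cohort = rep(c("normal", "tumor"), c(nN, nT)))
    expression_matrix(genes$gene_id, 2^lx, samples)
  })
}

#' Generate synthetic TFBS tracks
#'
#' For each configured factor a binding site (width `tfbs_width`, centred
#' at the TSS) is placed in a gene's promoter with the per-cluster
#' probability from `tfbs_probs` (so e.g. the EZH2-like factor is enriched
#' in C3 promoters). An additional `NEUTRAL` factor is placed uniformly at
#' random, independent of gene class.
#'
#' @inheritParams make_expression
#' @return named list of interval `data.frame`s, one per factor plus
#'   `NEUTRAL`.
#' @export
make_tfbs_tracks <- function(genome, manifest, config) {
  cfg <- config
  genes <- genome$genes
  cls <- manifest$genes$class[match(genes$gene_id, manifest$genes$gene_id)]
  with_seed(cfg$seed + 303L, {
    tracks <- lapply(cfg$tfbs_probs, function(pv) {
      pr <- ifelse(cls %in% names(pv), pv[cls], pv[["other"]])
      hit <- rbinom(nrow(genes), 1, pr) == 1
      st <- pmax(genes$tss[hit] - cfg$tfbs_width %/% 2, 0)
      intervals(genes$chrom[hit], st, st + cfg$tfbs_width,
                name = genes$gene_id[hit])
    })
    nst <- floor(runif(cfg$n_neutral_sites, 0,
                       genome$chrom_length[[1]] - cfg$tfbs_width))
    tracks$NEUTRAL <- intervals(names(genome$chrom_length)[1], nst,
                                nst + cfg$tfbs_width,
                                name = paste0("n", seq_along(nst)))
    tracks
  })
}

#' Generate the survival table linked to methylation variance
#'
#' Each patient carries a small CpG panel whose stationary noise level is
#' set by a per-patient restoring force: half the patients get
#' `theta_normal` (low variance), half `theta_tumor` (high variance). The
#' variance covariate is the realized mean squared deviation of the
#' patient's panel from the per-CpG population mean. The hazard is
#' `baseline_hazard * hr_true^[high-variance]` with exponential event
#' times and uniform censoring on `(0, censor_horizon)`.
#'
#' @inheritParams make_expression
#' @return list with `survival` (a survival `data.frame` with `variance`,
#'   `age`, `sex`, `alcohol`) and `truth` (`patient_id`, `high_variance`,
#'   `hazard`).
#' @export
make_survival <- function(manifest, config) {
  cfg <- config
  with_seed(cfg$seed + 404L, {
    n <- cfg$n_patients
    L <- cfg$n_survival_cpgs
    high <- rep(c(FALSE, TRUE), length.out = n)
    theta <- ifelse(high, cfg$theta_tumor, cfg$theta_normal)
    panel <- vapply(seq_len(n), function(i)
      rstationary_ou(L, 0.5, theta[i], cfg$sigma), numeric(L))
    mu_hat <- rowMeans(panel)
    variance <- colMeans((panel - mu_hat)^2)
    hazard <- cfg$baseline_hazard * cfg$hr_true^high
    tt <- rexp(n, rate = hazard)
    cens <- runif(n, 0, cfg$censor_horizon)
    surv <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      time_days = pmax(pmin(tt, cens), 1e-3),
      event = as.integer(tt <= cens),
      age = round(rnorm(n, 60, 8)),
      sex = rbinom(n, 1, 0.5),
      alcohol = rbinom(n, 1, 0.4),
      variance = variance)
    list(survival = surv,
         truth = data.frame(patient_id = surv$patient_id,
                            high_variance = high, hazard = hazard))
  })
}

#' Generate the complete synthetic study
#'
#' Runs [make_genome()], [make_methylome_cohort()], [make_expression()],
#' [make_tfbs_tracks()] and [make_survival()] under one config, optionally
#' writing every artifact in the package's on-disk formats.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory; created if missing.
#' @return list with `genome`, `methylome`, `manifest`, `expression`,
#'   `tfbs`, `survival`.
#' @export
simulate_study <- function(config = sim_config(), outdir = NULL) {
  genome <- make_genome(config)
  mc <- make_methylome_cohort(genome, config)
  expr <- make_expression(genome, mc$manifest, config)
  tfbs <- make_tfbs_tracks(genome, mc$manifest, config)
  surv <- make_survival(mc$manifest, config)
  study <- list(genome = genome, methylome = mc$methylome,
                manifest = mc$manifest, expression = expr, tfbs = tfbs,
                survival = surv)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(outdir, f)
    write_methylome(mc$methylome, fp("methylome.tsv"))
    write_sample_sheet(mc$methylome$samples, fp("samples.tsv"))
    write_gene_table(genome$genes[, setdiff(names(genome$genes), "island_tss")],
                     fp("genes.tsv"))
    write_expression(expr, fp("expression.tsv"))
    write_survival(surv$survival, fp("survival.tsv"))
    for (tn in names(genome$tracks))
      write_intervals(genome$tracks[[tn]], fp(paste0(tn, ".bed")))
    for (tn in names(tfbs))
      write_intervals(tfbs[[tn]], fp(paste0("tfbs_", tn, ".bed")))
    data.table::fwrite(mc$manifest$cpg, fp("truth_cpg.tsv"), sep = "\t")
    data.table::fwrite(mc$manifest$genes, fp("truth_genes.tsv"), sep = "\t")
  }
  study
}
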