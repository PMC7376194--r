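#' Promoter windows around transcription start sites
#'
#' The promoter is the strand-aware window from `up` bp upstream to `down`
#' bp downstream of the TSS (defaults 4500/500): `[tss - up, tss + down)`
#' on the + strand, `[tss - down, tss + up)` on the - strand, clipped at 0.
#'
#' @param genes gene table (see [read_gene_table()]).
#' @param up,down window extent in bp (defaults 4500 and 500).
#' @return interval `data.frame`, `name` = gene id, one row per gene.
#' @export
promoter_windows <- function(genes, up = 4500, down = 500) {
  genes <- validate_gene_table(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - up, genes$tss - down)
  end <- ifelse(plus, genes$tss + down, genes$tss + up)
  intervals(genes$chrom, pmax(start, 0), end, name = genes$gene_id,
            strand = genes$strand)
}

#' Call differentially expressed genes
#'
#' Per gene, a Wilcoxon rank-sum test compares tumor against normal
#' `log2(TPM + c)`; p-values are BH-adjusted across genes. The fold change
#' is `log2(mean tumor TPM + c) - log2(mean normal TPM + c)`. Status is
#' `up` when `log2fc >= lfc_min` and `q < alpha_q`, `down` symmetrically,
#' otherwise `ns`.
#'
#' @param e an `expression_matrix`.
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @param alpha_q q-value cutoff (default 0.05).
#' @param pseudocount additive constant `c` (default 1).
#' @return `data.frame`: `gene_id`, `log2fc`, `p`, `q`, `status`.
#' @export
call_degs <- function(e, lfc_min = 1, alpha_q = 0.05, pseudocount = 1) {
  stopifnot(inherits(e, "expression_matrix"))
  ni <- which(e$samples$cohort == "normal")
  ti <- which(e$samples$cohort == "tumor")
  if (length(ni) < 2 || length(ti) < 2)
    stopf("each cohort needs at least 2 samples")
  lx <- log2(e$tpm + pseudocount)
  log2fc <- log2(rowMeans(e$tpm[, ti, drop = FALSE]) + pseudocount) -
    log2(rowMeans(e$tpm[, ni, drop = FALSE]) + pseudocount)
  p <- vapply(seq_along(e$gene_ids), function(i) {
    a <- lx[i, ti]; b <- lx[i, ni]
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
    # exact null distribution when there are no ties, normal approx otherwise
    suppressWarnings(wilcox.test(a, b)$p.value)
  }, numeric(1))
  q <- bh_adjust(p)
  status <- rep("ns", length(p))
  status[log2fc >= lfc_min & q < alpha_q] <- "up"
  status[log2fc <= -lfc_min & q < alpha_q] <- "down"
  data.frame(gene_id = e$gene_ids, log2fc = log2fc, p = p, q = q,
             status = status, stringsAsFactors = FALSE)
}

#' Classify genes into promoter-methylation x expression quadrants (C1-C4)
#'
#' A gene enters the classification when at least one significant DMR
#' (`q_region <= dmr_q_max`) overlaps its promoter and the gene is an
#' up/down DEG. The promoter methylation direction is taken from the
#' overlapping DMR with the smallest `q_region` (ties: larger
#' `|mean_delta|`, then leftmost). Quadrants: C1 = (hyper, down),
#' C2 = (hypo, up), C3 = (hyper, up), C4 = (hypo, down).
#'
#' @param dmrs DMR table with `q_region` (see
#'   [aggregate_dmr_significance()]).
#' @param promoters promoter intervals (`name` = gene id, see
#'   [promoter_windows()]).
#' @param degs DEG table from [call_degs()].
#' @param dmr_q_max region-level significance cutoff (default 0.01).
#' @return list with `assignments` (`gene_id`, `prom_direction`,
#'   `expr_direction`, `cluster`) and `counts` (named C1-C4 vector).
#' @export
classify_quadrants <- function(dmrs, promoters, degs, dmr_q_max = 0.01) {
  if (!"q_region" %in% names(dmrs))
    stopf("dmrs lack q_region; run aggregate_dmr_significance() first")
  sig <- dmrs[dmrs$q_region <= dmr_q_max, , drop = FALSE]
  empty <- data.frame(gene_id = character(0), prom_direction = character(0),
                      expr_direction = character(0), cluster = character(0))
  counts0 <- stats::setNames(integer(4), paste0("C", 1:4))
  if (!nrow(sig))
    return(list(assignments = empty, counts = counts0))
  div <- intervals(sig$chrom, sig$start, sig$end, name = sig$direction)
  hits <- overlap(promoters, div)
  if (!nrow(hits))
    return(list(assignments = empty, counts = counts0))
  picks <- lapply(split(hits$subject, promoters$name[hits$query]), function(ix) {
    o <- order(sig$q_region[ix], -abs(sig$mean_delta[ix]), sig$start[ix])
    ix[o[1]]
  })
  prom <- data.frame(gene_id = names(picks),
                     prom_direction = sig$direction[unlist(picks)],
                     stringsAsFactors = FALSE)
  deg <- degs[degs$status %in% c("up", "down"), c("gene_id", "status")]
  names(deg)[2] <- "expr_direction"
  asg <- merge(prom, deg, by = "gene_id")
  asg$cluster <- quadrant_label(asg$prom_direction, asg$expr_direction)
  asg <- asg[order(asg$gene_id), , drop = FALSE]
  rownames(asg) <- NULL
  counts <- counts0
  tab <- table(asg$cluster)
  counts[names(tab)] <- as.integer(tab)
  list(assignments = asg, counts = counts)
}

quadrant_label <- function(prom_direction, expr_direction) {
  key <- paste(prom_direction, expr_direction)
  map <- c("hyper down" = "C1", "hypo up" = "C2",
           "hyper up" = "C3", "hypo down" = "C4")
  unname(map[key])
}

#' Promoter versus gene-body methylation contrast per cluster
#'
#' For each classified gene, averages DMC deltas falling in its promoter
#' and in its gene body (gene span minus the promoter window), summarizes
#' per cluster, and compares the C1 and C3 body means with a two-group
#' one-way ANOVA. Genes without body DMCs are excluded from the body
#' summary and counted.
#'
#' @param dmcs DMC table from [call_dmcs()].
#' @param genes gene table.
#' @param clusters named character vector gene id -> cluster.
#' @param up,down promoter window (defaults 4500/500).
#' @return list with `per_gene`, `per_cluster`, `c1_vs_c3_body`
#'   (`c(f_stat, p)` or `NULL`), `n_no_body_dmcs`.
#' @export
genebody_promoter_contrast <- function(dmcs, genes, clusters,
                                       up = 4500, down = 500) {
  genes <- validate_gene_table(genes)
  genes <- genes[genes$gene_id %in% names(clusters), , drop = FALSE]
  if (!nrow(genes)) stopf("no genes with cluster assignments")
  prom <- promoter_windows(genes, up, down)
  siv <- sites_as_intervals(data.frame(chrom = dmcs$chrom, pos = dmcs$pos))
  body <- intervals(genes$chrom, genes$body_start, genes$body_end,
                    name = genes$gene_id)
  ph <- overlap(prom, siv)
  bh <- overlap(body, siv)
  in_prom <- split(ph$subject, prom$name[ph$query])
  in_body_raw <- split(bh$subject, body$name[bh$query])
  per_gene <- data.frame(gene_id = genes$gene_id,
                         cluster = unname(clusters[genes$gene_id]),
                         prom_mean_delta = NA_real_,
                         body_mean_delta = NA_real_,
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(per_gene))) {
    g <- per_gene$gene_id[i]
    pm <- in_prom[[g]]
    bm <- setdiff(in_body_raw[[g]], pm)  # body = gene span minus promoter
    if (length(pm)) per_gene$prom_mean_delta[i] <- mean(dmcs$delta[pm])
    if (length(bm)) per_gene$body_mean_delta[i] <- mean(dmcs$delta[bm])
  }
  summarize <- function(v, cl) {
    ok <- !is.na(v)
    groups <- split(v[ok], cl[ok])
    data.frame(cluster = names(groups), n = lengths(groups),
               mean = vapply(groups, mean, numeric(1)),
               sd = vapply(groups, function(x)
                 if (length(x) > 1) sd(x) else NA_real_, numeric(1)),
               row.names = NULL)
  }
  per_cluster <- list(
    promoter = summarize(per_gene$prom_mean_delta, per_gene$cluster),
    body = summarize(per_gene$body_mean_delta, per_gene$cluster))
  bodies <- split(per_gene$body_mean_delta[!is.na(per_gene$body_mean_delta)],
                  per_gene$cluster[!is.na(per_gene$body_mean_delta)])
  test <- NULL
  if (all(c("C1", "C3") %in% names(bodies)) &&
      length(bodies$C1) >= 2 && length(bodies$C3) >= 2)
    test <- anova_f(bodies[c("C1", "C3")])
  list(per_gene = per_gene, per_cluster = per_cluster,
       c1_vs_c3_body = test,
       n_no_body_dmcs = sum(is.na(per_gene$body_mean_delta)))
}

#' Co-expression partners of a target gene by permutation null
#'
#' Computes the Pearson correlation of every gene with the target across
#' samples (on `log2(TPM + 1)`), builds a null distribution by correlating
#' each gene against `n_perm` sample-permuted copies of the target (pooled
#' across genes), assigns empirical two-sided p-values, BH-adjusts, and
#' returns genes with adjusted p below `alpha`. Zero-variance genes are
#' excluded with a note.
#'
#' @param e an `expression_matrix` with >= 4 samples.
#' @param target gene id to correlate against.
#' @param n_perm permutations (default 1000).
#' @param alpha adjusted-p cutoff (default 0.01).
#' @param seed RNG seed.
#' @return list with `table` (all testable genes: `gene_id`, `r`, `p`,
#'   `q`), `significant` (gene ids with `q < alpha`), `n_excluded`.
#' @export
coexpression_null <- function(e, target, n_perm = 1000, alpha = 0.01,
                              seed = 1) {
  stopifnot(inherits(e, "expression_matrix"))
  if (ncol(e$tpm) < 4) stopf("need at least 4 samples")
  ti <- match(target, e$gene_ids)
  if (is.na(ti)) stopf("unknown target gene '%s'", target)
  lx <- log2(e$tpm + 1)
  tv <- lx[ti, ]
  if (sd(tv) == 0) stopf("target gene has zero variance")
  ok <- apply(lx, 1, sd) > 0
  ok[ti] <- FALSE
  n_excluded <- sum(!ok) - 1L
  x <- lx[ok, , drop = FALSE]
  r <- as.numeric(cor(t(x), tv))
  null_r <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(i)
      as.numeric(cor(t(x), sample(tv)))))
  })
  nn <- length(null_r)
  p <- vapply(abs(r), function(a) (1 + sum(abs(null_r) >= a)) / (nn + 1),
              numeric(1))
  q <- bh_adjust(p)
  tab <- data.frame(gene_id = e$gene_ids[ok], r = r, p = p, q = q,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$q, -abs(tab$r)), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, significant = tab$gene_id[tab$q < alpha],
       n_excluded = n_excluded)
}

#' Stratify patients by methylation variance and fit a Cox model
#'
#' `stratify_by_variance()` adds a `var_group` column: `high` when the
#' patient's methylation-variance covariate exceeds the median, else `low`
#' (the median patient falls in the low group). `fit_cox()` fits a Cox
#' proportional-hazards model (Efron ties) of survival on the group plus
#' any additional covariates and reports the hazard ratio of the group
#' coefficient with its Wald test and 95% CI.
#'
#' @param variance named numeric vector, one variance value per patient
#'   (names = patient ids).
#' @param surv survival `data.frame` (see [read_survival()]).
#' @return `stratify_by_variance()`: `surv` with `variance` and
#'   `var_group` columns.
#' @export
stratify_by_variance <- function(variance, surv) {
  surv <- validate_survival(surv)
  if (!all(surv$patient_id %in% names(variance)))
    stopf("variance values missing for some patients")
  v <- variance[surv$patient_id]
  surv$variance <- as.numeric(v)
  surv$var_group <- ifelse(surv$variance > median(surv$variance),
                           "high", "low")
  surv
}

#' @rdname stratify_by_variance
#' @param covariates character vector of extra covariate column names
#'   (e.g. `c("age", "sex", "alcohol")`).
#' @param group_col name of the grouping column (default `"var_group"`).
#' @return `fit_cox()`: list with `hr`, `ci95`, `wald_p`, `coef`, `fit`.
#' @export
fit_cox <- function(surv, covariates = character(0),
                    group_col = "var_group") {
  surv <- validate_survival(surv)
  if (all(surv$event == 0)) stopf("all observations censored; cannot fit")
  if (!group_col %in% names(surv)) stopf("missing column '%s'", group_col)
  surv[[group_col]] <- factor(surv[[group_col]], levels = c("low", "high"))
  fml <- stats::reformulate(c(group_col, covariates),
                            response = "survival::Surv(time_days, event)")
  # separation is detected below via the coefficient scale, so coxph's own
  # non-convergence warnings are redundant here
  fit <- suppressWarnings(survival::coxph(fml, data = surv, ties = "efron"))
  cf <- summary(fit)$coefficients
  row <- grep(paste0("^", group_col), rownames(cf))[1]
  beta <- cf[row, "coef"]; se <- cf[row, "se(coef)"]
  if (!is.finite(beta) || !is.finite(se) || se > 1e3)
    stopf("Cox fit did not converge (separation?)")
  list(hr = exp(beta),
       ci95 = exp(beta + c(-1, 1) * qnorm(0.975) * se),
       wald_p = cf[row, "Pr(>|z|)"],
       coef = beta, fit = fit)
}
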