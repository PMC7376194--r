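#' Coverage and completeness filter
#'
#' Retains exactly the CpG loci where every sample has a present methylation
#' ratio and, when coverages are available, a coverage of at least `min_cov`
#' reads (threshold inclusive). Locus order is preserved.
#'
#' @param m a `methylome_matrix`.
#' @param min_cov minimum per-sample read coverage (default 5).
#' @return filtered `methylome_matrix`.
#' @export
filter_matrix <- function(m, min_cov = 5) {
  stopifnot(inherits(m, "methylome_matrix"))
  if (min_cov < 1) stopf("min_cov must be >= 1")
  keep <- stats::complete.cases(m$ratios)
  if (!is.null(m$coverages))
    keep <- keep & apply(!is.na(m$coverages) & m$coverages >= min_cov, 1, all)
  methylome_matrix(m$loci[keep, , drop = FALSE],
                   m$ratios[keep, , drop = FALSE],
                   if (!is.null(m$coverages)) m$coverages[keep, , drop = FALSE],
                   m$samples)
}

#' One-way ANOVA F statistic and p-value
#'
#' Classical fixed-effects one-way analysis of variance over `k >= 2`
#' groups: `F = (SSB / (k - 1)) / (SSW / (N - k))`, p from the upper tail
#' of the F distribution with `(k - 1, N - k)` degrees of freedom. For two
#' groups F equals the square of the pooled-variance two-sample t
#' statistic. When every value is identical the convention `(F = 0, p = 1)`
#' is returned.
#'
#' @param groups list of two or more numeric vectors, each of length >= 2.
#' @return named vector `c(f_stat, p)`.
#' @export
anova_f <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stopf("need at least two groups")
  n <- lengths(groups)
  if (any(n < 2)) stopf("each group must have at least 2 values")
  k <- length(groups)
  N <- sum(n)
  gm <- vapply(groups, mean, numeric(1))
  grand <- sum(gm * n) / N
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - gm[i])^2),
                    numeric(1)))
  if (ssw == 0 && ssb == 0) return(c(f_stat = 0, p = 1))
  if (ssw == 0) return(c(f_stat = Inf, p = 0))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  c(f_stat = f, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}

# Vectorized two-group one-way ANOVA over matrix rows; same conventions as
# anova_f(). Used by call_dmcs where per-row loops would be prohibitive.
row_anova2 <- function(x_a, x_b) {
  na <- ncol(x_a); nb <- ncol(x_b); N <- na + nb
  ma <- rowMeans(x_a); mb <- rowMeans(x_b)
  grand <- (na * ma + nb * mb) / N
  ssb <- na * (ma - grand)^2 + nb * (mb - grand)^2
  ssw <- rowSums((x_a - ma)^2) + rowSums((x_b - mb)^2)
  f <- (ssb / 1) / (ssw / (N - 2))
  p <- pf(f, 1, N - 2, lower.tail = FALSE)
  zero <- ssw == 0 & ssb == 0
  f[zero] <- 0; p[zero] <- 1
  sat <- ssw == 0 & ssb > 0
  f[sat] <- Inf; p[sat] <- 0
  list(f = f, p = p, mean_a = ma, mean_b = mb)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns q-values in the input order: `q_(i) = min_{j >= i} m p_(j) / j`
#' capped at 1. Backed by [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Call differentially methylated CpGs (DMCs)
#'
#' Per retained locus a one-way ANOVA compares the normal and tumor ratio
#' vectors; p-values are BH-adjusted over all tested loci and loci with
#' `q < alpha_q` are reported, with direction `hyper` when the tumor mean
#' exceeds the normal mean and `hypo` otherwise. Run [filter_matrix()]
#' first.
#'
#' @param m a (filtered, complete) `methylome_matrix`.
#' @param alpha_q q-value cutoff (default 0.05).
#' @param keep_all also return non-significant loci (flagged) - used for
#'   calibration studies.
#' @return `data.frame` with columns `chrom`, `pos`, `mean_normal`,
#'   `mean_tumor`, `delta`, `f_stat`, `p`, `q`, `direction`; attribute
#'   `n_tested` carries the BH universe size.
#' @export
call_dmcs <- function(m, alpha_q = 0.05, keep_all = FALSE) {
  stopifnot(inherits(m, "methylome_matrix"))
  ni <- cohort_cols(m, "normal"); ti <- cohort_cols(m, "tumor")
  if (length(ni) < 2 || length(ti) < 2)
    stopf("each cohort needs at least 2 samples")
  if (any(is.na(m$ratios)))
    stopf("matrix contains missing ratios; run filter_matrix() first")
  a <- row_anova2(m$ratios[, ni, drop = FALSE], m$ratios[, ti, drop = FALSE])
  q <- bh_adjust(a$p)
  delta <- a$mean_b - a$mean_a
  res <- data.frame(chrom = m$loci$chrom, pos = m$loci$pos,
                    mean_normal = a$mean_a, mean_tumor = a$mean_b,
                    delta = delta, f_stat = a$f, p = a$p, q = q,
                    direction = ifelse(delta > 0, "hyper", "hypo"),
                    stringsAsFactors = FALSE)
  res$significant <- res$q < alpha_q
  if (!keep_all) {
    res <- res[res$significant, , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "n_tested") <- nrow(m$loci)
  res
}

#' Shannon entropy of per-CpG methylation levels
#'
#' Values are histogrammed over ten equal-width bins on `[0, 1]` (the last
#' bin right-closed), normalized to a probability vector, and the entropy
#' `-sum p ln p` is taken over non-empty bins. Reported in nats; bounded by
#' `ln(1 / bin_width)`.
#'
#' @param values methylation ratios in `[0, 1]`.
#' @param bin_width histogram bin width (default 0.10, i.e. ten bins).
#' @return entropy in nats.
#' @export
cpg_entropy <- function(values, bin_width = 0.10) {
  values <- values[!is.na(values)]
  if (!length(values)) stopf("no values supplied")
  nb <- round(1 / bin_width)
  idx <- pmin(floor(values / bin_width), nb - 1) + 1
  p <- tabulate(idx, nbins = nb) / length(values)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Per-CpG sample variance
#'
#' @param values numeric vector, length >= 2.
#' @return unbiased sample variance (denominator `n - 1`).
#' @export
cpg_variance <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stopf("variance needs at least 2 values")
  var(values)
}

#' Cohort heterogeneity profile: per-CpG variance and entropy
#'
#' Computes, per locus and per cohort, the sample variance and Shannon
#' entropy of methylation ratios, plus cohort summaries (mean and sd across
#' loci) and two-sample t-tests comparing tumor against normal across loci
#' for each metric. Higher tumor values indicate increased stochastic
#' methylation noise in the tumor cohort.
#'
#' @param m a complete `methylome_matrix` with >= 2 samples per cohort.
#' @param bin_width entropy bin width (default 0.10).
#' @return list with `per_locus` (`data.frame`), `summary`, and the two
#'   t-test results (`variance_test`, `entropy_test`).
#' @export
cohort_heterogeneity <- function(m, bin_width = 0.10) {
  stopifnot(inherits(m, "methylome_matrix"))
  ni <- cohort_cols(m, "normal"); ti <- cohort_cols(m, "tumor")
  if (length(ni) < 2 || length(ti) < 2)
    stopf("each cohort needs at least 2 samples")
  xn <- m$ratios[, ni, drop = FALSE]; xt <- m$ratios[, ti, drop = FALSE]
  var_n <- rowSums((xn - rowMeans(xn))^2) / (length(ni) - 1)
  var_t <- rowSums((xt - rowMeans(xt))^2) / (length(ti) - 1)
  ent_n <- apply(xn, 1, cpg_entropy, bin_width = bin_width)
  ent_t <- apply(xt, 1, cpg_entropy, bin_width = bin_width)
  per_locus <- data.frame(chrom = m$loci$chrom, pos = m$loci$pos,
                          var_normal = var_n, var_tumor = var_t,
                          entropy_normal = ent_n, entropy_tumor = ent_t)
  summ <- data.frame(
    cohort = c("normal", "tumor"),
    mean_variance = c(mean(var_n), mean(var_t)),
    sd_variance = c(sd(var_n), sd(var_t)),
    mean_entropy = c(mean(ent_n), mean(ent_t)),
    sd_entropy = c(sd(ent_n), sd(ent_t)))
  list(per_locus = per_locus, summary = summ,
       variance_test = t.test(var_t, var_n),
       entropy_test = t.test(ent_t, ent_n))
}

#' Per-patient methylation variance covariate
#'
#' For each sample, the mean squared deviation of its ratios from the
#' per-CpG mean of its own cohort, averaged over loci. Used to stratify
#' patients into high/low methylation-variance groups for survival
#' analysis.
#'
#' @param m a complete `methylome_matrix`.
#' @return named numeric vector, one value per sample.
#' @export
patient_variance <- function(m) {
  stopifnot(inherits(m, "methylome_matrix"))
  out <- numeric(nrow(m$samples))
  for (coh in c("normal", "tumor")) {
    ci <- cohort_cols(m, coh)
    x <- m$ratios[, ci, drop = FALSE]
    mu <- rowMeans(x)
    out[ci] <- colMeans((x - mu)^2)
  }
  stats::setNames(out, m$samples$sample_id)
}

#' Methylation metaprofile around transcription start sites
#'
#' Each CpG is assigned a strand-aware signed distance to the nearest TSS
#' (upstream negative), binned into `2 * span / bin` windows covering
#' `[-span, span)`; the per-bin mean ratio is computed per cohort and then
#' z-normalized across bins. Bins with no CpGs are `NA`.
#'
#' @param m a complete `methylome_matrix`.
#' @param genes gene table (see [read_gene_table()]).
#' @param span half-width of the window around the TSS in bp (default
#'   15000).
#' @param bin bin width in bp (default 200); must divide `span`.
#' @return list with `bin_start` (signed distances), `normal`, `tumor`
#'   (z-normalized profiles), `n_cpgs` per bin.
#' @export
tss_metaprofile <- function(m, genes, span = 15000, bin = 200) {
  stopifnot(inherits(m, "methylome_matrix"))
  genes <- validate_gene_table(genes)
  if (!nrow(genes)) stopf("genes must be non-empty")
  if (span %% bin != 0) stopf("bin (%d) must divide span (%d)", bin, span)
  nbins <- 2L * span %/% bin
  # nearest TSS per CpG, per chromosome
  dist <- rep(NA_real_, nrow(m$loci))
  for (ch in unique(m$loci$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    li <- which(m$loci$chrom == ch)
    if (!nrow(g) || !length(li)) next
    ord <- order(g$tss)
    tss <- g$tss[ord]; strand <- g$strand[ord]
    pos <- m$loci$pos[li]
    j <- findInterval(pos, tss)
    lo <- pmax(j, 1L); hi <- pmin(j + 1L, length(tss))
    use_hi <- abs(pos - tss[hi]) < abs(pos - tss[lo])
    nearest <- ifelse(use_hi, hi, lo)
    d <- pos - tss[nearest]
    d[strand[nearest] == "-"] <- -d[strand[nearest] == "-"]
    dist[li] <- d
  }
  inside <- !is.na(dist) & dist >= -span & dist < span
  idx <- floor((dist[inside] + span) / bin) + 1L
  profile_for <- function(cols) {
    mv <- rowMeans(m$ratios[inside, cols, drop = FALSE])
    means <- vapply(seq_len(nbins), function(b) {
      v <- mv[idx == b]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    mu <- mean(means, na.rm = TRUE); s <- sd(means, na.rm = TRUE)
    if (is.na(s) || s == 0) means * 0 else (means - mu) / s
  }
  list(bin_start = seq(-span, span - bin, by = bin),
       normal = profile_for(cohort_cols(m, "normal")),
       tumor = profile_for(cohort_cols(m, "tumor")),
       n_cpgs = tabulate(idx, nbins = nbins))
}
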