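test_that("coverage/completeness filter equals a brute-force row scan", {
  set.seed(3)
  n <- 60
  ratios <- matrix(runif(n * 4), n, 4)
  ratios[sample(length(ratios), 15)] <- NA
  cov <- matrix(rnbinom(n * 4, mu = 8, size = 3), n, 4)
  m <- toy_methylome(ratios, coverages = cov)
  f <- filter_matrix(m, min_cov = 5)
  keep <- vapply(seq_len(n), function(i)
    all(!is.na(m$ratios[i, ])) && all(m$coverages[i, ] >= 5), logical(1))
  expect_equal(nrow(f$loci), sum(keep))
  expect_equal(f$loci$pos, m$loci$pos[keep])
  # threshold is inclusive at exactly min_cov
  m2 <- toy_methylome(matrix(0.5, 1, 4), coverages = matrix(5, 1, 4))
  expect_equal(nrow(filter_matrix(m2, 5)$loci), 1)
  expect_error(filter_matrix(m, min_cov = 0), "min_cov")
})

test_that("one-way ANOVA matches hand sums of squares and the t-test oracle", {
  res <- anova_f(list(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)))
  expect_equal(unname(res["f_stat"]), 13.5, tolerance = 1e-12)
  expect_equal(unname(res["p"]), pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(anova_f(list(c(1, 1), c(1, 1))), c(f_stat = 0, p = 1))
  expect_error(anova_f(list(1, c(1, 2))), "at least 2")
  set.seed(10)
  for (i in 1:50) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    f <- anova_f(list(a, b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(unname(f["f_stat"]), unname(tt$statistic^2), tolerance = 1e-10)
    expect_equal(unname(f["p"]), tt$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.02, 0.04)),
               c(0.02, 0.02, 0.08 / 3, 0.04))
  expect_equal(bh_adjust(rep(0.03, 5)), rep(0.03, 5))
  set.seed(4)
  for (i in 1:100) {
    p <- runif(sample(1:6, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  p <- runif(20)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("DMC calling recovers planted direction and respects its invariants", {
  cfg <- sim_config(chrom_length = 4e5, n_islands = 16, n_genes = 32,
                    seed = 21)
  st <- simulate_study(cfg)
  dmcs <- call_dmcs(filter_matrix(st$methylome))
  expect_true(all(dmcs$q >= dmcs$p))
  expect_true(all((dmcs$direction == "hyper") == (dmcs$delta > 0)))
  expect_equal(sum(dmcs$direction == "hyper") + sum(dmcs$direction == "hypo"),
               nrow(dmcs))
  truth <- st$manifest$cpg
  key <- paste(dmcs$chrom, dmcs$pos)
  tkey <- paste(truth$chrom, truth$pos)
  dir_truth <- truth$direction[match(key, tkey)]
  called_true <- dir_truth != "none"
  # planted shifts dominate the calls and directions agree where planted
  expect_gt(mean(called_true), 0.9)
  expect_gt(mean(dmcs$direction[called_true] == dir_truth[called_true]), 0.99)
  expect_error(call_dmcs(toy_methylome(matrix(runif(8), 2, 4), n_normal = 1)),
               "at least 2")
})

test_that("per-CpG entropy follows the 10-bin Shannon definition", {
  expect_equal(cpg_entropy(c(0.31, 0.32, 0.33)), 0)
  expect_equal(cpg_entropy(seq(0.05, 0.95, by = 0.1)), log(10))
  expect_equal(cpg_entropy(c(0.05, 0.15, 0.25, 0.35)), log(4))
  # invariant to perturbations that stay inside a bin; bounded by ln 10
  expect_equal(cpg_entropy(c(0.11, 0.19, 0.41, 0.49)),
               cpg_entropy(c(0.15, 0.12, 0.45, 0.42)))
  set.seed(8)
  for (i in 1:20) expect_lte(cpg_entropy(runif(30)), log(10))
  # 1.0 falls in the last (right-closed) bin
  expect_equal(cpg_entropy(c(1, 1, 1)), 0)
  expect_error(cpg_entropy(numeric(0)), "no values")
})

test_that("variance and heterogeneity profiles detect designed tumor noise", {
  expect_equal(cpg_variance(c(0, 1)), 0.5)
  expect_equal(cpg_variance(rep(0.3, 5)), 0)
  expect_error(cpg_variance(0.5), "at least 2")
  cfg <- sim_config_null(theta_tumor = 0.2, chrom_length = 3e5,
                         n_islands = 10, n_genes = 10, seed = 9)
  st <- simulate_study(cfg)
  h <- cohort_heterogeneity(filter_matrix(st$methylome))
  expect_gt(h$summary$mean_variance[2], h$summary$mean_variance[1])
  expect_gt(h$summary$mean_entropy[2], h$summary$mean_entropy[1])
  expect_lt(h$variance_test$p.value, 0.01)
  expect_lt(h$entropy_test$p.value, 0.01)
})

test_that("TSS metaprofile bins are strand-aware and flat under uniformity", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = c("chr1", "chr2"),
                      strand = c("+", "-"), tss = 50000,
                      body_start = c(50000, 30000), body_end = c(70000, 50000))
  ratios <- matrix(0.5, 2, 4)
  m <- toy_methylome(ratios, pos = c(50050, 50050), chrom = c("chr1", "chr2"))
  prof <- tss_metaprofile(m, genes)
  expect_equal(length(prof$normal), 150)
  # + strand: TSS+50 -> bin covering [0,200) = index 76 (1-based)
  expect_equal(prof$bin_start[which(prof$n_cpgs == 1)],
               c(-200, 0))  # chr2 CpG reflects to -50; chr1 stays +50
  expect_true(all(prof$normal[!is.na(prof$normal)] == 0))
  expect_error(tss_metaprofile(m, genes, span = 15000, bin = 170), "divide")
})
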