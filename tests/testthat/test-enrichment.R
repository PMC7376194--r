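test_that("site annotation honours precedence and matches a brute-force scan", {
  tracks <- list(promoter = intervals("chr1", 0, 100),
                 intron = intervals("chr1", 50, 200))
  sites <- data.frame(chrom = "chr1", pos = c(60, 150, 500))
  ann <- annotate_sites(sites, tracks, precedence = c("promoter", "intron"))
  expect_equal(ann$labels, c("promoter", "intron", "unannotated"))
  expect_equal(sum(ann$composition$fraction), 1)
  expect_error(annotate_sites(sites, tracks, precedence = "enhancer"),
               "missing from tracks")
  set.seed(12)
  fuzz_tracks <- list(a = random_intervals(15, "chr1"),
                      b = random_intervals(15, "chr1"))
  fs <- data.frame(chrom = "chr1", pos = sample.int(1000, 80) - 1)
  ann2 <- annotate_sites(fs, fuzz_tracks, precedence = c("a", "b"))
  want <- vapply(seq_len(nrow(fs)), function(i) {
    for (tn in c("a", "b")) {
      tr <- fuzz_tracks[[tn]]
      if (any(fs$pos[i] >= tr$start & fs$pos[i] < tr$end)) return(tn)
    }
    "unannotated"
  }, character(1))
  expect_equal(ann2$labels, want)
  expect_equal(sum(ann2$composition$count), nrow(fs))
})

test_that("TFBS proportion-ratio enrichment follows the composition framing", {
  # factor A holds 5% of TFBS bp but receives 10% of TFBS-overlapping DMCs
  tracks <- list(A = intervals("chr1", 0, 50),
                 B = intervals("chr1", 1000, 1950))
  sites <- data.frame(chrom = "chr1",
                      pos = c(10, 20, seq(1010, 1180, by = 10)))
  res <- tfbs_enrichment_ratio(sites, tracks)
  expect_equal(res$bg_prop, c(0.05, 0.95))
  expect_equal(res$obs_prop, c(0.1, 0.9))
  expect_equal(res$ratio[res$factor_name == "A"], 2.0)
  # factor with no overlapping DMC
  tracks$C <- intervals("chr1", 5000, 5100)
  expect_equal(tfbs_enrichment_ratio(sites, tracks)$ratio[3], 0)
  expect_error(tfbs_enrichment_ratio(sites, list(Z = intervals("chr1", 0, 1)[0, ])),
               "zero total")
})

test_that("uniform random sites give near-neutral TFBS ratios", {
  set.seed(77)
  st <- seq(0, 90000, by = 10000)
  tracks <- list(A = intervals("chr1", st, st + 200),
                 B = intervals("chr1", st + 5000, st + 5800))
  n <- 4000
  sites <- data.frame(chrom = "chr1", pos = sample.int(1e5, n) - 1)
  res <- tfbs_enrichment_ratio(sites, tracks)
  # +-3 binomial sd around neutrality on the observed proportion
  for (i in 1:2) {
    tol <- 3 * sqrt(res$bg_prop[i] * (1 - res$bg_prop[i]) /
                      (res$n_sites[1] + res$n_sites[2]))
    expect_lt(abs(res$obs_prop[i] - res$bg_prop[i]), tol)
  }
})

test_that("permutation overlap test is calibrated, deterministic and seeded", {
  uni <- c(chr1 = 10000)
  q <- intervals("chr1", c(100, 5000), c(150, 5050))
  whole <- intervals("chr1", 0, 10000)
  full <- permutation_overlap_test(q, whole, uni, n_perm = 50, seed = 1)
  expect_equal(full$p, 1)
  expect_true(is.na(full$z))
  inside <- permutation_overlap_test(
    intervals("chr1", 100, 110), intervals("chr1", 90, 120),
    c(chr1 = 1e6), n_perm = 199, seed = 2)
  expect_equal(inside$p, 1 / 200)
  r1 <- permutation_overlap_test(q, intervals("chr1", 0, 3000), uni,
                                 n_perm = 100, seed = 3)
  r2 <- permutation_overlap_test(q, intervals("chr1", 0, 3000), uni,
                                 n_perm = 100, seed = 3)
  expect_identical(r1, r2)
  expect_gte(r1$p, 1 / 101)
})

test_that("Fisher region enrichment equals exact hypergeometric enumeration", {
  p_direct <- brute_fisher_p(30, 10, 10, 50)
  expect_equal(p_direct, phyper(29, 40, 60, 40, lower.tail = FALSE),
               tolerance = 1e-12)
  # engineered universe realizing the (30,10,10,50) table at 1 kb bins
  uni <- c(chr1 = 100000)
  bin_of <- function(i) intervals("chr1", (i - 1) * 1000, i * 1000 - 10)
  q_bins <- 1:40; s_bins <- c(1:30, 41:50)
  query <- do.call(rbind, lapply(q_bins, bin_of))
  set_iv <- do.call(rbind, lapply(s_bins, bin_of))
  res <- fisher_region_enrichment(query, list(S = set_iv), uni)
  expect_equal(res$table$a, 30)
  expect_equal(res$table$odds_ratio, 15)
  expect_equal(res$table$p, p_direct, tolerance = 1e-12)
  expect_equal(res$filtered$set, "S")
  # query identical to the set: maximal association
  res2 <- fisher_region_enrichment(query, list(Q = query), uni)
  expect_equal(res2$table$b, 0)
  expect_lt(res2$table$p, 1e-20)
  set.seed(15)
  for (i in 1:20) {
    N <- sample(20:200, 1)
    a <- sample.int(10, 1); b <- sample.int(10, 1); c_ <- sample.int(10, 1)
    d <- N - a - b - c_
    if (d < 0) next
    expect_equal(brute_fisher_p(a, b, c_, d),
                 phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("promoter site counting compares clusters and handles edge cases", {
  prom <- intervals("chr1", c(0, 10000, 20000), c(5000, 15000, 25000),
                    name = c("g1", "g2", "g3"))
  sites <- intervals("chr1", c(100, 600, 10100), c(300, 800, 10300))
  clusters <- c(g1 = "C3", g2 = "C1", g3 = "C1")
  res <- count_promoter_sites(prom, sites, clusters)
  expect_equal(res$per_gene$count, c(2, 1, 0))
  expect_equal(res$per_cluster$mean[res$per_cluster$cluster == "C3"], 2)
  none <- count_promoter_sites(prom, sites[0, ], clusters)
  expect_equal(none$per_gene$count, c(0, 0, 0))
  expect_null(none$anova)
})

test_that("hypergeometric gene-set test matches direct enumeration", {
  pop <- paste0("g", 1:20)
  res <- hypergeom_geneset(pop[1:5], pop[c(1:4, 10)], pop)
  expect_equal(unname(res["overlap"]), 4)
  expect_equal(unname(res["p"]), 76 / 15504, tolerance = 1e-12)
  expect_equal(unname(hypergeom_geneset(pop[1:5], pop[c(1:4, 10)], pop,
                                        n_sets = 100)["bonferroni_p"]),
               min(1, 100 * 76 / 15504))
  expect_equal(unname(hypergeom_geneset(pop[1], pop[2:4], pop)["p"]), 1,
               tolerance = 1e-9)
  expect_equal(unname(hypergeom_geneset(pop, pop[1:7], pop)["p"]), 1)
  expect_error(hypergeom_geneset(c(pop[1], "zz"), pop[1:2], pop), "subset")
})
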