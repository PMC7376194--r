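#' Annotate sites by precedence over named tracks
#'
#' Each site receives the label of the first track in `precedence` that
#' contains it, or `"unannotated"` when no track does. The composition
#' table gives the fraction of sites per label (fractions sum to 1).
#'
#' @param sites `data.frame` with `chrom`, `pos`.
#' @param tracks named list of interval `data.frame`s.
#' @param precedence ordered character vector of track names (default: the
#'   conventional promoter > exon > intron > enhancer > cgi order,
#'   restricted to the supplied tracks).
#' @return list with `labels` (per site) and `composition` (`data.frame`
#'   of counts and fractions).
#' @export
annotate_sites <- function(sites, tracks,
                           precedence = intersect(
                             c("promoter", "exon", "intron", "enhancer", "cgi"),
                             names(tracks))) {
  if (!all(precedence %in% names(tracks)))
    stopf("precedence names missing from tracks: %s",
          paste(setdiff(precedence, names(tracks)), collapse = ", "))
  siv <- sites_as_intervals(sites)
  labels <- rep("unannotated", nrow(sites))
  unset <- rep(TRUE, nrow(sites))
  for (tn in precedence) {
    if (!any(unset)) break
    hits <- overlap(siv, tracks[[tn]])
    hit_sites <- unique(hits$query)
    take <- hit_sites[unset[hit_sites]]
    labels[take] <- tn
    unset[take] <- FALSE
  }
  lv <- c(precedence, "unannotated")
  counts <- table(factor(labels, levels = lv))
  list(labels = labels,
       composition = data.frame(label = lv,
                                count = as.integer(counts),
                                fraction = as.numeric(counts) / nrow(sites)))
}

#' TFBS enrichment as a proportion ratio
#'
#' For each factor, the observed proportion is the share of
#' TFBS-overlapping DMC sites that fall in that factor's track; the
#' background proportion is the factor's share of total TFBS base pairs.
#' Enrichment is their ratio (1 = neutral).
#'
#' @param dmc_sites `data.frame` with `chrom`, `pos`.
#' @param tfbs_tracks named list of interval `data.frame`s, one per factor.
#' @return `data.frame` per factor: `factor_name`, `n_sites`, `obs_prop`,
#'   `bg_prop`, `ratio`.
#' @export
tfbs_enrichment_ratio <- function(dmc_sites, tfbs_tracks) {
  if (!length(tfbs_tracks)) stopf("no TFBS tracks supplied")
  bp <- vapply(tfbs_tracks, function(tr) sum(tr$end - tr$start), numeric(1))
  if (sum(bp) <= 0) stopf("zero total TFBS base pairs in background")
  siv <- sites_as_intervals(dmc_sites)
  n_in <- vapply(tfbs_tracks, function(tr)
    length(unique(overlap(siv, tr)$query)), numeric(1))
  in_any <- Reduce(union, lapply(tfbs_tracks, function(tr)
    unique(overlap(siv, tr)$query)), integer(0))
  denom <- length(in_any)
  obs <- if (denom > 0) n_in / denom else rep(0, length(n_in))
  bg <- bp / sum(bp)
  data.frame(factor_name = names(tfbs_tracks), n_sites = as.integer(n_in),
             obs_prop = obs, bg_prop = bg, ratio = obs / bg,
             row.names = NULL)
}

#' Permutation test for interval-set overlap
#'
#' The statistic is the number of query elements overlapping the subject
#' set. The null distribution relocates each query element uniformly and
#' independently (length-preserving) within the universe `n_perm` times.
#' `z = (obs - mean(null)) / sd(null)`; the empirical p-value is
#' `(1 + #[null >= obs]) / (n_perm + 1)`. Deterministic given `seed`.
#'
#' @param query interval `data.frame` (or sites with `chrom`, `pos`).
#' @param subject interval `data.frame`.
#' @param universe named numeric vector of chromosome lengths covering all
#'   inputs.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `obs`, `null_mean`, `null_sd`, `z` (`NA` when the
#'   null sd is 0), `p`, `n_perm`.
#' @export
permutation_overlap_test <- function(query, subject, universe,
                                     n_perm = 1000, seed = 1) {
  if (!is.null(query$pos) && is.null(query$start))
    query <- sites_as_intervals(query)
  query <- validate_intervals(query)
  subject <- validate_intervals(subject)
  if (!all(query$chrom %in% names(universe)) ||
      !all(subject$chrom %in% names(universe)))
    stopf("universe must name every chromosome used")
  if (any(query$end > universe[query$chrom]))
    stopf("query extends beyond the universe")
  count_hits <- function(q) length(unique(overlap(q, subject)$query))
  obs <- count_hits(query)
  widths <- query$end - query$start
  chroms <- names(universe)
  clen <- as.numeric(universe)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ci <- sample.int(length(chroms), nrow(query), replace = TRUE,
                       prob = clen / sum(clen))
      maxs <- clen[ci] - widths
      if (any(maxs < 0)) stopf("query element wider than a universe chromosome")
      st <- floor(runif(nrow(query), 0, maxs + 1))
      count_hits(data.frame(chrom = chroms[ci], start = st,
                            end = st + widths, name = ".", strand = "."))
    }, numeric(1))
  })
  mu <- mean(null); sdv <- sd(null)
  list(obs = obs, null_mean = mu, null_sd = sdv,
       z = if (sdv > 0) (obs - mu) / sdv else NA_real_,
       p = (1 + sum(null >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Fisher's exact region-set enrichment over a binned universe
#'
#' The universe is tiled into equal bins (default 1 kb) forming the
#' contingency population; for each region set a 2x2 table of bins
#' (query-overlap x set-overlap) is tested one-sided for enrichment via
#' the hypergeometric upper tail. The odds ratio is `(a d) / (b c)` with a
#' Haldane 0.5 correction when any cell is zero. The filtered output keeps
#' sets with `p < p_max` and `OR > or_min`.
#'
#' @param query interval `data.frame`.
#' @param region_sets named list of interval `data.frame`s.
#' @param universe named chromosome lengths.
#' @param bin_size tile width in bp (default 1000).
#' @param p_max,or_min filter thresholds (defaults 0.05 and 2, the
#'   conventional region-set enrichment cutoffs).
#' @return list with `table` (all sets: `set`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`, `q`) and `filtered` (the rows passing both
#'   thresholds).
#' @export
fisher_region_enrichment <- function(query, region_sets, universe,
                                     bin_size = 1000, p_max = 0.05,
                                     or_min = 2) {
  query <- validate_intervals(query)
  if (any(query$end > universe[query$chrom]))
    stopf("universe smaller than the query span")
  bins <- do.call(rbind, lapply(names(universe), function(ch) {
    st <- seq(0, universe[[ch]] - 1, by = bin_size)
    data.frame(chrom = ch, start = st,
               end = pmin(st + bin_size, universe[[ch]]),
               name = ".", strand = ".")
  }))
  nb <- nrow(bins)
  q_bins <- unique(overlap(bins, query)$query)
  rows <- lapply(names(region_sets), function(sn) {
    s_bins <- unique(overlap(bins, region_sets[[sn]])$query)
    a <- length(intersect(q_bins, s_bins))
    b <- length(q_bins) - a
    c_ <- length(s_bins) - a
    d <- nb - a - b - c_
    p <- phyper(a - 1, length(s_bins), nb - length(s_bins), length(q_bins),
                lower.tail = FALSE)
    or <- if (min(a, b, c_, d) == 0)
      ((a + .5) * (d + .5)) / ((b + .5) * (c_ + .5))
    else (a * d) / (b * c_)
    data.frame(set = sn, a = a, b = b, c = c_, d = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p)
  list(table = tab,
       filtered = tab[tab$p < p_max & tab$odds_ratio > or_min, , drop = FALSE])
}

#' Count factor binding sites per gene promoter and compare clusters
#'
#' Counts, per gene, the binding-site intervals overlapping its promoter,
#' summarizes per cluster (mean, sd), and tests for a cluster effect with
#' a one-way ANOVA over per-gene counts. Empty clusters are excluded with
#' a warning; if the factor has no sites at all the ANOVA is skipped.
#'
#' @param promoters interval `data.frame`, one row per gene (`name` =
#'   gene id).
#' @param sites interval `data.frame` of binding sites for one factor.
#' @param clusters named character vector mapping gene id to cluster label
#'   (e.g. C1-C4).
#' @return list with `per_gene` (`gene_id`, `cluster`, `count`),
#'   `per_cluster` summary and `anova` (`c(f_stat, p)` or `NULL`).
#' @export
count_promoter_sites <- function(promoters, sites, clusters) {
  promoters <- validate_intervals(promoters)
  counts <- integer(nrow(promoters))
  if (nrow(sites)) {
    hits <- overlap(promoters, sites)
    tab <- table(hits$query)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  per_gene <- data.frame(gene_id = promoters$name,
                         cluster = unname(clusters[promoters$name]),
                         count = counts, stringsAsFactors = FALSE)
  per_gene <- per_gene[!is.na(per_gene$cluster), , drop = FALSE]
  groups <- split(per_gene$count, per_gene$cluster)
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty)) {
    warning("excluding empty cluster(s): ", paste(empty, collapse = ", "))
    groups <- groups[lengths(groups) > 0]
  }
  per_cluster <- data.frame(cluster = names(groups),
                            n = lengths(groups),
                            mean = vapply(groups, mean, numeric(1)),
                            sd = vapply(groups, sd, numeric(1)),
                            row.names = NULL)
  an <- NULL
  if (nrow(sites) && sum(per_gene$count) > 0 && length(groups) >= 2 &&
      all(lengths(groups) >= 2))
    an <- anova_f(groups)
  list(per_gene = per_gene, per_cluster = per_cluster, anova = an)
}

#' Hypergeometric gene-set over-representation test
#'
#' Upper-tail probability of observing at least the seen overlap between a
#' selected gene list and an annotation set drawn from a finite
#' population, with a Bonferroni adjustment across the number of sets
#' tested.
#'
#' @param selected character vector of selected genes (subset of
#'   `population`).
#' @param gene_set character vector of annotation-set genes (subset of
#'   `population`).
#' @param population character vector of all genes.
#' @param n_sets number of sets in the tested family (default 1).
#' @return named vector `c(overlap, p, bonferroni_p)`.
#' @export
hypergeom_geneset <- function(selected, gene_set, population, n_sets = 1) {
  if (!all(selected %in% population)) stopf("selected not subset of population")
  if (!all(gene_set %in% population)) stopf("gene_set not subset of population")
  k <- length(intersect(selected, gene_set))
  p <- phyper(k - 1, length(gene_set), length(population) - length(gene_set),
              length(selected), lower.tail = FALSE)
  c(overlap = k, p = p, bonferroni_p = min(1, p * n_sets))
}
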