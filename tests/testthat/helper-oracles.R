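# Independent brute-force oracles used to cross-check the implementation.

# all-pairs quadratic interval overlap
brute_overlap <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] == subject$chrom[j] &&
        max(query$start[i], subject$start[j]) <
        min(query$end[i], subject$end[j]))
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(query = integer(0), subject = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2])
}

# literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# one-sided Fisher p by direct hypergeometric enumeration of a 2x2 table
brute_fisher_p <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  K <- a + c_          # set-positive
  n <- a + b           # query-positive
  ks <- a:min(K, n)
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# brute-force 1-D Cox partial-likelihood maximization (no tied event times)
brute_cox_hr <- function(time, event, x) {
  logpl <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    s
  }
  opt <- stats::optimize(logpl, c(-8, 8), maximum = TRUE, tol = 1e-10)
  exp(opt$maximum)
}

# independent greedy re-derivation of the DMC-linkage construction
brute_dmr_merge <- function(dmcs, max_gap = 150) {
  res <- list()
  cur <- integer(0)
  flush <- function() {
    if (length(cur) >= 2) res[[length(res) + 1L]] <<- cur
    cur <<- integer(0)
  }
  for (i in seq_len(nrow(dmcs))) {
    if (length(cur)) {
      prev <- cur[length(cur)]
      ok <- dmcs$chrom[i] == dmcs$chrom[prev] &&
        dmcs$pos[i] - dmcs$pos[prev] <= max_gap &&
        dmcs$direction[i] == dmcs$direction[prev]
      if (!ok) flush()
    }
    cur <- c(cur, i)
  }
  flush()
  res
}

# small methylome fixture: values supplied as a loci x samples matrix
toy_methylome <- function(ratios, pos = seq_len(nrow(ratios)) * 100,
                          chrom = "chr1", n_normal = ncol(ratios) %/% 2,
                          coverages = NULL) {
  n <- ncol(ratios)
  methylome_matrix(
    loci = data.frame(chrom = chrom, pos = pos, strand = "+"),
    ratios = ratios, coverages = coverages,
    samples = data.frame(
      sample_id = sprintf("s%02d", seq_len(n)),
      cohort = rep(c("normal", "tumor"), c(n_normal, n - n_normal))))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                             max_len = 50) {
  st <- sample.int(max_pos, n, replace = TRUE) - 1
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = st, end = st + sample.int(max_len, n, replace = TRUE),
             name = ".", strand = ".")
}
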