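#' Build differentially methylated regions by DMC linkage
#'
#' A single left-to-right sweep per chromosome links consecutive DMCs into a
#' region while (1) the next DMC lies within `max_gap` bp of the previous
#' one (inclusive; 150 bp by default, the minimum CpG-island size) and
#' (2) the methylation direction is consistent (all hypo- or all
#' hypermethylated). Regions with at least two member DMCs are emitted;
#' singletons are discarded. The region interval is
#' `[first_pos, last_pos + 1)` and its CpG density is the member count
#' divided by the span in bp, so every emitted DMR has density
#' `>= 2 / (max_gap + 1)` (0.0132 at the defaults, i.e. at least 0.01).
#'
#' @param dmcs `data.frame` from [call_dmcs()] (needs `chrom`, `pos`,
#'   `direction`, `delta`, `p`, `q`), sorted by `(chrom, pos)` with no
#'   duplicate positions.
#' @param max_gap maximum distance between successive member DMCs in bp
#'   (default 150).
#' @return `data.frame` with columns `chrom`, `start`, `end`, `direction`,
#'   `n_dmcs`, `span`, `density`, `mean_delta` and a list-column
#'   `member_idx` of row indices into `dmcs`.
#' @export
build_dmrs <- function(dmcs, max_gap = 150) {
  need <- c("chrom", "pos", "direction")
  if (!all(need %in% names(dmcs)))
    stopf("dmcs must have columns %s", paste(need, collapse = ", "))
  n <- nrow(dmcs)
  if (n == 0)
    return(empty_dmrs())
  ord <- order(dmcs$chrom, dmcs$pos)
  if (!identical(ord, seq_len(n)))
    stopf("dmcs must be sorted by (chrom, pos)")
  if (any(duplicated(dmcs[, c("chrom", "pos")])))
    stopf("duplicate DMC positions")
  same_chrom <- dmcs$chrom[-1] == dmcs$chrom[-n]
  linked <- logical(n - 1)
  if (n > 1)
    linked <- same_chrom &
      (dmcs$pos[-1] - dmcs$pos[-n] <= max_gap) &
      (dmcs$direction[-1] == dmcs$direction[-n])
  run_id <- cumsum(c(1L, !linked))
  runs <- split(seq_len(n), run_id)
  runs <- runs[lengths(runs) >= 2]
  if (!length(runs)) return(empty_dmrs())
  rows <- lapply(runs, function(ix) {
    first <- dmcs$pos[ix[1]]; last <- dmcs$pos[ix[length(ix)]]
    span <- last - first + 1
    data.frame(chrom = dmcs$chrom[ix[1]], start = first, end = last + 1,
               direction = dmcs$direction[ix[1]], n_dmcs = length(ix),
               span = span, density = length(ix) / span,
               mean_delta = if ("delta" %in% names(dmcs))
                 mean(dmcs$delta[ix]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$member_idx <- unname(runs)
  out
}

empty_dmrs <- function() {
  out <- data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), direction = character(0),
                    n_dmcs = integer(0), span = numeric(0),
                    density = numeric(0), mean_delta = numeric(0))
  out$member_idx <- list()
  out
}

#' Summaries of DMR size and CpG density
#'
#' Histograms of region span (50-bp bins) and CpG density (0.005 bins),
#' plus direction counts. Counts are conserved: each histogram totals the
#' number of input DMRs.
#'
#' @param dmrs output of [build_dmrs()] (non-empty).
#' @param size_bin span histogram bin width in bp (default 50).
#' @param density_bin density histogram bin width (default 0.005).
#' @return list with `size_hist`, `density_hist` (`data.frame`s with
#'   `bin_lo`, `bin_hi`, `count`) and `direction_counts`.
#' @export
dmr_stats <- function(dmrs, size_bin = 50, density_bin = 0.005) {
  if (!nrow(dmrs)) stopf("no DMRs supplied")
  hist_of <- function(x, w) {
    lo <- floor(x / w) * w
    tab <- table(lo)
    data.frame(bin_lo = as.numeric(names(tab)),
               bin_hi = as.numeric(names(tab)) + w,
               count = as.integer(tab))
  }
  list(size_hist = hist_of(dmrs$span, size_bin),
       density_hist = hist_of(dmrs$density, density_bin),
       direction_counts = table(dmrs$direction))
}

#' Region-level significance for DMRs
#'
#' Aggregates member-DMC p-values (direction-aligned, treated as one-sided
#' within a region) into a region p-value, then BH-adjusts across regions.
#' Methods: `"stouffer"` combines member z-scores
#' `z = sum(qnorm(1 - p_i)) / sqrt(k)`; `"min_q"` takes the smallest member
#' q-value Bonferroni-scaled by the member count.
#'
#' @param dmrs output of [build_dmrs()].
#' @param dmcs the DMC table the regions were built from.
#' @param method `"stouffer"` (default) or `"min_q"`.
#' @return `dmrs` with added `p_region`, `q_region` and an attribute
#'   `method`.
#' @export
aggregate_dmr_significance <- function(dmrs, dmcs, method = c("stouffer", "min_q")) {
  method <- match.arg(method)
  if (!nrow(dmrs)) {
    dmrs$p_region <- numeric(0); dmrs$q_region <- numeric(0)
    return(dmrs)
  }
  p_region <- vapply(dmrs$member_idx, function(ix) {
    k <- length(ix)
    if (method == "stouffer") {
      # cap member p away from {0, 1} to keep qnorm finite
      pm <- pmin(pmax(dmcs$p[ix], 1e-300), 1 - 1e-16)
      z <- sum(qnorm(pm, lower.tail = FALSE)) / sqrt(k)
      pnorm(z, lower.tail = FALSE)
    } else {
      min(1, min(dmcs$q[ix]) * k)
    }
  }, numeric(1))
  dmrs$p_region <- p_region
  dmrs$q_region <- bh_adjust(p_region)
  attr(dmrs, "method") <- method
  dmrs
}

#' Write DMRs as BED6 (name = direction, score = round(1000 * density))
#'
#' @param dmrs output of [build_dmrs()].
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  iv <- intervals(dmrs$chrom, dmrs$start, dmrs$end, name = dmrs$direction)
  out <- data.frame(iv$chrom,
                    format(iv$start, scientific = FALSE, trim = TRUE),
                    format(iv$end, scientific = FALSE, trim = TRUE),
                    iv$name, round(1000 * dmrs$density), iv$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
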