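#' Construct a genomic interval table
#'
#' Intervals are represented as a plain `data.frame` with columns `chrom`,
#' `start`, `end`, `name`, `strand` using 0-based half-open coordinates
#' (BED-native). This is the container for every region track in the package
#' (promoters, gene bodies, CpG islands, enhancers, TFBS, DMRs).
#'
#' @param chrom character chromosome names.
#' @param start,end integer-like 0-based half-open bounds; `end > start >= 0`.
#' @param name optional labels (default `"."`).
#' @param strand one of `"+"`, `"-"`, `"."` per interval (default `"."`).
#' @return a validated interval `data.frame`.
#' @export
intervals <- function(chrom, start, end, name = ".", strand = ".") {
  if (length(chrom) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      strand = character(0)))
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   name = as.character(name), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
}

#' @rdname intervals
#' @param x a candidate interval `data.frame`.
#' @export
validate_intervals <- function(x) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stopf("interval table must have columns %s", paste(need, collapse = ", "))
  if (is.null(x$name)) x$name <- "."
  if (is.null(x$strand)) x$strand <- "."
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stopf("interval coordinates must not be NA")
  if (any(x$start < 0))
    stopf("negative interval coordinate (start %s)", min(x$start))
  bad <- which(x$end <= x$start)
  if (length(bad))
    stopf("interval end <= start at row %d (%s:%s-%s)",
          bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]])
  if (any(!x$strand %in% c("+", "-", ".")))
    stopf("strand must be one of '+', '-', '.'")
  x[, c("chrom", "start", "end", "name", "strand")]
}

#' Overlapping pairs between two interval sets
#'
#' Reports a (query, subject) index pair whenever
#' `max(start_q, start_s) < min(end_q, end_s)` (half-open overlap,
#' strand-agnostic). Backed by [IRanges::findOverlaps()]; coordinates are
#' converted from the package's 0-based half-open convention at the boundary.
#'
#' @param query,subject interval `data.frame`s (see [intervals()]).
#' @return `data.frame` with integer columns `query`, `subject`, ordered by
#'   query index then subject index. Empty inputs give zero rows.
#' @export
overlap <- function(query, subject) {
  query <- validate_intervals(query)
  subject <- validate_intervals(subject)
  out <- list()
  if (nrow(query) && nrow(subject)) {
    for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
      qi <- which(query$chrom == ch)
      si <- which(subject$chrom == ch)
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(query$start[qi] + 1L, query$end[qi]),
        IRanges::IRanges(subject$start[si] + 1L, subject$end[si]))
      if (length(hits))
        out[[ch]] <- data.frame(query = qi[S4Vectors::queryHits(hits)],
                                subject = si[S4Vectors::subjectHits(hits)])
    }
  }
  if (!length(out))
    return(data.frame(query = integer(0), subject = integer(0)))
  res <- do.call(rbind, unname(out))
  res <- res[order(res$query, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Point sites (chrom, pos) as degenerate 1-bp intervals, for reuse of overlap()
sites_as_intervals <- function(sites) {
  intervals(sites$chrom, sites$pos, sites$pos + 1)
}

#' Read a BED3/BED6 file as an interval table
#'
#' Missing BED fields are defaulted (`name = "."`, `strand = "."`); the score
#' column is ignored. Coordinates are kept 0-based half-open, exactly as on
#' disk.
#'
#' @param path BED file path.
#' @param track_name optional label overriding the name column when absent.
#' @return interval `data.frame`.
#' @export
read_intervals <- function(path, track_name = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (ncol(dt) < 3)
    stopf("BED file %s has fewer than 3 columns", path)
  df <- data.frame(chrom = as.character(dt[[1]]),
                   start = as.numeric(dt[[2]]), end = as.numeric(dt[[3]]),
                   name = if (ncol(dt) >= 4) as.character(dt[[4]])
                          else track_name %||% ".",
                   strand = if (ncol(dt) >= 6) as.character(dt[[6]]) else ".",
                   stringsAsFactors = FALSE)
  validate_intervals(df)
}

#' Write an interval table as BED6
#'
#' @param x interval `data.frame`.
#' @param path output path.
#' @param score numeric score column (default 0).
#' @export
write_intervals <- function(x, path, score = 0) {
  x <- validate_intervals(x)
  out <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                    format(x$end, scientific = FALSE, trim = TRUE),
                    x$name, score, x$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
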