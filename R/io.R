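#' Construct a methylome matrix
#'
#' The central input of the pipeline: per-CpG methylation ratios (and
#' optionally read coverages) over two labeled cohorts. Loci are sorted by
#' `(chrom, pos)`; ratios must lie in `[0, 1]` where present; missing values
#' are `NA` (never 0).
#'
#' @param loci `data.frame` with columns `chrom`, `pos`, `strand` (CpG
#'   position of the C on the + strand; strand retained but ignored by
#'   analysis).
#' @param ratios numeric matrix, loci x samples, values in `[0, 1]` or `NA`.
#' @param coverages optional non-negative integer matrix of the same shape.
#' @param samples `data.frame` with columns `sample_id`, `cohort`
#'   (`"normal"` or `"tumor"`); at least one sample per cohort.
#' @return an object of class `methylome_matrix` (a list with the validated
#'   components).
#' @export
methylome_matrix <- function(loci, ratios, coverages = NULL, samples) {
  ratios <- as.matrix(ratios)
  if (!all(c("chrom", "pos") %in% names(loci)))
    stopf("loci must have columns chrom, pos")
  if (is.null(loci$strand)) loci$strand <- "+"
  if (nrow(loci) != nrow(ratios))
    stopf("loci (%d) and ratios (%d rows) disagree", nrow(loci), nrow(ratios))
  if (!all(c("sample_id", "cohort") %in% names(samples)))
    stopf("samples must have columns sample_id, cohort")
  if (ncol(ratios) != nrow(samples))
    stopf("ratios has %d columns but %d samples", ncol(ratios), nrow(samples))
  bad <- which(!is.na(ratios) & (ratios < 0 | ratios > 1), arr.ind = TRUE)
  if (nrow(bad))
    stopf("methylation ratio outside [0,1] at locus row %d, sample %s (value %.4g)",
          bad[1, 1], samples$sample_id[bad[1, 2]], ratios[bad[1, , drop = FALSE]])
  if (any(!samples$cohort %in% c("normal", "tumor")))
    stopf("unknown sample label '%s' (expected normal/tumor)",
          setdiff(samples$cohort, c("normal", "tumor"))[1])
  if (!all(c("normal", "tumor") %in% samples$cohort))
    stopf("need at least one sample per cohort")
  if (!is.null(coverages)) {
    coverages <- as.matrix(coverages)
    if (!identical(dim(coverages), dim(ratios)))
      stopf("coverages and ratios dimensions disagree")
    if (any(coverages < 0, na.rm = TRUE))
      stopf("coverage must be non-negative")
  }
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, c("chrom", "pos", "strand"), drop = FALSE]
  rownames(loci) <- NULL
  ratios <- ratios[ord, , drop = FALSE]
  if (!is.null(coverages)) coverages <- coverages[ord, , drop = FALSE]
  colnames(ratios) <- samples$sample_id
  if (!is.null(coverages)) colnames(coverages) <- samples$sample_id
  structure(list(loci = loci, ratios = ratios, coverages = coverages,
                 samples = samples[, c("sample_id", "cohort")]),
            class = "methylome_matrix")
}

#' @export
print.methylome_matrix <- function(x, ...) {
  cat(sprintf("methylome_matrix: %d CpG loci x %d samples (%d normal, %d tumor)%s\n",
              nrow(x$loci), nrow(x$samples),
              sum(x$samples$cohort == "normal"),
              sum(x$samples$cohort == "tumor"),
              if (is.null(x$coverages)) ", no coverages" else ""))
  invisible(x)
}

#' @export
dim.methylome_matrix <- function(x) c(nrow(x$loci), nrow(x$samples))

cohort_cols <- function(m, cohort) which(m$samples$cohort == cohort)

#' Read / write the methylome TSV format
#'
#' On-disk layout: tab-separated with header
#' `chrom  pos  strand  <s1>_ratio  <s1>_cov ... ` (one ratio/coverage column
#' pair per sample; the `_cov` columns may be absent). Cohort labels come
#' from a sidecar sample sheet (`sample_id`, `cohort`). Missing values are
#' written as `NA`. Read and write round-trip losslessly.
#'
#' @param path methylome TSV path.
#' @param samples sample sheet: a path or a `data.frame` with `sample_id`,
#'   `cohort`.
#' @return [read_methylome()] returns a `methylome_matrix`.
#' @export
read_methylome <- function(path, samples) {
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = "NA")
  if (!all(c("chrom", "pos", "strand") %in% names(dt)))
    stopf("%s: expected header chrom, pos, strand, <sample>_ratio[, <sample>_cov]", path)
  rcols <- grep("_ratio$", names(dt), value = TRUE)
  if (!length(rcols)) stopf("%s: no *_ratio columns found", path)
  ids <- sub("_ratio$", "", rcols)
  if (!setequal(ids, samples$sample_id))
    stopf("sample sheet ids do not match ratio columns (%s)",
          paste(symdiff_chr(ids, samples$sample_id), collapse = ", "))
  ids <- samples$sample_id
  if (any(!is.finite(dt$pos)))
    stopf("%s: malformed position at line %d", path,
          which(!is.finite(dt$pos))[1] + 1L)
  ratios <- as.matrix(dt[, paste0(ids, "_ratio"), drop = FALSE])
  bad <- which(!is.na(ratios) & (ratios < 0 | ratios > 1), arr.ind = TRUE)
  if (nrow(bad))
    stopf("%s: ratio outside [0,1] at line %d", path, bad[1, 1] + 1L)
  ccols <- paste0(ids, "_cov")
  coverages <- if (all(ccols %in% names(dt)))
    as.matrix(dt[, ccols, drop = FALSE]) else NULL
  methylome_matrix(loci = dt[, c("chrom", "pos", "strand")],
                   ratios = ratios, coverages = coverages, samples = samples)
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))

#' @rdname read_methylome
#' @param m a `methylome_matrix`.
#' @export
write_methylome <- function(m, path) {
  stopifnot(inherits(m, "methylome_matrix"))
  ids <- m$samples$sample_id
  out <- m$loci
  for (i in seq_along(ids)) {
    out[[paste0(ids[i], "_ratio")]] <- fmt_num(m$ratios[, i])
    if (!is.null(m$coverages))
      out[[paste0(ids[i], "_cov")]] <- m$coverages[, i]
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

# full-precision decimal formatting so write->read is lossless
fmt_num <- function(x) {
  s <- formatC(x, digits = 17, format = "g")
  s[is.na(x)] <- NA
  s
}

#' @rdname read_methylome
#' @export
read_sample_sheet <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("sample_id", "cohort") %in% names(dt)))
    stopf("%s: sample sheet needs columns sample_id, cohort", path)
  if (any(!dt$cohort %in% c("normal", "tumor")))
    stopf("%s: unknown sample label '%s'", path,
          setdiff(dt$cohort, c("normal", "tumor"))[1])
  dt[, c("sample_id", "cohort")]
}

#' @rdname read_methylome
#' @export
write_sample_sheet <- function(samples, path) {
  data.table::fwrite(samples[, c("sample_id", "cohort")], path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Export one sample's methylation ratios as bedGraph
#'
#' @param m a `methylome_matrix`.
#' @param sample_id sample to export.
#' @param path output path.
#' @export
write_bedgraph <- function(m, sample_id, path) {
  i <- match(sample_id, m$samples$sample_id)
  if (is.na(i)) stopf("unknown sample '%s'", sample_id)
  keep <- !is.na(m$ratios[, i])
  out <- data.frame(m$loci$chrom[keep],
                    format(m$loci$pos[keep], scientific = FALSE, trim = TRUE),
                    format(m$loci$pos[keep] + 1, scientific = FALSE, trim = TRUE),
                    fmt_num(m$ratios[keep, i]))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the gene table
#'
#' TSV with header `gene_id  chrom  strand  tss  body_start  body_end`.
#' `tss` is a 0-based point contained in the gene span; strand is `+` or
#' `-`; gene ids must be unique.
#'
#' @param path gene table path.
#' @return `data.frame` of gene models.
#' @export
read_gene_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  validate_gene_table(dt, path)
}

validate_gene_table <- function(dt, what = "gene table") {
  need <- c("gene_id", "chrom", "strand", "tss", "body_start", "body_end")
  if (!all(need %in% names(dt)))
    stopf("%s: expected columns %s", what, paste(need, collapse = ", "))
  if (anyDuplicated(dt$gene_id))
    stopf("%s: duplicate gene_id '%s'", what,
          dt$gene_id[duplicated(dt$gene_id)][1])
  if (any(!dt$strand %in% c("+", "-")))
    stopf("%s: gene strand must be + or -", what)
  if (any(dt$body_end <= dt$body_start))
    stopf("%s: body_end must exceed body_start", what)
  if (any(dt$tss < dt$body_start | dt$tss > dt$body_end))
    stopf("%s: tss must lie within the gene span", what)
  dt[, need]
}

#' @rdname read_gene_table
#' @param genes gene `data.frame`.
#' @export
write_gene_table <- function(genes, path) {
  data.table::fwrite(validate_gene_table(genes), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write the expression matrix
#'
#' TSV with header `gene_id  <s1>_tpm  <s2>_tpm ...`; TPM values are
#' non-negative; cohort labels come from the sample sheet.
#'
#' @param path expression TSV path.
#' @param samples sample sheet path or `data.frame`.
#' @return an `expression_matrix`: list with `gene_ids`, `tpm` (genes x
#'   samples), `samples`.
#' @export
read_expression <- function(path, samples) {
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!"gene_id" %in% names(dt)) stopf("%s: missing gene_id column", path)
  tcols <- grep("_tpm$", names(dt), value = TRUE)
  ids <- sub("_tpm$", "", tcols)
  if (!setequal(ids, samples$sample_id))
    stopf("%s: sample sheet ids do not match tpm columns", path)
  tpm <- as.matrix(dt[, paste0(samples$sample_id, "_tpm"), drop = FALSE])
  expression_matrix(dt$gene_id, tpm, samples)
}

#' @rdname read_expression
#' @param gene_ids unique gene identifiers.
#' @param tpm non-negative genes x samples matrix.
#' @export
expression_matrix <- function(gene_ids, tpm, samples) {
  tpm <- as.matrix(tpm)
  if (anyDuplicated(gene_ids)) stopf("duplicate gene_id in expression matrix")
  if (any(tpm < 0, na.rm = TRUE)) stopf("TPM must be non-negative")
  if (nrow(tpm) != length(gene_ids)) stopf("gene_ids/tpm shape mismatch")
  if (ncol(tpm) != nrow(samples)) stopf("tpm/sample sheet shape mismatch")
  colnames(tpm) <- samples$sample_id
  structure(list(gene_ids = as.character(gene_ids), tpm = tpm,
                 samples = samples[, c("sample_id", "cohort")]),
            class = "expression_matrix")
}

#' @rdname read_expression
#' @param e an `expression_matrix`.
#' @export
write_expression <- function(e, path) {
  out <- data.frame(gene_id = e$gene_ids, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(e$tpm)))
    out[[paste0(e$samples$sample_id[i], "_tpm")]] <- fmt_num(e$tpm[, i])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write the patient survival table
#'
#' TSV with header `patient_id  time_days  event  age  sex  alcohol`
#' (covariate columns beyond `event` are free-form but these three are
#' conventional). `time_days > 0`; `event` is 0 (censored) or 1 (death).
#'
#' @param path survival table path.
#' @return `data.frame`.
#' @export
read_survival <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  validate_survival(dt, path)
}

validate_survival <- function(dt, what = "survival table") {
  if (!all(c("patient_id", "time_days", "event") %in% names(dt)))
    stopf("%s: expected columns patient_id, time_days, event", what)
  if (any(dt$time_days <= 0)) stopf("%s: time_days must be positive", what)
  if (any(!dt$event %in% c(0, 1)))
    stopf("%s: event must be 0 or 1", what)
  dt
}

#' @rdname read_survival
#' @param surv survival `data.frame`.
#' @export
write_survival <- function(surv, path) {
  data.table::fwrite(validate_survival(surv), path, sep = "\t", quote = FALSE)
  invisible(path)
}
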