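#' Run the full analysis pipeline on a configuration
#'
#' Executes, in order: optional synthetic-study generation (or reading the
#' configured input files), coverage/completeness filtering, DMC calling,
#' DMR construction with region-level significance, annotation composition
#' and promoter site counting, DEG calling with quadrant classification,
#' and (when survival inputs are present) variance stratification with a
#' Cox fit. Any stage failure aborts with the stage name. The returned run
#' manifest records the package version, all parameters, per-stage record
#' counts and md5 checksums of every file written, and is sufficient to
#' re-run identically; two runs with the same config and seed produce
#' byte-identical manifests.
#'
#' @param config named list (or YAML file path) with optional entries:
#'   `simulate` (logical, default TRUE), `sim` (overrides passed to
#'   [sim_config()]), `methylome`, `samples`, `genes`, `expression`,
#'   `survival` (input paths when `simulate` is FALSE), `min_cov`,
#'   `alpha_q`, `max_gap`, `agg_method`, `dmr_q_max`, `lfc_min`, `deg_q`,
#'   `promoter_up`, `promoter_down`, `seed`.
#' @param outdir output directory for stage outputs and `manifest.json`.
#' @return the manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  p <- list(simulate = TRUE, min_cov = 5, alpha_q = 0.05, max_gap = 150,
            agg_method = "stouffer", dmr_q_max = 0.01, lfc_min = 1,
            deg_q = 0.05, promoter_up = 4500, promoter_down = 500, seed = 1)
  p[names(config)] <- config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log_stage <- function(name) message("[methylscape] stage: ", name)
  stage <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  counts <- list()

  inputs <- stage("input", {
    if (isTRUE(p$simulate)) {
      sim_args <- p$sim %||% list()
      sim_args$seed <- sim_args$seed %||% p$seed
      cfg <- do.call(sim_config, sim_args)
      study <- simulate_study(cfg, outdir = file.path(outdir, "sim"))
      written <- c(written, list.files(file.path(outdir, "sim"),
                                       full.names = TRUE))
      list(methylome = study$methylome,
           genes = study$genome$genes[, c("gene_id", "chrom", "strand",
                                          "tss", "body_start", "body_end")],
           expression = study$expression,
           survival = study$survival$survival, study = study)
    } else {
      for (f in c("methylome", "samples", "genes", "expression")) {
        if (is.null(p[[f]])) stopf("config field '%s' is required", f)
        if (!file.exists(p[[f]])) stopf("input '%s' not found: %s", f, p[[f]])
      }
      list(methylome = read_methylome(p$methylome, p$samples),
           genes = read_gene_table(p$genes),
           expression = read_expression(p$expression, p$samples),
           survival = if (!is.null(p$survival)) read_survival(p$survival))
    }
  })
  counts$cpgs_input <- nrow(inputs$methylome$loci)

  filtered <- stage("filter", filter_matrix(inputs$methylome, p$min_cov))
  counts$cpgs_retained <- nrow(filtered$loci)

  dmcs <- stage("dmc", call_dmcs(filtered, alpha_q = p$alpha_q))
  counts$dmcs <- nrow(dmcs)
  counts$dmcs_hypo <- sum(dmcs$direction == "hypo")
  counts$dmcs_hyper <- sum(dmcs$direction == "hyper")
  f_dmc <- file.path(outdir, "dmc.tsv")
  data.table::fwrite(dmcs[, setdiff(names(dmcs), "significant")], f_dmc,
                     sep = "\t")
  written <- c(written, f_dmc)

  dmrs <- stage("dmr", {
    d <- build_dmrs(dmcs, max_gap = p$max_gap)
    aggregate_dmr_significance(d, dmcs, method = p$agg_method)
  })
  counts$dmrs <- nrow(dmrs)
  f_dmr <- file.path(outdir, "dmr.tsv")
  data.table::fwrite(dmrs[, setdiff(names(dmrs), "member_idx")], f_dmr,
                     sep = "\t")
  written <- c(written, f_dmr)
  if (nrow(dmrs)) {
    f_bed <- file.path(outdir, "dmr.bed")
    write_dmr_bed(dmrs, f_bed)
    written <- c(written, f_bed)
  }

  promoters <- promoter_windows(inputs$genes, p$promoter_up, p$promoter_down)
  comp <- stage("enrich", {
    tracks <- if (!is.null(inputs$study))
      inputs$study$genome$tracks else list(promoter = promoters)
    annotate_sites(data.frame(chrom = dmcs$chrom, pos = dmcs$pos), tracks,
                   precedence = names(tracks))
  })
  f_comp <- file.path(outdir, "composition.tsv")
  data.table::fwrite(comp$composition, f_comp, sep = "\t")
  written <- c(written, f_comp)

  integ <- stage("integrate", {
    degs <- call_degs(inputs$expression, lfc_min = p$lfc_min,
                      alpha_q = p$deg_q)
    quad <- classify_quadrants(dmrs, promoters, degs,
                               dmr_q_max = p$dmr_q_max)
    list(degs = degs, quad = quad)
  })
  counts$degs <- sum(integ$degs$status != "ns")
  counts$quadrant_genes <- nrow(integ$quad$assignments)
  counts$quadrants <- as.list(integ$quad$counts)
  f_deg <- file.path(outdir, "deg.tsv")
  data.table::fwrite(integ$degs, f_deg, sep = "\t")
  f_quad <- file.path(outdir, "clusters.tsv")
  data.table::fwrite(integ$quad$assignments, f_quad, sep = "\t")
  written <- c(written, f_deg, f_quad)

  if (!is.null(inputs$survival)) {
    sv <- stage("survival", {
      surv <- inputs$survival
      if (!"variance" %in% names(surv))
        stopf("survival table lacks a 'variance' column")
      surv <- stratify_by_variance(
        stats::setNames(surv$variance, surv$patient_id), surv)
      fit_cox(surv, covariates = intersect(c("age", "sex", "alcohol"),
                                           names(surv)))
    })
    counts$cox_hr <- sv$hr
    counts$cox_p <- sv$wald_p
  }

  manifest <- list(
    package = "methylscape",
    version = as.character(utils::packageVersion("methylscape")),
    parameters = p[order(names(p))],
    counts = counts,
    files = {
      rel <- sort(written)
      stats::setNames(as.list(unname(tools::md5sum(rel))),
                      sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])",
                                           "\\\\\\1", outdir), "/?"),
                          "", rel))
    })
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  writeLines(json, file.path(outdir, "manifest.json"))
  invisible(manifest)
}
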