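#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> plant regulator -> preprocess -> filter ->
#' differential tests -> motif regulation analysis -> evaluation (PCA,
#' annotation overlap against the planted ground truth, parameter recovery),
#' logging each stage. When `workdir` is given, the dataset, the result
#' tables and a markdown + JSON report are written there.
#'
#' @param config a [sim_config()].
#' @param workdir optional output directory.
#' @param fdr FDR cutoff for significance calls.
#' @param method summarization method (see [summarize_probes()]).
#' @param motifs motif set for the regulator analysis.
#' @param quiet suppress stage logging.
#' @return list of class `splicedex_report` with elements `dataset`,
#'   `filter_report`, `differential`, `crosstab`, `fox2`, `pca`,
#'   `overlap_curve`, `recovery`, `config`.
#' @export
run_pipeline <- function(config = sim_config(), workdir = NULL, fdr = 0.05,
                         method = "median_polish",
                         motifs = motif_set("strict"), quiet = FALSE) {
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    log_stage("[splicedex] %s (seed %d)", name, config$seed)
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  dataset <- stage("simulate", {
    d <- simulate_dataset(config)
    if (config$n_fox2_up_exons + config$n_fox2_down_exons > 0)
      d <- plant_fox2_regulation(d, config)
    d
  })
  prep <- stage("preprocess", preprocess(dataset, method = method))
  filtered <- stage("filter", apply_filters(prep))
  diff <- stage("test", run_differential(filtered, fdr = fdr))

  fox2 <- NULL
  if (nrow(dataset$truth$fox2_targets) > 0 ||
      length(dataset$intron_windows) > 0) {
    fox2 <- stage("fox2", fox2_analysis(
      diff$exon,
      2^filtered$probeset_log2, 2^filtered$gene_log2,
      dataset$annotation, dataset$design, dataset$intron_windows,
      motifs = motifs))
  }

  evalr <- stage("evaluate", {
    pca <- pca_summary(filtered$gene_log2, dataset$design)
    known <- dataset$truth$exon_effects$probeset_id[
      dataset$truth$exon_effects$tissue_das |
        dataset$truth$exon_effects$stage_das]
    curve <- annotation_overlap_curve(diff$exon, known)
    rec <- recovery_metrics(diff, dataset$truth)
    list(pca = pca, curve = curve, recovery = rec)
  })

  report <- structure(list(
    dataset = dataset,
    filter_report = filtered$report,
    differential = diff,
    crosstab = diff$crosstab,
    fox2 = fox2,
    pca = evalr$pca,
    overlap_curve = evalr$curve,
    recovery = evalr$recovery,
    config = config
  ), class = "splicedex_report")

  if (!is.null(workdir)) {
    stage("write", write_report(report, workdir))
  }
  report
}

#' Write pipeline outputs and a markdown report
#'
#' @param report a `splicedex_report` from [run_pipeline()].
#' @param workdir output directory.
#' @return paths written, invisibly.
#' @export
write_report <- function(report, workdir) {
  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  write_dataset(report$dataset, file.path(workdir, "dataset"))
  wt <- function(df, f) utils::write.table(
    df, file.path(workdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$differential$gene, "gene_results.tsv")
  wt(report$differential$exon, "exon_results.tsv")
  wt(report$overlap_curve, "overlap_curve.tsv")
  wt(report$recovery, "recovery_metrics.tsv")
  if (!is.null(report$fox2) && nrow(report$fox2$records) > 0)
    wt(report$fox2$records, "fox2_records.tsv")

  summary <- list(
    filter_report = .report_json(report$filter_report),
    crosstab = unclass(report$crosstab),
    fox2 = if (!is.null(report$fox2))
      lapply(report$fox2$tests, function(t) t[setdiff(names(t), "comparison")]),
    pca_variance_explained = report$pca$variance_explained,
    seed = report$config$seed
  )
  jsonlite::write_json(summary, file.path(workdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  md <- c(
    "# splicedex pipeline report", "",
    sprintf("Seed %d; %d genes; %d samples.", report$config$seed,
            report$config$n_genes, sum(report$config$design$n_replicates)), "",
    "## Filtering",
    sprintf("- meta probe sets kept: %d / %d",
            report$filter_report$n_metaprobesets_kept,
            report$filter_report$n_metaprobesets_in),
    sprintf("- probe sets kept: %d / %d (cross-hyb %d, dead %d)",
            report$filter_report$n_probesets_kept,
            report$filter_report$n_probesets_in,
            length(report$filter_report$removed_crosshyb),
            length(report$filter_report$removed_dead)), "",
    "## Differential expression and splicing",
    sprintf("- genes significant (tissue / stage / both): %d / %d / %d",
            report$crosstab$genes_tissue, report$crosstab$genes_stage,
            report$crosstab$genes_both),
    sprintf("- exons significant (tissue / stage / both): %d / %d / %d",
            report$crosstab$exons_tissue, report$crosstab$exons_stage,
            report$crosstab$exons_both),
    sprintf("- genes with >= 1 significant exon: %d",
            report$crosstab$genes_with_sig_exon), "",
    "## PCA",
    sprintf("- first two components explain %.1f%% of the variance",
            100 * sum(report$pca$variance_explained[1:2])), "",
    "## Motif regulation",
    if (!is.null(report$fox2)) {
      vapply(report$fox2$tests, function(t) sprintf(
        "- %s: n_down=%d, n_up=%d, fold difference of means %.3g, one-tailed Welch p = %.4g",
        t$comparison, t$n_down, t$n_up, t$fold_difference_of_means,
        t$p_one_tailed), character(1))
    } else "- not run", "",
    "## Overlap with known alternative events",
    apply(report$overlap_curve, 1, function(r) sprintf(
      "- FDR <= %s: %s significant, %.1f%% overlap",
      format(r[["fdr_threshold"]]), format(r[["n_significant"]]),
      as.numeric(r[["pct_overlap"]]))), "",
    "## Recovery of planted effects",
    apply(report$recovery, 1, function(r) sprintf(
      "- %s: recall %.2f, precision %.2f, realized FDR %.3f",
      r[["family"]], as.numeric(r[["recall"]]), as.numeric(r[["precision"]]),
      as.numeric(r[["realized_fdr"]])))
  )
  writeLines(unlist(md), file.path(workdir, "report.md"))
  invisible(workdir)
}

.report_json <- function(fr) {
  list(n_metaprobesets_in = fr$n_metaprobesets_in,
       n_metaprobesets_kept = fr$n_metaprobesets_kept,
       n_probesets_in = fr$n_probesets_in,
       n_probesets_kept = fr$n_probesets_kept,
       n_removed_unexpressed = length(fr$removed_unexpressed),
       n_removed_crosshyb = length(fr$removed_crosshyb),
       n_removed_dead = length(fr$removed_dead),
       thresholds = fr$thresholds)
}

#' @export
print.splicedex_report <- function(x, ...) {
  cat("<splicedex_report>\n")
  print(x$filter_report)
  print(x$crosstab)
  if (!is.null(x$fox2)) print(x$fox2)
  print(x$pca)
  invisible(x)
}
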