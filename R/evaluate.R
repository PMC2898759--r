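#' PCA summary of an expression matrix
#'
#' Features are centered per row before decomposition; returns the fraction
#' of variance explained per component and the per-sample scores on the
#' first two components, labelled by the design.
#'
#' @param m feature x sample matrix (log2 gene expression by convention).
#' @param design per-sample design table.
#' @param n_components how many variance fractions to report.
#' @return list of class `pca_summary`: `variance_explained`,
#'   `sample_scores` (data frame with PC1, PC2, tissue, stage).
#' @export
pca_summary <- function(m, design, n_components = min(dim(m)) - 1L) {
  centered <- m - rowMeans(m)
  if (all(abs(centered) < .Machine$double.eps^.5))
    .stopf("pca_summary: constant matrix, PCA undefined")
  pc <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  n_components <- min(n_components, length(ve))
  scores <- data.frame(sample_id = colnames(m),
                       PC1 = pc$x[, 1],
                       PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0,
                       tissue = design$tissue[match(colnames(m), design$sample_id)],
                       stage = design$stage[match(colnames(m), design$sample_id)],
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(variance_explained = ve[seq_len(n_components)],
                 sample_scores = scores),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  ve <- x$variance_explained
  cat(sprintf("<pca_summary> PC1 %.1f%%, PC2 %.1f%% (first two: %.1f%%)\n",
              100 * ve[1], 100 * ve[2], 100 * sum(ve[1:2])))
  invisible(x)
}

#' Overlap between significant exons and a known-alternative-events set
#'
#' For each FDR threshold, the percentage of stage-significant exons present
#' in a user-supplied set of known alternative events (here typically the
#' synthetic ground truth, or any annotation-derived id set). Tightening the
#' threshold should enrich for true events, so the curve is expected to be
#' nondecreasing on well-powered data.
#'
#' @param exon_res exon-level result table from [run_differential()].
#' @param known_events character vector of probe-set ids.
#' @param thresholds decreasing FDR thresholds.
#' @param family which q-value family to threshold (`"stage"` or `"tissue"`).
#' @return data frame with `fdr_threshold`, `n_significant`, `pct_overlap`
#'   (NA where nothing is significant).
#' @export
annotation_overlap_curve <- function(exon_res, known_events,
                                     thresholds = c(0.05, 0.02, 0.01, 0.005, 0.001),
                                     family = c("stage", "tissue")) {
  family <- match.arg(family)
  if (length(known_events) == 0)
    warning("annotation_overlap_curve: empty known-events set")
  q <- if (family == "stage") exon_res$q_stage else exon_res$q_tissue
  rows <- lapply(sort(thresholds, decreasing = TRUE), function(th) {
    sig <- exon_res$feature_id[!is.na(q) & q <= th]
    n <- length(sig)
    pct <- if (n == 0) NA_real_
           else if (length(known_events) == 0) 0
           else 100 * length(intersect(sig, known_events)) / n
    data.frame(fdr_threshold = th, n_significant = n, pct_overlap = pct)
  })
  do.call(rbind, rows)
}

#' Parameter-recovery metrics against the synthetic ground truth
#'
#' Confusion counts, precision, recall and the realized false discovery
#' proportion at the significance cutoff, for each of the four effect
#' families: gene-tissue, gene-stage, exon-tissue, exon-stage. Only features
#' present in the result tables (the filtered universe) are scored.
#'
#' @param diff a `splicedex_differential` object.
#' @param truth the `truth` element of a `splicedex_dataset`.
#' @return data frame, one row per family, with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `realized_fdr`.
#' @export
recovery_metrics <- function(diff, truth) {
  score <- function(called_ids, true_ids, universe) {
    called <- intersect(called_ids, universe)
    true_u <- intersect(true_ids, universe)
    tp <- length(intersect(called, true_u))
    fp <- length(setdiff(called, true_u))
    fn <- length(setdiff(true_u, called))
    data.frame(tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               realized_fdr = if (tp + fp > 0) fp / (tp + fp) else 0)
  }
  ge <- truth$gene_effects
  ex <- truth$exon_effects
  g_univ <- diff$gene$feature_id
  e_univ <- diff$exon$feature_id
  if (!any(g_univ %in% ge$gene_id))
    .stopf("recovery_metrics: results and truth share no gene ids")
  fams <- rbind(
    cbind(family = "gene_tissue",
          score(diff$gene$feature_id[diff$gene$significant_tissue],
                ge$gene_id[ge$tissue_de], g_univ)),
    cbind(family = "gene_stage",
          score(diff$gene$feature_id[diff$gene$significant_stage],
                ge$gene_id[ge$stage_de], g_univ)),
    cbind(family = "exon_tissue",
          score(diff$exon$feature_id[diff$exon$significant_tissue],
                ex$probeset_id[ex$tissue_das], e_univ)),
    cbind(family = "exon_stage",
          score(diff$exon$feature_id[diff$exon$significant_stage],
                ex$probeset_id[ex$stage_das], e_univ))
  )
  rownames(fams) <- NULL
  fams
}
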