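#' Expressed-gene filter (chip-quartile rule)
#'
#' A gene is called "not expressed" on a chip when its summarized value lies
#' strictly below the lower quartile (25th percentile, linear interpolation)
#' of all gene values on that chip. Genes not expressed on **all** chips are
#' removed; `require = "all"` switches to the stricter variant where a gene
#' must exceed the quartile on every chip to survive. A mean-based variant
#' (`mode = "mean"`) compares each gene's cross-sample mean against every
#' chip's quartile instead.
#'
#' @param genes linear-scale gene x sample expression matrix.
#' @param quartile quantile level of the chip threshold.
#' @param require `"any"` (default: kept if expressed on at least one chip)
#'   or `"all"` (kept only if expressed on every chip).
#' @param mode `"per_sample"` (default) or `"mean"`.
#' @return character vector of kept gene ids.
#' @export
expressed_gene_filter <- function(genes, quartile = 0.25,
                                  require = c("any", "all"),
                                  mode = c("per_sample", "mean")) {
  require <- match.arg(require)
  mode <- match.arg(mode)
  thr <- apply(genes, 2, stats::quantile, probs = quartile, type = 7)
  vals <- if (mode == "mean")
    matrix(rowMeans(genes), nrow(genes), ncol(genes)) else genes
  not_expressed <- sweep(vals, 2, thr, `<`)
  removed <- if (require == "any") apply(not_expressed, 1, all)
             else apply(not_expressed, 1, any)
  rownames(genes)[!removed]
}

#' Cross-hybridization filter
#'
#' Removes probe sets whose intensity ratio to their meta probe set exceeds
#' 5, the signature of a probe picking up signal from other transcripts.
#'
#' @param probesets linear-scale probe-set x sample matrix.
#' @param genes linear-scale gene x sample matrix.
#' @param annotation probe-set -> meta-probe-set mapping (per-probe table
#'   accepted).
#' @param ratio_cutoff removal boundary (strictly greater than).
#' @param agg aggregate per-sample ratios by `"mean"` (default) or `"max"`.
#' @return character vector of removed probe-set ids.
#' @export
crosshyb_filter <- function(probesets, genes, annotation, ratio_cutoff = 5,
                            agg = c("mean", "max")) {
  agg <- match.arg(agg)
  map <- ps_to_gene(annotation)
  g <- map[rownames(probesets)]
  if (anyNA(g)) .stopf("crosshyb_filter: unmapped probe sets")
  gm <- genes[g, , drop = FALSE]
  if (any(gm <= 0)) .stopf("crosshyb_filter: nonpositive gene expression")
  ratio <- probesets / gm
  stat <- if (agg == "mean") rowMeans(ratio) else apply(ratio, 1, max)
  rownames(probesets)[stat > ratio_cutoff]
}

#' Dead (unresponsive) probe-set filter
#'
#' Per chip, the Benjamini-Hochberg cutoff at the given FDR is computed over
#' that chip's DABG p-value distribution (the largest p(i) with
#' p(i) <= fdr * i / m, or 0 when none qualifies). A probe set is dead when
#' its DABG p-value strictly exceeds the chip cutoff on every chip.
#'
#' @param dabg_p probe-set x sample DABG p-value matrix.
#' @param fdr per-chip FDR level.
#' @return character vector of removed (dead) probe-set ids.
#' @export
dead_probeset_filter <- function(dabg_p, fdr = 0.05) {
  m <- nrow(dabg_p)
  cutoffs <- apply(dabg_p, 2, function(p) {
    sp <- sort(p)
    ok <- sp <= fdr * seq_len(m) / m
    if (any(ok)) sp[max(which(ok))] else 0
  })
  if (any(cutoffs == 0))
    warning("dead_probeset_filter: no detection on some chips (cutoff 0)")
  above <- sweep(dabg_p, 2, cutoffs, `>`)
  rownames(dabg_p)[apply(above, 1, all)]
}

#' Log2-transform an expression matrix
#'
#' Variance-stabilizing log transform; errors on nonpositive values naming
#' the offending feature and sample.
#'
#' @param m linear-scale matrix, strictly positive.
#' @return log2 matrix with attribute `log2 = TRUE`.
#' @export
log_transform <- function(m) {
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    .stopf("log_transform: nonpositive value at feature %s, sample %s",
           rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]])
  out <- log2(m)
  attr(out, "log2") <- TRUE
  out
}

# map probeset_id -> metaprobeset_id from a per-probe or per-probe-set table
ps_to_gene <- function(annotation) {
  u <- unique(annotation[, c("probeset_id", "metaprobeset_id")])
  stats::setNames(u$metaprobeset_id, u$probeset_id)
}

#' Apply the three data-quality filters and the log transform
#'
#' Filters run in order: unexpressed genes (removing their constituent probe
#' sets), cross-hybridizing probe sets, dead probe sets; finally both
#' matrices are log2-transformed. Thresholds and bookkeeping are returned in
#' a filter report.
#'
#' @param prep a `splicedex_preprocessed` object (or list with
#'   `probeset_expr`, `gene_expr`, `dabg`, `annotation`, `design`).
#' @param quartile chip-quartile level for the expressed-gene filter.
#' @param ratio_cutoff cross-hybridization ratio boundary.
#' @param dabg_fdr per-chip FDR level for the dead filter.
#' @param require_expressed see [expressed_gene_filter()].
#' @return list of class `splicedex_filtered`: `probeset_log2`, `gene_log2`
#'   (log2 matrices restricted to kept features), `annotation`, `design`,
#'   and `report` (a `filter_report`).
#' @export
apply_filters <- function(prep, quartile = 0.25, ratio_cutoff = 5,
                          dabg_fdr = 0.05, require_expressed = c("any", "all")) {
  require_expressed <- match.arg(require_expressed)
  genes <- prep$gene_expr
  ps <- prep$probeset_expr
  map <- ps_to_gene(prep$annotation)

  n_genes_in <- nrow(genes)
  n_ps_in <- nrow(ps)

  kept_genes <- expressed_gene_filter(genes, quartile, require_expressed)
  removed_unexpressed <- setdiff(rownames(genes), kept_genes)
  genes <- genes[kept_genes, , drop = FALSE]
  keep_ps <- rownames(ps)[map[rownames(ps)] %in% kept_genes]
  removed_with_gene <- setdiff(rownames(ps), keep_ps)
  ps <- ps[keep_ps, , drop = FALSE]

  removed_crosshyb <- crosshyb_filter(ps, genes, prep$annotation, ratio_cutoff)
  ps <- ps[setdiff(rownames(ps), removed_crosshyb), , drop = FALSE]

  # chip-specific detection threshold from the chip's full DABG distribution
  dead_all <- dead_probeset_filter(prep$dabg, dabg_fdr)
  removed_dead <- intersect(rownames(ps), dead_all)
  ps <- ps[setdiff(rownames(ps), removed_dead), , drop = FALSE]

  report <- structure(list(
    n_metaprobesets_in = n_genes_in,
    n_metaprobesets_kept = nrow(genes),
    n_probesets_in = n_ps_in,
    n_probesets_kept = nrow(ps),
    removed_unexpressed = removed_unexpressed,
    removed_with_gene = removed_with_gene,
    removed_crosshyb = removed_crosshyb,
    removed_dead = removed_dead,
    thresholds = list(quartile = quartile, ratio_cutoff = ratio_cutoff,
                      dabg_fdr = dabg_fdr, require_expressed = require_expressed)
  ), class = "filter_report")

  structure(list(
    probeset_log2 = log_transform(ps),
    gene_log2 = log_transform(genes),
    annotation = prep$annotation,
    design = prep$design,
    report = report
  ), class = "splicedex_filtered")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  meta probe sets: %d -> %d (%d unexpressed)\n",
              x$n_metaprobesets_in, x$n_metaprobesets_kept,
              length(x$removed_unexpressed)))
  cat(sprintf("  probe sets: %d -> %d (%d cross-hyb, %d dead)\n",
              x$n_probesets_in, x$n_probesets_kept,
              length(x$removed_crosshyb), length(x$removed_dead)))
  cat(sprintf("  thresholds: quartile %.2f, ratio > %g, DABG FDR %.2f\n",
              x$thresholds$quartile, x$thresholds$ratio_cutoff,
              x$thresholds$dabg_fdr))
  invisible(x)
}
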