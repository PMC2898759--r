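#' Splicing index: exon expression normalized by gene expression
#'
#' `si = log2(probe-set / gene)` per sample. A change in the splicing index
#' across conditions indicates differential exon inclusion rather than a
#' whole-gene expression change, which cancels in the ratio.
#'
#' @param probesets linear-scale probe-set x sample matrix.
#' @param genes linear-scale gene x sample matrix.
#' @param annotation probe-set -> gene mapping table.
#' @return probe-set x sample matrix of log2 splicing indices.
#' @export
splicing_index <- function(probesets, genes, annotation) {
  map <- ps_to_gene(annotation)
  g <- map[rownames(probesets)]
  if (anyNA(g)) .stopf("splicing_index: unmapped probe sets")
  gm <- genes[g, , drop = FALSE]
  if (any(gm <= 0)) .stopf("splicing_index: nonpositive gene expression")
  if (any(probesets <= 0)) .stopf("splicing_index: nonpositive probe-set expression")
  si <- log2(probesets) - log2(gm)
  rownames(si) <- rownames(probesets)
  si
}

#' Tissue contrast: pooled-variance two-sample t-test
#'
#' Compares embryo against placenta using only the stages present in both
#' tissues (E9.5 and E11.5); E8.5 embryo samples are excluded so the pooled
#' groups are stage-matched.
#'
#' @param values per-sample numeric vector (log2 scale), named or ordered as
#'   `design$sample_id`.
#' @param design per-sample design table (`sample_id`, `tissue`, `stage`).
#' @return list with `t`, `df`, `p` (two-sided). Zero pooled variance yields
#'   `NA` statistics (the feature is flagged upstream and excluded from FDR).
#' @export
tissue_test <- function(values, design) {
  shared <- intersect(design$stage[design$tissue == "embryo"],
                      design$stage[design$tissue == "placenta"])
  use <- design$stage %in% shared
  g <- design$tissue[use]
  x <- values[use][g == "embryo"]
  y <- values[use][g == "placenta"]
  pooled_t(x, y)
}

pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) .stopf("tissue_test: need >= 2 samples per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (sp2 <= 0) return(list(t = NA_real_, df = df, p = NA_real_))
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Stage effect for the unbalanced design
#'
#' The missing E8.5 placenta cell rules out a standard two-way ANOVA, so the
#' stage effect is tested within each tissue and the two p-values are
#' combined: a pooled two-sample t-test in placenta (E9.5 vs E11.5), a
#' one-way fixed-effects ANOVA in embryo (E8.5, E9.5, E11.5), and Fisher's
#' method on the pair (chi-square, 4 df) under the joint null of no stage
#' variation in either tissue.
#'
#' @inheritParams tissue_test
#' @return list with `p_stage_placenta`, `p_stage_embryo`, `X2_combined`,
#'   `p_stage_combined` (NA when either component is undefined).
#' @export
stage_test <- function(values, design) {
  pl <- design$tissue == "placenta"
  em <- design$tissue == "embryo"
  p1 <- pooled_t(values[pl & design$stage == "E9.5"],
                 values[pl & design$stage == "E11.5"])$p
  p2 <- oneway_f(values[em], design$stage[em])$p
  if (is.na(p1) || is.na(p2))
    return(list(p_stage_placenta = p1, p_stage_embryo = p2,
                X2_combined = NA_real_, p_stage_combined = NA_real_))
  fc <- fisher_combine(c(p1, p2))
  list(p_stage_placenta = p1, p_stage_embryo = p2,
       X2_combined = fc$X2, p_stage_combined = fc$p)
}

oneway_f <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  if (any(gn < 2)) .stopf("stage_test: need >= 2 replicates per stage")
  ssb <- sum(gn * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  if (ssw <= 0) return(list(F = NA_real_, df1 = k - 1, df2 = n - k, p = NA_real_))
  F <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = F, df1 = k - 1, df2 = n - k,
       p = stats::pf(F, k - 1, n - k, lower.tail = FALSE))
}

#' Fisher's combined probability test
#'
#' `X2 = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom under the joint null.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return list with `X2`, `df`, and the combined `p`.
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0) .stopf("fisher_combine: empty input")
  if (any(pvalues <= 0 | pvalues > 1 | is.na(pvalues)))
    .stopf("fisher_combine: p-values must lie in (0, 1]")
  X2 <- -2 * sum(log(pvalues))
  k <- length(pvalues)
  list(X2 = X2, df = 2 * k,
       p = stats::pchisq(X2, df = 2 * k, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up adjustment `q_(i) = min_{j >= i}(p_(j) * m / j)`, capped at 1 and
#' reported in input order. NA inputs propagate as NA without entering the
#' adjustment. Delegates to [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values.
#' @return vector of q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  out <- rep(NA_real_, length(pvalues))
  ok <- !is.na(pvalues)
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

## vectorized per-row engines -------------------------------------------------

.row_group_stats <- function(m, idx) {
  x <- m[, idx, drop = FALSE]
  n <- length(idx)
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (n - 1)
  list(mu = mu, v = v, n = n)
}

.row_tissue_test <- function(m, design) {
  shared <- intersect(design$stage[design$tissue == "embryo"],
                      design$stage[design$tissue == "placenta"])
  use <- design$stage %in% shared
  a <- .row_group_stats(m, which(use & design$tissue == "embryo"))
  b <- .row_group_stats(m, which(use & design$tissue == "placenta"))
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$v + (b$n - 1) * b$v) / df
  t <- (a$mu - b$mu) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  t[sp2 <= 0] <- NA_real_
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(t_tissue = t, p_tissue = p)
}

.row_stage_test <- function(m, design) {
  pl95 <- which(design$tissue == "placenta" & design$stage == "E9.5")
  pl115 <- which(design$tissue == "placenta" & design$stage == "E11.5")
  a <- .row_group_stats(m, pl95)
  b <- .row_group_stats(m, pl115)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$v + (b$n - 1) * b$v) / df
  t <- (a$mu - b$mu) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  t[sp2 <= 0] <- NA_real_
  p1 <- 2 * stats::pt(-abs(t), df)

  em <- design$tissue == "embryo"
  stg <- unique(design$stage[em])
  parts <- lapply(stg, function(s) .row_group_stats(m, which(em & design$stage == s)))
  ntot <- sum(vapply(parts, `[[`, 0, "n"))
  grand <- Reduce(`+`, lapply(parts, function(p) p$n * p$mu)) / ntot
  ssb <- Reduce(`+`, lapply(parts, function(p) p$n * (p$mu - grand)^2))
  ssw <- Reduce(`+`, lapply(parts, function(p) (p$n - 1) * p$v))
  k <- length(stg)
  F <- (ssb / (k - 1)) / (ssw / (ntot - k))
  F[ssw <= 0] <- NA_real_
  p2 <- stats::pf(F, k - 1, ntot - k, lower.tail = FALSE)

  # Fisher combination across the two within-tissue tests
  X2 <- -2 * (log(p1) + log(p2))
  pc <- stats::pchisq(X2, df = 4, lower.tail = FALSE)
  data.frame(p_stage_placenta = p1, p_stage_embryo = p2,
             X2_combined = X2, p_stage_combined = pc)
}

.differential_table <- function(m, design, level, fdr) {
  tt <- .row_tissue_test(m, design)
  st <- .row_stage_test(m, design)
  res <- cbind(data.frame(feature_id = rownames(m), level = level,
                          stringsAsFactors = FALSE), tt, st)
  res$q_tissue <- bh_fdr(res$p_tissue)
  res$q_stage <- bh_fdr(res$p_stage_combined)
  res$significant_tissue <- !is.na(res$q_tissue) & res$q_tissue <= fdr
  res$significant_stage <- !is.na(res$q_stage) & res$q_stage <= fdr
  rownames(res) <- NULL
  res
}

#' Run gene- and exon-level differential tests with FDR control
#'
#' Gene-level tests run on log2 gene expression; exon-level tests run on the
#' log2 splicing index, so whole-gene shifts cancel and only isoform-level
#' changes register. BH adjustment is applied separately within each level
#' and effect family (tissue; combined stage). Features with zero variance in
#' a family are excluded from that family's adjustment (q = NA).
#'
#' @param filtered a `splicedex_filtered` object from [apply_filters()].
#' @param fdr FDR significance cutoff.
#' @return list of class `splicedex_differential`: `gene` and `exon` result
#'   data frames and `crosstab` (see [cross_tabulate()]).
#' @export
run_differential <- function(filtered, fdr = 0.05) {
  design <- filtered$design
  gene_res <- .differential_table(filtered$gene_log2, design, "gene", fdr)
  si <- filtered$probeset_log2 -
    filtered$gene_log2[ps_to_gene(filtered$annotation)[rownames(filtered$probeset_log2)], ,
                       drop = FALSE]
  rownames(si) <- rownames(filtered$probeset_log2)
  exon_res <- .differential_table(si, design, "exon", fdr)
  ct <- cross_tabulate(gene_res, exon_res, filtered$annotation)
  structure(list(gene = gene_res, exon = exon_res, crosstab = ct,
                 splicing_index = si, fdr = fdr),
            class = "splicedex_differential")
}

#' Cross-tabulate significant genes and exons
#'
#' Tallies, at each level, the features significant for the tissue effect
#' only, the stage effect only, or both, plus gene-level summaries of exon
#' calls: genes containing at least one significant exon, genes with both
#' tissue- and stage-significant exons, and exons significant for both
#' effects at once.
#'
#' @param gene_res,exon_res result tables from [run_differential()].
#' @param annotation probe-set -> gene mapping.
#' @return a named list of counts (class `splicedex_crosstab`).
#' @export
cross_tabulate <- function(gene_res, exon_res, annotation) {
  g_t <- gene_res$significant_tissue
  g_s <- gene_res$significant_stage
  e_t <- exon_res$significant_tissue
  e_s <- exon_res$significant_stage
  map <- ps_to_gene(annotation)
  exon_gene <- map[exon_res$feature_id]
  genes_t <- unique(exon_gene[e_t])
  genes_s <- unique(exon_gene[e_s])
  structure(list(
    genes_tissue_only = sum(g_t & !g_s),
    genes_stage_only = sum(g_s & !g_t),
    genes_both = sum(g_t & g_s),
    genes_tissue = sum(g_t),
    genes_stage = sum(g_s),
    exons_tissue_only = sum(e_t & !e_s),
    exons_stage_only = sum(e_s & !e_t),
    exons_both = sum(e_t & e_s),
    exons_tissue = sum(e_t),
    exons_stage = sum(e_s),
    genes_with_sig_exon = length(unique(exon_gene[e_t | e_s])),
    genes_with_tissue_and_stage_exons = length(intersect(genes_t, genes_s)),
    same_exon_both = sum(e_t & e_s)
  ), class = "splicedex_crosstab")
}

#' @export
print.splicedex_crosstab <- function(x, ...) {
  cat("<crosstab>\n")
  cat(sprintf("  genes: %d tissue / %d stage / %d both\n",
              x$genes_tissue, x$genes_stage, x$genes_both))
  cat(sprintf("  exons: %d tissue / %d stage / %d both (same exon)\n",
              x$exons_tissue, x$exons_stage, x$same_exon_both))
  cat(sprintf("  genes with >= 1 significant exon: %d\n", x$genes_with_sig_exon))
  invisible(x)
}
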