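#' Build a GC-bin background model from anti-genomic probes
#'
#' Anti-genomic probes hybridize to no genomic sequence and measure
#' non-specific binding as a function of GC content. The model groups their
#' intensities into 5 equal-width GC bins covering 0-100%.
#'
#' @param ag_gc per-probe GC percentage of the anti-genomic probes.
#' @param ag_intensities anti-genomic probe x sample intensity matrix (or a
#'   vector of pooled draws).
#' @param n_bins number of equal-width GC bins.
#' @return object of class `background_model`: bin edges, per-bin pooled
#'   intensities, and (when a matrix was supplied) per-bin per-sample
#'   intensities.
#' @export
background_model <- function(ag_gc, ag_intensities, n_bins = 5L) {
  edges <- .gc_bin_edges(n_bins)
  bin <- .gc_bin_index(ag_gc, edges)
  m <- if (is.matrix(ag_intensities)) ag_intensities else
    matrix(ag_intensities, ncol = 1L)
  pooled <- split(as.vector(m), rep(bin, ncol(m)))
  if (length(pooled) < n_bins || any(vapply(pooled, length, 1L) == 0L))
    .stopf("background model error: empty GC bin")
  per_sample <- lapply(seq_len(n_bins), function(b) m[bin == b, , drop = FALSE])
  structure(list(edges = edges,
                 pooled = pooled,
                 per_sample = if (is.matrix(ag_intensities)) per_sample,
                 sample_ids = colnames(ag_intensities)),
            class = "background_model")
}

#' Background-correct probe intensities against GC-matched controls
#'
#' Subtracts, from each probe, the median anti-genomic intensity of its GC
#' bin, flooring the result at `eps` so downstream log transforms stay
#' defined. Correction uses each sample's own anti-genomic draws when
#' `per_sample = TRUE` and the model carries them, else the pooled
#' distribution.
#'
#' @param raw probe x sample intensity matrix.
#' @param gc per-probe GC percentage (recycled across samples).
#' @param bg a [background_model()].
#' @param per_sample subtract per-sample bin medians instead of pooled.
#' @param eps floor for corrected intensities (intensity units).
#' @return corrected matrix, same shape as `raw`.
#' @export
background_correct <- function(raw, gc, bg, per_sample = FALSE, eps = 1.0) {
  bin <- .gc_bin_index(gc, bg$edges)
  if (per_sample && !is.null(bg$per_sample)) {
    med <- vapply(bg$per_sample, function(m) apply(m, 2, stats::median),
                  numeric(ncol(raw)))       # samples x bins
    corr <- raw - t(med)[bin, , drop = FALSE]
  } else {
    med <- vapply(bg$pooled, stats::median, numeric(1))
    corr <- raw - med[bin]
  }
  pmax(corr, eps)
}

#' Quantile-normalize columns to a common distribution
#'
#' Every sample (column) is mapped onto the mean of the sorted columns, the
#' standard reference distribution for multi-array normalization; ranks
#' within each column are preserved and ties receive the mean of the tied
#' target values. Delegates to [limma::normalizeQuantiles()].
#'
#' @param m numeric matrix, features x samples (probes or summarized).
#' @return matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2L) {
    warning("quantile_normalize: single sample, returning input unchanged")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Summarize probe intensities to probe-set or meta-probe-set expression
#'
#' The default summarization is Tukey median polish on log2 intensities
#' (the RMA-style robust fit): per feature, the fitted overall plus column
#' effects are exponentiated back to the linear scale, so probe affinity
#' (row) effects are removed. `method = "mean"` is the per-feature
#' arithmetic mean on the linear scale.
#'
#' @param probes probe x sample intensity matrix (strictly positive).
#' @param annotation data frame mapping `probe_id` to `probeset_id` and
#'   `metaprobeset_id`.
#' @param level `"probeset"` (exon) or `"metaprobeset"` (gene).
#' @param method `"median_polish"` or `"mean"`.
#' @param maxiter median-polish sweep count.
#' @return feature x sample expression matrix, linear scale.
#' @export
summarize_probes <- function(probes, annotation,
                             level = c("probeset", "metaprobeset"),
                             method = c("median_polish", "mean"),
                             maxiter = 10L) {
  level <- match.arg(level)
  method <- match.arg(method)
  key <- if (level == "probeset") "probeset_id" else "metaprobeset_id"
  map <- annotation[[key]][match(rownames(probes), annotation$probe_id)]
  if (anyNA(map))
    .stopf("summarize: %d probes missing from annotation", sum(is.na(map)))
  feats <- unique(map)

  if (method == "mean") {
    out <- rowsum(probes, group = map, reorder = FALSE) /
      as.vector(table(factor(map, levels = unique(map))))
    return(out[feats, , drop = FALSE])
  }

  lg <- log2(probes)
  S <- ncol(probes)
  out <- matrix(NA_real_, length(feats), S,
                dimnames = list(feats, colnames(probes)))
  # group features by probe count so each group polishes as one 3-d array
  idx_by_feat <- split(seq_len(nrow(probes)), factor(map, levels = feats))
  sizes <- lengths(idx_by_feat)
  if (any(sizes == 0L)) {
    warning("summarize: features with zero probes excluded")
    idx_by_feat <- idx_by_feat[sizes > 0L]
    sizes <- sizes[sizes > 0L]
  }
  for (kk in unique(sizes)) {
    which_f <- names(sizes)[sizes == kk]
    rows <- unlist(idx_by_feat[which_f], use.names = FALSE)
    z <- lg[rows, , drop = FALSE]              # (k * F) x S, probe-major
    out[which_f, ] <- .median_polish_grouped(z, k = kk, F = length(which_f),
                                             maxiter = maxiter)
  }
  2^out
}

# Tukey median polish run simultaneously over F features sharing probe
# count k; input z is (k*F) x S with probes of one feature contiguous.
# Returns the F x S fitted column profile (overall + column effects),
# matching stats::medpolish feature by feature, including its per-feature
# convergence rule (relative change of sum |residual| below eps).
.median_polish_grouped <- function(z, k, F, maxiter = 10L, eps = 0.01) {
  S <- ncol(z)
  r <- rep(0, k * F)                 # row (probe) effects
  ce <- matrix(0, F, S)              # column effects per feature
  m <- numeric(F)                    # overall per feature
  feat_of_row <- rep(seq_len(F), each = k)
  oldsum <- numeric(F)
  active <- rep(TRUE, F)
  for (it in seq_len(maxiter)) {
    af <- which(active)
    if (!length(af)) break
    rows <- which(feat_of_row %in% af)
    ka <- length(af)
    za <- z[rows, , drop = FALSE]

    rd <- .row_medians(za)
    za <- za - rd
    r[rows] <- r[rows] + rd
    delta <- .row_medians(ce[af, , drop = FALSE])
    ce[af, ] <- ce[af, , drop = FALSE] - delta
    m[af] <- m[af] + delta
    # per-feature, per-sample median over the k probes
    cd <- matrix(.col_medians(matrix(za, nrow = k)), ka, S)
    za <- za - cd[rep(seq_len(ka), each = k), , drop = FALSE]
    ce[af, ] <- ce[af, , drop = FALSE] + cd
    delta2 <- .col_medians(matrix(r[rows], nrow = k))
    r[rows] <- r[rows] - rep(delta2, each = k)
    m[af] <- m[af] + delta2

    z[rows, ] <- za
    newsum <- rowSums(matrix(colSums(matrix(abs(za), nrow = k)), ka, S))
    conv <- newsum == 0 | abs(newsum - oldsum[af]) < eps * newsum
    active[af] <- !conv
    oldsum[af] <- newsum
  }
  m + ce
}

#' Detection-above-background (DABG) p-values
#'
#' For each probe, the empirical probability that an intensity at least as
#' large as the observed one arises from the GC-matched anti-genomic
#' background: `p = (1 + #\{bg >= x\}) / (N + 1)` (add-one rule, so p stays
#' in (0, 1]). Probe p-values are combined into a per-probe-set p-value with
#' Fisher's method.
#'
#' @param probes raw probe x sample intensity matrix.
#' @param gc per-probe GC percentage.
#' @param bg a [background_model()].
#' @param annotation probe -> probe-set mapping.
#' @param per_sample compare against each sample's own background draws.
#' @return list with `probeset_p` (probe-set x sample matrix in (0,1]) and
#'   `probe_p` (probe x sample matrix).
#' @export
dabg <- function(probes, gc, bg, annotation, per_sample = FALSE) {
  bin <- .gc_bin_index(gc, bg$edges)
  S <- ncol(probes)
  probe_p <- matrix(NA_real_, nrow(probes), S, dimnames = dimnames(probes))
  for (b in seq_along(bg$pooled)) {
    rows <- which(bin == b)
    if (!length(rows)) next
    if (per_sample && !is.null(bg$per_sample)) {
      for (s in seq_len(S)) {
        ref <- sort(bg$per_sample[[b]][, s])
        n <- length(ref)
        ge <- n - findInterval(probes[rows, s], ref, left.open = TRUE)
        probe_p[rows, s] <- (1 + ge) / (n + 1)
      }
    } else {
      ref <- sort(bg$pooled[[b]])
      n <- length(ref)
      ge <- n - findInterval(probes[rows, , drop = FALSE], ref, left.open = TRUE)
      probe_p[rows, ] <- (1 + ge) / (n + 1)
    }
  }
  map <- annotation$probeset_id[match(rownames(probes), annotation$probe_id)]
  ps_ids <- unique(map)
  # Fisher's method per probe set and sample: X2 = -2 sum(log p), df = 2k
  lp <- rowsum(log(probe_p), group = map, reorder = FALSE)
  kcount <- as.vector(table(factor(map, levels = ps_ids)))
  ps_p <- stats::pchisq(-2 * lp[ps_ids, , drop = FALSE],
                        df = 2 * kcount, lower.tail = FALSE)
  # guard against exact zeros from tiny probe p
  ps_p[ps_p == 0] <- .Machine$double.xmin
  list(probeset_p = ps_p, probe_p = probe_p)
}

#' Run the full preprocessing chain on a dataset
#'
#' Background-correct, quantile-normalize, summarize to exon and gene level,
#' and compute DABG p-values (on the raw intensities, as detection is defined
#' against the raw background distribution).
#'
#' Undetected (dead) probe sets contribute floor-level values after
#' background correction; a model-based summarizer explains such probes away
#' as low affinities, but an additive log-scale polish lets them deflate the
#' gene's absolute level. To match the intended meta-probe-set semantics,
#' probes of probe sets that fail detection on every chip (see
#' [dead_probeset_filter()]) are excluded from the gene-level summary
#' (never from the probe-set level, where the dead filter needs them).
#'
#' @param dataset a `splicedex_dataset` (or a list with the same fields).
#' @param method summarization method, see [summarize_probes()].
#' @param per_sample_bg use per-sample anti-genomic draws (default pooled).
#' @param dabg_fdr per-chip FDR used to flag undetected probe sets for the
#'   gene-level summary exclusion.
#' @return list of class `splicedex_preprocessed`: `probeset_expr`,
#'   `gene_expr` (linear-scale matrices), `dabg` (probe-set p matrix),
#'   `annotation`, `design`, `background`.
#' @export
preprocess <- function(dataset, method = c("median_polish", "mean"),
                       per_sample_bg = FALSE, dabg_fdr = 0.05) {
  method <- match.arg(method)
  bg <- background_model(dataset$antigenomic$gc_percent,
                         dataset$antigenomic$intensities)
  d <- dabg(dataset$intensities, dataset$gc_percent, bg, dataset$annotation,
            per_sample = per_sample_bg)
  corr <- background_correct(dataset$intensities, dataset$gc_percent, bg,
                             per_sample = per_sample_bg)
  norm <- quantile_normalize(corr)

  ann <- dataset$annotation
  dead_ps <- dead_probeset_filter(d$probeset_p, fdr = dabg_fdr)
  gene_probes <- !(ann$probeset_id[match(rownames(norm), ann$probe_id)] %in% dead_ps)
  # a gene whose probe sets are all undetected keeps its probes
  gene_of_probe <- ann$metaprobeset_id[match(rownames(norm), ann$probe_id)]
  empty <- !gene_of_probe %in% gene_of_probe[gene_probes]
  gene_probes <- gene_probes | empty

  structure(list(
    probeset_expr = summarize_probes(norm, ann, "probeset", method),
    gene_expr = summarize_probes(norm[gene_probes, , drop = FALSE], ann,
                                 "metaprobeset", method),
    dabg = d$probeset_p,
    annotation = ann,
    design = dataset$design,
    background = bg
  ), class = "splicedex_preprocessed")
}
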