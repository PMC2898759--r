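#' Motif sets for RNA-binding-protein site scanning
#'
#' `"strict"` is the single hexamer UGCAUG, the highest-specificity Fox-family
#' binding site. `"all"` is a relaxed family of five related sites; the
#' default relaxed list is a documented placeholder (UGCAUG, GCAUG, UGCACG,
#' AGCAUG, UGCAUA) that users studying real data should replace with their
#' own curated list via `motifs =`.
#'
#' @param name `"strict"`, `"all"`, or `"custom"`.
#' @param motifs character vector of IUPAC motifs over A/C/G/U (or T), used
#'   when `name = "custom"`.
#' @return object of class `motif_set` (name + motif list, RNA alphabet).
#' @export
motif_set <- function(name = c("strict", "all", "custom"), motifs = NULL) {
  name <- match.arg(name)
  m <- switch(name,
    strict = "UGCAUG",
    all = c("UGCAUG", "GCAUG", "UGCACG", "AGCAUG", "UGCAUA"),
    custom = motifs
  )
  if (is.null(m) || length(m) == 0) .stopf("motif_set: empty motif list")
  m <- toupper(m)
  if (any(nchar(m) < 4)) .stopf("motif_set: motifs must be >= 4 nt")
  structure(list(name = name, motifs = m), class = "motif_set")
}

#' Scan a sequence window for motif occurrences
#'
#' Reports every exact occurrence of each motif (IUPAC codes in the motif
#' expand; overlapping hits are allowed; N in the window never matches).
#' T and U are equivalent: both motif and window are compared in DNA space.
#'
#' @param window a character string over A/C/G/T/U/N.
#' @param motifs a [motif_set()].
#' @return data frame with columns `motif` and `offset` (0-based), one row
#'   per hit; zero rows when nothing matches.
#' @export
scan_motifs <- function(window, motifs) {
  if (!inherits(motifs, "motif_set")) motifs <- motif_set("custom", motifs)
  w <- toupper(window)
  if (grepl("[^ACGTUN]", w))
    .stopf("scan_motifs: invalid character in window")
  w_dna <- chartr("U", "T", w)
  subj <- Biostrings::DNAString(w_dna)
  hits <- lapply(motifs$motifs, function(m) {
    pat <- chartr("U", "T", m)
    st <- Biostrings::start(Biostrings::matchPattern(
      pat, subj, fixed = c(pattern = FALSE, subject = TRUE)))
    if (length(st) == 0) return(NULL)
    data.frame(motif = m, offset = st - 1L, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(motif = character(), offset = integer(),
                       stringsAsFactors = FALSE)
  hits[order(hits$offset), , drop = FALSE]
}

#' Select significant cassette exons
#'
#' Returns the probe sets that are stage-significant in the exon-level
#' splicing-index results and carry a cassette-exon event annotation.
#'
#' @param exon_res exon-level result table from [run_differential()].
#' @param annotation per-probe or per-probe-set table with `probeset_id` and
#'   `event_class`.
#' @return character vector of probe-set ids.
#' @export
select_cassette_exons <- function(exon_res, annotation) {
  cls <- unique(annotation[, c("probeset_id", "event_class")])
  cassette <- cls$probeset_id[cls$event_class == "cassette"]
  exon_res$feature_id[exon_res$significant_stage &
                        exon_res$feature_id %in% cassette]
}

#' Exon inclusion ratio between two conditions
#'
#' `ratio = [mean_A(ps) / mean_A(gene)] / [mean_B(ps) / mean_B(gene)]` on the
#' linear scale: the probe-set level normalized to its meta probe set,
#' compared between conditions. A ratio above 1 means inclusion of the exon
#' is higher in condition A. Group means are used because replicates are
#' unpaired across conditions.
#'
#' @param ps_values per-sample probe-set expression (linear).
#' @param gene_values per-sample gene expression (linear).
#' @param design per-sample design table.
#' @param cond_a,cond_b lists with elements `tissue` and `stage` naming the
#'   two conditions.
#' @return the (linear) inclusion ratio.
#' @export
inclusion_ratio <- function(ps_values, gene_values, design, cond_a, cond_b) {
  pick <- function(cond) {
    use <- design$tissue == cond$tissue & design$stage == cond$stage
    if (sum(use) < 2) .stopf("inclusion_ratio: < 2 replicates in a condition")
    use
  }
  a <- pick(cond_a); b <- pick(cond_b)
  ma_ps <- mean(ps_values[a]); mb_ps <- mean(ps_values[b])
  ma_g <- mean(gene_values[a]); mb_g <- mean(gene_values[b])
  if (min(ma_ps, mb_ps, ma_g, mb_g) <= 0)
    .stopf("inclusion_ratio: nonpositive condition mean")
  (ma_ps / ma_g) / (mb_ps / mb_g)
}

#' One-tailed unpaired Welch's t-test
#'
#' Welch t statistic with Welch-Satterthwaite degrees of freedom; the
#' one-tailed p-value is for the alternative `mean(x) > mean(y)`.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @return list with `t`, `df`, `p_one_tailed`, and the two group means.
#' @export
welch_one_tailed <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    .stopf("welch_one_tailed: need >= 2 values per group")
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  if (v1 + v2 <= 0) return(list(t = NA_real_, df = NA_real_,
                                p_one_tailed = NA_real_,
                                mean_x = mean(x), mean_y = mean(y)))
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p_one_tailed = stats::pt(t, df, lower.tail = FALSE),
       mean_x = mean(x), mean_y = mean(y))
}

#' Position-dependent motif regulation analysis of cassette-exon inclusion
#'
#' The full regulator analysis: selects stage-significant cassette exons,
#' scans their 100 nt splice-site-proximal intron windows for binding
#' motifs, classifies exons by motif side (upstream / downstream / both /
#' none), computes inclusion ratios for each comparison, and tests the
#' directional hypothesis that downstream binding promotes inclusion while
#' upstream binding promotes skipping: a one-tailed unpaired Welch test of
#' mean(log2 ratio | downstream motif) > mean(log2 ratio | upstream motif),
#' on exons with motifs on exactly one side. Ratios are log-transformed to
#' stabilize their variance; the linear fold difference between the class
#' means is reported alongside.
#'
#' @param exon_res exon-level results from [run_differential()].
#' @param probeset_expr,gene_expr linear-scale expression matrices (the
#'   filtered universe).
#' @param annotation annotation table with `probeset_id`, `metaprobeset_id`,
#'   `event_class`.
#' @param design per-sample design table.
#' @param intron_windows named character vector
#'   (`"<probeset>|upstream"` / `"|downstream"`).
#' @param motifs a [motif_set()] (default strict).
#' @param comparisons named list of condition pairs; each element is
#'   `list(a = list(tissue=, stage=), b = list(tissue=, stage=))`. Default:
#'   E11.5 vs E8.5 within embryo, and E11.5 embryo vs E11.5 placenta.
#' @param min_per_class minimum exons per motif class for the test.
#' @return list of class `splicedex_fox2`: `records` (per-exon table with
#'   motif hits, side class and ratios) and `tests` (per comparison:
#'   `n_up`, `n_down`, class means of the log2 ratios, linear
#'   `fold_difference_of_means`, `t_welch`, `df_welch`, `p_one_tailed`;
#'   p is NA with a note when a class is underpowered).
#' @export
fox2_analysis <- function(exon_res, probeset_expr, gene_expr, annotation,
                          design, intron_windows,
                          motifs = motif_set("strict"),
                          comparisons = default_fox2_comparisons(),
                          min_per_class = 2L) {
  sel <- select_cassette_exons(exon_res, annotation)
  sel <- sel[sel %in% rownames(probeset_expr)]
  sel <- sel[sprintf("%s|upstream", sel) %in% names(intron_windows) &
               sprintf("%s|downstream", sel) %in% names(intron_windows)]
  map <- ps_to_gene(annotation)

  if (length(sel) == 0) {
    return(structure(list(
      records = data.frame(), tests = lapply(comparisons, function(x)
        list(n_up = 0L, n_down = 0L, p_one_tailed = NA_real_,
             note = "no significant cassette exons"))),
      class = "splicedex_fox2"))
  }

  n_hits <- function(ps, side) {
    nrow(scan_motifs(intron_windows[[sprintf("%s|%s", ps, side)]], motifs))
  }
  up_n <- vapply(sel, n_hits, 1L, side = "upstream")
  dn_n <- vapply(sel, n_hits, 1L, side = "downstream")
  side_class <- ifelse(up_n > 0 & dn_n > 0, "both",
                ifelse(up_n > 0, "upstream",
                ifelse(dn_n > 0, "downstream", "none")))

  ratios <- vapply(names(comparisons), function(cn) {
    cmp <- comparisons[[cn]]
    vapply(sel, function(ps)
      inclusion_ratio(probeset_expr[ps, ], gene_expr[map[[ps]], ], design,
                      cmp$a, cmp$b), numeric(1))
  }, numeric(length(sel)))
  ratios <- matrix(ratios, nrow = length(sel),
                   dimnames = list(sel, names(comparisons)))

  records <- data.frame(
    probeset_id = sel, gene_id = unname(map[sel]),
    n_hits_upstream = up_n, n_hits_downstream = dn_n,
    side_class = side_class, stringsAsFactors = FALSE, row.names = NULL)
  for (cn in names(comparisons)) {
    records[[paste0("ratio_", cn)]] <- ratios[, cn]
    records[[paste0("log2_ratio_", cn)]] <- log2(ratios[, cn])
  }

  tests <- lapply(names(comparisons), function(cn) {
    lr <- log2(ratios[, cn])
    dn <- lr[side_class == "downstream"]
    up <- lr[side_class == "upstream"]
    out <- list(comparison = cn, n_up = length(up), n_down = length(dn),
                mean_log_ratio_up = if (length(up)) mean(up) else NA_real_,
                mean_log_ratio_down = if (length(dn)) mean(dn) else NA_real_,
                fold_difference_of_means =
                  if (length(up) && length(dn))
                    mean(2^dn) / mean(2^up) else NA_real_)
    if (length(dn) < min_per_class || length(up) < min_per_class) {
      out$t_welch <- NA_real_; out$df_welch <- NA_real_
      out$p_one_tailed <- NA_real_
      out$note <- "underpowered: fewer than 2 exons in a motif class"
    } else {
      w <- welch_one_tailed(dn, up)
      out$t_welch <- w$t; out$df_welch <- w$df
      out$p_one_tailed <- w$p_one_tailed
    }
    out
  })
  names(tests) <- names(comparisons)
  structure(list(records = records, tests = tests, motifs = motifs),
            class = "splicedex_fox2")
}

#' Default regulator-analysis comparisons
#'
#' E11.5 vs E8.5 within embryo, and E11.5 embryo vs E11.5 placenta: the two
#' contrasts with the largest regulator expression differences in the design.
#'
#' @return named list of condition pairs for [fox2_analysis()].
#' @export
default_fox2_comparisons <- function() {
  list(
    e115_vs_e85 = list(a = list(tissue = "embryo", stage = "E11.5"),
                       b = list(tissue = "embryo", stage = "E8.5")),
    e115e_vs_p115 = list(a = list(tissue = "embryo", stage = "E11.5"),
                         b = list(tissue = "placenta", stage = "E11.5"))
  )
}

#' @export
print.splicedex_fox2 <- function(x, ...) {
  cat("<fox2 analysis>\n")
  for (t in x$tests) {
    cat(sprintf("  %s: n_down=%d n_up=%d fold_diff=%.3g p=%.4g\n",
                t$comparison, t$n_down, t$n_up,
                t$fold_difference_of_means,
                t$p_one_tailed))
  }
  invisible(x)
}
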