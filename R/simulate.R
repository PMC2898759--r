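#' Simulate a probe-level exon-array dataset with known ground truth
#'
#' Generates raw probe intensities for an unbalanced tissue-by-stage design,
#' together with anti-genomic background probes, a probe -> probe set -> meta
#' probe set annotation with genomic coordinates, splice-site-proximal intron
#' windows for cassette-annotated exons, and a ground-truth table of every
#' planted effect.
#'
#' The generative model, per gene g and sample s: the log2 gene level is
#' `baseline_g + tissue effect + stage effect`; each probe set adds its
#' planted splicing-index shift; each probe adds a fixed affinity offset and
#' Gaussian log2 noise; the linear intensity is that signal plus a draw from
#' the GC-bin background distribution. Unexpressed genes emit background
#' only; dead probe sets hybridize below background (attenuated by
#' `dead_attenuation_log2`); cross-hybridizing probe sets sit
#' `crosshyb_log2_offset` log2 units above their gene. All output is
#' deterministic given `config$seed`.
#'
#' Motif-coupled regulation is planted separately by
#' [plant_fox2_regulation()]; this function only designates the regulator
#' gene and generates motif-free intron windows.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `splicedex_dataset`: a list with elements
#'   `intensities` (probe x sample matrix), `gc_percent` (named per-probe
#'   vector), `antigenomic` (list: `gc_percent`, `intensities`),
#'   `annotation` (per-probe data frame), `design` (per-sample data frame),
#'   `intron_windows` (named character vector, names
#'   `"<probeset>|upstream"` / `"|downstream"`, 100 nt each), `truth`
#'   (list: `gene_effects`, `exon_effects`, `fox2_targets`,
#'   `fox2_gene_id`), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)

  design <- expand_design(config$design)
  S <- nrow(design)

  ## ---- feature universe -------------------------------------------------
  n_genes <- config$n_genes
  gene_ids <- sprintf("MPS%05d", seq_len(n_genes))
  n_exons <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]),
                    n_genes, replace = TRUE)
  ps_gene_idx <- rep(seq_len(n_genes), n_exons)
  exon_rank <- unlist(lapply(n_exons, seq_len), use.names = FALSE)
  ps_ids <- sprintf("%s_PS%02d", gene_ids[ps_gene_idx], exon_rank)
  n_ps <- length(ps_ids)
  k <- config$probes_per_probeset
  probe_ps_idx <- rep(seq_len(n_ps), each = k)
  probe_ids <- sprintf("%s_PR%d", ps_ids[probe_ps_idx], rep(seq_len(k), n_ps))
  n_probes <- length(probe_ids)

  gc_percent <- round(stats::runif(n_probes, 10, 90), 1)
  names(gc_percent) <- probe_ids

  ## ---- event-class annotation (emulating a known-alt-events track) ------
  event_class <- rep("none", n_ps)
  is_first <- exon_rank == 1L
  is_last <- exon_rank == n_exons[ps_gene_idx]
  middle <- which(!is_first & !is_last)
  n_cas <- min(length(middle), round(config$frac_cassette_annotated * n_ps))
  if (n_cas > 0)
    event_class[sample(middle, n_cas)] <- "cassette"
  firsts <- which(is_first)
  lasts <- which(is_last & !is_first)
  if (length(firsts) > 1)
    event_class[sample(firsts, max(1, round(0.10 * length(firsts))))] <- "alt_promoter"
  if (length(lasts) > 1)
    event_class[sample(lasts, max(1, round(0.10 * length(lasts))))] <- "alt_3end"
  # mutually exclusive pairs: adjacent unannotated middle exons
  me_pool <- which(event_class == "none" & !is_first & !is_last)
  me_pool <- me_pool[(me_pool + 1L) %in% me_pool &
                       ps_gene_idx[me_pool] == ps_gene_idx[pmin(me_pool + 1L, n_ps)] &
                       event_class[pmin(me_pool + 1L, n_ps)] == "none"]
  n_me <- min(length(me_pool), max(0, round(0.02 * n_ps)))
  if (n_me > 0) {
    me_first <- sample(me_pool, n_me)
    me_first <- me_first[!((me_first - 1L) %in% me_first)]  # avoid chained pairs
    event_class[me_first] <- "mutually_exclusive"
    event_class[me_first + 1L] <- "mutually_exclusive"
  }

  ## ---- planted gene effects ---------------------------------------------
  unexpressed <- rep(FALSE, n_genes)
  n_unexpr <- round(config$frac_unexpressed_genes * n_genes)
  if (n_unexpr > 0) unexpressed[sample(n_genes, n_unexpr)] <- TRUE
  expressed_idx <- which(!unexpressed)

  regulator_idx <- sample(expressed_idx, 1L)
  fox2_gene_id <- gene_ids[regulator_idx]

  tissue_de <- stage_de <- rep(FALSE, n_genes)
  tissue_lfc <- stage_lfc <- rep(0, n_genes)
  de_pool <- setdiff(expressed_idx, regulator_idx)
  n_de <- round(config$frac_de_genes * length(expressed_idx))
  if (n_de > length(de_pool))
    .stopf("configuration error: frac_de_genes leaves no eligible genes")
  if (n_de > 0) {
    de_idx <- sample(de_pool, n_de)
    kind <- sample(c("tissue", "stage", "both"), n_de, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
    t_idx <- de_idx[kind != "stage"]
    s_idx <- de_idx[kind != "tissue"]
    tissue_de[t_idx] <- TRUE
    tissue_lfc[t_idx] <- sample(c(-1, 1), length(t_idx), TRUE) * config$de_log2fc
    stage_de[s_idx] <- TRUE
    stage_lfc[s_idx] <- sample(c(-1, 1), length(s_idx), TRUE) * config$de_log2fc
  }

  ## ---- planted probe-set artifacts and isoform effects -------------------
  dead <- crosshyb <- tissue_das <- stage_das <- rep(FALSE, n_ps)
  tissue_si <- stage_si <- rep(0, n_ps)
  ps_eligible <- which(!unexpressed[ps_gene_idx] & ps_gene_idx != regulator_idx)

  n_dead <- round(config$frac_dead_probesets * n_ps)
  n_xh <- round(config$frac_crosshyb_probesets * n_ps)
  if (n_dead + n_xh > length(ps_eligible))
    .stopf("configuration error: artifact fractions exceed eligible probe sets")
  art <- if (n_dead + n_xh > 0) sample(ps_eligible, n_dead + n_xh) else integer()
  dead[art[seq_len(n_dead)]] <- TRUE
  crosshyb[art[n_dead + seq_len(n_xh)]] <- TRUE

  das_pool <- setdiff(which(event_class != "none"), c(which(dead | crosshyb),
                                                      setdiff(seq_len(n_ps), ps_eligible)))
  n_das <- round(config$frac_das_exons * n_ps)
  if (n_das > 0) {
    if (length(das_pool) < n_das)
      .stopf("configuration error: only %d annotated probe sets eligible for %d DAS effects",
             length(das_pool), n_das)
    das_idx <- sample(das_pool, n_das)
    fam <- sample(c("tissue", "stage"), n_das, replace = TRUE)
    sgn <- sample(c(-1, 1), n_das, TRUE)
    for (j in seq_len(n_das)) {
      i <- das_idx[j]
      ids <- i
      if (event_class[i] == "mutually_exclusive") {
        # partner exon moves in the opposite direction
        partner <- if (i < n_ps && ps_gene_idx[i + 1L] == ps_gene_idx[i] &&
                       event_class[i + 1L] == "mutually_exclusive") i + 1L
                   else i - 1L
        if (partner >= 1 && partner <= n_ps && !dead[partner] && !crosshyb[partner])
          ids <- c(i, partner)
      }
      s2 <- config$das_delta_si * sgn[j] * c(1, -1)[seq_along(ids)]
      if (fam[j] == "tissue") {
        tissue_das[ids] <- TRUE
        tissue_si[ids] <- s2
      } else {
        stage_das[ids] <- TRUE
        stage_si[ids] <- s2
      }
    }
  }

  ## ---- expression surface -----------------------------------------------
  baseline <- stats::rnorm(n_genes, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  is_embryo <- design$tissue == "embryo"
  sfrac <- .stage_frac(design$stage)
  # gene-level log2 mean per sample: tissue effect applied to embryo,
  # stage effect as a gradient over developmental time in both tissues
  gene_mu <- outer(baseline, rep(1, S)) +
    outer(tissue_lfc, as.numeric(is_embryo)) +
    outer(stage_lfc, sfrac)

  si <- matrix(0, n_ps, S)
  if (any(tissue_das)) si <- si + outer(tissue_si, as.numeric(is_embryo))
  if (any(stage_das)) si <- si + outer(stage_si, sfrac)

  ps_level <- gene_mu[ps_gene_idx, , drop = FALSE] + si +
    crosshyb * config$crosshyb_log2_offset

  affinity <- stats::rnorm(n_probes, 0, config$probe_affinity_sd)
  probe_log2 <- ps_level[probe_ps_idx, , drop = FALSE] + affinity +
    matrix(stats::rnorm(n_probes * S, 0, config$noise_sd), n_probes, S)

  bin <- .gc_bin_index(gc_percent)
  bg_mu <- config$bg_mu_by_gc[bin]
  bg_draw <- matrix(2^stats::rnorm(n_probes * S, bg_mu, config$bg_sd),
                    n_probes, S)

  intens <- 2^probe_log2 + bg_draw
  # background-only and attenuated-background probes
  probe_unexpr <- unexpressed[ps_gene_idx][probe_ps_idx]
  probe_dead <- dead[probe_ps_idx]
  if (any(probe_unexpr))
    intens[probe_unexpr, ] <- bg_draw[probe_unexpr, ]
  if (any(probe_dead)) {
    nd <- sum(probe_dead)
    intens[probe_dead, ] <- matrix(
      2^stats::rnorm(nd * S, bg_mu[probe_dead] - config$dead_attenuation_log2,
                     config$bg_sd), nd, S)
  }
  dimnames(intens) <- list(probe_ids, design$sample_id)

  ## ---- anti-genomic background probes ------------------------------------
  n_ag <- config$n_antigenomic_per_bin
  ag_gc <- rep(c(10, 30, 50, 70, 90), each = n_ag)
  ag_mu <- config$bg_mu_by_gc[.gc_bin_index(ag_gc)]
  ag <- matrix(2^stats::rnorm(length(ag_gc) * S, ag_mu, config$bg_sd),
               length(ag_gc), S,
               dimnames = list(sprintf("AG%05d", seq_along(ag_gc)),
                               design$sample_id))
  names(ag_gc) <- rownames(ag)

  ## ---- annotation with fabricated coordinates ----------------------------
  exon_start <- 10000L + (exon_rank - 1L) * 2000L
  gene_chrom <- sprintf("chr%d", (seq_len(n_genes) - 1L) %% 19L + 1L)
  gene_strand <- sample(c("+", "-"), n_genes, TRUE)
  probe_off <- (rep(seq_len(k), n_ps) - 1L) * 30L
  annotation <- data.frame(
    probe_id = probe_ids,
    probeset_id = ps_ids[probe_ps_idx],
    metaprobeset_id = gene_ids[ps_gene_idx[probe_ps_idx]],
    chrom = gene_chrom[ps_gene_idx[probe_ps_idx]],
    start = exon_start[probe_ps_idx] + probe_off,
    end = exon_start[probe_ps_idx] + probe_off + 25L,
    strand = gene_strand[ps_gene_idx[probe_ps_idx]],
    event_class = event_class[probe_ps_idx],
    stringsAsFactors = FALSE
  )

  ## ---- motif-free intron windows for cassette-annotated exons ------------
  cas_ps <- ps_ids[event_class == "cassette"]
  intron_windows <- make_clean_windows(cas_ps)

  truth <- list(
    gene_effects = data.frame(
      gene_id = gene_ids, unexpressed = unexpressed,
      tissue_de = tissue_de, stage_de = stage_de,
      tissue_lfc = tissue_lfc, stage_lfc = stage_lfc,
      is_regulator = seq_len(n_genes) == regulator_idx,
      stringsAsFactors = FALSE),
    exon_effects = data.frame(
      probeset_id = ps_ids, gene_id = gene_ids[ps_gene_idx],
      event_class = event_class,
      tissue_das = tissue_das, stage_das = stage_das,
      tissue_si_shift = tissue_si, stage_si_shift = stage_si,
      dead = dead, crosshyb = crosshyb,
      fox2_side = NA_character_, fox2_sign = 0,
      stringsAsFactors = FALSE),
    fox2_targets = data.frame(probeset_id = character(), side = character(),
                              sign = numeric(), stringsAsFactors = FALSE),
    fox2_gene_id = fox2_gene_id
  )

  structure(list(
    intensities = intens,
    gc_percent = gc_percent,
    antigenomic = list(gc_percent = ag_gc, intensities = ag),
    annotation = annotation,
    design = design,
    intron_windows = intron_windows,
    truth = truth,
    config = config
  ), class = "splicedex_dataset")
}

# expand a (tissue, stage, n_replicates) layout into one row per array
expand_design <- function(design_tbl) {
  rows <- lapply(seq_len(nrow(design_tbl)), function(i) {
    r <- design_tbl[i, ]
    data.frame(
      sample_id = sprintf("%s_%s_%d", r$tissue, r$stage, seq_len(r$n_replicates)),
      tissue = r$tissue, stage = r$stage, replicate = seq_len(r$n_replicates),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# default motif family used to scrub generated windows, DNA alphabet;
# keeping windows free of the whole family makes planted sides unambiguous
.scrub_motifs <- function() c("GCATG", "TGCACG", "AGCATG", "TGCATA", "TGCATG")

# random 100 nt windows, rejection-sampled to contain none of the scrub motifs
make_clean_windows <- function(cassette_ps, width = 100L) {
  n <- 2L * length(cassette_ps)
  if (n == 0L) return(stats::setNames(character(), character()))
  gen <- function(m) {
    vapply(seq_len(m), function(i)
      paste(sample(c("A", "C", "G", "T"), width, TRUE), collapse = ""),
      character(1))
  }
  w <- gen(n)
  motifs <- .scrub_motifs()
  repeat {
    bad <- Reduce(`|`, lapply(motifs, function(m) grepl(m, w, fixed = TRUE)))
    if (!any(bad)) break
    w[bad] <- gen(sum(bad))
  }
  names(w) <- c(sprintf("%s|upstream", cassette_ps),
                sprintf("%s|downstream", cassette_ps))
  w
}

#' Plant motif-coupled splicing regulation driven by a regulator gene
#'
#' Multiplies the designated regulator gene's expression across embryo stages
#' so that it reaches `fox2_fold_e85_e115` at E11.5 relative to E8.5 (flat in
#' placenta), couples the splicing index of selected cassette exons to the
#' regulator level (positively for exons with a downstream-intron motif,
#' negatively for upstream-intron motifs), and writes the UGCAUG site (DNA:
#' TGCATG) into the corresponding 100 nt intron window. Non-target windows
#' were rejection-sampled free of the motif family at generation time.
#'
#' @param dataset a `splicedex_dataset` from [simulate_dataset()].
#' @param config the same [sim_config()]; `n_fox2_up_exons`,
#'   `n_fox2_down_exons`, `fox2_fold_e85_e115` and `fox2_coupling` control
#'   the planting. Deterministic given `config$seed`.
#' @return the modified `splicedex_dataset` with `truth$fox2_targets` filled.
#' @export
plant_fox2_regulation <- function(dataset, config = dataset$config) {
  n_up <- config$n_fox2_up_exons
  n_dn <- config$n_fox2_down_exons
  if (n_up + n_dn == 0L) return(dataset)
  set.seed(config$seed + 1000003L)

  ex <- dataset$truth$exon_effects
  ge <- dataset$truth$gene_effects
  reg_id <- dataset$truth$fox2_gene_id
  eligible <- ex$event_class == "cassette" & !ex$tissue_das & !ex$stage_das &
    !ex$dead & !ex$crosshyb & ex$gene_id != reg_id &
    !ge$unexpressed[match(ex$gene_id, ge$gene_id)]
  pool <- ex$probeset_id[eligible]
  if (length(pool) < n_up + n_dn)
    .stopf("planting error: %d eligible cassette exons, %d required",
           length(pool), n_up + n_dn)

  targets <- sample(pool, n_up + n_dn)
  side <- c(rep("downstream", n_dn), rep("upstream", n_up))
  sgn <- ifelse(side == "downstream", 1, -1) * sign(config$fox2_coupling)

  design <- dataset$design
  sfrac <- .stage_frac(design$stage) * (design$tissue == "embryo")
  reg_log2 <- log2(config$fox2_fold_e85_e115) * sfrac  # regulator offset/sample

  ann <- dataset$annotation
  intens <- dataset$intensities

  # regulator gene expression ramps across embryo stages
  reg_probes <- ann$probe_id[ann$metaprobeset_id == reg_id]
  intens[reg_probes, ] <- sweep(intens[reg_probes, , drop = FALSE], 2,
                                2^reg_log2, `*`)

  coup <- abs(config$fox2_coupling)
  for (j in seq_along(targets)) {
    pr <- ann$probe_id[ann$probeset_id == targets[j]]
    shift <- sgn[j] * coup * reg_log2
    intens[pr, ] <- sweep(intens[pr, , drop = FALSE], 2, 2^shift, `*`)
    # write the motif into the matching intron window
    key <- sprintf("%s|%s", targets[j], side[j])
    w <- dataset$intron_windows[[key]]
    off <- sample.int(nchar(w) - 6L + 1L, 1L)
    substr(w, off, off + 5L) <- "TGCATG"
    dataset$intron_windows[[key]] <- w
  }

  ti <- match(targets, ex$probeset_id)
  ex$fox2_side[ti] <- side
  ex$fox2_sign[ti] <- sgn
  ex$stage_das[ti] <- TRUE
  ex$stage_si_shift[ti] <- sgn * coup * log2(config$fox2_fold_e85_e115)
  ri <- ge$gene_id == reg_id
  ge$stage_de[ri] <- TRUE
  ge$stage_lfc[ri] <- log2(config$fox2_fold_e85_e115)

  dataset$intensities <- intens
  dataset$truth$exon_effects <- ex
  dataset$truth$gene_effects <- ge
  dataset$truth$fox2_targets <- data.frame(probeset_id = targets, side = side,
                                           sign = sgn, stringsAsFactors = FALSE)
  dataset
}

#' @export
print.splicedex_dataset <- function(x, ...) {
  cat("<splicedex_dataset>\n")
  cat(sprintf("  %d probes x %d samples; %d probe sets, %d genes\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$annotation$probeset_id)),
              length(unique(x$annotation$metaprobeset_id))))
  cat(sprintf("  %d intron windows; %d planted regulator targets; seed %d\n",
              length(x$intron_windows), nrow(x$truth$fox2_targets),
              x$config$seed))
  invisible(x)
}
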