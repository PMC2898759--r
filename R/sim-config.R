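#' Simulation configuration for the synthetic exon-array generator
#'
#' Builds and validates the parameter set controlling [simulate_dataset()].
#' The defaults emulate the study design the pipeline targets: two tissues
#' (embryo at stages E8.5/E9.5/E11.5, placenta at E9.5/E11.5) with five
#' biological replicates per tissue/stage (25 arrays), log-normal probe
#' intensities on top of a GC-dependent non-specific background, and planted
#' whole-gene expression effects, isoform (splicing-index) effects, and data
#' artifacts (unexpressed genes, dead probe sets, cross-hybridizing probe
#' sets) recorded in a ground-truth table.
#'
#' @param n_genes number of meta probe sets (genes) to simulate.
#' @param exons_per_gene integer range `c(min, max)`; each gene draws its
#'   probe-set (exon) count uniformly from this range.
#' @param probes_per_probeset probes interrogating each exon.
#' @param design data frame with columns `tissue`, `stage`, `n_replicates`
#'   (one row per tissue/stage cell). Default: embryo x {E8.5, E9.5, E11.5}
#'   and placenta x {E9.5, E11.5}, 5 replicates each.
#' @param frac_de_genes proportion of expressed genes given whole-gene
#'   differential-expression effects (tissue and/or stage).
#' @param frac_das_exons proportion of eligible probe sets given
#'   differential-splicing (splicing-index) effects.
#' @param de_log2fc whole-gene effect size, log2 units.
#' @param das_delta_si splicing-index shift for planted isoform effects,
#'   log2 units.
#' @param frac_unexpressed_genes proportion of genes emitting background only.
#' @param frac_dead_probesets proportion of probe sets (within expressed
#'   genes) that are unresponsive.
#' @param frac_crosshyb_probesets proportion of probe sets (within expressed
#'   genes) planted as cross-hybridizing (intensity far above their gene).
#' @param noise_sd probe-level log2 noise standard deviation.
#' @param probe_affinity_sd standard deviation of the per-probe affinity
#'   offset (log2 units), drawn once per probe.
#' @param baseline_log2_mean,baseline_log2_sd log2 location and spread of
#'   expressed-gene baselines. The default spread is deliberately narrow
#'   (a tight common expression scale) so the quantile-based expression
#'   filter has a well-defined planted ground truth; see the methods
#'   vignette.
#' @param bg_mu_by_gc log2 mean of the background intensity in each of the 5
#'   GC bins (low to high GC).
#' @param bg_sd log2 standard deviation of the background distribution.
#' @param n_antigenomic_per_bin anti-genomic control probes per GC bin.
#' @param dead_attenuation_log2 how many log2 units dimmer than their GC-bin
#'   background dead probes hybridize.
#' @param crosshyb_log2_offset log2 offset added to cross-hybridizing probe
#'   sets (default 5, i.e. 32x their gene level, well past the ratio-5
#'   filter boundary).
#' @param frac_cassette_annotated fraction of probe sets carrying a
#'   "cassette" event annotation (the pool from which motif-regulated exons
#'   are drawn).
#' @param n_fox2_up_exons,n_fox2_down_exons number of cassette exons coupled
#'   to the regulator through an upstream-/downstream-intron motif.
#' @param fox2_fold_e85_e115 fold change of the regulator gene between E8.5
#'   and E11.5 embryos (default 2, flat in placenta).
#' @param fox2_coupling splicing-index log2 shift per regulator log2 unit;
#'   positive couples downstream-motif exons positively (sign is flipped for
#'   upstream-motif exons). A negative value inverts both directions.
#' @param seed integer RNG seed; all generator output is deterministic given
#'   the config.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()], [plant_fox2_regulation()]
#' @export
sim_config <- function(n_genes = 500L,
                       exons_per_gene = c(6L, 12L),
                       probes_per_probeset = 4L,
                       design = default_design(),
                       frac_de_genes = 0.10,
                       frac_das_exons = 0.05,
                       de_log2fc = 1.0,
                       das_delta_si = 2.0,
                       frac_unexpressed_genes = 0.05,
                       frac_dead_probesets = 0.02,
                       frac_crosshyb_probesets = 0.02,
                       noise_sd = 0.7,
                       probe_affinity_sd = 0.5,
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 0.1,
                       bg_mu_by_gc = c(3, 3.5, 4, 4.5, 5),
                       bg_sd = 0.5,
                       n_antigenomic_per_bin = 500L,
                       dead_attenuation_log2 = 2,
                       crosshyb_log2_offset = 5,
                       frac_cassette_annotated = 0.15,
                       n_fox2_up_exons = 20L,
                       n_fox2_down_exons = 20L,
                       fox2_fold_e85_e115 = 2.0,
                       fox2_coupling = 1.65,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    probes_per_probeset = as.integer(probes_per_probeset),
    design = design,
    frac_de_genes = frac_de_genes,
    frac_das_exons = frac_das_exons,
    de_log2fc = de_log2fc,
    das_delta_si = das_delta_si,
    frac_unexpressed_genes = frac_unexpressed_genes,
    frac_dead_probesets = frac_dead_probesets,
    frac_crosshyb_probesets = frac_crosshyb_probesets,
    noise_sd = noise_sd,
    probe_affinity_sd = probe_affinity_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    bg_mu_by_gc = bg_mu_by_gc,
    bg_sd = bg_sd,
    n_antigenomic_per_bin = as.integer(n_antigenomic_per_bin),
    dead_attenuation_log2 = dead_attenuation_log2,
    crosshyb_log2_offset = crosshyb_log2_offset,
    frac_cassette_annotated = frac_cassette_annotated,
    n_fox2_up_exons = as.integer(n_fox2_up_exons),
    n_fox2_down_exons = as.integer(n_fox2_down_exons),
    fox2_fold_e85_e115 = fox2_fold_e85_e115,
    fox2_coupling = fox2_coupling,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default unbalanced tissue-by-stage design
#'
#' Two tissues with five biological replicates per tissue/stage; the placenta
#' lacks the E8.5 time point, which is what makes the design unbalanced.
#'
#' @param n_replicates replicates per tissue/stage cell.
#' @return data frame with columns `tissue`, `stage`, `n_replicates`.
#' @export
default_design <- function(n_replicates = 5L) {
  data.frame(
    tissue = c("embryo", "embryo", "embryo", "placenta", "placenta"),
    stage = c("E8.5", "E9.5", "E11.5", "E9.5", "E11.5"),
    n_replicates = as.integer(n_replicates),
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  props <- c("frac_de_genes", "frac_das_exons", "frac_unexpressed_genes",
             "frac_dead_probesets", "frac_crosshyb_probesets",
             "frac_cassette_annotated")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      .stopf("configuration error: %s must be a proportion in [0, 1]", p)
  }
  if (cfg$n_genes < 1L) .stopf("configuration error: n_genes must be >= 1")
  if (length(cfg$exons_per_gene) != 2L ||
      cfg$exons_per_gene[1] < 1L ||
      cfg$exons_per_gene[2] < cfg$exons_per_gene[1])
    .stopf("configuration error: exons_per_gene must be an increasing range")
  if (cfg$probes_per_probeset < 1L)
    .stopf("configuration error: probes_per_probeset must be >= 1")
  d <- cfg$design
  if (!all(c("tissue", "stage", "n_replicates") %in% names(d)))
    .stopf("configuration error: design needs tissue, stage, n_replicates")
  if (any(d$n_replicates < 2L))
    .stopf("configuration error: design replicate counts must be >= 2")
  if (!all(d$stage %in% c("E8.5", "E9.5", "E11.5")))
    .stopf("configuration error: stages must be among E8.5, E9.5, E11.5")
  if (cfg$fox2_fold_e85_e115 <= 0)
    .stopf("configuration error: fox2_fold_e85_e115 must be > 0")
  if (length(cfg$bg_mu_by_gc) != 5L)
    .stopf("configuration error: bg_mu_by_gc must give 5 GC-bin means")
  if (cfg$noise_sd < 0 || cfg$bg_sd <= 0)
    .stopf("configuration error: noise/background sd must be positive")
  n_unexpr <- round(cfg$frac_unexpressed_genes * cfg$n_genes)
  if (cfg$n_genes - n_unexpr < 1L)
    .stopf("configuration error: no expressed genes left under %s",
           "frac_unexpressed_genes")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes x %d-%d exons x %d probes; %d samples\n",
              x$n_genes, x$exons_per_gene[1], x$exons_per_gene[2],
              x$probes_per_probeset, sum(x$design$n_replicates)))
  cat(sprintf("  DE: %.0f%% genes at %.2g log2FC; DAS: %.0f%% exons at %.2g SI units\n",
              100 * x$frac_de_genes, x$de_log2fc,
              100 * x$frac_das_exons, x$das_delta_si))
  cat(sprintf("  artifacts: %.0f%% unexpressed, %.0f%% dead, %.0f%% cross-hyb\n",
              100 * x$frac_unexpressed_genes, 100 * x$frac_dead_probesets,
              100 * x$frac_crosshyb_probesets))
  cat(sprintf("  regulator: %d up + %d down exons, fold %.2g, coupling %.2g; seed %d\n",
              x$n_fox2_up_exons, x$n_fox2_down_exons,
              x$fox2_fold_e85_e115, x$fox2_coupling, x$seed))
  invisible(x)
}
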