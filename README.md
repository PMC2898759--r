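# splicedex

Genome-wide alternative-splicing analysis of exon-microarray probe data,
with a synthetic ground-truth generator for validating every step.

## The problem

Exon arrays measure every exon of a transcriptome with small probe sets,
grouped into meta probe sets per gene. Detecting differential splicing from
such data requires separating isoform changes from whole-gene expression
changes, and protecting the analysis from three classic artifacts:
unexpressed genes, cross-hybridizing probe sets, and unresponsive ("dead")
probes. `splicedex` implements the complete pipeline for an unbalanced
developmental design — embryo sampled at stages E8.5/E9.5/E11.5 and placenta
at E9.5/E11.5, five biological replicates each (25 arrays) — where the
missing placenta time point rules out a standard two-way ANOVA.

The core quantity is the **splicing index**

    SI(e, s) = log2( probe-set expression(e, s) / gene expression(g(e), s) )

in which whole-gene changes cancel, leaving isoform-level signal. The
statistics around it:

* **preprocessing** — GC-matched background correction against anti-genomic
  control probes, quantile normalization, median-polish summarization to
  exon and gene level, and detection-above-background (DABG) p-values
  `p = (1 + #{bg >= x}) / (N + 1)`;
* **quality filters** — chip-quartile expression filter, probe-set/gene
  ratio > 5 cross-hybridization filter, per-chip BH-cutoff dead-probe
  filter;
* **differential tests** — tissue: pooled two-sample t on the stages shared
  by both tissues; stage: placenta t-test and embryo one-way ANOVA combined
  by Fisher's method (X² = −2Σ ln p, χ² with 4 df); Benjamini–Hochberg FDR
  at 0.05 per level and effect family;
* **motif regulation** — for stage-significant cassette exons, scans the
  100 nt splice-site-proximal intron windows for Fox-family binding sites
  (UGCAUG), computes between-condition inclusion ratios normalized to the
  gene, and tests the positional hypothesis (downstream binding promotes
  inclusion, upstream promotes skipping) with a one-tailed unpaired Welch
  t-test on log ratios;
* **evaluation** — PCA variance decomposition, overlap of significant exons
  with a known-events set as the FDR threshold tightens, and
  precision/recall against the generator's planted truth.

## Worked example

```r
library(splicedex)

cfg <- sim_config(n_genes = 150, seed = 7)   # 25 arrays, planted truth
rep <- run_pipeline(cfg, quiet = TRUE)
print(rep)
```

```
<filter_report>
  meta probe sets: 150 -> 142 (8 unexpressed)
  probe sets: 1350 -> 1222 (27 cross-hyb, 27 dead)
  thresholds: quartile 0.25, ratio > 5, DABG FDR 0.05
<crosstab>
  genes: 28 tissue / 11 stage / 6 both
  exons: 84 tissue / 72 stage / 33 both (same exon)
  genes with >= 1 significant exon: 77
<fox2 analysis>
  e115_vs_e85: n_down=17 n_up=16 fold_diff=9.63 p=7.397e-28
  e115e_vs_p115: n_down=17 n_up=16 fold_diff=8.54 p=9.792e-27
<pca_summary> PC1 49.7%, PC2 13.2% (first two: 62.8%)
```

Reading the output: the filters removed exactly the planted artifacts (8
unexpressed genes, 27 cross-hybridizing and 27 dead probe sets). Of the kept
features, 84 exons changed splicing index between tissues and 72 across
stages at FDR 0.05. The motif analysis found 17 significant cassette exons
with a downstream-intron UGCAUG and 16 with an upstream one; their inclusion
ratios between E11.5 and E8.5 embryos differ nearly 10-fold in the predicted
direction (downstream > 1 > upstream, one-tailed Welch p ≈ 7e-28 — the
planted coupling is strong at this noise level). PCA places tissue on PC1
and developmental stage on PC2.

Recovery against the planted truth (`rep$recovery`) shows recall 1.0 for
tissue effects and ~0.9 for stage effects; the realized false-discovery
proportion at gene level is inflated by isoform-to-gene leakage (a large
planted splicing shift moves the robust gene summary too), which the methods
vignette discusses — the numbers above are what the pipeline actually
measures, not a cleaned-up view.

Every analysis step is exported on its own (`background_correct`,
`quantile_normalize`, `summarize_probes`, `dabg`, `apply_filters`,
`splicing_index`, `tissue_test`, `stage_test`, `fisher_combine`, `bh_fdr`,
`scan_motifs`, `inclusion_ratio`, `welch_one_tailed`, `fox2_analysis`,
`pca_summary`, ...), and datasets round-trip through plain-text files
(`write_dataset` / `read_dataset`: TSV + FASTA + YAML + JSON manifest).
A thin command-line wrapper lives at `exec/splicedex`
(`splicedex run --seed 1 --genes 500 --workdir out/`).

## Vignette

`vignettes/splicing-index-pipeline.Rmd` documents the statistical model, the
generator's assumptions and defaults (and what they deliberately do not
emulate about real arrays), numerical conventions, and known limitations.
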