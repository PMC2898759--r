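---
title: "Splicing-index analysis of exon arrays: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing-index analysis of exon arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedex)
```

# The problem

Exon microarrays interrogate every known and predicted exon of a genome with
small groups of probes (a *probe set* per exon), and group probe sets into
*meta probe sets* representing whole transcripts. Comparing exon-level
expression across conditions confounds two things: whole-gene expression
changes and genuine isoform changes. The *splicing index* separates them:

$$\mathrm{SI}_{e,s} = \log_2 \frac{\text{probe-set expression}_{e,s}}
                                  {\text{gene expression}_{g(e),s}}$$

A whole-gene shift moves numerator and denominator together and cancels; a
change in exon inclusion moves only the numerator. Differential tests on the
splicing index therefore detect alternative splicing, alternative promoters,
alternative 3' ends and mutually exclusive exons rather than transcription
changes.

`splicedex` implements the full analysis for a specific, unbalanced
developmental design — two tissues (embryo at E8.5, E9.5, E11.5; placenta at
E9.5 and E11.5 only) with five biological replicates per tissue/stage, 25
arrays in all — together with a seeded synthetic probe-level generator that
provides ground truth for every claim the pipeline makes.

# The statistical model

## Preprocessing

1. **Background correction.** Anti-genomic control probes (probes matching no
   genomic sequence) estimate non-specific binding as a function of GC
   content. Probes are assigned to 5 equal-width GC bins; the bin median is
   subtracted and the result floored at 1 intensity unit so logs stay
   defined. Pooled anti-genomic draws are the default; per-sample draws are a
   switch (`per_sample_bg`), since either convention is defensible and the
   choice is not identifiable from summarized data.
2. **Quantile normalization** across all 25 arrays (every column mapped onto
   the mean of the sorted columns, ties receiving the mean of the tied
   targets), via `limma::normalizeQuantiles`.
3. **Summarization** to probe-set and meta-probe-set expression. The default
   is Tukey median polish on log2 intensities, with the fitted overall +
   column effects exponentiated back to the linear scale — the RMA-style
   robust summary. The per-feature arithmetic mean is available as
   `method = "mean"`. A model-based multiplicative fit (PLIER-style) would
   absorb an unresponsive probe into a small affinity estimate; an additive
   log-scale polish instead lets a block of floor-level probes deflate the
   gene's *absolute* level (its overall term includes the median of the row
   effects). To keep meta-probe-set semantics comparable, probes belonging to
   probe sets that fail detection on every chip are excluded from the
   gene-level summary (never from the probe-set level, which the dead-probe
   filter itself consumes).
4. **DABG.** Detection-above-background p-values use the add-one empirical
   rule against the GC-matched background, \(p = (1 + \#\{bg \ge x\})/(N+1)\),
   which keeps p in (0, 1] (p = 0 would break both Fisher's method and log
   transforms). Probe p-values combine to probe-set p-values by Fisher's
   method.

## Quality filters

Three filters remove the classic exon-array artifacts, in order:

* **Unexpressed genes.** Per chip, the threshold is the lower quartile (25th
  percentile, linear interpolation) of all meta-probe-set values on that
  chip; a gene below the threshold on *every* chip is removed, along with
  its probe sets. The strictness parallels the dead-probe rule ("in all
  samples"); a variant requiring expression on every chip
  (`require_expressed = "all"`) and a mean-based variant are switches.
* **Cross-hybridizing probe sets.** Removed when the mean over samples of
  the probe-set/meta-probe-set intensity ratio is strictly greater than 5
  (a max-over-samples variant is a switch).
* **Dead probe sets.** Per chip, a Benjamini–Hochberg cutoff at FDR 0.05 is
  computed over that chip's full DABG p-value distribution; a probe set whose
  p-value strictly exceeds the cutoff on every chip is unresponsive.

Finally values are log2-transformed (variance stabilization). All filters
operate on the linear scale; removal boundaries are strict inequalities.

## Differential testing in an unbalanced design

The missing E8.5 placenta cell rules out a standard two-way ANOVA, so:

* **Tissue effect:** pooled-variance two-sample t-test of embryo versus
  placenta using only the stages present in both tissues (E9.5 + E11.5,
  n = 10 vs 10). E8.5 embryo samples are excluded so the pooled groups are
  stage-matched.
* **Stage effect:** a pooled t-test within placenta (E9.5 vs E11.5) and a
  one-way fixed-effects ANOVA within embryo (three stages), combined with
  Fisher's method: \(X^2 = -2(\ln p_1 + \ln p_2) \sim \chi^2_4\) under the
  joint null.
* Gene-level tests run on log2 gene expression; exon-level tests on the log2
  splicing index. BH adjustment is applied separately within each
  level × effect family, and significance is called at FDR 0.05.
* Features with zero variance in a family are excluded from that family
  before adjustment (q = NA) rather than assigned p = 1, which would deflate
  the FDR denominator.

The "two-sample t-test" is the classic pooled-variance Student t; a Welch
variant is deliberately reserved for the motif analysis below, where group
variances have no reason to be equal.

## Position-dependent motif regulation

Fox/Rbfox-family splicing factors bind (U)GCAUG elements in the introns
flanking a cassette exon, with a strongly position-dependent effect:
downstream binding promotes inclusion, upstream binding promotes skipping.
The analysis:

1. selects stage-significant probe sets annotated as cassette exons;
2. scans the 100 nt intron windows abutting each splice site for motifs
   (exact matching, T≡U, overlapping hits allowed, N never matches; IUPAC
   codes in motifs expand); the strict set is the UGCAUG hexamer, and a
   relaxed 5-motif placeholder family is provided that users should replace
   with a curated list (`motif_set("custom", ...)`) for real analyses;
3. computes, per exon, the inclusion ratio between two conditions:
   \([\bar{ps}_A/\bar{g}_A] / [\bar{ps}_B/\bar{g}_B]\) on group means
   (replicates are unpaired across conditions, so per-replicate ratios are
   undefined). Default comparisons: E11.5 vs E8.5 within embryo, and E11.5
   embryo vs E11.5 placenta — the contrasts with the largest regulator
   differences in this design;
4. log-transforms the ratios (variance stabilization) and runs a one-tailed
   unpaired Welch t-test of mean(log ratio | downstream motif) >
   mean(log ratio | upstream motif). Exons with motifs on both sides or on
   neither are excluded — the directional hypothesis concerns the two clean
   classes. With fewer than 2 exons in either class the analysis reports
   itself underpowered instead of a p-value.

Windows are taken on the pre-mRNA sense strand with BED-style 0-based
half-open coordinates; minus-strand genes would be reverse-complemented
before scanning.

# The synthetic-data generator

`simulate_dataset()` emulates the probe-level structure of the study design;
it makes no claim of sequence identity with any real array or gene.

Per gene \(g\) and sample \(s\), the log2 gene level is
\(\mu_{gs} = b_g + \beta_t \cdot [\text{embryo}] + \beta_s \cdot f(\text{stage})\)
with \(f\) mapping E8.5, E9.5, E11.5 to 0, 0.5, 1. Probe sets add their
planted splicing-index shift, probes add a fixed affinity offset
(Normal(0, 0.5) log2 units) and Normal(0, `noise_sd`) noise, and the linear
intensity is \(2^{\text{signal}}\) plus a log-normal GC-bin background draw.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| design | 2 tissues × {3,2} stages × 5 replicates | the study layout; the missing E8.5 placenta cell is the point |
| `exons_per_gene` | 6–12 | the real array averages roughly a dozen probe sets per core transcript |
| `probes_per_probeset` | 4 | the real array's probe count per probe set |
| `noise_sd` | 0.7 log2 | typical probe-level replicate noise for single-probe exon measurements |
| `de_log2fc`, `das_delta_si` | 1, 2 | a 2-fold gene change and a 4-fold inclusion change: moderate, detectable effects |
| `baseline_log2_sd` | 0.1 | see below |
| `bg_mu_by_gc` | 3–5 log2 by GC bin | background rising with GC, about 1.5–2 orders below signal |
| `fox2_fold_e85_e115` | 2 | the regulator doubles across embryo stages, flat in placenta |
| `fox2_coupling` | 1.65 | gives a ~10-fold inclusion-ratio difference between downstream- and upstream-motif classes, the magnitude seen for strongly regulated Rbfox targets |

**The narrow baseline spread deserves emphasis.** Real arrays span several
log2 units of expression, and on real data the quartile-based expression
filter removes a large fraction of genuinely low-expressed genes — that is
its job. A benchmark generator, however, needs a well-defined ground truth
for "unexpressed": expressed genes are therefore clustered tightly
(sd 0.1 log2) far above background, so the chip quartile falls between the
two populations and membership in the bottom quartile churns with noise
rather than tracking a biological low tail. Passing filter-recovery tests on
this generator says the *decision rules* are implemented correctly; it says
nothing about how many borderline genes a real experiment would lose.

Artifacts: unexpressed genes emit background draws only. Dead probe sets
hybridize 2 log2 units *below* their GC-bin background — an unresponsive
probe's chemistry binds weakly even non-specifically. (A probe emitting
draws from exactly the background distribution would be statistically
indistinguishable from background on any single chip, making "recall" an
incoherent target.) Cross-hybridizing probe sets sit 5 log2 units (32×)
above their gene, well past the ratio-5 boundary.

Isoform effects are planted on annotated event classes: cassette exons
(middle exons), alternative promoters (first exon), alternative 3' ends
(last exon), and mutually exclusive pairs (adjacent middle exons shifted in
opposite directions). The regulator module (`plant_fox2_regulation()`) ramps
one designated gene 2-fold across embryo stages, couples target-exon
splicing indices to that ramp (positively for downstream-motif exons,
negatively for upstream), writes TGCATG into the matching 100 nt window, and
records everything in the truth tables. All windows are rejection-sampled
free of the entire default motif family at generation time, so a planted
side is unambiguous and enlarging the motif set can only add hits at planted
positions.

What the generator does *not* emulate: real probe sequences or CEL-level
spatial artifacts, probe-specific cross-hybridization structure, correlated
biological replicates, wide expression dynamic range, and annotation error.
Results on this generator are statements about the pipeline's statistics,
not about any real tissue.

# Numerical choices and degenerate inputs

* Background-corrected intensities are floored at 1.0 so the log transform
  is total; `log_transform()` still errors, naming the feature and sample,
  if handed nonpositive values directly.
* The DABG add-one rule keeps p in (0, 1]; exact zeros after the chi-square
  combination are clamped to the smallest positive double.
* The vectorized median polish reproduces `stats::medpolish` feature by
  feature, including its convergence rule (relative residual change < 0.01,
  10 sweeps maximum); features sharing a probe count are polished
  simultaneously as a 3-d array for speed.
* Quantile normalization of a single sample is a warning no-op; ties take
  the mean of the tied target values.
* Zero-variance features get NA statistics and are dropped from the affected
  FDR family. Chips on which nothing passes DABG get a cutoff of 0 with a
  warning, making every probe set "dead" on that chip.
* Boundary strictness everywhere follows the rules' wording: ratio exactly 5
  is kept; DABG p exactly at the cutoff is detected; a gene exactly at the
  chip quartile is expressed.

# Interactions the pipeline measures honestly

Two effects discovered on synthetic data are worth knowing about:

* **Isoform-to-gene leakage.** A large splicing-index shift on one exon
  moves the robust gene summary slightly, so sibling exons acquire small
  opposite splicing-index shifts and the gene itself a small expression
  shift. With many replicates and low noise these can reach significance.
  This is faithful behavior of any summarization-based pipeline — exon and
  gene estimates share probes — and it inflates the realized false-discovery
  proportion of `recovery_metrics()` relative to the planted truth when
  effects are dense and large. The BH guarantee applies to the test's null
  hypothesis, which these features genuinely violate.
* **Filter coupling.** Dead probe sets deflate their gene's additive-polish
  summary; without the gene-level exclusion described above, genes carrying
  dead exons would be removed as "unexpressed" and drag their probe sets out
  of the dead filter's accounting.

# Problem sizes

The shipped tests and the acceptance script run the generator at 150–2,000
genes (roughly 1,000–18,000 probe sets, 25 arrays), sizes chosen so the full
suite completes in minutes on one core while keeping every Monte-Carlo
margin comfortable. All stages are vectorized across features; a 2,000-gene
dataset preprocesses in a few seconds.

# Known limitations

* PLIER itself is not reimplemented; median polish is a documented,
  pluggable substitute, and no numeric agreement with PLIER output is
  claimed.
* The relaxed motif list is a placeholder; replicating a specific published
  motif family requires supplying it via `motif_set("custom", ...)`.
* The overlap curve substitutes the synthetic truth (or any user-supplied
  id set) for a genome-browser alternative-events track.
* Gene-level and exon-level analyses share the filtered universe; the
  alternative (unfiltered universe for gene-level BH) is not implemented.
* The one-tailed Welch test assumes exons are independent observations;
  exons of the same gene share a meta-probe-set denominator.
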