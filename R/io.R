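#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `intensities.tsv` (probe_id, gc_percent, one column per sample),
#' `antigenomic.tsv` (same layout), `annotation.tsv`, `design.tsv`,
#' `intron_windows.fasta`, `truth.tsv` (gene and exon ground truth stacked,
#' with a `level` column), `config.yaml`, and a `manifest.json` listing the
#' seven data files with their MD5 checksums. The files round-trip
#' losslessly through [read_dataset()] (numeric values are written at full
#' precision).
#'
#' @param dataset a `splicedex_dataset`.
#' @param directory output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
write_dataset <- function(dataset, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  tsv <- function(df, file) {
    path <- file.path(directory, file)
    ok <- try(utils::write.table(format(df, digits = 17, trim = TRUE,
                                        scientific = FALSE),
                                 path, sep = "\t", quote = FALSE,
                                 row.names = FALSE), silent = TRUE)
    if (inherits(ok, "try-error"))
      .stopf("write_dataset: failed writing %s", path)
    path
  }
  int_df <- data.frame(probe_id = rownames(dataset$intensities),
                       gc_percent = unname(dataset$gc_percent),
                       dataset$intensities, check.names = FALSE)
  ag_df <- data.frame(probe_id = rownames(dataset$antigenomic$intensities),
                      gc_percent = unname(dataset$antigenomic$gc_percent),
                      dataset$antigenomic$intensities, check.names = FALSE)
  truth_df <- .truth_to_table(dataset$truth)

  files <- c(
    tsv(int_df, "intensities.tsv"),
    tsv(ag_df, "antigenomic.tsv"),
    tsv(dataset$annotation, "annotation.tsv"),
    tsv(dataset$design, "design.tsv"),
    {
      fa <- file.path(directory, "intron_windows.fasta")
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(dataset$intron_windows), fa)
      fa
    },
    tsv(truth_df, "truth.tsv"),
    {
      cy <- file.path(directory, "config.yaml")
      cfg <- unclass(dataset$config)
      cfg$design <- as.list(cfg$design)
      yaml::write_yaml(cfg, cy)
      cy
    }
  )
  manifest <- list(
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))),
    n_files = length(files)
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.truth_to_table <- function(truth) {
  ge <- truth$gene_effects
  ex <- truth$exon_effects
  g <- data.frame(level = "gene", feature_id = ge$gene_id,
                  gene_id = ge$gene_id, event_class = NA,
                  unexpressed = ge$unexpressed,
                  tissue_effect = ge$tissue_de, stage_effect = ge$stage_de,
                  tissue_shift = ge$tissue_lfc, stage_shift = ge$stage_lfc,
                  dead = NA, crosshyb = NA,
                  is_regulator = ge$is_regulator,
                  fox2_side = NA, fox2_sign = NA,
                  stringsAsFactors = FALSE)
  e <- data.frame(level = "exon", feature_id = ex$probeset_id,
                  gene_id = ex$gene_id, event_class = ex$event_class,
                  unexpressed = NA,
                  tissue_effect = ex$tissue_das, stage_effect = ex$stage_das,
                  tissue_shift = ex$tissue_si_shift,
                  stage_shift = ex$stage_si_shift,
                  dead = ex$dead, crosshyb = ex$crosshyb,
                  is_regulator = NA,
                  fox2_side = ex$fox2_side, fox2_sign = ex$fox2_sign,
                  stringsAsFactors = FALSE)
  rbind(g, e)
}

.table_to_truth <- function(df, fox2_gene_id) {
  g <- df[df$level == "gene", ]
  e <- df[df$level == "exon", ]
  list(
    gene_effects = data.frame(
      gene_id = g$feature_id, unexpressed = as.logical(g$unexpressed),
      tissue_de = as.logical(g$tissue_effect),
      stage_de = as.logical(g$stage_effect),
      tissue_lfc = g$tissue_shift, stage_lfc = g$stage_shift,
      is_regulator = as.logical(g$is_regulator), stringsAsFactors = FALSE),
    exon_effects = data.frame(
      probeset_id = e$feature_id, gene_id = e$gene_id,
      event_class = e$event_class,
      tissue_das = as.logical(e$tissue_effect),
      stage_das = as.logical(e$stage_effect),
      tissue_si_shift = e$tissue_shift, stage_si_shift = e$stage_shift,
      dead = as.logical(e$dead), crosshyb = as.logical(e$crosshyb),
      fox2_side = ifelse(e$fox2_side %in% c("upstream", "downstream"),
                         e$fox2_side, NA_character_),
      fox2_sign = e$fox2_sign, stringsAsFactors = FALSE),
    fox2_targets = {
      t <- e[!is.na(e$fox2_side) & e$fox2_side %in% c("upstream", "downstream"), ]
      data.frame(probeset_id = t$feature_id, side = t$fox2_side,
                 sign = t$fox2_sign, stringsAsFactors = FALSE)
    },
    fox2_gene_id = fox2_gene_id
  )
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory directory containing the seven data files.
#' @return a `splicedex_dataset`.
#' @export
read_dataset <- function(directory) {
  rd <- function(file, ...) {
    path <- file.path(directory, file)
    if (!file.exists(path)) .stopf("read_dataset: missing file %s", path)
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
  }
  int <- rd("intensities.tsv")
  intens <- as.matrix(int[, -(1:2), drop = FALSE])
  rownames(intens) <- int$probe_id
  gc <- stats::setNames(int$gc_percent, int$probe_id)

  ag <- rd("antigenomic.tsv")
  ag_m <- as.matrix(ag[, -(1:2), drop = FALSE])
  rownames(ag_m) <- ag$probe_id
  ag_gc <- stats::setNames(ag$gc_percent, ag$probe_id)

  annotation <- rd("annotation.tsv")
  design <- rd("design.tsv")
  truth_df <- rd("truth.tsv")

  fa <- Biostrings::readDNAStringSet(file.path(directory, "intron_windows.fasta"))
  windows <- stats::setNames(as.character(fa), names(fa))

  cfg <- yaml::read_yaml(file.path(directory, "config.yaml"))
  cfg$design <- as.data.frame(cfg$design, stringsAsFactors = FALSE)
  cfg <- do.call(sim_config, cfg[names(cfg) %in% names(formals(sim_config))])

  truth <- .table_to_truth(truth_df,
                           truth_df$gene_id[truth_df$level == "gene" &
                                              as.logical(truth_df$is_regulator)][1])
  structure(list(
    intensities = intens, gc_percent = gc,
    antigenomic = list(gc_percent = ag_gc, intensities = ag_m),
    annotation = annotation, design = design,
    intron_windows = windows, truth = truth, config = cfg
  ), class = "splicedex_dataset")
}
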