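test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_genes = 25, n_fox2_up_exons = 3, n_fox2_down_exons = 3,
                    seed = 7)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$intensities, d2$intensities)
  expect_identical(d1$antigenomic$intensities, d2$antigenomic$intensities)
  expect_identical(d1$truth$exon_effects, d2$truth$exon_effects)
  expect_identical(d1$intron_windows, d2$intron_windows)
  # planting is deterministic too
  p1 <- plant_fox2_regulation(d1, cfg)
  p2 <- plant_fox2_regulation(d2, cfg)
  expect_identical(p1$intensities, p2$intensities)
  d3 <- simulate_dataset(sim_config(n_genes = 25, seed = 8))
  expect_false(identical(d1$intensities, d3$intensities))
})

test_that("planted flag counts follow the configured fractions", {
  cfg <- sim_config(n_genes = 100, frac_unexpressed_genes = 0.1, seed = 3)
  d <- simulate_dataset(cfg)
  ge <- d$truth$gene_effects
  expect_identical(sum(ge$unexpressed), 10L)
  n_ps <- length(unique(d$annotation$probeset_id))
  ex <- d$truth$exon_effects
  expect_identical(sum(ex$dead), as.integer(round(0.02 * n_ps)))
  expect_identical(sum(ex$crosshyb), as.integer(round(0.02 * n_ps)))
  # effects never land on excluded features
  expect_false(any(ge$unexpressed & (ge$tissue_de | ge$stage_de)))
  expect_false(any(ex$dead & (ex$tissue_das | ex$stage_das)))
  expect_false(any(ex$crosshyb & (ex$tissue_das | ex$stage_das)))
})

test_that("a zero-effect configuration plants nothing", {
  cfg <- sim_config(n_genes = 30, frac_de_genes = 0, frac_das_exons = 0,
                    frac_unexpressed_genes = 0, frac_dead_probesets = 0,
                    frac_crosshyb_probesets = 0, n_fox2_up_exons = 0,
                    n_fox2_down_exons = 0, seed = 1)
  d <- simulate_dataset(cfg)
  expect_false(any(d$truth$gene_effects$tissue_de))
  expect_false(any(d$truth$gene_effects$stage_de))
  expect_false(any(d$truth$exon_effects$tissue_das))
  expect_false(any(d$truth$exon_effects$stage_das))
  expect_identical(nrow(d$truth$fox2_targets), 0L)
})

test_that("dataset structure satisfies its invariants", {
  d <- small_dataset()
  expect_identical(ncol(d$intensities), sum(d$config$design$n_replicates))
  expect_setequal(rownames(d$intensities), d$annotation$probe_id)
  expect_false(anyNA(d$intensities))
  expect_true(all(d$intensities >= 0))
  # every cassette-annotated probe set has both 100 nt windows
  cas <- unique(d$annotation$probeset_id[d$annotation$event_class == "cassette"])
  expect_true(all(sprintf("%s|upstream", cas) %in% names(d$intron_windows)))
  expect_true(all(sprintf("%s|downstream", cas) %in% names(d$intron_windows)))
  expect_true(all(nchar(d$intron_windows) == 100L))
})

test_that("motif planting writes the site on the labelled side only", {
  d <- small_dataset()
  strict <- motif_set("strict")
  tg <- d$truth$fox2_targets
  expect_gt(nrow(tg), 0)
  for (i in seq_len(nrow(tg))) {
    target_side <- tg$side[i]
    other_side <- setdiff(c("upstream", "downstream"), target_side)
    w_t <- d$intron_windows[[sprintf("%s|%s", tg$probeset_id[i], target_side)]]
    w_o <- d$intron_windows[[sprintf("%s|%s", tg$probeset_id[i], other_side)]]
    expect_gt(nrow(scan_motifs(w_t, strict)), 0)
    expect_identical(nrow(scan_motifs(w_o, strict)), 0L)
  }
  # non-target cassette windows carry no site
  non_target <- setdiff(names(d$intron_windows),
                        sprintf("%s|%s", tg$probeset_id, tg$side))
  hits <- vapply(d$intron_windows[non_target],
                 function(w) nrow(scan_motifs(w, strict)), integer(1))
  expect_true(all(hits == 0))
})

test_that("downstream-coupled exons gain inclusion as stages advance", {
  d <- small_dataset()
  tg <- d$truth$fox2_targets
  ex <- d$truth$exon_effects
  planted <- ex[match(tg$probeset_id, ex$probeset_id), ]
  expect_true(all(planted$stage_si_shift[tg$side == "downstream"] > 0))
  expect_true(all(planted$stage_si_shift[tg$side == "upstream"] < 0))
  # visible in the raw intensities of a downstream-coupled probe set
  dn <- tg$probeset_id[tg$side == "downstream"][1]
  probes <- d$annotation$probe_id[d$annotation$probeset_id == dn]
  des <- d$design
  m <- log2(d$intensities[probes, , drop = FALSE])
  e115 <- mean(m[, des$tissue == "embryo" & des$stage == "E11.5"])
  e85 <- mean(m[, des$tissue == "embryo" & des$stage == "E8.5"])
  expect_gt(e115, e85)
})

test_that("regulator expression doubles from E8.5 to E11.5 in embryo", {
  # Monte-Carlo over seeds: summarized expression ratio near the planted fold
  ratios <- vapply(1:8, function(s) {
    cfg <- sim_config(n_genes = 40, n_fox2_up_exons = 4, n_fox2_down_exons = 4,
                      seed = 100 + s)
    d <- plant_fox2_regulation(simulate_dataset(cfg), cfg)
    prep <- preprocess(d)
    reg <- d$truth$fox2_gene_id
    des <- d$design
    v <- prep$gene_expr[reg, ]
    mean(v[des$tissue == "embryo" & des$stage == "E11.5"]) /
      mean(v[des$tissue == "embryo" & des$stage == "E8.5"])
  }, numeric(1))
  expect_gt(mean(ratios), 1.8)
  expect_lt(mean(ratios), 2.2)
  # flat in placenta
  cfg <- sim_config(n_genes = 40, n_fox2_up_exons = 4, n_fox2_down_exons = 4,
                    seed = 101)
  d <- plant_fox2_regulation(simulate_dataset(cfg), cfg)
  prep <- preprocess(d)
  des <- d$design
  v <- prep$gene_expr[d$truth$fox2_gene_id, ]
  pl_ratio <- mean(v[des$tissue == "placenta" & des$stage == "E11.5"]) /
    mean(v[des$tissue == "placenta" & des$stage == "E9.5"])
  expect_lt(abs(log2(pl_ratio)), 0.5)
})

test_that("planting fails gracefully without enough cassette exons", {
  cfg <- sim_config(n_genes = 10, frac_cassette_annotated = 0.01,
                    n_fox2_up_exons = 20, n_fox2_down_exons = 20, seed = 1)
  d <- simulate_dataset(cfg)
  expect_error(plant_fox2_regulation(d, cfg), "planting error")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_de_genes = 1.2), "proportion")
  expect_error(sim_config(design = data.frame(
    tissue = "embryo", stage = "E8.5", n_replicates = 1L)), "replicate")
  expect_error(sim_config(fox2_fold_e85_e115 = 0), "fox2_fold")
  expect_error(sim_config(n_genes = 10, frac_unexpressed_genes = 1),
               "configuration error")
})
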