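test_that("splicing index is the log2 exon/gene ratio", {
  ann <- data.frame(probe_id = "p", probeset_id = "ps", metaprobeset_id = "g",
                    stringsAsFactors = FALSE)
  ps <- matrix(c(8, 4, 4), 1, 3, dimnames = list("ps", paste0("s", 1:3)))
  g <- matrix(c(4, 4, 8), 1, 3, dimnames = list("g", paste0("s", 1:3)))
  si <- splicing_index(ps, g, ann)
  expect_equal(unname(si["ps", ]), c(1, 0, -1))
  # ps == gene everywhere gives identically zero
  expect_true(all(splicing_index(g, g,
    data.frame(probe_id = "p", probeset_id = "g", metaprobeset_id = "g")) == 0))
  # doubling the gene in one sample lowers si by exactly 1 there
  g2 <- g; g2[1, 2] <- g[1, 2] * 2
  expect_equal(splicing_index(ps, g2, ann)[1, 2], si[1, 2] - 1)
  expect_error(splicing_index(ps, g * 0, ann), "nonpositive")
})

test_that("tissue test matches the pooled-variance t-test oracle", {
  des <- design25()
  # hand-checkable example mapped onto the shared-stage samples
  x <- numeric(25); names(x) <- des$sample_id
  set.seed(5)
  x[] <- rnorm(25)
  res <- tissue_test(x, des)
  shared <- des$stage %in% c("E9.5", "E11.5")
  oracle <- t.test(x[shared & des$tissue == "embryo"],
                   x[shared & des$tissue == "placenta"], var.equal = TRUE)
  expect_equal(res$t, unname(oracle$statistic))
  expect_equal(res$df, unname(oracle$parameter))
  expect_equal(res$p, oracle$p.value)
  # E8.5 embryo samples must not influence the tissue contrast
  x2 <- x
  x2[des$stage == "E8.5"] <- x2[des$stage == "E8.5"] + 100
  res2 <- tissue_test(x2, des)
  expect_equal(res2$t, res$t)
  # location invariance
  res3 <- tissue_test(x + 7, des)
  expect_equal(res3$t, res$t)
  expect_equal(res3$p, res$p)
})

test_that("pooled t on the two-by-four example gives the textbook value", {
  out <- splicedex:::pooled_t(c(1, 1, 2, 2), c(3, 3, 4, 4))
  oracle <- t.test(c(1, 1, 2, 2), c(3, 3, 4, 4), var.equal = TRUE)
  expect_equal(out$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(out$df, 6)
  expect_equal(out$p, oracle$p.value, tolerance = 1e-12)
  # equal means with nonzero variance: t = 0, p = 1
  out0 <- splicedex:::pooled_t(c(1, 2, 1, 2), c(1, 2, 2, 1))
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 1)
  # zero pooled variance flags NA
  expect_true(is.na(splicedex:::pooled_t(c(1, 1), c(1, 1))$p))
})

test_that("stage test combines the placenta t and embryo ANOVA by Fisher", {
  des <- design25()
  set.seed(6)
  x <- rnorm(25); names(x) <- des$sample_id
  res <- stage_test(x, des)
  pl <- des$tissue == "placenta"
  p1 <- t.test(x[pl & des$stage == "E9.5"], x[pl & des$stage == "E11.5"],
               var.equal = TRUE)$p.value
  em <- des$tissue == "embryo"
  p2 <- summary(aov(x[em] ~ factor(des$stage[em])))[[1]][["Pr(>F)"]][1]
  expect_equal(res$p_stage_placenta, p1)
  expect_equal(res$p_stage_embryo, p2, tolerance = 1e-10)
  expect_equal(res$X2_combined, -2 * (log(p1) + log(p2)))
  expect_equal(res$p_stage_combined,
               pchisq(res$X2_combined, 4, lower.tail = FALSE))
  # a huge embryo stage effect dominates the combination
  x2 <- x
  x2[em] <- rep(c(0, 0, 5), each = 5) + rnorm(15, 0, 0.01)
  res2 <- stage_test(x2, des)
  expect_lt(res2$p_stage_combined, res2$p_stage_placenta)
})

test_that("Fisher combination matches the df = 4 closed form", {
  f <- fisher_combine(c(0.5, 0.5))
  expect_equal(f$X2, 2.7726, tolerance = 1e-4)
  expect_equal(f$p, 0.5966, tolerance = 1e-4)
  f2 <- fisher_combine(c(0.05, 1))
  expect_equal(f2$X2, 5.9915, tolerance = 1e-4)
  expect_equal(f2$p, 0.1998, tolerance = 1e-4)
  expect_equal(fisher_combine(c(1, 1))$X2, 0)
  expect_equal(fisher_combine(c(1, 1))$p, 1)
  # closed form exp(-x/2) * (1 + x/2) for two p-values
  set.seed(8)
  p <- matrix(runif(200), ncol = 2)
  for (i in seq_len(nrow(p))) {
    f <- fisher_combine(p[i, ])
    expect_equal(f$p, exp(-f$X2 / 2) * (1 + f$X2 / 2), tolerance = 1e-10)
  }
  expect_error(fisher_combine(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("BH q-values match the brute-force step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  # NA p-values stay NA and do not affect the others
  p <- c(0.01, NA, 0.5)
  q <- bh_fdr(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_bruteforce(p[c(1, 3)]))
  expect_identical(bh_fdr(numeric()), numeric())
})

test_that("q-values are monotone and significance sets shrink with the FDR", {
  set.seed(10)
  p <- c(runif(80), runif(20)^4)
  q <- bh_fdr(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= p))
  s1 <- sum(q <= 0.05)
  s2 <- sum(q <= 0.01)
  expect_lte(s2, s1)
})

test_that("run_differential flags planted effects and tallies the cross-tab", {
  diffr <- small_differential()
  d <- small_dataset()
  tr <- d$truth
  # planted tissue-DE genes in the kept universe are detected
  kept <- diffr$gene$feature_id
  planted <- intersect(tr$gene_effects$gene_id[tr$gene_effects$tissue_de], kept)
  called <- diffr$gene$feature_id[diffr$gene$significant_tissue]
  expect_gt(mean(planted %in% called), 0.8)
  # cross-tab set algebra
  ct <- diffr$crosstab
  expect_lte(ct$genes_both, min(ct$genes_tissue, ct$genes_stage))
  expect_identical(ct$genes_tissue_only + ct$genes_both, ct$genes_tissue)
  expect_identical(ct$exons_stage_only + ct$exons_both, ct$exons_stage)
  expect_lte(ct$same_exon_both, min(ct$exons_tissue, ct$exons_stage))
  expect_lte(ct$genes_with_tissue_and_stage_exons, ct$genes_with_sig_exon)
  # q >= p and flags consistent with q <= fdr
  ok <- !is.na(diffr$exon$q_tissue)
  expect_true(all(diffr$exon$q_tissue[ok] >= diffr$exon$p_tissue[ok] - 1e-12))
  expect_identical(diffr$exon$significant_tissue,
                   !is.na(diffr$exon$q_tissue) & diffr$exon$q_tissue <= 0.05)
})

test_that("whole-gene shifts leave the splicing index silent", {
  # plant DE without DAS; exon-level calls should stay near the null rate
  cfg <- sim_config(n_genes = 150, frac_de_genes = 0.3, frac_das_exons = 0,
                    de_log2fc = 2, frac_unexpressed_genes = 0,
                    frac_dead_probesets = 0, frac_crosshyb_probesets = 0,
                    n_fox2_up_exons = 0, n_fox2_down_exons = 0, seed = 14)
  d <- simulate_dataset(cfg)
  diffr <- run_differential(apply_filters(preprocess(d)))
  n_exon_calls <- sum(diffr$exon$significant_tissue) +
    sum(diffr$exon$significant_stage)
  expect_lte(n_exon_calls, ceiling(0.01 * nrow(diffr$exon)))
})

test_that("vectorized row tests agree with the scalar implementations", {
  des <- design25()
  set.seed(15)
  m <- matrix(rnorm(10 * 25), 10, 25,
              dimnames = list(paste0("f", 1:10), des$sample_id))
  vt <- splicedex:::.row_tissue_test(m, des)
  vs <- splicedex:::.row_stage_test(m, des)
  for (i in 1:10) {
    st <- tissue_test(m[i, ], des)
    expect_equal(vt$t_tissue[i], st$t)
    expect_equal(vt$p_tissue[i], st$p)
    ss <- stage_test(m[i, ], des)
    expect_equal(vs$p_stage_placenta[i], ss$p_stage_placenta)
    expect_equal(vs$p_stage_embryo[i], ss$p_stage_embryo)
    expect_equal(vs$p_stage_combined[i], ss$p_stage_combined)
  }
})
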