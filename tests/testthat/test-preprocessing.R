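test_that("background correction subtracts the GC-bin median with a floor", {
  # middle bin has median 40; other bins filled so the model is valid
  bg <- background_model(c(rep(50, 5), 10, 30, 70, 90),
                         c(10, 30, 40, 50, 90, 999, 999, 999, 999))
  raw <- matrix(c(100, 10), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
  out <- background_correct(raw, gc = c(50, 50), bg = bg)
  expect_equal(out["p1", 1], 60)
  expect_equal(out["p2", 1], 1.0)  # floored at eps
  expect_error(background_model(rep(50, 9), 1:9), "empty GC bin")
})

test_that("constant background reduces to an elementwise max", {
  set.seed(2)
  b <- 25
  gc_cover <- rep(c(10, 30, 50, 70, 90), 6)
  bg <- background_model(gc_cover, rep(b, 30))
  raw <- matrix(rexp(60, rate = 1 / 50), 12, 5)
  rownames(raw) <- paste0("p", 1:12)
  out <- background_correct(raw, gc = runif(12, 0, 100), bg = bg)
  expect_equal(out, pmax(raw - b, 1.0), ignore_attr = TRUE)
})

test_that("quantile normalization maps columns onto the mean sorted vector", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))
  # identical columns are a fixed point
  m2 <- cbind(x = c(5, 1, 9), y = c(5, 1, 9))
  expect_equal(quantile_normalize(m2), m2)
})

test_that("quantile normalization equalizes distributions and keeps ranks", {
  set.seed(4)
  m <- matrix(rlnorm(600, 5, 1), 100, 6)
  out <- quantile_normalize(m)
  sorted <- apply(out, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-12)
  for (j in 1:6) expect_identical(rank(out[, j]), rank(m[, j]))
  expect_equal(diff(range(colMeans(out))), 0, tolerance = 1e-12)
  expect_warning(quantile_normalize(m[, 1, drop = FALSE]), "single sample")
})

test_that("median polish summarization matches stats::medpolish per feature", {
  set.seed(11)
  for (k in c(2, 3, 5)) {
    n_feat <- 4
    probes <- matrix(2^rnorm(k * n_feat * 6, 8, 1), k * n_feat, 6)
    rownames(probes) <- paste0("pr", seq_len(nrow(probes)))
    ann <- data.frame(probe_id = rownames(probes),
                      probeset_id = rep(paste0("ps", 1:n_feat), each = k),
                      metaprobeset_id = "g1", stringsAsFactors = FALSE)
    out <- summarize_probes(probes, ann, "probeset")
    for (f in 1:n_feat) {
      block <- log2(probes[ann$probeset_id == paste0("ps", f), , drop = FALSE])
      mp <- stats::medpolish(block, trace.iter = FALSE, maxiter = 10)
      expect_equal(unname(out[paste0("ps", f), ]),
                   unname(2^(mp$overall + mp$col)), tolerance = 1e-8)
    }
  }
})

test_that("summarization handles singleton, proportional and constant cases", {
  ann <- data.frame(probe_id = c("a1", "b1", "b2"),
                    probeset_id = c("A", "B", "B"),
                    metaprobeset_id = c("gA", "gB", "gB"),
                    stringsAsFactors = FALSE)
  m <- rbind(a1 = c(3, 7, 11), b1 = c(2, 4, 8), b2 = c(4, 8, 16))
  colnames(m) <- paste0("s", 1:3)
  # singleton feature equals its probe under either method
  expect_equal(summarize_probes(m, ann, "probeset", "mean")["A", ],
               m["a1", ])
  expect_equal(summarize_probes(m, ann, "probeset", "median_polish")["A", ],
               m["a1", ])
  # two probes that are exact 2x scalings: rank-1 log2 matrix, zero residuals,
  # summarized profile proportional to either probe
  ps <- summarize_probes(m, ann, "probeset", "median_polish")["B", ]
  expect_equal(unname(ps / ps[1]), unname(m["b1", ] / m["b1", 1]),
               tolerance = 1e-12)
  # constant matrix summarizes to the constant
  mc <- matrix(5, 3, 4, dimnames = list(c("a1", "b1", "b2"), paste0("s", 1:4)))
  out <- summarize_probes(mc, ann, "probeset", "median_polish")
  expect_equal(unname(out), matrix(5, 2, 4), tolerance = 1e-12)
})

test_that("mean summarization recovers the true level within sampling error", {
  set.seed(21)
  mu <- 7; sigma <- 0.6; k <- 8; S <- 25
  probes <- matrix(2^rnorm(k * S, mu, sigma), k, S)
  rownames(probes) <- paste0("p", 1:k)
  ann <- data.frame(probe_id = rownames(probes), probeset_id = "ps1",
                    metaprobeset_id = "g1", stringsAsFactors = FALSE)
  out <- summarize_probes(probes, ann, "probeset", "mean")
  est <- mean(log2(out))
  # log of mean of lognormals carries a +sigma^2/2 bias in natural units
  bias <- sigma^2 / 2 * log(2)
  expect_lt(abs(est - mu - bias), 3 * sigma / sqrt(k * S) + 0.05)
})

test_that("DABG p-values follow the add-one empirical formula", {
  bg <- background_model(c(rep(50, 99), 10, 30, 70, 90),
                         c(seq_len(99), rep(1e6, 4)))
  ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                    probeset_id = c("A", "B", "C"),
                    metaprobeset_id = c("gA", "gB", "gC"),
                    stringsAsFactors = FALSE)
  probes <- matrix(c(1000, 0.5, 50.5), 3, 1,
                   dimnames = list(c("p1", "p2", "p3"), "s1"))
  d <- dabg(probes, gc = c(50, 50, 50), bg = bg, annotation = ann)
  expect_equal(d$probe_p["p1", 1], 1 / 100)  # beats all 99 draws
  expect_equal(d$probe_p["p2", 1], 1)        # below every draw
  expect_equal(d$probe_p["p3", 1], (1 + 49) / 100)
  # single-probe set: Fisher of one p is that p
  expect_equal(d$probeset_p["A", 1], d$probe_p["p1", 1], tolerance = 1e-12)
  expect_equal(d$probeset_p["B", 1], 1, tolerance = 1e-12)
})

test_that("DABG p-values are uniform on background-only probes", {
  set.seed(33)
  n_bg <- 50000
  bg <- background_model(runif(n_bg, 0, 100), 2^rnorm(n_bg, 4, 0.5))
  n <- 2000
  ann <- data.frame(probe_id = paste0("p", 1:n),
                    probeset_id = paste0("ps", 1:n),
                    metaprobeset_id = paste0("g", 1:n),
                    stringsAsFactors = FALSE)
  probes <- matrix(2^rnorm(n, 4, 0.5), n, 1,
                   dimnames = list(ann$probe_id, "s1"))
  d <- dabg(probes, gc = runif(n, 0, 100), bg = bg, annotation = ann)
  ks <- suppressWarnings(stats::ks.test(d$probe_p[, 1], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("preprocess returns consistent matrices", {
  prep <- small_preprocessed()
  d <- small_dataset()
  expect_identical(colnames(prep$probeset_expr), d$design$sample_id)
  expect_setequal(rownames(prep$probeset_expr),
                  unique(d$annotation$probeset_id))
  expect_setequal(rownames(prep$gene_expr),
                  unique(d$annotation$metaprobeset_id))
  expect_true(all(prep$probeset_expr > 0))
  expect_true(all(prep$gene_expr > 0))
  expect_true(all(prep$dabg > 0 & prep$dabg <= 1))
})
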