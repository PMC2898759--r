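# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 25-sample design table (one row per array)
design25 <- function() splicedex:::expand_design(default_design())

# small dataset with all effect types planted, regulator included
small_dataset <- function() cached("small_dataset", {
  cfg <- sim_config(n_genes = 60, n_fox2_up_exons = 6, n_fox2_down_exons = 6,
                    seed = 42)
  plant_fox2_regulation(simulate_dataset(cfg), cfg)
})

small_preprocessed <- function() cached("small_preprocessed",
                                        preprocess(small_dataset()))

small_filtered <- function() cached("small_filtered",
                                    apply_filters(small_preprocessed()))

small_differential <- function() cached("small_differential",
                                        run_differential(small_filtered()))

# brute-force BH step-up, the independent oracle for bh_fdr
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)  # rank of p[i]
    q[i] <- min(vapply(j:m, function(r) p[o[r]] * m / r, numeric(1)), 1)
  }
  q
}

# brute-force all-offsets substring scan (T/U-equivalent), oracle for scan_motifs
scan_bruteforce <- function(window, motifs) {
  w <- chartr("U", "T", toupper(window))
  hits <- list()
  for (m in motifs) {
    md <- chartr("U", "T", toupper(m))
    L <- nchar(md)
    for (off in 0:(nchar(w) - L)) {
      if (substr(w, off + 1, off + L) == md)
        hits[[length(hits) + 1]] <- data.frame(motif = m, offset = off,
                                               stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(motif = character(), offset = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$offset), , drop = FALSE]
}

random_window <- function(n = 100) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}
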