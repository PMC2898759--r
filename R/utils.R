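# internal helpers shared across modules

# 5 equal-width GC bins covering [0, 100]%
.gc_bin_edges <- function(n_bins = 5L) seq(0, 100, length.out = n_bins + 1L)

# map GC percentages to bin indices; edges cover [0,100] so every value lands
.gc_bin_index <- function(gc, edges = .gc_bin_edges()) {
  if (any(gc < edges[1] | gc > edges[length(edges)]))
    stop("GC content outside [0, 100]")
  findInterval(gc, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

# numeric position of a developmental stage on [0, 1]; drives planted
# stage gradients (E8.5 -> 0, E9.5 -> 0.5, E11.5 -> 1)
.stage_frac <- function(stage) {
  f <- c(E8.5 = 0, E9.5 = 0.5, E11.5 = 1)[stage]
  unname(f)
}

# row medians via matrixStats (fast path for the vectorized median polish)
.row_medians <- function(m) matrixStats::rowMedians(m)
.col_medians <- function(m) matrixStats::colMedians(m)

.is_log2 <- function(m) isTRUE(attr(m, "log2"))

# mean silhouette width of a 1- or 2-column score matrix under a label vector,
# euclidean distance; used for the PCA separation diagnostics
.silhouette_width <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  n <- nrow(scores)
  d <- as.matrix(stats::dist(scores))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(levels(labels), as.character(labels[i])),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
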