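# Shared fixture generators. Everything is built in code under fixed seeds.

# White-noise panel.
noise_panel <- function(t_points, n_nodes, seed = 1L, tr = 1) {
  set.seed(seed)
  ts_panel(matrix(rnorm(t_points * n_nodes), t_points, n_nodes),
           node_labels = paste0("p", seq_len(n_nodes)), tr_seconds = tr)
}

# Panel of mutually independent AR(1) nodes (the null generator).
ar1_panel <- function(t_points, n_nodes, coef = 0.5, seed = 1L) {
  set.seed(seed)
  x <- vapply(seq_len(n_nodes), function(i) {
    as.numeric(stats::arima.sim(list(ar = coef), t_points))
  }, numeric(t_points))
  ts_panel(x, node_labels = paste0("p", seq_len(n_nodes)), tr_seconds = 1)
}

# Random binary digraph over n nodes with a given number of edges drawn
# uniformly over the n^2 positions (self-loops allowed).
random_digraph <- function(n, n_edges, seed) {
  set.seed(seed)
  g <- matrix(0L, n, n)
  g[sample.int(n * n, min(n_edges, n * n))] <- 1L
  g
}

# All 2^(n^2) binary digraphs over n nodes (used for exhaustive oracles).
all_digraphs <- function(n) {
  cells <- n * n
  lapply(seq_len(2^cells) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(cells)]
    matrix(bits, n, n)
  })
}

# Brute-force confusion counts over all ordered pairs (directed protocol).
oracle_directed_counts <- function(truth, predicted) {
  n <- nrow(truth)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    t_ <- truth[i, j] != 0; p_ <- predicted[i, j] != 0
    if (t_ && p_) tp <- tp + 1L
    else if (!t_ && p_) fp <- fp + 1L
    else if (t_ && !p_) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Brute-force adjacency-protocol counts over unordered pairs.
oracle_adjacency_counts <- function(truth, predicted) {
  n <- nrow(truth)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    t_ <- truth[i, j] != 0 || truth[j, i] != 0
    p_ <- predicted[i, j] != 0 || predicted[j, i] != 0
    if (t_ && p_) tp <- tp + 1L
    else if (!t_ && p_) fp <- fp + 1L
    else if (t_ && !p_) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_f1 <- function(counts) {
  p <- if (counts["tp"] + counts["fp"] > 0)
    counts[["tp"]] / (counts[["tp"]] + counts[["fp"]]) else 0
  r <- if (counts["tp"] + counts["fn"] > 0)
    counts[["tp"]] / (counts[["tp"]] + counts[["fn"]]) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

# Hand-buildable lagged_edges object for orientation tests.
make_edges <- function(n_nodes, tau_max, lagged = NULL, lag0 = NULL,
                       alpha_level = 0.01) {
  if (is.null(lagged)) {
    lagged <- data.frame(i = integer(0), j = integer(0), lag = integer(0))
  }
  if (is.null(lag0)) lag0 <- data.frame(i = integer(0), j = integer(0))
  structure(list(lagged = lagged, lag0 = lag0, alpha_level = alpha_level,
                 tau_max = tau_max, n_nodes = n_nodes),
            class = "lagged_edges")
}
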