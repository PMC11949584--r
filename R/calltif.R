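#' Temporal multiple-comparison correction across lags
#'
#' A summary-graph edge i -> j is declared when any of the tau_max + 1
#' per-lag tests rejects, so the per-test threshold must be deflated to keep
#' the probability of a type-I error on that single edge decision below the
#' prescribed bound alpha. Under a uniform prior on the per-lag null
#' hypotheses and non-negative dependence of the nulls across lags, the
#' bound is alpha_level * (tau_max + 1) * 2^tau_max, hence
#'
#'   alpha_level = alpha / ((tau_max + 1) * 2^tau_max).
#'
#' The correction factor (tau_max + 1) * 2^tau_max replaces the factor
#' (tau_max + 1) of a plain Bonferroni correction across lags. Note this
#' bounds the error of one edge decision, not a family-wise rate across
#' edges.
#'
#' @param alpha_overall Prescribed bound on P(type I error) per summary
#'   edge, in (0, 1).
#' @param tau_max Non-negative integer maximum lag.
#' @return The per-test significance threshold.
#' @examples
#' corrected_alpha(0.01, 3)  # 0.01 / 32 = 0.0003125
#' @export
corrected_alpha <- function(alpha_overall, tau_max) {
  if (!is.numeric(alpha_overall) || length(alpha_overall) != 1L ||
      alpha_overall <= 0 || alpha_overall >= 1) {
    stop("alpha_overall must be a single number in (0, 1)")
  }
  tau_max <- as.integer(tau_max)
  if (length(tau_max) != 1L || is.na(tau_max) || tau_max < 0L) {
    stop("tau_max must be a single non-negative integer")
  }
  alpha_overall / ((tau_max + 1) * 2^tau_max)
}

#' Per-test threshold policy
#'
#' In `corrected` mode the per-test threshold is derived from the overall
#' type-I bound via [corrected_alpha()]; in `manual` mode the user supplies
#' `alpha_level` directly (the practice used when optimising the threshold
#' against a known ground truth in simulated data).
#'
#' @param alpha_overall Overall type-I bound in (0, 1).
#' @param tau_max Maximum lag.
#' @param alpha_level Optional manual per-test threshold; supplying it
#'   switches the policy to `manual` mode.
#' @return A `threshold_policy` object.
#' @export
threshold_policy <- function(alpha_overall = 0.01, tau_max = 3L,
                             alpha_level = NULL) {
  tau_max <- as.integer(tau_max)
  if (is.null(alpha_level)) {
    alpha_level <- corrected_alpha(alpha_overall, tau_max)
    mode <- "corrected"
  } else {
    if (!is.numeric(alpha_level) || length(alpha_level) != 1L ||
        alpha_level <= 0 || alpha_level >= 1) {
      stop("alpha_level must be a single number in (0, 1)")
    }
    mode <- "manual"
  }
  structure(list(alpha_overall = alpha_overall, tau_max = tau_max,
                 alpha_level = alpha_level, mode = mode),
            class = "threshold_policy")
}

#' Threshold the edge tensor into a lagged edge set
#'
#' Keeps, for every (source i, target j, lag tau), the tests whose p-value
#' is strictly below the per-test threshold. Lagged hits (tau >= 1,
#' including self-edges i = j) are directed X_i(t - tau) -> X_j(t);
#' contemporaneous hits are undirected pair marks recorded once in
#' canonical i < j form.
#'
#' @param tensor An [test_all_pairs()] result.
#' @param policy A [threshold_policy()]; its `tau_max` must match the
#'   tensor.
#' @return A `lagged_edges` object: data frames `lagged` (columns `i`, `j`,
#'   `lag`) and `lag0` (columns `i`, `j`, with `i < j`), plus the
#'   `alpha_level` applied.
#' @export
threshold_edges <- function(tensor, policy) {
  stopifnot(inherits(tensor, "edge_tensor"),
            inherits(policy, "threshold_policy"))
  if (policy$tau_max != tensor$tau_max) {
    stop("policy tau_max (", policy$tau_max,
         ") does not match tensor tau_max (", tensor$tau_max, ")")
  }
  a <- policy$alpha_level
  N <- length(tensor$node_labels)
  lagged <- data.frame(i = integer(0), j = integer(0), lag = integer(0))
  if (tensor$tau_max > 0L) {
    hits <- which(tensor$pval[, , -1L, drop = FALSE] < a, arr.ind = TRUE)
    if (nrow(hits)) {
      lagged <- data.frame(i = hits[, 1L], j = hits[, 2L], lag = hits[, 3L])
    }
  }
  p0 <- tensor$pval[, , 1L]
  p0[lower.tri(p0, diag = TRUE)] <- NA_real_  # canonical i < j
  hits0 <- which(p0 < a, arr.ind = TRUE)
  lag0 <- data.frame(i = as.integer(hits0[, 1L]), j = as.integer(hits0[, 2L]))
  structure(list(lagged = lagged, lag0 = lag0, alpha_level = a,
                 tau_max = tensor$tau_max, n_nodes = N),
            class = "lagged_edges")
}

#' Orient contemporaneous edge marks
#'
#' Resolves each undirected contemporaneous mark between nodes i and j
#' using the lagged evidence, exploiting the anatomical prior that
#' reciprocal connections are far more common than unidirectional ones:
#' \itemize{
#'   \item no lagged edge between i and j in either direction: emit the
#'     reciprocal pair i -> j and j -> i at lag 0;
#'   \item lagged edges in one direction only: emit that direction at
#'     lag 0 only;
#'   \item lagged edges in both directions: emit both lag-0 directions.
#' }
#'
#' @param edges A [threshold_edges()] result.
#' @return A data frame of directed lag-0 edges (columns `i`, `j`).
#' @export
orient_contemporaneous <- function(edges) {
  stopifnot(inherits(edges, "lagged_edges"))
  lag0 <- edges$lag0
  if (nrow(lag0) && any(lag0$i >= lag0$j)) {
    stop("malformed lag-0 marks: expected canonical i < j pairs")
  }
  out_i <- integer(0); out_j <- integer(0)
  cross <- edges$lagged[edges$lagged$i != edges$lagged$j, , drop = FALSE]
  for (r in seq_len(nrow(lag0))) {
    i <- lag0$i[r]; j <- lag0$j[r]
    fwd <- any(cross$i == i & cross$j == j)   # i -> j at some tau >= 1
    bwd <- any(cross$i == j & cross$j == i)
    if (fwd == bwd) {  # neither or both: reciprocal lag-0 pair
      out_i <- c(out_i, i, j); out_j <- c(out_j, j, i)
    } else if (fwd) {
      out_i <- c(out_i, i); out_j <- c(out_j, j)
    } else {
      out_i <- c(out_i, j); out_j <- c(out_j, i)
    }
  }
  data.frame(i = out_i, j = out_j)
}

#' Collapse directed lagged edges into a summary graph
#'
#' Applies the OR rule across lags: the summary graph has an edge i -> j
#' iff a directed edge i -> j exists at any lag tau >= 0 (lag-0 edges must
#' already be oriented). Edge strength is the minimum p-value across the
#' contributing lags (the symmetric lag-0 p-value is shared by both
#' directions when a reciprocal contemporaneous pair contributes); entries
#' without an edge carry strength 1.
#'
#' @param edges A [threshold_edges()] result (supplies the lagged edges and
#'   threshold).
#' @param oriented_lag0 The [orient_contemporaneous()] output.
#' @param tensor The [test_all_pairs()] tensor the edges came from.
#' @return A `summary_graph`: `adjacency` (0/1 N x N, `[i, j]` = 1 meaning
#'   i -> j; self-loops allowed), `strength` (minimum contributing
#'   p-values), `lag_provenance` (logical N x N x (tau_max + 1)),
#'   `node_labels`, `alpha_level`, `tau_max`.
#' @export
collapse_summary <- function(edges, oriented_lag0, tensor) {
  stopifnot(inherits(edges, "lagged_edges"), inherits(tensor, "edge_tensor"))
  N <- length(tensor$node_labels)
  tau_max <- tensor$tau_max
  dn <- list(tensor$node_labels, tensor$node_labels,
             paste0("lag", 0:tau_max))
  prov <- array(FALSE, c(N, N, tau_max + 1L), dimnames = dn)
  if (nrow(edges$lagged)) {
    prov[cbind(edges$lagged$i, edges$lagged$j, edges$lagged$lag + 1L)] <- TRUE
  }
  if (nrow(oriented_lag0)) {
    prov[cbind(oriented_lag0$i, oriented_lag0$j, 1L)] <- TRUE
  }
  adjacency <- matrix(0L, N, N, dimnames = dn[1:2])
  strength <- matrix(1, N, N, dimnames = dn[1:2])
  for (i in seq_len(N)) for (j in seq_len(N)) {
    lags <- which(prov[i, j, ])
    if (length(lags)) {
      adjacency[i, j] <- 1L
      strength[i, j] <- min(tensor$pval[i, j, lags])
    }
  }
  structure(
    list(adjacency = adjacency, strength = strength, lag_provenance = prov,
         node_labels = tensor$node_labels, alpha_level = edges$alpha_level,
         tau_max = tau_max),
    class = "summary_graph"
  )
}

#' @export
print.summary_graph <- function(x, ...) {
  n_edges <- sum(x$adjacency)
  N <- length(x$node_labels)
  cat("<summary_graph> ", N, " nodes, ", n_edges, " directed edges",
      " (density ", round(n_edges / max(1, N * N), 3), "), tau_max = ",
      x$tau_max, ", alpha_level = ", format(x$alpha_level), "\n", sep = "")
  invisible(x)
}

#' Run the full causal discovery pipeline
#'
#' End-to-end structure learning on a time-series panel: build the lagged
#' design, run all momentary conditional-independence partial-correlation
#' tests with complete lagged conditioning sets, threshold with the
#' (corrected or manual) per-test significance level, orient the
#' contemporaneous marks from lagged evidence, and OR-collapse across lags
#' into a directed summary graph. The whole pipeline is deterministic given
#' the panel.
#'
#' @param panel A [ts_panel()].
#' @param tau_max Maximum lag; default 3 (suited to TR ~0.7 s; use 2 for
#'   slower sampling such as TR = 1.2 s).
#' @param alpha_overall Overall per-edge type-I bound; default 0.01.
#' @param alpha_level Optional manual per-test threshold overriding the
#'   cross-lag correction (used when calibrating against a known ground
#'   truth).
#' @param standardize Passed to [build_lagged_design()].
#' @return A list with `graph` (the [collapse_summary()] `summary_graph`),
#'   `tensor` (the full [test_all_pairs()] `edge_tensor`) and `policy`.
#' @examples
#' set.seed(42)
#' x1 <- stats::arima.sim(list(ar = 0.5), 400)
#' x2 <- 0.8 * c(0, head(x1, -1)) + rnorm(400)
#' p <- ts_panel(cbind(a = as.numeric(x1), b = x2), tr_seconds = 1)
#' fit <- run_calltif(p, tau_max = 2, alpha_overall = 0.01)
#' fit$graph$adjacency
#' @export
run_calltif <- function(panel, tau_max = 3L, alpha_overall = 0.01,
                        alpha_level = NULL, standardize = TRUE) {
  design <- build_lagged_design(panel, tau_max, standardize = standardize)
  tensor <- test_all_pairs(design)
  policy <- threshold_policy(alpha_overall, tau_max, alpha_level)
  edges <- threshold_edges(tensor, policy)
  oriented <- orient_contemporaneous(edges)
  graph <- collapse_summary(edges, oriented, tensor)
  list(graph = graph, tensor = tensor, policy = policy)
}
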