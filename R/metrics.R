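# Coerce a summary_graph or 0/1 matrix to a binary adjacency matrix.
as_adjacency <- function(graph) {
  if (inherits(graph, "summary_graph")) {
    return(graph$adjacency)
  }
  g <- as.matrix(graph)
  if (nrow(g) != ncol(g)) stop("adjacency must be square")
  (g != 0) * 1L
}

# Check two graphs share a node set; returns aligned adjacency matrices
# (second reordered to the first's labels when both are labelled).
align_graphs <- function(truth, predicted) {
  gt <- as_adjacency(truth); gp <- as_adjacency(predicted)
  if (nrow(gt) != nrow(gp)) {
    stop("graphs have different node counts: ", nrow(gt), " vs ", nrow(gp))
  }
  lt <- rownames(gt); lp <- rownames(gp)
  if (!is.null(lt) && !is.null(lp)) {
    if (!setequal(lt, lp)) stop("graphs have different node label sets")
    gp <- gp[lt, lt, drop = FALSE]
  }
  list(truth = gt, predicted = gp)
}

f1_from_counts <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a predicted digraph against a ground truth
#'
#' Treats structure recovery as binary classification over edges, under two
#' protocols: the directed protocol scores all n^2 ordered pairs (self-loops
#' included, since damped autocorrelation makes them part of the truth);
#' the adjacency protocol first collapses both graphs to undirected (edge
#' iff a directed edge in at least one direction) and scores the n(n-1)/2
#' unordered pairs.
#'
#' @param truth,predicted Binary adjacency matrices (or `summary_graph`
#'   objects) over the same node set; `[i, j] = 1` means i -> j.
#' @return An `evaluation_report` list: `precision_directed`,
#'   `recall_directed`, `f1_directed`, `precision_adjacency`,
#'   `recall_adjacency`, `f1_adjacency`, and `counts` (TP/FP/FN/TN for both
#'   protocols).
#' @examples
#' truth <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
#' evaluate_graphs(truth, truth)$f1_directed  # 1
#' @export
evaluate_graphs <- function(truth, predicted) {
  g <- align_graphs(truth, predicted)
  gt <- g$truth; gp <- g$predicted
  n <- nrow(gt)
  tp <- sum(gt == 1 & gp == 1)
  fp <- sum(gt == 0 & gp == 1)
  fn <- sum(gt == 1 & gp == 0)
  tn <- as.integer(n * n) - tp - fp - fn
  dir_scores <- f1_from_counts(tp, fp, fn)

  ut <- (gt + t(gt)) > 0; up <- (gp + t(gp)) > 0
  keep <- upper.tri(ut)
  tp_a <- sum(ut[keep] & up[keep])
  fp_a <- sum(!ut[keep] & up[keep])
  fn_a <- sum(ut[keep] & !up[keep])
  tn_a <- as.integer(n * (n - 1) / 2) - tp_a - fp_a - fn_a
  adj_scores <- f1_from_counts(tp_a, fp_a, fn_a)

  structure(
    list(precision_directed = dir_scores$precision,
         recall_directed = dir_scores$recall,
         f1_directed = dir_scores$f1,
         precision_adjacency = adj_scores$precision,
         recall_adjacency = adj_scores$recall,
         f1_adjacency = adj_scores$f1,
         counts = list(
           directed = c(tp = tp, fp = fp, fn = fn, tn = tn),
           adjacency = c(tp = tp_a, fp = fp_a, fn = fn_a, tn = tn_a))),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("directed:  P = %.4f  R = %.4f  F1 = %.4f\n",
              x$precision_directed, x$recall_directed, x$f1_directed))
  cat(sprintf("adjacency: P = %.4f  R = %.4f  F1 = %.4f\n",
              x$precision_adjacency, x$recall_adjacency, x$f1_adjacency))
  invisible(x)
}

#' Node degree and causal flow
#'
#' For each node i of a (binary or weighted) digraph with adjacency G:
#' degree_i = (sum_j G\[i, j\] + sum_j G\[j, i\]) / N (normalized total
#' degree) and causal_flow_i = (sum_j G\[i, j\] - sum_j G\[j, i\]) / N
#' (out-degree minus in-degree; positive marks a net causal source,
#' negative a net sink). Sums run over all j including j = i, so flows
#' always sum to zero exactly.
#'
#' @param graph Adjacency matrix (weighted allowed) or `summary_graph`.
#' @return A data frame with columns `node`, `degree`, `causal_flow`.
#' @export
degree_and_flow <- function(graph) {
  if (inherits(graph, "summary_graph")) graph <- graph$adjacency
  g <- as.matrix(graph)
  if (nrow(g) != ncol(g)) stop("adjacency must be square")
  N <- nrow(g)
  out_sum <- rowSums(g)
  in_sum <- colSums(g)
  labels <- rownames(g)
  if (is.null(labels)) labels <- as.character(seq_len(N))
  # flow as a single quotient keeps sum(flow) = 0 exact for binary graphs
  data.frame(node = labels, degree = (out_sum + in_sum) / N,
             causal_flow = (out_sum - in_sum) / N, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Node partition into subnetworks
#'
#' @param node Character vector of node labels.
#' @param subnetwork Subnetwork label per node (e.g. the seven resting
#'   state networks plus subcortex).
#' @param hemisphere Optional hemisphere label per node; combined with the
#'   subnetwork (`"<subnetwork>_<hemisphere>"`) when given, mirroring the
#'   per-hemisphere aggregation used for cortical parcellations.
#' @return A `node_partition` data frame with columns `node`, `group`.
#' @export
node_partition <- function(node, subnetwork, hemisphere = NULL) {
  node <- as.character(node)
  if (anyDuplicated(node)) stop("each node must be mapped exactly once")
  group <- as.character(subnetwork)
  if (!is.null(hemisphere)) group <- paste(group, hemisphere, sep = "_")
  structure(data.frame(node = node, group = group,
                       stringsAsFactors = FALSE),
            class = c("node_partition", "data.frame"))
}

#' Aggregate a parcel-level digraph into a subnetwork digraph
#'
#' The weight of the edge from subnetwork a to subnetwork b is the number
#' of ordered node pairs (u in a, v in b, u != v) with an edge u -> v,
#' normalized by the number of possible such pairs: |a| * |b| for a != b
#' and |a| * (|a| - 1) within a subnetwork (self-loops excluded).
#'
#' @param graph Binary adjacency or `summary_graph`.
#' @param partition A [node_partition()] covering every graph node.
#' @param threshold Optional: weights strictly below it are zeroed (0.5 is
#'   a typical visualisation choice).
#' @return Weighted adjacency matrix over subnetwork groups.
#' @export
subnetwork_graph <- function(graph, partition, threshold = NULL) {
  g <- as_adjacency(graph)
  labels <- rownames(g)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(g)))
  idx <- match(labels, partition$node)
  if (anyNA(idx)) {
    stop("partition does not cover node(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  groups <- partition$group[idx]
  glev <- unique(partition$group)
  sizes <- vapply(glev, function(a) sum(groups == a), integer(1))
  if (any(sizes == 0L)) {
    stop("empty subnetwork(s): ", paste(glev[sizes == 0L], collapse = ", "))
  }
  W <- matrix(0, length(glev), length(glev), dimnames = list(glev, glev))
  diag(g) <- 0L  # node self-loops never count toward subnetwork weights
  for (a in seq_along(glev)) {
    for (b in seq_along(glev)) {
      cnt <- sum(g[groups == glev[a], groups == glev[b], drop = FALSE])
      denom <- if (a == b) sizes[a] * (sizes[a] - 1L) else sizes[a] * sizes[b]
      W[a, b] <- if (denom > 0) cnt / denom else 0
    }
  }
  if (!is.null(threshold)) W[W < threshold] <- 0
  W
}

#' Group-level graphs
#'
#' `group_average` is the entrywise mean of binary graphs (entry = fraction
#' of subjects with that edge); `group_intersection` keeps only the edges
#' present in every graph.
#'
#' @param graphs List of binary adjacency matrices (or `summary_graph`s)
#'   over identical node sets.
#' @return A probability matrix (`group_average`) or binary adjacency
#'   (`group_intersection`).
#' @export
group_average <- function(graphs) {
  mats <- align_graph_list(graphs)
  Reduce(`+`, mats) / length(mats)
}

#' @rdname group_average
#' @export
group_intersection <- function(graphs) {
  mats <- align_graph_list(graphs)
  (Reduce(`+`, mats) == length(mats)) * 1L
}

align_graph_list <- function(graphs) {
  if (!length(graphs)) stop("need at least one graph")
  first <- as_adjacency(graphs[[1L]])
  lapply(graphs, function(g) align_graphs(first, g)$predicted)
}

#' Functional connectivity graph
#'
#' Binary undirected graph from pairwise Pearson correlation over the
#' concatenated sessions of a panel: an edge is placed between two nodes
#' iff the two-sided t-test of their correlation has p < alpha
#' (uncorrected). Constant nodes receive no edges, with a warning.
#'
#' @param panel A [ts_panel()].
#' @param alpha Significance level; default 0.01.
#' @return Binary symmetric adjacency with zero diagonal.
#' @export
functional_graph <- function(panel, alpha = 0.01) {
  stopifnot(inherits(panel, "ts_panel"))
  X <- panel$values
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 time points")
  sds <- apply(X, 2L, stats::sd)
  const <- sds < .Machine$double.eps^0.5
  if (any(const)) {
    warning("constant node(s) get no edges: ",
            paste(panel$node_labels[const], collapse = ", "))
  }
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0
  P <- pval_from_rho_mat(R, n - 2L)
  adj <- (P < alpha) * 1L
  adj[const, ] <- 0L; adj[, const] <- 0L
  diag(adj) <- 0L
  dimnames(adj) <- list(panel$node_labels, panel$node_labels)
  adj
}

pval_from_rho_mat <- function(R, dof) {
  P <- matrix(pval_from_rho(pmin(1, pmax(-1, as.vector(R))), dof),
              nrow(R), ncol(R))
  P
}

#' Unique per-lag contributions to a summary graph
#'
#' For each lag tau, the percentage of summary edges whose lag provenance
#' is exactly \{tau\} — i.e. edges that the final graph owes to that lag
#' alone. Edges supported by multiple lags belong to no single lag, so the
#' percentages sum to at most 100.
#'
#' @param summary A `summary_graph` with provenance.
#' @return Named numeric vector of percentages, one entry per lag 0..tau_max.
#' @export
lag_contribution <- function(summary) {
  stopifnot(inherits(summary, "summary_graph"))
  prov <- summary$lag_provenance
  n_lags <- dim(prov)[3L]
  total <- sum(summary$adjacency)
  out <- stats::setNames(numeric(n_lags), paste0("lag", seq_len(n_lags) - 1L))
  if (total == 0L) {
    warning("empty summary graph; all lag contributions zero")
    return(out)
  }
  support <- apply(prov, c(1L, 2L), sum)
  for (l in seq_len(n_lags)) {
    only <- prov[, , l] & support == 1L
    out[l] <- 100 * sum(only) / total
  }
  out
}
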