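#' Time-series panel
#'
#' Container for one or more sessions of multivariate time-series
#' measurements (e.g. parcellated BOLD): a numeric matrix with one row per
#' time point and one named column per node, the repetition time (TR) of the
#' acquisition, and the session structure. Lags are never taken across a
#' session boundary.
#'
#' @param values Numeric matrix, time points x nodes. No missing or
#'   non-finite entries.
#' @param node_labels Character vector of unique node names, one per column.
#'   Defaults to the column names of `values`.
#' @param tr_seconds Positive sampling interval in seconds.
#' @param session_lengths Integer vector of contiguous session lengths
#'   summing to `nrow(values)`. Default: a single session.
#'
#' @return An object of class `ts_panel` with elements `values`,
#'   `node_labels`, `tr_seconds` and `session_lengths`.
#' @examples
#' p <- ts_panel(matrix(rnorm(40), 20, 2,
#'                      dimnames = list(NULL, c("a", "b"))), tr_seconds = 0.72)
#' n_nodes(p)
#' @export
ts_panel <- function(values, node_labels = colnames(values),
                     tr_seconds = 1, session_lengths = nrow(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(node_labels)) {
    node_labels <- paste0("V", seq_len(ncol(values)))
  }
  node_labels <- as.character(node_labels)
  if (length(node_labels) != ncol(values)) {
    stop("number of node labels (", length(node_labels),
         ") does not match number of columns (", ncol(values), ")")
  }
  if (anyDuplicated(node_labels)) {
    stop("node labels must be unique; duplicated: ",
         paste(unique(node_labels[duplicated(node_labels)]), collapse = ", "))
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("tr_seconds must be a single positive number")
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("panel values must be finite; first offending entry at row ",
         bad[1L], ", column ", bad[2L])
  }
  session_lengths <- as.integer(session_lengths)
  if (any(session_lengths < 1L) || sum(session_lengths) != nrow(values)) {
    stop("session_lengths must be positive and sum to nrow(values)")
  }
  colnames(values) <- node_labels
  structure(
    list(values = values, node_labels = node_labels,
         tr_seconds = as.numeric(tr_seconds),
         session_lengths = session_lengths),
    class = "ts_panel"
  )
}

#' @export
print.ts_panel <- function(x, ...) {
  cat("<ts_panel> ", nrow(x$values), " time points x ", length(x$node_labels),
      " nodes, TR = ", x$tr_seconds, " s, ",
      length(x$session_lengths), " session(s)\n", sep = "")
  invisible(x)
}

#' @rdname ts_panel
#' @param panel A `ts_panel`.
#' @export
n_nodes <- function(panel) length(panel$node_labels)

#' @rdname ts_panel
#' @export
n_sessions <- function(panel) length(panel$session_lengths)

# Row index ranges of each session, as a list of integer vectors.
session_rows <- function(panel) {
  ends <- cumsum(panel$session_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

#' Build the aligned lagged design matrix
#'
#' Materialises the lagged variable set X_k(t - s), s = 0..tau_max, that
#' every conditional-independence test consumes. For each usable time point
#' t (those with a full history of tau_max preceding samples inside the same
#' session) the design row holds the value of node k at time t - s in the
#' column mapped to (k, s). Rows from multiple sessions are stacked; no row
#' ever mixes values across a session boundary.
#'
#' @param panel A [ts_panel()].
#' @param tau_max Non-negative integer maximum lag.
#' @param standardize If `TRUE` (default), each design column is
#'   mean-centred and scaled to unit sample variance. Constant columns are
#'   left centred only and flagged in `constant_cols`.
#'
#' @return An object of class `lagged_design`: a list with `matrix` (rows =
#'   usable time points, columns = N * (tau_max + 1)), `column_map` (a
#'   data frame with `node`, `label`, `lag` per column), `n_effective`,
#'   `tau_max`, `node_labels`, `standardized` and `constant_cols`.
#' @details Column order is lag-major within node blocks: for node k the
#'   columns are (k, lag 0), (k, lag 1), ..., (k, lag tau_max). Column names
#'   are `<label>.l<lag>`.
#' @examples
#' p <- ts_panel(matrix(rnorm(20), 10, 2), tr_seconds = 1)
#' d <- build_lagged_design(p, tau_max = 3)
#' dim(d$matrix)  # 7 x 8
#' @export
build_lagged_design <- function(panel, tau_max, standardize = TRUE) {
  stopifnot(inherits(panel, "ts_panel"))
  tau_max <- as.integer(tau_max)
  if (length(tau_max) != 1L || is.na(tau_max) || tau_max < 0L) {
    stop("tau_max must be a single non-negative integer")
  }
  short <- which(panel$session_lengths <= tau_max + 1L)
  if (length(short)) {
    stop("session(s) ", paste(short, collapse = ", "), " too short: need ",
         "length > tau_max + 1 = ", tau_max + 1L, " time points, got ",
         paste(panel$session_lengths[short], collapse = ", "))
  }
  N <- n_nodes(panel)
  lags <- 0:tau_max
  column_map <- data.frame(
    node = rep(seq_len(N), each = tau_max + 1L),
    label = rep(panel$node_labels, each = tau_max + 1L),
    lag = rep(lags, times = N)
  )
  blocks <- lapply(session_rows(panel), function(rows) {
    seg <- panel$values[rows, , drop = FALSE]
    tt <- seq.int(tau_max + 1L, length(rows))  # session-local usable times
    out <- matrix(0, length(tt), N * (tau_max + 1L))
    for (col in seq_len(nrow(column_map))) {
      out[, col] <- seg[tt - column_map$lag[col], column_map$node[col]]
    }
    out
  })
  mat <- do.call(rbind, blocks)
  colnames(mat) <- paste0(column_map$label, ".l", column_map$lag)
  constant_cols <- integer(0)
  if (isTRUE(standardize)) {
    mu <- colMeans(mat)
    mat <- sweep(mat, 2L, mu, "-")
    sdv <- apply(mat, 2L, stats::sd)
    constant_cols <- which(sdv < .Machine$double.eps^0.5)
    scale_by <- ifelse(seq_along(sdv) %in% constant_cols, 1, sdv)
    mat <- sweep(mat, 2L, scale_by, "/")
  }
  structure(
    list(matrix = mat, column_map = column_map,
         n_effective = nrow(mat), tau_max = tau_max,
         node_labels = panel$node_labels,
         standardized = isTRUE(standardize),
         constant_cols = constant_cols),
    class = "lagged_design"
  )
}

#' @export
print.lagged_design <- function(x, ...) {
  cat("<lagged_design> ", x$n_effective, " rows x ", ncol(x$matrix),
      " lagged variables (", length(x$node_labels), " nodes, tau_max = ",
      x$tau_max, ")\n", sep = "")
  invisible(x)
}

# Column indices of the design for a given lag (across all nodes) or for a
# given node. Used throughout the CI engine.
design_cols <- function(design, lag = NULL, node = NULL) {
  keep <- rep(TRUE, nrow(design$column_map))
  if (!is.null(lag)) keep <- keep & design$column_map$lag %in% lag
  if (!is.null(node)) keep <- keep & design$column_map$node %in% node
  which(keep)
}
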