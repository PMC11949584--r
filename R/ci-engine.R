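#' Partial correlation test
#'
#' Computes the sample partial correlation rho(x, y | Z) as the Pearson
#' correlation of the residuals of `x` and `y` after least-squares
#' projection onto `[1, Z]` (an intercept is always included), and the
#' two-sided p-value for the null hypothesis rho = 0 from the t statistic
#' `rho * sqrt(dof / (1 - rho^2))` with `dof = n - |Z| - 2`.
#'
#' Rank-deficient conditioning sets are reduced: redundant columns are
#' dropped with a warning and the degrees of freedom adjusted to the number
#' of retained columns.
#'
#' @param x,y Numeric vectors of equal length.
#' @param conditioning Numeric matrix of conditioning variables with the
#'   same row count (or `NULL` / zero columns for a marginal correlation
#'   test).
#' @return A list with `rho`, `pval` and `dof`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); z <- rnorm(200); y <- x + z + rnorm(200)
#' partial_correlation(x, y, cbind(z))
#' @export
partial_correlation <- function(x, y, conditioning = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (is.null(conditioning)) {
    conditioning <- matrix(numeric(0), n, 0)
  }
  conditioning <- as.matrix(conditioning)
  if (nrow(conditioning) != n) {
    stop("conditioning must have the same number of rows as x and y")
  }
  qz <- qr(cbind(1, conditioning))
  n_cond <- qz$rank - 1L  # retained conditioning columns
  if (n_cond < ncol(conditioning)) {
    warning("conditioning set is rank deficient: dropped ",
            ncol(conditioning) - n_cond, " redundant column(s); ",
            "degrees of freedom adjusted")
  }
  dof <- n - n_cond - 2L
  if (dof < 1L) {
    stop("insufficient degrees of freedom: need n >= |Z| + 3 = ",
         n_cond + 3L, " rows, got ", n)
  }
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  rho <- max(-1, min(1, rho))
  list(rho = rho, pval = pval_from_rho(rho, dof), dof = dof)
}

# Two-sided p-value of the t statistic rho * sqrt(dof / (1 - rho^2)).
pval_from_rho <- function(rho, dof) {
  p <- numeric(length(rho))
  sat <- abs(rho) >= 1 - .Machine$double.eps
  p[sat] <- 0
  r <- rho[!sat]
  tstat <- r * sqrt(dof / (1 - r^2))
  p[!sat] <- 2 * stats::pt(abs(tstat), dof, lower.tail = FALSE)
  p
}

#' Momentary conditional-independence tests over all lagged pairs
#'
#' Runs the complete battery of partial-correlation tests that drives the
#' causal discovery: for every ordered node pair (i, j) and every lag
#' tau in 1..tau_max (including i = j, i.e. lagged self-influence), the test
#' of X_i(t - tau) against X_j(t) conditioned on all lagged variables
#' \{X_k(t - s): s = 1..tau_max\} except X_i(t - tau) itself; and for every
#' unordered pair (i, j), i != j, the contemporaneous test of X_i(t)
#' against X_j(t) conditioned on all lagged variables. No contemporaneous
#' variable is ever part of a conditioning set.
#'
#' Lagged tests are computed from the precision matrix of the joint set
#' (all lagged variables, target), one matrix inversion per target node;
#' contemporaneous tests correlate the residuals of the contemporaneous
#' block after projection on all lagged variables. Both routes are exactly
#' the textbook partial correlation.
#'
#' @param design A [build_lagged_design()] result.
#' @return An object of class `edge_tensor`: arrays `rho` and `pval` of
#'   dimension N x N x (tau_max + 1), slice `[ , , tau + 1]` holding the
#'   test of source lag `tau`; `dof`, an integer per lag; `n_effective`;
#'   `node_labels`; `tau_max`. The lag-0 slices are symmetric and their
#'   diagonal is `NA` (a variable is not tested against itself at lag 0).
#' @export
test_all_pairs <- function(design) {
  stopifnot(inherits(design, "lagged_design"))
  N <- length(design$node_labels)
  tau_max <- design$tau_max
  n <- design$n_effective
  lag_cols <- design_cols(design, lag = seq_len(tau_max))
  cont_cols <- design_cols(design, lag = 0L)
  n_lagged <- length(lag_cols)

  dof <- integer(tau_max + 1L)
  dof[1L] <- n - n_lagged - 2L          # lag 0: Z = all lagged variables
  if (tau_max > 0L) dof[-1L] <- n - (n_lagged - 1L) - 2L
  if (any(dof < 1L)) {
    stop("insufficient effective sample size (", n, " rows) for ",
         n_lagged, " conditioning variables; need n >= |Z| + 3")
  }

  dn <- list(design$node_labels, design$node_labels,
             paste0("lag", 0:tau_max))
  rho <- array(NA_real_, c(N, N, tau_max + 1L), dimnames = dn)
  pval <- array(NA_real_, c(N, N, tau_max + 1L), dimnames = dn)

  L <- design$matrix[, lag_cols, drop = FALSE]
  X0 <- design$matrix[, cont_cols, drop = FALSE]

  # Contemporaneous block: residualise on [1, L], then pairwise correlate.
  qL <- qr(cbind(1, L))
  E <- qr.resid(qL, X0)
  R0 <- suppressWarnings(stats::cor(E))
  R0[!is.finite(R0)] <- 0
  diag(R0) <- NA_real_
  rho[, , 1L] <- pmin(1, pmax(-1, R0))
  p0 <- matrix(NA_real_, N, N)
  off <- which(!is.na(R0))
  p0[off] <- pval_from_rho(rho[, , 1L][off], dof[1L])
  pval[, , 1L] <- p0

  if (tau_max > 0L) {
    # Per target j: precision matrix of (all lagged variables, X_j(t)).
    # The (c, target) entry yields rho(X_c, X_j | all lagged minus X_c).
    lag_map <- design$column_map[lag_cols, ]
    Lc <- sweep(L, 2L, colMeans(L), "-")
    for (j in seq_len(N)) {
      y <- X0[, j] - mean(X0[, j])
      S <- crossprod(cbind(Lc, y)) / (n - 1)
      Om <- tryCatch(solve(S), error = function(e) NULL)
      if (is.null(Om)) {
        # Singular joint covariance (collinear lagged variables): fall back
        # to explicit per-test residualisation with drop-and-warn.
        for (c in seq_len(n_lagged)) {
          res <- partial_correlation(L[, c], X0[, j],
                                     L[, -c, drop = FALSE])
          rho[lag_map$node[c], j, lag_map$lag[c] + 1L] <- res$rho
          pval[lag_map$node[c], j, lag_map$lag[c] + 1L] <- res$pval
        }
        next
      }
      m <- n_lagged + 1L
      r <- -Om[seq_len(n_lagged), m] / sqrt(diag(Om)[seq_len(n_lagged)] * Om[m, m])
      r <- pmin(1, pmax(-1, r))
      for (c in seq_len(n_lagged)) {
        rho[lag_map$node[c], j, lag_map$lag[c] + 1L] <- r[c]
      }
      pv <- pval_from_rho(r, dof[2L])
      for (c in seq_len(n_lagged)) {
        pval[lag_map$node[c], j, lag_map$lag[c] + 1L] <- pv[c]
      }
    }
  }

  structure(
    list(rho = rho, pval = pval, dof = dof, n_effective = n,
         node_labels = design$node_labels, tau_max = tau_max),
    class = "edge_tensor"
  )
}

#' @export
print.edge_tensor <- function(x, ...) {
  cat("<edge_tensor> ", length(x$node_labels), " nodes, lags 0..",
      x$tau_max, ", n_effective = ", x$n_effective, "\n", sep = "")
  invisible(x)
}

#' Serialise an edge tensor to a long-format table
#'
#' One row per (source, target, lag) test: columns `source`, `target`,
#' `lag`, `rho`, `pval`, `dof`. Untested entries (lag-0 diagonal) are
#' omitted.
#'
#' @param tensor An [test_all_pairs()] result.
#' @return A data frame.
#' @export
edge_tensor_table <- function(tensor) {
  stopifnot(inherits(tensor, "edge_tensor"))
  N <- length(tensor$node_labels)
  grid <- expand.grid(i = seq_len(N), j = seq_len(N), tau = 0:tensor$tau_max)
  grid <- grid[!(grid$tau == 0L & grid$i == grid$j), ]
  idx <- cbind(grid$i, grid$j, grid$tau + 1L)
  data.frame(
    source = tensor$node_labels[grid$i],
    target = tensor$node_labels[grid$j],
    lag = grid$tau,
    rho = tensor$rho[idx],
    pval = tensor$pval[idx],
    dof = tensor$dof[grid$tau + 1L],
    stringsAsFactors = FALSE
  )
}
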