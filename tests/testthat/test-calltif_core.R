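test_that("cross-lag correction follows the closed form", {
  expect_identical(corrected_alpha(0.01, 3), 0.01 / 32)
  expect_identical(corrected_alpha(0.05, 0), 0.05)
  expect_equal(corrected_alpha(0.01, 2), 0.01 / 12)
  expect_error(corrected_alpha(0, 3), "in \\(0, 1\\)")
  expect_error(corrected_alpha(0.01, -1), "non-negative")

  pol <- threshold_policy(0.01, 3)
  expect_equal(pol$alpha_level, 0.0003125)
  expect_equal(pol$mode, "corrected")
  expect_equal(threshold_policy(0.01, 3, alpha_level = 0.01)$mode, "manual")
})

test_that("thresholding is strict and respects the lag structure", {
  # constructed tensor: 2 nodes, tau_max = 1
  dn <- list(c("a", "b"), c("a", "b"), c("lag0", "lag1"))
  pv <- array(1, c(2, 2, 2), dimnames = dn)
  pv[, , 1][cbind(c(1, 2), c(2, 1))] <- 0.5  # symmetric lag 0
  pv[1, 2, 2] <- 0.01                        # a -> b at lag 1
  pv[2, 2, 2] <- 0.01                        # b -> b self lag 1
  diag(pv[, , 1]) <- NA
  tensor <- structure(list(rho = pv * 0, pval = pv, dof = c(10L, 10L),
                           n_effective = 20L, node_labels = c("a", "b"),
                           tau_max = 1L), class = "edge_tensor")

  got <- threshold_edges(tensor, threshold_policy(alpha_level = 0.02,
                                                  tau_max = 1))
  expect_equal(got$lagged[order(got$lagged$i), ],
               data.frame(i = c(1L, 2L), j = c(2L, 2L), lag = c(1L, 1L)),
               ignore_attr = TRUE)
  expect_equal(nrow(got$lag0), 0)

  # boundary: p exactly equal to the threshold is excluded
  at <- threshold_edges(tensor, threshold_policy(alpha_level = 0.01,
                                                 tau_max = 1))
  expect_equal(nrow(at$lagged), 0)

  # all p = 1 gives the empty set
  pv[] <- 1; diag(pv[, , 1]) <- NA
  tensor$pval <- pv
  none <- threshold_edges(tensor, threshold_policy(0.01, 1))
  expect_equal(nrow(none$lagged) + nrow(none$lag0), 0)
})

test_that("contemporaneous orientation follows the three lagged-evidence cases", {
  # no lagged edge between the pair: reciprocal lag-0 pair
  e <- make_edges(3, 3, lag0 = data.frame(i = 1L, j = 2L))
  got <- orient_contemporaneous(e)
  expect_setequal(paste(got$i, got$j), c("1 2", "2 1"))

  # lagged edge 1 -> 2 at tau = 2 only: that direction only
  e <- make_edges(3, 3, lagged = data.frame(i = 1L, j = 2L, lag = 2L),
                  lag0 = data.frame(i = 1L, j = 2L))
  got <- orient_contemporaneous(e)
  expect_equal(paste(got$i, got$j), "1 2")

  # both lagged directions (tau = 1 and tau = 3): both lag-0 directions
  e <- make_edges(3, 3,
                  lagged = data.frame(i = c(1L, 2L), j = c(2L, 1L),
                                      lag = c(1L, 3L)),
                  lag0 = data.frame(i = 1L, j = 2L))
  got <- orient_contemporaneous(e)
  expect_setequal(paste(got$i, got$j), c("1 2", "2 1"))

  # lagged self-loops never influence orientation of a pair
  e <- make_edges(3, 3, lagged = data.frame(i = 1L, j = 1L, lag = 1L),
                  lag0 = data.frame(i = 1L, j = 2L))
  expect_setequal(paste(orient_contemporaneous(e)$i,
                        orient_contemporaneous(e)$j), c("1 2", "2 1"))

  # malformed marks rejected
  bad <- make_edges(3, 3, lag0 = data.frame(i = 2L, j = 1L))
  expect_error(orient_contemporaneous(bad), "canonical")
})

test_that("OR-collapse records provenance and minimum-p strength", {
  dn <- list(c("a", "b"), c("a", "b"), paste0("lag", 0:2))
  pv <- array(1, c(2, 2, 3), dimnames = dn)
  pv[1, 2, 1] <- pv[2, 1, 1] <- 1e-9   # lag 0, symmetric
  pv[1, 2, 2] <- 1e-5                  # lag 1
  pv[1, 2, 3] <- 0.9                   # lag 2: not significant
  diag(pv[, , 1]) <- NA
  tensor <- structure(list(rho = pv * 0, pval = pv, dof = c(10L, 10L, 10L),
                           n_effective = 30L, node_labels = c("a", "b"),
                           tau_max = 2L), class = "edge_tensor")
  edges <- threshold_edges(tensor, threshold_policy(alpha_level = 1e-4,
                                                    tau_max = 2))
  oriented <- orient_contemporaneous(edges)
  g <- collapse_summary(edges, oriented, tensor)
  expect_equal(unname(g$adjacency["a", "b"]), 1L)
  expect_equal(unname(g$adjacency["b", "a"]), 0L)  # lag0 followed lag-1 direction
  expect_equal(unname(g$strength["a", "b"]), 1e-9) # min over contributing lags
  expect_equal(which(g$lag_provenance["a", "b", ]), c(lag0 = 1L, lag1 = 2L))
  expect_equal(unname(g$strength["b", "a"]), 1)

  # edge present only at tau = 2 still reaches the summary
  pv2 <- array(1, c(2, 2, 3), dimnames = dn); diag(pv2[, , 1]) <- NA
  pv2[2, 1, 3] <- 1e-6
  tensor$pval <- pv2
  edges2 <- threshold_edges(tensor, threshold_policy(alpha_level = 1e-4,
                                                     tau_max = 2))
  g2 <- collapse_summary(edges2, orient_contemporaneous(edges2), tensor)
  expect_equal(unname(g2$adjacency["b", "a"]), 1L)
})

test_that("full pipeline recovers a planted bivariate system", {
  p <- simulate_var(list(matrix(c(0, 0.8, 0, 0), 2, 2, byrow = TRUE)),
                    diag(2), 2000, seed = 21)
  g <- run_calltif(p, tau_max = 2, alpha_overall = 0.01)$graph
  expect_equal(unname(g$adjacency[1, 2]), 1L)
  expect_equal(unname(g$adjacency[2, 1]), 0L)

  # correlated innovations additionally produce a reciprocal lag-0 pair
  # between the otherwise-unconnected nodes 3 and 4
  B <- matrix(0, 4, 4); B[1, 2] <- 0.8
  S <- diag(4); S[3, 4] <- S[4, 3] <- 0.5
  p2 <- simulate_var(list(B), S, 2000, seed = 22)
  g2 <- run_calltif(p2, tau_max = 2, alpha_overall = 0.01)$graph
  expect_equal(unname(g2$adjacency[3, 4]), 1L)
  expect_equal(unname(g2$adjacency[4, 3]), 1L)
  expect_true(g2$lag_provenance[3, 4, 1] && g2$lag_provenance[4, 3, 1])
})

test_that("edge sets grow monotonically in the threshold", {
  p <- ar1_panel(400, 4, seed = 23)
  te <- test_all_pairs(build_lagged_design(p, 2))
  levels <- c(1e-4, 1e-3, 1e-2, 0.1)
  sets <- lapply(levels, function(a) {
    e <- threshold_edges(te, threshold_policy(alpha_level = a, tau_max = 2))
    g <- collapse_summary(e, orient_contemporaneous(e), te)
    which(g$adjacency == 1L)
  })
  for (k in seq_along(levels)[-1]) {
    expect_true(all(sets[[k - 1]] %in% sets[[k]]))
  }
})

test_that("pipeline is deterministic and self-consistent", {
  p <- ar1_panel(500, 5, seed = 24)
  f1 <- run_calltif(p, 3, 0.01)
  f2 <- run_calltif(p, 3, 0.01)
  expect_identical(f1$graph, f2$graph)

  g <- f1$graph; te <- f1$tensor
  edge_idx <- which(g$adjacency == 1L, arr.ind = TRUE)
  for (r in seq_len(nrow(edge_idx))) {
    expect_lt(g$strength[edge_idx[r, 1], edge_idx[r, 2]], g$alpha_level)
  }
  prov_idx <- which(g$lag_provenance, arr.ind = TRUE)
  for (r in seq_len(nrow(prov_idx))) {
    expect_lt(te$pval[prov_idx[r, 1], prov_idx[r, 2], prov_idx[r, 3]],
              g$alpha_level)
  }
})

test_that("relabeling nodes conjugates the summary graph", {
  p <- simulate_var(list(matrix(c(0, 0.7, 0, 0, 0, 0.7, 0, 0, 0), 3, 3,
                                byrow = TRUE)), diag(3), 1500, seed = 25)
  g <- run_calltif(p, 2, 0.01)$graph
  perm <- c(3, 1, 2)
  pp <- ts_panel(p$values[, perm], node_labels = p$node_labels[perm],
                 tr_seconds = 1)
  gp <- run_calltif(pp, 2, 0.01)$graph
  expect_equal(gp$adjacency[p$node_labels, p$node_labels], g$adjacency)
  expect_equal(gp$strength[p$node_labels, p$node_labels], g$strength)
})
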