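test_that("evaluate_graphs matches hand-enumerated confusion counts", {
  truth <- matrix(0L, 3, 3); truth[1, 2] <- truth[2, 3] <- truth[3, 1] <- 1L
  truth[1, 1] <- 1L                                  # self-loop
  pred <- matrix(0L, 3, 3); pred[1, 2] <- pred[2, 3] <- pred[2, 1] <- 1L
  rep <- evaluate_graphs(truth, pred)
  expect_equal(rep$counts$directed, c(tp = 2, fp = 1, fn = 2, tn = 4))
  expect_equal(rep$precision_directed, 2 / 3)
  expect_equal(rep$recall_directed, 1 / 2)
  expect_equal(rep$f1_directed, 4 / 7)
  expect_equal(rep$counts$adjacency[c("tp", "fp", "fn")],
               c(tp = 2, fp = 0, fn = 1))
  expect_equal(rep$f1_adjacency, 0.8)

  # degenerate protocols
  expect_equal(evaluate_graphs(truth, truth)$f1_directed, 1)
  expect_equal(evaluate_graphs(truth, truth)$f1_adjacency, 1)
  empty <- matrix(0L, 3, 3)
  expect_equal(evaluate_graphs(truth, empty)$recall_directed, 0)
  expect_equal(evaluate_graphs(truth, empty)$f1_directed, 0)
  expect_error(evaluate_graphs(truth, matrix(0L, 4, 4)), "node counts")
})

test_that("evaluate_graphs agrees with the exhaustive oracle", {
  # all 512 3-node digraphs against a rotating set of predictions
  graphs3 <- all_digraphs(3)
  preds <- graphs3[seq(1, 512, by = 37)]
  for (k in seq_along(graphs3)) {
    truth <- graphs3[[k]]
    pred <- preds[[(k %% length(preds)) + 1L]]
    rep <- evaluate_graphs(truth, pred)
    cd <- oracle_directed_counts(truth, pred)
    ca <- oracle_adjacency_counts(truth, pred)
    expect_identical(unname(rep$counts$directed), unname(cd))
    expect_identical(unname(rep$counts$adjacency), unname(ca))
    expect_equal(rep$f1_directed, oracle_f1(cd))
    expect_equal(rep$f1_adjacency, oracle_f1(ca))
  }
  # plus random 4-node pairs
  for (s in 1:25) {
    truth <- random_digraph(4, sample(0:16, 1), seed = s)
    pred <- random_digraph(4, sample(0:16, 1), seed = 1000 + s)
    rep <- evaluate_graphs(truth, pred)
    expect_identical(unname(rep$counts$directed),
                     unname(oracle_directed_counts(truth, pred)))
    expect_identical(unname(rep$counts$adjacency),
                     unname(oracle_adjacency_counts(truth, pred)))
  }
})

test_that("degree and causal flow follow the normalized formulas", {
  g <- matrix(0L, 10, 10)
  g[1, 2:4] <- 1L  # 3 out-edges
  g[5, 1] <- 1L    # 1 in-edge
  df <- degree_and_flow(g)
  expect_equal(df$degree[1], 0.4)
  expect_equal(df$causal_flow[1], 0.2)
  iso <- df[10, ]
  expect_equal(iso$degree, 0)
  expect_equal(iso$causal_flow, 0)

  # conservation and oracle agreement on every 3-node digraph
  for (g3 in all_digraphs(3)) {
    df3 <- degree_and_flow(g3)
    expect_equal(sum(df3$causal_flow), 0)
    expect_equal(df3$degree, (rowSums(g3) + colSums(g3)) / 3)
  }

  # weighted graphs use weighted sums
  w <- matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE)
  expect_equal(degree_and_flow(w)$causal_flow, c(0.25, -0.25))
})

test_that("subnetwork aggregation normalizes by possible pair counts", {
  part <- node_partition(paste0("n", 1:5), c("A", "A", "B", "B", "B"))
  g <- matrix(0L, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  g[1:2, 3:5] <- 1L  # complete bipartite A -> B
  W <- subnetwork_graph(g, part)
  expect_equal(unname(W["A", "B"]), 1)
  expect_equal(unname(W["B", "A"]), 0)

  g2 <- g; g2[1, 4:5] <- 0L; g2[2, 5] <- 0L  # 3 of 6 pairs remain
  expect_equal(unname(subnetwork_graph(g2, part)["A", "B"]), 0.5)
  expect_equal(unname(subnetwork_graph(g2, part, threshold = 0.51)["A", "B"]), 0)

  # within-subnetwork weight: |a|(|a|-1) pairs, self-loops ignored
  g3 <- matrix(0L, 5, 5, dimnames = dimnames(g))
  g3[3, 4] <- g3[4, 3] <- g3[3, 3] <- 1L
  expect_equal(unname(subnetwork_graph(g3, part)["B", "B"]), 2 / 6)

  expect_error(
    subnetwork_graph(g, node_partition(paste0("n", 1:4), rep("A", 4))),
    "cover")
})

test_that("subnetwork weights agree with a brute-force pair count", {
  for (s in 1:20) {
    g <- random_digraph(4, sample(0:16, 1), seed = 40 + s)
    dimnames(g) <- list(paste0("n", 1:4), paste0("n", 1:4))
    set.seed(90 + s)
    grp <- sample(c("x", "y"), 4, replace = TRUE)
    if (length(unique(grp)) < 2) grp[1] <- setdiff(c("x", "y"), grp)[1]
    part <- node_partition(paste0("n", 1:4), grp)
    W <- subnetwork_graph(g, part)
    for (a in unique(grp)) for (b in unique(grp)) {
      cnt <- 0; denom <- 0
      for (u in which(grp == a)) for (v in which(grp == b)) {
        if (u == v) next
        denom <- denom + 1
        cnt <- cnt + g[u, v]
      }
      expect_equal(unname(W[a, b]), if (denom > 0) cnt / denom else 0)
    }
  }
})

test_that("group graphs take entrywise mean and intersection", {
  g1 <- random_digraph(4, 6, seed = 61)
  g2 <- random_digraph(4, 6, seed = 62)
  expect_equal(group_average(list(g1, g1)), g1, ignore_attr = TRUE)
  expect_equal(group_intersection(list(g1, g1)), g1, ignore_attr = TRUE)

  graphs <- list(g1, g1, g1, g2)
  avg <- group_average(graphs)
  expect_equal(avg, (3 * g1 + g2) / 4, ignore_attr = TRUE)
  inter <- group_intersection(graphs)
  expect_equal(inter, g1 * g2, ignore_attr = TRUE)
  expect_error(group_average(list(g1, matrix(0, 3, 3))), "node counts")
})

test_that("functional graph thresholds pairwise correlation tests", {
  set.seed(70)
  x <- rnorm(100)
  p <- ts_panel(cbind(a = x, b = x, c = rnorm(100)), tr_seconds = 1)
  fg <- functional_graph(p, alpha = 0.01)
  expect_equal(unname(fg["a", "b"]), 1L)
  expect_true(all(diag(fg) == 0))
  expect_equal(fg, t(fg))
  expect_equal(functional_graph(p, alpha = 0), matrix(0L, 3, 3),
               ignore_attr = TRUE)

  pc <- ts_panel(cbind(a = rnorm(50), b = rep(1, 50)), tr_seconds = 1)
  expect_warning(fgc <- functional_graph(pc), "constant")
  expect_true(all(fgc == 0))

  # null calibration: ~alpha of pairs edged under independence
  edged <- 0; total <- 0
  for (s in 1:40) {
    pn <- noise_panel(120, 6, seed = 700 + s)
    f <- functional_graph(pn, alpha = 0.05)
    edged <- edged + sum(f[upper.tri(f)]); total <- total + 15
  }
  expect_lt(abs(edged / total - 0.05), 0.025)
})

test_that("lag contributions count single-lag provenance percentages", {
  mk <- function(prov) {
    N <- dim(prov)[1]
    structure(list(adjacency = (apply(prov, c(1, 2), any)) * 1L,
                   strength = matrix(1, N, N), lag_provenance = prov,
                   node_labels = paste0("n", seq_len(N)),
                   alpha_level = 0.01, tau_max = dim(prov)[3] - 1L),
              class = "summary_graph")
  }
  # 10 edges in a 4-node graph: 7 lag-0 only, 2 lag-1 only, 1 multi-lag
  prov <- array(FALSE, c(4, 4, 3))
  cells <- which(diag(4) == 0)[1:10]
  for (k in 1:7) prov[, , 1][cells[k]] <- TRUE
  for (k in 8:9) prov[, , 2][cells[k]] <- TRUE
  prov[, , 1][cells[10]] <- TRUE; prov[, , 3][cells[10]] <- TRUE
  got <- lag_contribution(mk(prov))
  expect_equal(unname(got), c(70, 20, 0))
  expect_lte(sum(got), 100)

  # all edges lag 0 only
  prov0 <- array(FALSE, c(3, 3, 2)); prov0[1, 2, 1] <- prov0[2, 1, 1] <- TRUE
  expect_equal(unname(lag_contribution(mk(prov0))), c(100, 0))

  empty <- array(FALSE, c(3, 3, 2))
  expect_warning(z <- lag_contribution(mk(empty)), "empty")
  expect_equal(unname(z), c(0, 0))
})

test_that("adjacency collapse commutes with node relabeling", {
  for (s in 1:10) {
    truth <- random_digraph(5, 8, seed = 500 + s)
    pred <- random_digraph(5, 8, seed = 600 + s)
    perm <- sample(5)
    r1 <- evaluate_graphs(truth, pred)
    r2 <- evaluate_graphs(truth[perm, perm], pred[perm, perm])
    expect_equal(r1$f1_adjacency, r2$f1_adjacency)
    expect_equal(r1$f1_directed, r2$f1_directed)
  }
})
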