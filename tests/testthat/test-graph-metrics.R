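test_that("thresholding zeroes small weights, idempotently and monotonically", {
  g <- graph_from_upper(c(0.05, 0.3, 0.7), 3)
  gt <- threshold_graph(g, 0.1)
  expect_equal(sort(gt$weights[upper.tri(gt$weights)]), c(0, 0.3, 0.7))
  expect_identical(threshold_graph(g, 0)$weights, g$weights)
  expect_true(all(threshold_graph(g, 1.01)$weights == 0))
  expect_identical(threshold_graph(threshold_graph(g, 0.3), 0.3)$weights,
                   threshold_graph(g, 0.3)$weights)

  set.seed(20)
  gr <- connectivity_graph(random_weight_matrix(7), directed = FALSE)
  e1 <- threshold_graph(gr, 0.2)$weights > 0
  e2 <- threshold_graph(gr, 0.5)$weights > 0
  expect_true(all(e1[e2]))  # edge set shrinks as w_min grows
})

test_that("connectivity detection treats positive weights as edges", {
  expect_true(is_connected(graph_from_upper(rep(0.4, 6), 4)))
  g_iso <- graph_from_upper(c(0.5, 0, 0, 0.5, 0, 0), 4)
  expect_false(is_connected(g_iso))

  # two triangles joined by one surviving edge
  W <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    W[p[1], p[2]] <- W[p[2], p[1]] <- 0.8
  }
  W[3, 4] <- W[4, 3] <- 0.2
  expect_true(is_connected(connectivity_graph(W, FALSE)))
  expect_false(is_connected(threshold_graph(connectivity_graph(W, FALSE),
                                            0.5)))
})

test_that("rich club keeps the top-degree nodes with a deterministic tie rule", {
  set.seed(21)
  W <- random_weight_matrix(20, density = 0.9)
  g <- connectivity_graph(W, FALSE)
  rc <- rich_club_subgraph(g, 0.1)
  expect_identical(nrow(rc$weights), 2L)
  top2 <- order(-rowSums(W))[1:2]
  expect_setequal(rc$node_ids, top2)

  # star: the hub always survives
  Ws <- matrix(0, 6, 6)
  Ws[1, 2:6] <- Ws[2:6, 1] <- 0.9
  rcs <- rich_club_subgraph(connectivity_graph(Ws, FALSE), 0.34)
  expect_true(1L %in% rcs$node_ids)

  # equal degrees: lowest ids selected
  geq <- graph_from_upper(rep(0.5, 10), 5)
  expect_identical(rich_club_subgraph(geq, 0.4)$node_ids, 1:2)

  expect_error(rich_club_subgraph(geq, 0.1), "fewer than 2")
})

test_that("degree features follow the weighted/normalized definitions", {
  geq <- graph_from_upper(rep(0.3, 6), 4)
  df <- degree_features(geq)
  expect_equal(df$deg_n, rep(1, 4))
  expect_equal(df$deg_w, rep(0.9, 4))

  g <- graph_from_upper(c(0.2, 0.8, 0), 3)  # node 1 carries 0.2 and 0.8
  df2 <- degree_features(g)
  expect_equal(df2$deg_w[1], 1.0)
  expect_equal(df2$deg_n[1], 1.0 / (2 * 0.8))

  set.seed(22)
  for (rep in 1:5) {
    gr <- connectivity_graph(random_weight_matrix(8), FALSE)
    dn <- degree_features(gr)$deg_n
    expect_true(all(dn >= 0 & dn <= 1))
  }
})

test_that("shortest paths minimize summed inverse weights", {
  # chain a-b-c with weights 0.5: dist(a, c) = 4
  g <- graph_from_upper(c(0.5, 0, 0.5), 3)
  d <- graph_shortest_paths(g)
  expect_equal(d[1, 3], 4)

  # strong two-hop route beats a weak direct edge
  g2 <- graph_from_upper(c(0.5, 0.2, 0.5), 3)
  expect_equal(graph_shortest_paths(g2)[1, 3], 4)

  set.seed(23)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    directed <- rep %% 2 == 0
    W <- random_weight_matrix(n, density = 0.5, directed = directed)
    g <- connectivity_graph(W, directed)
    expect_equal(graph_shortest_paths(g), brute_force_dists(W, directed),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("closeness centrality matches hand arithmetic and scales with
           weights", {
  tri <- graph_from_upper(rep(0.5, 3), 3)
  expect_equal(closeness_centrality(tri), rep(0.5, 3))

  set.seed(24)
  W <- random_weight_matrix(6, density = 0.9)
  g <- connectivity_graph(W, FALSE)
  cw <- closeness_centrality(g)
  g2 <- connectivity_graph(3 * W, FALSE)
  expect_equal(closeness_centrality(g2), 3 * cw, tolerance = 1e-12)

  perm <- c(4L, 2L, 6L, 1L, 3L, 5L)
  gp <- connectivity_graph(W[perm, perm], FALSE)
  expect_equal(closeness_centrality(gp), cw[perm], tolerance = 1e-12)

  expect_error(closeness_centrality(graph_from_upper(c(0.5, 0, 0, 0.5, 0, 0),
                                                     4)), "connected")
})

test_that("the weighted clustering coefficient reduces to the binary one on
           binary graphs", {
  tri <- graph_from_upper(rep(1, 3), 3)
  expect_equal(clustering_coefficient(tri), rep(1, 3))

  path <- graph_from_upper(c(1, 0, 1), 3)
  expect_equal(clustering_coefficient(path)[2], 0)

  set.seed(25)
  for (rep in 1:30) {
    n <- 10
    A <- random_weight_matrix(n, density = 0.5) > 0
    W <- A * 1
    g <- connectivity_graph(W, FALSE)
    cc <- clustering_coefficient(g)
    k <- rowSums(A)
    tri_count <- diag(W %*% W %*% W) / 2
    oracle <- ifelse(k >= 2, 2 * tri_count / (k * (k - 1)), 0)
    expect_equal(cc, oracle, tolerance = 1e-12)
  }
})

test_that("modularity evaluation and maximization are mutually consistent", {
  set.seed(26)
  W <- random_weight_matrix(9, density = 0.6)
  g <- connectivity_graph(W, FALSE)
  # whole graph as one community: Q = 0 exactly
  expect_equal(modularity_value(g, rep(1L, 9)), 0)

  r <- graph_modularity(g)
  expect_equal(r$Q, modularity_value(g, r$membership), tolerance = 1e-12)
  expect_gte(r$Q, modularity_value(g, seq_len(9)))
  expect_gte(r$Q, 0)

  expect_error(graph_modularity(connectivity_graph(
    matrix(c(0, 1, 0, 0), 2, 2), directed = TRUE)), "undirected")
})

test_that("the multilevel heuristic agrees with an independent community
           detector on planted structure", {
  set.seed(27)
  n <- 24
  blocks <- rep(1:3, each = 8)
  W <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (blocks[i] == blocks[j]) 0.8 else 0.05
      if (runif(1) < p) W[i, j] <- W[j, i] <- runif(1, 0.5, 1)
    }
  }
  g <- connectivity_graph(W, FALSE)
  r <- graph_modularity(g)
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE)
  q_ref <- igraph::modularity(igraph::cluster_louvain(ig))
  expect_gte(r$Q, q_ref - 1e-9)
  # recovered communities match the planted blocks
  expect_identical(max(r$membership), 3L)
  split_sizes <- tapply(blocks, r$membership, function(b) length(unique(b)))
  expect_true(all(split_sizes == 1))
})

test_that("feature vectors have the documented dimension and invariances", {
  set.seed(28)
  W <- random_weight_matrix(10, density = 0.9)
  g <- connectivity_graph(W, FALSE)
  fv <- feature_vector(g)
  expect_length(fv, 22L)
  expect_true(all(is.finite(fv)))
  expect_identical(unname(fv["n_nodes_scaled"]), 0.1)

  Wd <- random_weight_matrix(10, density = 0.9, directed = TRUE)
  fvd <- feature_vector(connectivity_graph(Wd, TRUE))
  expect_length(fvd, 21L)
  expect_false("modularity" %in% names(fvd))

  perm <- sample(10)
  fvp <- feature_vector(connectivity_graph(W[perm, perm], FALSE))
  expect_equal(fvp, fv, tolerance = 1e-10)

  # degenerate (all-equal-weight) distributions: sd = skew = kurtosis = 0
  geq <- graph_from_upper(rep(0.5, 6), 4)
  fve <- feature_vector(geq)
  expect_equal(unname(fve[c("weight_sd", "weight_skewness",
                            "weight_kurtosis")]), c(0, 0, 0))

  expect_error(feature_vector(graph_from_upper(c(0.5, 0, 0, 0.5, 0, 0), 4)),
               "connected")
})

test_that("mean graph weight averages all off-diagonal entries", {
  g <- graph_from_upper(c(0.6, 0, 0.3), 3)
  expect_equal(mean_edge_weight(g), mean(c(0.6, 0, 0.3, 0.6, 0, 0.3)))
  expect_equal(mean_edge_weight(threshold_graph(g, 0.5)), 0.2)
})
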