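test_that("sliding windows tile the series as specified", {
  expect_identical(sliding_windows(130, 130, 0),
                   cbind(start = 1L, end = 130L))
  # 50-point windows with 20% overlap: step 40, i.e. 10 points shared
  w <- sliding_windows(130, 50, 0.2)
  expect_identical(w[, "start"], c(1L, 41L, 81L))
  expect_identical(w[, "end"], c(50L, 90L, 130L))
  expect_identical(unname(w[1, "end"] - w[2, "start"] + 1L), 10L)

  w2 <- sliding_windows(100, 50, 0.2)
  expect_true(all(w2[, "end"] <= 100L))
  expect_error(sliding_windows(100, 50, 1), "step")
})

test_that("correlation edges match the covariance-formula oracle", {
  set.seed(11)
  x <- rnorm(130)
  expect_equal(edge_corr(x, x), 1.0)
  expect_equal(edge_corr(x, -x), 1.0)

  for (i in 1:20) {
    a <- rnorm(60)
    b <- rnorm(60)
    oracle <- abs(mean(a * b) - mean(a) * mean(b)) /
      sqrt((mean(a^2) - mean(a)^2) * (mean(b^2) - mean(b)^2))
    expect_equal(edge_corr(a, b), oracle, tolerance = 1e-12)
  }

  # lagged pair: the directed scan finds the lag and dominates undirected
  set.seed(12)
  x <- rnorm(130)
  y <- c(0, 0, x[1:128]) + rnorm(130, sd = 0.05)
  expect_gt(edge_corr(x, y, directed = TRUE), 0.95)
  expect_gte(edge_corr(x, y, directed = TRUE), edge_corr(x, y))

  expect_error(edge_corr(rep(1, 50), rnorm(50)), "degenerate|constant")
})

test_that("h2 captures nonlinear dependence that correlation misses", {
  x <- seq(-1, 1, length.out = 130)
  expect_equal(edge_h2(x, x + 0 * x), 1.0)
  y <- x^2
  expect_gte(edge_h2(x, y), 0.9)
  expect_lte(abs(cor(x, y)), 0.1)

  set.seed(13)
  nulls <- replicate(300, edge_h2(rnorm(130), rnorm(130)))
  expect_lt(quantile(nulls, 0.95), 0.3)
  expect_true(all(nulls >= 0 & nulls <= 1))
})

test_that("normalized mutual information is 1 for identical series and near 0
           for independent ones", {
  set.seed(14)
  x <- rnorm(130)
  expect_equal(edge_mit(x, x), 1.0)

  nulls <- replicate(300, edge_mit(rnorm(130), rnorm(130)))
  expect_lt(mean(nulls), 0.15)

  perms <- replicate(100, {
    a <- rnorm(130)
    edge_mit(a, sample(a))
  })
  # a random permutation carries no more information than an independent pair
  expect_lt(abs(mean(perms) - mean(nulls)), 0.05)
})

test_that("transfer entropy detects directed lagged coupling and stays near
           zero under the null", {
  set.seed(15)
  nulls <- replicate(300, edge_te(rnorm(130), rnorm(130), directed = TRUE))
  expect_lt(quantile(nulls, 0.95), 0.35)

  hits <- replicate(100, {
    x <- rnorm(130)
    y <- c(0, x[-130]) + rnorm(130, sd = 0.3)
    edge_te(x, y, directed = TRUE) > edge_te(y, x, directed = TRUE)
  })
  expect_gte(mean(hits), 0.9)

  # a self-driven target admits no extra information from an unrelated source
  selfs <- replicate(100, {
    y <- numeric(130)
    y[1] <- runif(1, 0.2, 0.8)
    for (t in 2:130) y[t] <- 3.8 * y[t - 1] * (1 - y[t - 1])
    edge_te(rnorm(130), y, directed = TRUE)
  })
  expect_lt(mean(selfs), mean(nulls) + 0.1)

  expect_error(edge_te(rnorm(10), rnorm(10)), "short")
})

test_that("build_graph assembles weights per spec contract", {
  tt <- 130
  set.seed(16)
  s <- as.numeric(scale(rnorm(tt)))
  ts3 <- structure(list(series = rbind(s, s, s) +
                          matrix(rnorm(3 * tt, sd = 1e-9), 3),
                        cluster_ids = 1:3),
                   class = "cluster_ts")
  g <- build_graph(ts3, edge_method_spec("corr", name = "BcorrU1"))
  off <- row(g$weights) != col(g$weights)
  expect_equal(unname(g$weights[off]), rep(1, 6), tolerance = 1e-6)
  expect_true(all(diag(g$weights) == 0))

  set.seed(17)
  x <- matrix(rnorm(4 * tt), 4, tt)
  ts4 <- structure(list(series = x, cluster_ids = 1:4), class = "cluster_ts")
  gu <- build_graph(ts4, edge_method_spec("corr", directed = FALSE))
  expect_identical(gu$weights, t(gu$weights))
  gd <- build_graph(ts4, edge_method_spec("TE", directed = TRUE,
                                          name = "BTED1"))
  expect_false(isTRUE(all.equal(gd$weights, t(gd$weights))))

  # permutation invariance: relabeling clusters permutes the weight matrix
  perm <- c(3L, 1L, 4L, 2L)
  tsp <- structure(list(series = x[perm, ], cluster_ids = 1:4),
                   class = "cluster_ts")
  gp <- build_graph(tsp, edge_method_spec("corr", directed = FALSE))
  expect_equal(gp$weights, gu$weights[perm, perm], tolerance = 1e-12)

  # degenerate cluster: incident edges zeroed with a warning
  xdeg <- rbind(x[1:3, ], rep(1, tt))
  tsd <- structure(list(series = xdeg, cluster_ids = 1:4),
                   class = "cluster_ts")
  expect_warning(gdz <- build_graph(tsd, edge_method_spec("corr")),
                 "constant")
  expect_true(all(gdz$weights[4, ] == 0) && all(gdz$weights[, 4] == 0))
})

test_that("windowed weights agree with full-window weights on stationary
           series", {
  set.seed(18)
  z <- rnorm(131)
  x <- z[-131] + rnorm(130, sd = 0.6)
  y <- z[-1] + rnorm(130, sd = 0.6)
  ts2 <- structure(list(series = rbind(x, y), cluster_ids = 1:2),
                   class = "cluster_ts")
  w_full <- build_graph(ts2, edge_method_spec("corr"))$weights[1, 2]
  w_win <- build_graph(ts2, edge_method_spec("corr", window_length = 50,
                                             window_overlap_fraction = 0.2)
  )$weights[1, 2]
  expect_lt(abs(w_full - w_win), 0.15)
})

test_that("adding independent noise to one series never increases the
           expected correlation weight", {
  set.seed(19)
  means <- vapply(c(0, 0.5, 1.5), function(noise) {
    mean(replicate(200, {
      z <- rnorm(80)
      x <- z + rnorm(80, sd = 0.3)
      y <- z + rnorm(80, sd = 0.3) + rnorm(80, sd = noise)
      edge_corr(x, y)
    }))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("the sixteen edge presets cover all families, directions and
           windows", {
  pr <- edge_presets()
  expect_length(pr, 16L)
  fams <- vapply(pr, `[[`, character(1), "family")
  dirs <- vapply(pr, `[[`, logical(1), "directed")
  wins <- vapply(pr, `[[`, integer(1), "window_length")
  expect_setequal(unique(fams), c("corr", "H2", "MIT", "TE"))
  expect_identical(sum(dirs), 8L)
  expect_identical(sort(unique(wins)), c(50L, 130L))
  expect_true(all(c("BcorrU1", "BH2D2", "BMITU2", "BTED1") %in% names(pr)))
})
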