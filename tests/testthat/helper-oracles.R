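# Independent oracles used to check the package's algorithms.

# shortest inverse-weight path distances by exhaustive enumeration of all
# simple paths (feasible up to ~8 nodes)
brute_force_dists <- function(W, directed = FALSE) {
  n <- nrow(W)
  cost <- ifelse(W > 0, 1 / W, Inf)
  if (!directed) cost <- pmin(cost, t(cost))
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  dfs <- function(v, target, visited, acc) {
    if (v == target) {
      D[visited[1L], target] <<- min(D[visited[1L], target], acc)
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (!(u %in% visited) && is.finite(cost[v, u])) {
        dfs(u, target, c(visited, u), acc + cost[v, u])
      }
    }
  }
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s != t) dfs(s, t, s, 0)
    }
  }
  D
}

# all set partitions of 1..n as membership vectors (restricted growth)
set_partitions <- function(n) {
  out <- list()
  rec <- function(s, m) {
    if (length(s) == n) {
      out[[length(out) + 1L]] <<- s
      return(invisible())
    }
    for (v in seq_len(m + 1L)) rec(c(s, v), max(m, v))
  }
  rec(1L, 1L)
  out
}

# univariate Student t log density with location/scale, textbook form
student_t_logpdf <- function(x, df, mu, scale) {
  z <- (x - mu) / scale
  lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi) - log(scale) -
    (df + 1) / 2 * log1p(z^2 / df)
}

# random symmetric weighted adjacency with zero diagonal
random_weight_matrix <- function(n, density = 0.6, directed = FALSE) {
  W <- matrix(0, n, n)
  if (directed) {
    off <- which(row(W) != col(W))
    W[off] <- stats::runif(length(off)) * (stats::runif(length(off)) < density)
  } else {
    u <- stats::runif(n * (n - 1) / 2)
    u <- u * (stats::runif(length(u)) < density)
    W[upper.tri(W)] <- u
    W <- W + t(W)
  }
  W
}
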