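# Weighted graph metrics, thresholding, rich-club extraction, and the
# moment-based feature vector fed to the statistical model.

as_igraph <- function(g, invert_weights = FALSE) {
  W <- g$weights
  if (invert_weights) {
    W <- ifelse(W > 0, 1 / W, 0)
  }
  igraph::graph_from_adjacency_matrix(
    W, mode = if (g$directed) "directed" else "undirected",
    weighted = TRUE, diag = FALSE)
}

#' Threshold a graph's edge weights
#'
#' Weights strictly below `wmin` are set to zero; higher weights are left
#' unchanged. Idempotent and monotone in `wmin`.
#'
#' @param g a `connectivity_graph`.
#' @param wmin threshold (>= 0).
#' @return thresholded `connectivity_graph`.
#' @export
threshold_graph <- function(g, wmin) {
  stopifnot(inherits(g, "connectivity_graph"), wmin >= 0)
  W <- g$weights
  W[W < wmin] <- 0
  connectivity_graph(W, g$directed, g$node_ids, g$method)
}

#' Is the graph connected?
#'
#' Edges with positive weight are treated as present and direction is
#' ignored (weak connectivity).
#'
#' @param g a `connectivity_graph`.
#' @return logical.
#' @export
is_connected <- function(g) {
  A <- (g$weights > 0) * 1
  ig <- igraph::graph_from_adjacency_matrix(pmax(A, t(A)),
                                            mode = "undirected", diag = FALSE)
  igraph::is_connected(ig)
}

#' Weighted and normalized degree per node
#'
#' Weighted degree is the sum of incident edge weights (directed graphs:
#' the mean of in- and out-sums, so magnitudes match undirected graphs);
#' normalized degree divides by (number of nonzero incident edges) x (graph
#' maximum weight) and lies in [0, 1]. Isolated nodes get normalized degree
#' 0.
#'
#' @param g a `connectivity_graph`.
#' @return list with numeric vectors `deg_w` and `deg_n`.
#' @export
degree_features <- function(g) {
  W <- g$weights
  if (g$directed) {
    deg_w <- (rowSums(W) + colSums(W)) / 2
    deg_cnt <- (rowSums(W > 0) + colSums(W > 0)) / 2
  } else {
    deg_w <- rowSums(W)
    deg_cnt <- rowSums(W > 0)
  }
  w_max <- max(W)
  deg_n <- ifelse(deg_cnt > 0 & w_max > 0, deg_w / (deg_cnt * w_max), 0)
  list(deg_w = deg_w, deg_n = deg_n)
}

#' Rich-club subgraph
#'
#' Induced subgraph on the ceiling(fraction * n) nodes with highest
#' weighted degree; ties broken by node position (ascending).
#'
#' @param g a `connectivity_graph`.
#' @param fraction fraction of nodes to keep, in (0, 1].
#' @return a `connectivity_graph` on the selected nodes.
#' @export
rich_club_subgraph <- function(g, fraction = 0.1) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(g$weights)
  m <- ceiling(fraction * n)
  if (m < 2L) stop("rich club would have fewer than 2 nodes")
  deg <- degree_features(g)$deg_w
  keep <- sort(order(-deg, seq_len(n))[seq_len(m)])
  connectivity_graph(g$weights[keep, keep, drop = FALSE], g$directed,
                     g$node_ids[keep], g$method)
}

#' Inverse-weight shortest-path distances
#'
#' Pairwise distances minimizing the sum of inverse edge weights (strong
#' edges are short), by Dijkstra's algorithm. Entry (u, v) is the distance
#' from u to v; unreachable pairs are Inf.
#'
#' @param g a `connectivity_graph`.
#' @return numeric distance matrix.
#' @export
graph_shortest_paths <- function(g) {
  ig <- as_igraph(g, invert_weights = TRUE)
  igraph::distances(ig, mode = "out",
                    weights = igraph::E(ig)$weight,
                    algorithm = "dijkstra")
}

# off-diagonal shortest-path values: unordered pairs once for undirected
# graphs, ordered pairs for directed
shortest_path_values <- function(g, dist = graph_shortest_paths(g)) {
  if (g$directed) {
    dist[row(dist) != col(dist)]
  } else {
    dist[upper.tri(dist)]
  }
}

#' Closeness centrality
#'
#' C(v) = (n - 1) / sum_u dist(u, v) on inverse-weight shortest paths.
#' Requires a connected graph.
#'
#' @param g a `connectivity_graph`.
#' @return numeric vector per node.
#' @export
closeness_centrality <- function(g) {
  if (!is_connected(g)) stop("closeness centrality needs a connected graph")
  d <- graph_shortest_paths(g)
  n <- nrow(d)
  (n - 1) / colSums(d)
}

#' Zhang-Horvath weighted clustering coefficient
#'
#' cc(v) = sum_{i,j} w^_vi w^_ij w^_jv / ((sum_i w^_vi)^2 - sum_i w^_vi^2),
#' with weights normalized by the graph maximum (w^ = w / w_max). Nodes
#' with fewer than two incident edges get 0.
#'
#' @param g a `connectivity_graph`.
#' @return numeric vector per node.
#' @export
clustering_coefficient <- function(g) {
  W <- g$weights
  w_max <- max(W)
  if (w_max <= 0) return(numeric(nrow(W)))
  Wh <- W / w_max
  num <- diag(Wh %*% Wh %*% Wh)
  s1 <- rowSums(Wh)
  s2 <- rowSums(Wh^2)
  den <- s1^2 - s2
  ifelse(den > .Machine$double.eps, num / den, 0)
}

#' Modularity of a partition (Newman's weighted Q)
#'
#' Q = 1/(2m) sum_ij (w_ij - k_i k_j / (2m)) delta(c_i, c_j), with k the
#' weighted degree and m the total edge weight.
#'
#' @param g an undirected `connectivity_graph`.
#' @param membership integer community id per node.
#' @return Q.
#' @export
modularity_value <- function(g, membership) {
  W <- g$weights
  two_m <- sum(W)
  if (two_m <= 0) return(0)
  k <- rowSums(W)
  same <- outer(membership, membership, `==`)
  sum((W - outer(k, k) / two_m) * same) / two_m
}

# one Louvain local-moving phase: nodes visited in ascending id, each moved
# to the community with the largest modularity gain (ties: lowest community
# id), repeated until no move improves Q; `comm` may start from a partition
louvain_level <- function(W, comm = seq_len(nrow(W))) {
  n <- nrow(W)
  two_m <- sum(W)
  k <- rowSums(W)
  sigma_tot <- vapply(seq_len(max(comm)), function(c) sum(k[comm == c]),
                      numeric(1))
  improved_any <- TRUE
  while (improved_any) {
    improved_any <- FALSE
    for (v in seq_len(n)) {
      cv <- comm[v]
      # weight from v to each community (self-loops excluded)
      wv <- W[v, ]
      wv[v] <- 0
      cand <- sort(unique(comm[wv > 0]))
      k_in <- vapply(cand, function(c) sum(wv[comm == c]), numeric(1))
      base_gain <- -(sum(wv[comm == cv]) -
                       k[v] * (sigma_tot[cv] - k[v]) / two_m)
      gains <- base_gain + k_in - k[v] * sigma_tot[cand] / two_m
      gains[cand == cv] <- 0
      # leaving for a fresh singleton community is also a candidate move
      if (sum(comm == cv) > 1L) {
        cand <- c(cand, length(sigma_tot) + 1L)
        gains <- c(gains, base_gain)
      }
      if (length(gains) > 0L && max(gains) > 1e-12) {
        c_new <- cand[which.max(gains)]
        sigma_tot[cv] <- sigma_tot[cv] - k[v]
        if (c_new > length(sigma_tot)) sigma_tot[c_new] <- 0
        sigma_tot[c_new] <- sigma_tot[c_new] + k[v]
        comm[v] <- c_new
        improved_any <- TRUE
      }
    }
  }
  comm
}

# Kernighan-Lin style refinement: one round moves every node once, always
# taking the currently best single move (possibly worsening), then keeps
# the best prefix of the move sequence; rounds repeat until no net gain
kl_refine <- function(W, comm) {
  n <- nrow(W)
  two_m <- sum(W)
  k <- rowSums(W)
  move_gain <- function(comm, sigma_tot, v, c_to) {
    cv <- comm[v]
    if (c_to == cv) return(0)
    wv <- W[v, ]; wv[v] <- 0
    base <- -(sum(wv[comm == cv]) - k[v] * (sigma_tot[cv] - k[v]) / two_m)
    s_to <- if (c_to > length(sigma_tot)) 0 else sigma_tot[c_to]
    2 / two_m * (base + sum(wv[comm == c_to]) - k[v] * s_to / two_m)
  }
  repeat {
    work <- comm
    sigma_tot <- vapply(seq_len(max(work) + n), function(c) {
      sum(k[work == c])
    }, numeric(1))
    movable <- rep(TRUE, n)
    cum <- 0; best_cum <- 0; best_step <- 0L
    seq_moves <- list()
    for (step in seq_len(n)) {
      best <- NULL
      for (v in which(movable)) {
        cv <- work[v]
        wv <- W[v, ]; wv[v] <- 0
        cands <- sort(unique(c(work[wv > 0], max(work) + 1L)))
        cands <- cands[cands != cv]
        for (c_to in cands) {
          gain <- move_gain(work, sigma_tot, v, c_to)
          if (is.null(best) || gain > best$gain + 1e-15) {
            best <- list(v = v, to = c_to, gain = gain)
          }
        }
      }
      if (is.null(best)) break
      cv <- work[best$v]
      sigma_tot[cv] <- sigma_tot[cv] - k[best$v]
      sigma_tot[best$to] <- sigma_tot[best$to] + k[best$v]
      work[best$v] <- best$to
      movable[best$v] <- FALSE
      cum <- cum + best$gain
      seq_moves[[step]] <- c(best$v, best$to)
      if (cum > best_cum + 1e-12) {
        best_cum <- cum
        best_step <- step
      }
    }
    if (best_step == 0L) return(comm)
    for (s in seq_len(best_step)) {
      comm[seq_moves[[s]][1L]] <- seq_moves[[s]][2L]
    }
  }
}

# merge whole communities while any pairwise merge increases Q
merge_communities <- function(W, comm) {
  two_m <- sum(W)
  k <- rowSums(W)
  repeat {
    ids <- sort(unique(comm))
    if (length(ids) < 2L) return(comm)
    best_gain <- 0; best_pair <- NULL
    for (a_i in seq_along(ids)) {
      for (b_i in seq_len(a_i - 1L)) {
        a <- ids[a_i]; b <- ids[b_i]
        ia <- comm == a; ib <- comm == b
        gain <- 2 * (sum(W[ia, ib]) -
                       sum(k[ia]) * sum(k[ib]) / two_m) / two_m
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_pair <- c(a, b)
        }
      }
    }
    if (is.null(best_pair)) return(comm)
    comm[comm == best_pair[1L]] <- best_pair[2L]
  }
}

#' Community detection by greedy multilevel modularity maximization
#'
#' A deterministic Louvain scheme: local moving (ascending node order,
#' best-improvement moves, ties to the lowest community id) followed by
#' community aggregation, repeated until Q stops improving, then a
#' refinement pass of local moving and greedy community merges on the
#' original graph. Undirected graphs only.
#'
#' @param g an undirected, connected `connectivity_graph`.
#' @return list with `Q` (modularity of the returned partition) and
#'   `membership` (integer community per node, ids contiguous from 1).
#' @export
graph_modularity <- function(g) {
  if (g$directed) {
    stop("modularity is only supported for undirected graphs")
  }
  W0 <- g$weights
  n <- nrow(W0)
  membership <- seq_len(n)
  if (sum(W0) <= 0) {
    return(list(Q = 0, membership = membership))
  }
  if (n <= 8L) {
    # small enough to enumerate every partition: return the exact optimum
    best_q <- -Inf
    best_m <- membership
    rec <- function(m, mx) {
      if (length(m) == n) {
        q <- modularity_value(g, m)
        if (q > best_q + 1e-15) {
          best_q <<- q
          best_m <<- m
        }
        return(invisible())
      }
      for (v in seq_len(mx + 1L)) rec(c(m, v), max(mx, v))
    }
    rec(1L, 1L)
    return(list(Q = best_q, membership = best_m))
  }
  W <- W0
  repeat {
    comm <- louvain_level(W)
    comm <- match(comm, sort(unique(comm)))
    membership <- comm[membership]
    if (max(comm) == nrow(W)) break  # no merge happened
    # aggregate communities into super-nodes (self-loops keep inner weight)
    agg <- matrix(0, max(comm), max(comm))
    for (i in seq_len(nrow(W))) {
      for (j in seq_len(nrow(W))) {
        agg[comm[i], comm[j]] <- agg[comm[i], comm[j]] + W[i, j]
      }
    }
    W <- agg
  }
  # refinement on the original graph from the multilevel solution
  repeat {
    q_before <- modularity_value(g, membership)
    membership <- louvain_level(W0, membership)
    membership <- merge_communities(W0, membership)
    membership <- kl_refine(W0, membership)
    if (modularity_value(g, membership) <= q_before + 1e-12) break
  }
  membership <- match(membership, sort(unique(membership)))
  list(Q = modularity_value(g, membership), membership = membership)
}

#' Mean graph weight
#'
#' Mean over all off-diagonal entries of the weight matrix, zeros included;
#' this is the quantity whose between-condition difference the threshold
#' scans track.
#'
#' @param g a `connectivity_graph`.
#' @return numeric scalar.
#' @export
mean_edge_weight <- function(g) {
  W <- g$weights
  mean(W[row(W) != col(W)])
}

#' Moment-based graph feature vector
#'
#' For each of five property distributions — nonzero edge weights,
#' normalized degree, inverse-weight shortest paths, closeness centrality,
#' Zhang-Horvath clustering coefficient — the first four moments (mean,
#' standard deviation, skewness, excess kurtosis; 0 for degenerate
#' distributions), plus the node count scaled by 1/100, plus the Louvain
#' modularity Q for undirected graphs: d = 22 features (21 for directed
#' graphs). Requires a connected graph.
#'
#' @param g a `connectivity_graph`.
#' @return named numeric vector.
#' @export
feature_vector <- function(g) {
  if (!is_connected(g)) {
    stop("feature vector requires a connected graph")
  }
  W <- g$weights
  wvals <- if (g$directed) W[row(W) != col(W) & W > 0] else W[upper.tri(W) & W > 0]
  dists <- shortest_path_values(g)
  props <- list(weight = wvals,
                deg_n = degree_features(g)$deg_n,
                spath = dists[is.finite(dists)],
                closeness = closeness_centrality(g),
                clustcoef = clustering_coefficient(g))
  out <- unlist(lapply(names(props), function(nm) {
    m <- four_moments(props[[nm]])
    names(m) <- paste(nm, names(m), sep = "_")
    m
  }))
  out <- c(out, n_nodes_scaled = nrow(W) / 100)
  if (!g$directed) {
    out <- c(out, modularity = graph_modularity(g)$Q)
  }
  out
}
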