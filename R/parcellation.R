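# Parcellation: turn a subject's voxel time series into clusters (graph
# nodes) by atlas labels, spatially constrained Ward clustering, or region
# growing and selection (RGS) gated by a broken-stick homogeneity criterion.

#' Voxel time-series matrix of a subject
#'
#' @param subject a `subject_volume`.
#' @return list with `series` (masked voxels x time matrix, mask order) and
#'   `coords` (voxel coordinates per row).
#' @export
subject_series <- function(subject) {
  stopifnot(inherits(subject, "subject_volume"))
  dims <- dim(subject$mask)
  tt <- dim(subject$data)[4L]
  coords <- mask_coords(subject$mask)
  flat <- matrix(subject$data, prod(dims), tt)
  list(series = flat[voxel_index(coords, dims), , drop = FALSE],
       coords = coords)
}

new_parcellation <- function(assignment, clusters, method_tag, coords, dims,
                             overlapping = FALSE) {
  structure(list(assignment = assignment, clusters = clusters,
                 method_tag = method_tag, coords = coords, dims = dims,
                 overlapping = overlapping),
            class = "parcellation")
}

#' Number of clusters in a parcellation
#' @param parc a `parcellation`.
#' @export
n_clusters <- function(parc) length(parc$clusters)

# voxel row closest to the cluster centroid, ties by lexicographic coordinate
cluster_center <- function(voxels, coords) {
  sub <- coords[voxels, , drop = FALSE]
  ctr <- colMeans(sub)
  d2 <- rowSums(sweep(sub, 2L, ctr)^2)
  ord <- order(d2, sub[, 1L], sub[, 2L], sub[, 3L])
  voxels[ord[1L]]
}

#' Atlas-based parcellation
#'
#' One cluster per nonzero label intersected with the subject mask; empty
#' intersections are dropped and the surviving clusters re-indexed
#' contiguously. The same label volume applied to every subject yields the
#' same node count across a cohort.
#'
#' @param subject a `subject_volume`.
#' @param labels a `label_volume` sharing the subject's grid shape.
#' @return a `parcellation` with method tag "atlas".
#' @export
atlas_parcellate <- function(subject, labels) {
  stopifnot(inherits(subject, "subject_volume"),
            inherits(labels, "label_volume"))
  if (!identical(dim(subject$mask), dim(labels$labels))) {
    stop("label volume and subject grid shapes differ")
  }
  ss <- subject_series(subject)
  coords <- ss$coords
  lab_at <- labels$labels[coords]
  clusters <- list()
  assignment <- integer(nrow(coords))
  next_id <- 0L
  for (l in seq_len(labels$n_regions)) {
    rows <- which(lab_at == l)
    if (length(rows) == 0L) next
    next_id <- next_id + 1L
    clusters[[next_id]] <- list(id = next_id, voxels = rows,
                                center = cluster_center(rows, coords))
    assignment[rows] <- next_id
  }
  new_parcellation(assignment, clusters, "atlas", coords, dim(subject$mask))
}

#' Spatially constrained Ward parcellation
#'
#' Agglomerative merging under the Ward (minimum increase of intra-cluster
#' variance) criterion, restricted to pairs of spatially adjacent clusters
#' (6-connectivity), until `k` clusters remain; clusters with fewer than `p`
#' voxels are then discarded and survivors re-indexed.
#'
#' @param subject a `subject_volume`.
#' @param k target number of clusters before size filtering.
#' @param p minimum cluster size in voxels.
#' @param method_tag tag stored in the result.
#' @return a `parcellation`.
#' @export
ward_parcellate <- function(subject, k, p = 1L,
                            method_tag = sprintf("ward_k%d_p%d", k, p)) {
  stopifnot(k >= 1L, p >= 1L)
  ss <- subject_series(subject)
  x <- ss$series
  coords <- ss$coords
  n <- nrow(x)
  if (k > n) stop("k exceeds the masked voxel count")

  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  centroids <- x
  active <- rep(TRUE, n)

  # Ward merge cost between clusters a, b: |a||b|/(|a|+|b|) * ||mu_a-mu_b||^2,
  # stored only for spatially adjacent pairs (others Inf).
  D <- matrix(Inf, n, n)
  edges <- voxel_adjacency_edges(coords, dims = dim(subject$mask))
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    d <- 0.5 * sum((x[i, ] - x[j, ])^2)
    D[i, j] <- d; D[j, i] <- d
  }

  n_active <- n
  while (n_active > k) {
    m <- arrayInd(which.min(D), dim(D))
    i <- min(m); j <- max(m)
    if (!is.finite(D[i, j])) {
      stop("no adjacent cluster pair left to merge; mask is disconnected")
    }
    ni <- sizes[i]; nj <- sizes[j]
    centroids[i, ] <- (ni * centroids[i, ] + nj * centroids[j, ]) / (ni + nj)
    sizes[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    neigh <- unique(c(which(is.finite(D[i, ])), which(is.finite(D[j, ]))))
    neigh <- setdiff(neigh[active[neigh]], c(i, j))
    D[j, ] <- Inf; D[, j] <- Inf
    D[i, ] <- Inf; D[, i] <- Inf
    for (kk in neigh) {
      d <- sizes[i] * sizes[kk] / (sizes[i] + sizes[kk]) *
        sum((centroids[i, ] - centroids[kk, ])^2)
      D[i, kk] <- d; D[kk, i] <- d
    }
    n_active <- n_active - 1L
  }

  keep <- which(active)[order(vapply(members[active], min, integer(1)))]
  clusters <- list()
  assignment <- integer(n)
  next_id <- 0L
  for (ci in keep) {
    if (sizes[ci] < p) next
    next_id <- next_id + 1L
    rows <- sort(members[[ci]])
    clusters[[next_id]] <- list(id = next_id, voxels = rows,
                                center = cluster_center(rows, coords))
    assignment[rows] <- next_id
  }
  if (next_id == 0L) stop("all clusters discarded by the size filter p")
  new_parcellation(assignment, clusters, method_tag, coords,
                   dim(subject$mask))
}

#' Broken-stick heterogeneity of a set of time series
#'
#' Eigenvalues of the N x N covariance of the series, scaled to sum to N,
#' are compared with the broken-stick baseline b_n = sum_{i=n..N} 1/i. The
#' count n0 of leading eigenvalues exceeding the baseline estimates the
#' number of independent signals; the interpolated heterogeneity h locates
#' the crossing between n0 and n0+1. A cluster carrying a single signal has
#' n0 = 1.
#'
#' @param ts numeric matrix, one series per row (N >= 2 rows).
#' @return list with `n0`, `h_interp`, `eigenvalues` (scaled, descending)
#'   and `baseline`.
#' @export
heterogeneity <- function(ts) {
  stopifnot(is.matrix(ts), nrow(ts) >= 2L)
  n <- nrow(ts)
  tt <- ncol(ts)
  vars <- apply(ts, 1L, stats::var)
  if (any(vars <= 0)) stop("constant (zero-variance) series in cluster")
  xc <- ts - rowMeans(ts)
  # eigenvalues of the N x N covariance via whichever Gram matrix is smaller
  if (n <= tt) {
    ev <- eigen(tcrossprod(xc) / (tt - 1), symmetric = TRUE,
                only.values = TRUE)$values
  } else {
    ev <- c(eigen(crossprod(xc) / (tt - 1), symmetric = TRUE,
                  only.values = TRUE)$values, numeric(n - tt))
  }
  ev <- pmax(ev, 0)
  ev <- sort(ev, decreasing = TRUE)[seq_len(n)]
  ev <- ev * n / sum(ev)
  baseline <- rev(cumsum(1 / rev(seq_len(n))))
  above <- ev > baseline
  n0 <- if (!above[1L]) 1L else {
    r <- rle(above)
    as.integer(r$lengths[1L])
  }
  n0 <- min(n0, n - 1L)
  h <- n0 + (ev[n0] - baseline[n0]) /
    ((ev[n0] - ev[n0 + 1L]) - (baseline[n0] - baseline[n0 + 1L]))
  list(n0 = as.integer(n0), h_interp = h, eigenvalues = ev,
       baseline = baseline)
}

# homogeneity gate used during RGS growth: a single dominant signal
is_homogeneous <- function(ts) heterogeneity(ts)$n0 == 1L

#' Region growing: candidate regions from every masked voxel seed
#'
#' Every masked voxel serves as the center of a candidate region. At each
#' step, among the 6-neighbours of the region whose Pearson correlation with
#' the current region-mean signal exceeds `T`, the highest-correlation voxel
#' is added, provided the grown region stays functionally homogeneous
#' (broken-stick n0 = 1). Growth stops when no neighbour qualifies.
#' Zero-variance voxels are skipped with a warning.
#'
#' @param subject a `subject_volume`.
#' @param T correlation threshold in (0, 1).
#' @return list of candidate regions, each `list(center, voxels)` (voxel row
#'   numbers in mask order), plus attribute `coords`.
#' @export
rgs_grow <- function(subject, T = 0.75) {
  stopifnot(T > 0, T < 1)
  ss <- subject_series(subject)
  x <- ss$series
  coords <- ss$coords
  dims <- dim(subject$mask)
  n <- nrow(x)
  vars <- apply(x, 1L, stats::var)
  degenerate <- vars <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance voxel(s) skipped as seeds")
  }
  idx_of <- integer(prod(dims))
  idx_of[voxel_index(coords, dims)] <- seq_len(n)

  neighbor_rows <- lapply(seq_len(n), function(i) {
    nb <- voxel_neighbors(coords[i, ], dims)
    r <- idx_of[voxel_index(nb, dims)]
    r[r > 0L & !degenerate[r]]
  })

  regions <- vector("list", 0L)
  for (seed in which(!degenerate)) {
    voxels <- seed
    region_sum <- x[seed, ]
    repeat {
      cand <- setdiff(unique(unlist(neighbor_rows[voxels])), voxels)
      if (length(cand) == 0L) break
      rmean <- region_sum / length(voxels)
      cors <- as.numeric(stats::cor(rmean, t(x[cand, , drop = FALSE])))
      ok <- which(cors > T)
      if (length(ok) == 0L) break
      ord <- ok[order(-cors[ok], coords[cand[ok], 1L], coords[cand[ok], 2L],
                      coords[cand[ok], 3L])]
      added <- FALSE
      for (o in ord) {
        v <- cand[o]
        if (is_homogeneous(x[c(voxels, v), , drop = FALSE])) {
          voxels <- c(voxels, v)
          region_sum <- region_sum + x[v, ]
          added <- TRUE
          break
        }
      }
      if (!added) break
    }
    regions[[length(regions) + 1L]] <- list(center = seed,
                                            voxels = sort(voxels))
  }
  attr(regions, "coords") <- coords
  attr(regions, "dims") <- dims
  regions
}

#' Region selection: largest-first selection with center suppression
#'
#' Iteratively selects the largest remaining candidate region and deletes
#' all candidates whose centers lie inside it (including itself). Selected
#' clusters may overlap spatially, but no selected cluster's center lies
#' inside another selected cluster. Clusters smaller than `p` voxels are
#' dropped afterwards.
#'
#' @param regions output of [rgs_grow()].
#' @param p minimum cluster size in voxels.
#' @param method_tag tag stored in the result.
#' @return a `parcellation` with `overlapping = TRUE`; voxels shared by
#'   several clusters are assigned (in `assignment`) to the containing
#'   cluster with the smallest id.
#' @export
rgs_select <- function(regions, p = 1L, method_tag = sprintf("RGS_p%d", p)) {
  stopifnot(length(regions) > 0L, p >= 1L)
  coords <- attr(regions, "coords")
  dims <- attr(regions, "dims")
  sizes <- vapply(regions, function(r) length(r$voxels), integer(1))
  centers <- vapply(regions, function(r) r$center, integer(1))
  alive <- rep(TRUE, length(regions))
  selected <- integer(0)
  while (any(alive)) {
    cand <- which(alive)
    pick <- cand[order(-sizes[cand], centers[cand])][1L]
    selected <- c(selected, pick)
    inside <- alive & (centers %in% regions[[pick]]$voxels)
    alive[inside] <- FALSE
    alive[pick] <- FALSE
  }
  selected <- selected[sizes[selected] >= p]
  if (length(selected) == 0L) {
    stop("no region survives the size filter p")
  }
  n_vox <- nrow(coords)
  clusters <- list()
  assignment <- integer(n_vox)
  disrupted <- 0L
  for (i in seq_along(selected)) {
    r <- regions[[selected[i]]]
    clusters[[i]] <- list(id = i, voxels = r$voxels, center = r$center)
    unset <- r$voxels[assignment[r$voxels] == 0L]
    assignment[unset] <- i
    if (!voxels_connected(coords[r$voxels, , drop = FALSE], dims)) {
      disrupted <- disrupted + 1L
    }
  }
  if (disrupted > 0L) {
    message(disrupted, " selected cluster(s) are spatially disconnected")
  }
  new_parcellation(assignment, clusters, method_tag, coords, dims,
                   overlapping = TRUE)
}

#' Mean time series per cluster
#'
#' Row c is the arithmetic mean over the voxels of cluster c at each time
#' point. With overlapping (RGS) clusters a voxel contributes to every
#' cluster that contains it.
#'
#' @param subject a `subject_volume`.
#' @param parc a `parcellation` of the same subject.
#' @return object of class `cluster_ts`: `series` (clusters x time matrix)
#'   and `cluster_ids`.
#' @export
extract_mean_timeseries <- function(subject, parc) {
  stopifnot(inherits(parc, "parcellation"))
  ss <- subject_series(subject)
  if (nrow(ss$coords) != nrow(parc$coords)) {
    stop("subject and parcellation voxel sets differ")
  }
  series <- t(vapply(parc$clusters, function(cl) {
    if (length(cl$voxels) == 0L) stop("empty cluster in parcellation")
    colMeans(ss$series[cl$voxels, , drop = FALSE])
  }, numeric(ncol(ss$series))))
  structure(list(series = series,
                 cluster_ids = vapply(parc$clusters, `[[`, integer(1), "id")),
            class = "cluster_ts")
}

#' Node-level summary of a parcellation
#'
#' Cluster count, mean voxels per cluster and mean per-cluster interpolated
#' heterogeneity (singleton clusters count as perfectly homogeneous, h = 1).
#'
#' @param parc a `parcellation`.
#' @param subject the matching `subject_volume`.
#' @return list with `n_nodes`, `mean_voxels_per_node`, `mean_heterogeneity`.
#' @export
parcellation_summary <- function(parc, subject) {
  ss <- subject_series(subject)
  sizes <- vapply(parc$clusters, function(cl) length(cl$voxels), integer(1))
  hs <- vapply(parc$clusters, function(cl) {
    if (length(cl$voxels) < 2L) return(1)
    heterogeneity(ss$series[cl$voxels, , drop = FALSE])$h_interp
  }, numeric(1))
  list(n_nodes = n_clusters(parc),
       mean_voxels_per_node = mean(sizes),
       mean_heterogeneity = mean(hs))
}

#' Named parcellation presets
#'
#' The survey's clustering presets: four Ward variants (k in {5000, 2000},
#' minimum size p in {10, 25}), two RGS variants (p = 55/50, T = 0.75) and
#' the atlas method. These target full-resolution data; tests and the
#' bundled analyses use synthetic-scale parameters instead.
#'
#' @return data.frame with columns method, family, k, p, T.
#' @export
clustering_presets <- function() {
  data.frame(
    method = c("ward1", "ward2", "ward3", "ward4", "RGS1", "RGS2", "atlas"),
    family = c(rep("ward", 4L), "RGS", "RGS", "atlas"),
    k = c(5000L, 5000L, 2000L, 2000L, NA, NA, NA),
    p = c(10L, 25L, 10L, 25L, 55L, 50L, NA),
    T = c(NA, NA, NA, NA, 0.75, 0.75, NA))
}
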