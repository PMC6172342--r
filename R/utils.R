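# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Face (6-connectivity) neighbours of voxel coordinates within a grid.
#'
#' @param coord integer vector (x, y, z), 1-based.
#' @param dims grid extents.
#' @return matrix of neighbour coordinates (possibly 0 rows).
#' @keywords internal
#' @noRd
voxel_neighbors <- function(coord, dims) {
  offs <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L),
                c(0L, -1L, 0L), c(0L, 1L, 0L),
                c(0L, 0L, -1L), c(0L, 0L, 1L))
  nb <- sweep(offs, 2L, as.integer(coord), `+`)
  keep <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
    nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
    nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
  nb[keep, , drop = FALSE]
}

#' Linear index of voxel coordinates in column-major (x fastest) order.
#' @keywords internal
#' @noRd
voxel_index <- function(coords, dims) {
  coords <- matrix(as.integer(coords), ncol = 3L)
  coords[, 1L] + (coords[, 2L] - 1L) * dims[1L] +
    (coords[, 3L] - 1L) * dims[1L] * dims[2L]
}

#' Adjacency (6-connectivity) among a set of voxels, as an edge list over
#' voxel row numbers.
#' @keywords internal
#' @noRd
voxel_adjacency_edges <- function(coords, dims) {
  n <- nrow(coords)
  idx <- voxel_index(coords, dims)
  row_of <- integer(prod(dims))
  row_of[idx] <- seq_len(n)
  from <- integer(0); to <- integer(0)
  # only +x, +y, +z offsets: each unordered pair appears once
  for (ax in 1:3) {
    nb <- coords
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= dims[ax]
    nb_idx <- voxel_index(nb[ok, , drop = FALSE], dims)
    nb_row <- row_of[nb_idx]
    present <- nb_row > 0L
    from <- c(from, which(ok)[present])
    to <- c(to, nb_row[present])
  }
  cbind(from, to)
}

#' Is a set of voxels a single 6-connected component?
#' @keywords internal
#' @noRd
voxels_connected <- function(coords, dims) {
  n <- nrow(coords)
  if (n <= 1L) return(TRUE)
  edges <- voxel_adjacency_edges(coords, dims)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::count_components(g) == 1L
}

#' Standardized central moments 2-4 plus the mean.
#'
#' Degenerate (zero-variance) samples get sd = skew = kurtosis = 0 by
#' convention so downstream feature vectors stay finite.
#' @keywords internal
#' @noRd
four_moments <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= .Machine$double.eps * max(1, m^2)) {
    return(c(mean = m, sd = 0, skewness = 0, kurtosis = 0))
  }
  c(mean = m,
    sd = sqrt(v),
    skewness = e1071::skewness(x, type = 1),
    kurtosis = e1071::kurtosis(x, type = 1))
}
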