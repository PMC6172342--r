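# Fixtures built in code: hand-made subject volumes and small cohorts.

# subject volume from an explicit voxels x time series matrix laid out on a
# given grid (x-fastest order over masked voxels)
make_subject_from_series <- function(series, dims, mask = NULL,
                                     condition = "C", tr = 3) {
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  coords <- which(mask, arr.ind = TRUE)[, 1:3, drop = FALSE]
  stopifnot(nrow(series) == nrow(coords))
  tt <- ncol(series)
  data <- array(0, dim = c(dims, tt))
  n_vox <- nrow(coords)
  data[cbind(coords[rep(seq_len(n_vox), tt), , drop = FALSE],
             rep(seq_len(tt), each = n_vox))] <- as.numeric(series)
  structure(list(data = data, mask = mask, tr_seconds = tr,
                 subject_id = "fixture", condition = condition,
                 ground_truth = NULL),
            class = "subject_volume")
}

# two spatially contiguous blocks carrying independent signals; the grid
# splits along x into left/right halves
make_two_block_subject <- function(dims = c(4L, 4L, 2L), tt = 130L,
                                   noise_sd = 0.01, seed = 1L) {
  set.seed(seed)
  s1 <- as.numeric(scale(sin(seq(0, 17, length.out = tt)) + rnorm(tt, sd = 0.2)))
  s2 <- as.numeric(scale(cos(seq(0, 29, length.out = tt)) + rnorm(tt, sd = 0.2)))
  coords <- which(array(TRUE, dim = dims), arr.ind = TRUE)
  left <- coords[, 1L] <= dims[1L] / 2
  n <- nrow(coords)
  series <- matrix(0, n, tt)
  series[left, ] <- matrix(rep(s1, sum(left)), ncol = tt, byrow = TRUE)
  series[!left, ] <- matrix(rep(s2, sum(!left)), ncol = tt, byrow = TRUE)
  series <- series + matrix(rnorm(n * tt, sd = noise_sd), n, tt)
  subj <- make_subject_from_series(series, dims)
  subj$ground_truth <- ifelse(left, 1L, 2L)
  subj
}

# small separable three-condition cohort shared by evaluation-level tests
make_separable_config <- function(seed = 77L) {
  synth_config(grid_shape = c(8L, 8L, 4L),
               coupling = list(C = uniform_coupling(4, 0.20),
                               MCI = uniform_coupling(4, 0.50),
                               AD = uniform_coupling(4, 0.80)),
               noise_sd = 0.5,
               cohort_sizes = c(C = 12L, MCI = 10L, AD = 10L),
               seed = seed)
}

# null cohort: identical coupling for every condition
make_null_config <- function(seed = 101L, sizes = c(C = 26L, MCI = 16L, AD = 14L)) {
  synth_config(coupling = list(C = uniform_coupling(4, 0.45),
                               MCI = uniform_coupling(4, 0.45),
                               AD = uniform_coupling(4, 0.45)),
               cohort_sizes = sizes, seed = seed)
}

# cohort whose C/AD coupling matrices cross: C moderate everywhere, AD weak
# except two strong pairs, so the mean-weight ordering flips with w_min
make_crossing_config <- function(seed = 55L) {
  ad <- uniform_coupling(8, 0.02)
  ad[1, 2] <- ad[2, 1] <- 0.95
  ad[3, 4] <- ad[4, 3] <- 0.95
  synth_config(grid_shape = c(8L, 8L, 4L), n_latent_clusters = 8L,
               coupling = list(C = uniform_coupling(8, 0.18),
                               MCI = uniform_coupling(8, 0.10),
                               AD = ad),
               noise_sd = 0.4,
               cohort_sizes = c(C = 14L, MCI = 4L, AD = 14L),
               seed = seed)
}

# tiny complete undirected graph from an upper-triangle weight vector
graph_from_upper <- function(w, n) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- w
  connectivity_graph(W + t(W), directed = FALSE)
}
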