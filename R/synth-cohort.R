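# Synthetic cohort generator: planted spatially contiguous clusters sharing
# latent AR(1) signals, mixed across clusters by a condition-specific
# coupling matrix, plus i.i.d. voxel noise. The generator provides the
# ground truth that the parcellation, connectivity and model stages are
# validated against.

CONDITIONS <- c("C", "MCI", "AD")

#' Build a condition-coupling matrix with constant off-diagonal coupling
#'
#' Convenience constructor for the symmetric unit-diagonal coupling matrices
#' used by [synth_config()]: all inter-cluster couplings equal `rho`.
#'
#' @param n_clusters number of latent clusters.
#' @param rho common inter-cluster coupling in [0, 1).
#' @return symmetric `n_clusters` x `n_clusters` matrix with unit diagonal.
#' @export
uniform_coupling <- function(n_clusters, rho) {
  stopifnot(n_clusters >= 1, rho >= 0, rho < 1)
  m <- matrix(rho, n_clusters, n_clusters)
  diag(m) <- 1
  m
}

#' Configuration for the synthetic rfMRI-like cohort
#'
#' Defines the study conditions the simulated data emulate: a three-condition
#' cohort (26 control, 16 mild cognitive impairment, 14 Alzheimer's disease)
#' of subjects whose voxel grids contain spatially contiguous clusters driven
#' by latent AR(1) signals. Conditions differ only through the coupling
#' matrix that correlates the latent cluster signals; by default the
#' inter-cluster coupling weakens with disease severity (0.6 / 0.45 / 0.3),
#' emulating the loss of long-range functional connectivity.
#'
#' @param grid_shape voxel grid extents, 3 positive integers.
#' @param n_timepoints time points per subject (130, i.e. 6.5 min at TR 3 s).
#' @param tr_seconds repetition time in seconds.
#' @param n_latent_clusters number of planted clusters.
#' @param coupling named list (C, MCI, AD) of symmetric coupling matrices in
#'   [0,1] with unit diagonal, one per condition.
#' @param noise_sd standard deviation of i.i.d. voxel noise added on top of
#'   the unit-variance cluster signal.
#' @param temporal_smoothing AR(1) coefficient of the latent signals, in
#'   [0, 1).
#' @param cohort_sizes named integer vector of subjects per condition.
#' @param seed master seed; per-subject seeds are derived from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(12L, 12L, 6L),
                         n_timepoints = 130L,
                         tr_seconds = 3.0,
                         n_latent_clusters = 4L,
                         coupling = list(
                           C   = uniform_coupling(n_latent_clusters, 0.60),
                           MCI = uniform_coupling(n_latent_clusters, 0.45),
                           AD  = uniform_coupling(n_latent_clusters, 0.30)),
                         noise_sd = 0.5,
                         temporal_smoothing = 0.3,
                         cohort_sizes = c(C = 26L, MCI = 16L, AD = 14L),
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            n_timepoints >= 1L, tr_seconds > 0,
            n_latent_clusters >= 1L,
            prod(grid_shape) >= n_latent_clusters,
            noise_sd >= 0,
            temporal_smoothing >= 0, temporal_smoothing < 1,
            all(cohort_sizes >= 1L),
            setequal(names(cohort_sizes), CONDITIONS),
            setequal(names(coupling), CONDITIONS))
  for (cond in CONDITIONS) {
    m <- coupling[[cond]]
    stopifnot(is.matrix(m),
              nrow(m) == n_latent_clusters, ncol(m) == n_latent_clusters,
              isTRUE(all.equal(m, t(m))),
              isTRUE(all.equal(unname(diag(m)), rep(1, nrow(m)))),
              all(m >= 0), all(m <= 1))
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds,
                 n_latent_clusters = as.integer(n_latent_clusters),
                 coupling = coupling,
                 noise_sd = noise_sd,
                 temporal_smoothing = temporal_smoothing,
                 cohort_sizes = cohort_sizes[CONDITIONS],
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Recursive-bisection tiling of a voxel set into contiguous regions
#'
#' Splits the voxel set into `n` regions by repeatedly bisecting the largest
#' region along its longest axis at the coordinate median. On cuboid grids
#' every region is a box, hence 6-connected. Deterministic.
#'
#' @param coords integer matrix of voxel coordinates (rows).
#' @param n number of regions.
#' @return integer vector of region ids (1..n) per row of `coords`.
#' @keywords internal
tile_partition <- function(coords, n) {
  stopifnot(n >= 1L, nrow(coords) >= n)
  parts <- list(seq_len(nrow(coords)))
  while (length(parts) < n) {
    sizes <- vapply(parts, length, integer(1))
    i <- which.max(sizes)
    rows <- parts[[i]]
    sub <- coords[rows, , drop = FALSE]
    spans <- apply(sub, 2L, function(v) diff(range(v)))
    ax <- which.max(spans)
    ord <- order(sub[, ax], sub[, 1L], sub[, 2L], sub[, 3L])
    half <- ceiling(length(rows) / 2)
    parts[[i]] <- rows[ord[seq_len(half)]]
    parts[[length(parts) + 1L]] <- rows[ord[-seq_len(half)]]
  }
  out <- integer(nrow(coords))
  for (k in seq_along(parts)) out[parts[[k]]] <- k
  out
}

#' Coordinates of all voxels in a logical mask, x-fastest order.
#' @keywords internal
#' @noRd
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)[, 1:3, drop = FALSE]
}

#' Simulate one subject's 4D voxel time series
#'
#' Each masked voxel carries the latent AR(1) signal of its planted cluster,
#' mixed across clusters by the Cholesky factor of the condition's coupling
#' matrix, plus i.i.d. Gaussian noise. Bitwise deterministic given
#' (config, condition, seed).
#'
#' @param config a [synth_config()].
#' @param condition one of "C", "MCI", "AD".
#' @param seed integer seed for this subject.
#' @param subject_id optional id string.
#' @return object of class `subject_volume` with fields `data`
#'   (x,y,z,t array), `mask`, `tr_seconds`, `subject_id`, `condition`, and
#'   `ground_truth` (planted cluster id per masked voxel, in mask order).
#' @export
simulate_subject <- function(config, condition, seed = config$seed,
                             subject_id = paste0("S", seed)) {
  stopifnot(inherits(config, "synth_config"))
  if (!condition %in% CONDITIONS) {
    stop("unknown condition label: ", condition)
  }
  dims <- config$grid_shape
  tt <- config$n_timepoints
  b <- config$n_latent_clusters
  mask <- array(TRUE, dim = dims)
  coords <- mask_coords(mask)
  planted <- tile_partition(coords, b)

  set.seed(seed)
  phi <- config$temporal_smoothing
  # stationary unit-variance AR(1) rows
  latents <- t(vapply(seq_len(b), function(i) {
    innov <- stats::rnorm(tt - 1L, sd = sqrt(1 - phi^2))
    as.numeric(stats::filter(c(stats::rnorm(1L), innov), phi,
                             method = "recursive"))
  }, numeric(tt)))
  cc <- config$coupling[[condition]]
  mixed <- if (b == 1L) latents else t(chol(cc)) %*% latents

  n_vox <- nrow(coords)
  noise <- matrix(stats::rnorm(n_vox * tt, sd = config$noise_sd), n_vox, tt)
  vox <- mixed[planted, , drop = FALSE] + noise
  data <- array(0, dim = c(dims, tt))
  data[cbind(coords[rep(seq_len(n_vox), tt), , drop = FALSE],
             rep(seq_len(tt), each = n_vox))] <- as.numeric(vox)

  structure(list(data = data, mask = mask, tr_seconds = config$tr_seconds,
                 subject_id = subject_id, condition = condition,
                 ground_truth = planted),
            class = "subject_volume")
}

#' Simulate a full cohort
#'
#' Returns `cohort_sizes` subjects per condition with distinct seeds derived
#' from the master seed.
#'
#' @param config a [synth_config()].
#' @return list of `subject_volume` objects with attribute `manifest`, a
#'   data.frame (subject_id, condition, seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  subjects <- list()
  manifest <- NULL
  i <- 0L
  for (cond in CONDITIONS) {
    for (k in seq_len(config$cohort_sizes[[cond]])) {
      i <- i + 1L
      seed <- config$seed + i
      id <- sprintf("S%03d_%s", i, cond)
      subjects[[i]] <- simulate_subject(config, cond, seed = seed,
                                        subject_id = id)
      manifest <- rbind(manifest,
                        data.frame(subject_id = id, condition = cond,
                                   seed = seed))
    }
  }
  attr(subjects, "manifest") <- manifest
  subjects
}

#' Synthetic atlas label volume
#'
#' Partitions the mask into `n_regions` contiguous regions by
#' recursive-bisection tiling; a stand-in for a cortical atlas, shared by all
#' subjects of a cohort.
#'
#' @param config a [synth_config()].
#' @param n_regions number of regions (at most the masked voxel count).
#' @return object of class `label_volume`: integer array `labels`
#'   (0 = background) and `n_regions`.
#' @export
make_atlas_labels <- function(config, n_regions) {
  stopifnot(inherits(config, "synth_config"))
  dims <- config$grid_shape
  mask <- array(TRUE, dim = dims)
  coords <- mask_coords(mask)
  if (n_regions > nrow(coords)) {
    stop("n_regions exceeds the masked voxel count")
  }
  ids <- tile_partition(coords, n_regions)
  labels <- array(0L, dim = dims)
  labels[coords] <- ids
  structure(list(labels = labels, n_regions = as.integer(n_regions)),
            class = "label_volume")
}
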