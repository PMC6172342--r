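test_that("atlas parcellation intersects labels with the mask", {
  dims <- c(4L, 4L, 2L)
  set.seed(1)
  series <- matrix(rnorm(prod(dims) * 40), prod(dims), 40)
  labels_arr <- array(0L, dim = dims)
  labels_arr[1:2, , ] <- 1L
  labels_arr[3, , ] <- 2L
  labels_arr[4, , ] <- 3L
  lab <- structure(list(labels = labels_arr, n_regions = 3L),
                   class = "label_volume")

  subj <- make_subject_from_series(series, dims)
  p <- atlas_parcellate(subj, lab)
  expect_identical(n_clusters(p), 3L)
  sizes <- vapply(p$clusters, function(cl) length(cl$voxels), integer(1))
  expect_identical(sizes, c(16L, 8L, 8L))

  # mask excluding label 3 entirely: that cluster is absent, ids contiguous
  mask <- array(TRUE, dim = dims)
  mask[4, , ] <- FALSE
  subj2 <- make_subject_from_series(series[as.logical(mask), ], dims, mask)
  p2 <- atlas_parcellate(subj2, lab)
  expect_identical(n_clusters(p2), 2L)
  expect_identical(vapply(p2$clusters, `[[`, integer(1), "id"), 1:2)

  bad <- structure(list(labels = array(1L, dim = c(2, 2, 2)), n_regions = 1L),
                   class = "label_volume")
  expect_error(atlas_parcellate(subj, bad), "shape")
})

test_that("ward clustering recovers planted blocks and applies the size filter", {
  subj <- make_two_block_subject(noise_sd = 0.01, seed = 4)
  p <- ward_parcellate(subj, k = 2)
  expect_identical(n_clusters(p), 2L)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(p$assignment, subj$ground_truth), 1)

  # every ward cluster is one connected component
  for (cl in p$clusters) {
    expect_true(fcsurvey:::voxels_connected(p$coords[cl$voxels, , drop = FALSE],
                                            dim(subj$mask)))
  }

  p1 <- ward_parcellate(subj, k = 1)
  expect_identical(n_clusters(p1), 1L)
  expect_identical(length(p1$clusters[[1]]$voxels), nrow(p1$coords))

  expect_error(ward_parcellate(subj, k = nrow(p$coords) + 1L), "exceeds")
})

test_that("ward size filter drops small clusters only", {
  # 6x1x1 grid: 4 voxels of one signal, 2 of another -> k=2 gives sizes 4, 2
  tt <- 60
  s1 <- sin(seq(0, 12, length.out = tt))
  s2 <- cos(seq(0, 23, length.out = tt))
  series <- rbind(matrix(rep(s1, 4), 4, byrow = TRUE),
                  matrix(rep(s2, 2), 2, byrow = TRUE))
  set.seed(2)
  series <- series + matrix(rnorm(6 * tt, sd = 1e-3), 6, tt)
  subj <- make_subject_from_series(series, c(6L, 1L, 1L))
  p <- ward_parcellate(subj, k = 2, p = 3)
  expect_identical(n_clusters(p), 1L)
  expect_identical(length(p$clusters[[1]]$voxels), 4L)
  expect_error(ward_parcellate(subj, k = 2, p = 5), "discarded")
})

test_that("broken-stick heterogeneity counts independent signals", {
  tt <- 130
  set.seed(3)
  s <- sin(seq(0, 20, length.out = tt))
  one <- matrix(rep(s, 20), 20, byrow = TRUE) +
    matrix(rnorm(20 * tt, sd = 1e-3), 20)
  h1 <- heterogeneity(one)
  expect_identical(h1$n0, 1L)
  expect_gte(h1$h_interp, 1)

  s2 <- cos(seq(0, 31, length.out = tt))
  two <- rbind(matrix(rep(s, 10), 10, byrow = TRUE),
               matrix(rep(s2, 10), 10, byrow = TRUE)) +
    matrix(rnorm(20 * tt, sd = 1e-3), 20)
  expect_identical(heterogeneity(two)$n0, 2L)

  # the broken-stick baseline sums to N
  expect_equal(sum(heterogeneity(one)$baseline), 20)
  expect_equal(sum(rev(cumsum(1 / rev(1:5)))), 5)

  # n0 invariant under row permutation and positive rescaling
  set.seed(4)
  perm <- sample(20)
  expect_identical(heterogeneity(two[perm, ])$n0, 2L)
  expect_identical(heterogeneity(3.7 * two)$n0, 2L)

  expect_error(heterogeneity(rbind(rep(1, tt), rnorm(tt))), "constant")
})

test_that("region growing respects correlation and homogeneity gates", {
  dims <- c(5L, 5L, 2L)
  tt <- 80
  set.seed(5)
  s <- as.numeric(scale(rnorm(tt)))
  homog <- matrix(rep(s, prod(dims)), prod(dims), byrow = TRUE) +
    matrix(rnorm(prod(dims) * tt, sd = 0.02), prod(dims))
  subj <- make_subject_from_series(homog, dims)
  regions <- rgs_grow(subj, T = 0.75)
  sizes <- vapply(regions, function(r) length(r$voxels), integer(1))
  expect_true(all(sizes >= 0.95 * prod(dims)))

  # two uncorrelated blocks: no region spans both
  subj2 <- make_two_block_subject(dims = c(4L, 4L, 2L), noise_sd = 0.05,
                                  seed = 6)
  regions2 <- rgs_grow(subj2, T = 0.75)
  for (r in regions2) {
    expect_identical(length(unique(subj2$ground_truth[r$voxels])), 1L)
  }

  # near-unit threshold keeps regions near-singleton on noisy data
  set.seed(7)
  noisy <- matrix(rnorm(prod(dims) * tt), prod(dims), tt)
  subj3 <- make_subject_from_series(noisy, dims)
  regions3 <- rgs_grow(subj3, T = 0.999)
  expect_true(all(vapply(regions3, function(r) length(r$voxels),
                         integer(1)) <= 2L))
})

test_that("region selection keeps largest regions and suppresses covered centers", {
  coords <- which(array(TRUE, dim = c(6L, 1L, 1L)), arr.ind = TRUE)
  mk <- function(regions) {
    attr(regions, "coords") <- coords
    attr(regions, "dims") <- c(6L, 1L, 1L)
    regions
  }
  # two disjoint candidates: both selected
  two <- mk(list(list(center = 1L, voxels = 1:3),
                 list(center = 5L, voxels = 4:6)))
  p <- rgs_select(two, p = 1)
  expect_identical(n_clusters(p), 2L)

  # one large region containing all other centers: one survivor
  nested <- mk(list(list(center = 1L, voxels = 1:6),
                    list(center = 2L, voxels = 2:3),
                    list(center = 5L, voxels = 5:6)))
  expect_identical(n_clusters(rgs_select(nested, p = 1)), 1L)

  # size filter arithmetic: sizes {4, 2} with p = 3 keeps one
  p2 <- rgs_select(mk(list(list(center = 1L, voxels = 1:4),
                           list(center = 6L, voxels = 5:6))), p = 3)
  expect_identical(n_clusters(p2), 1L)
  expect_error(rgs_select(two, p = 10), "survives")
})

test_that("cluster mean series and summaries follow their definitions", {
  dims <- c(4L, 1L, 1L)
  tt <- 30
  series <- rbind(matrix(0, 1, tt), matrix(2, 1, tt),
                  matrix(rep(sin(1:tt), 2), 2, byrow = TRUE))
  series <- series + matrix(rnorm(4 * tt, sd = 1e-8), 4, tt)
  subj <- make_subject_from_series(series, dims)
  coords <- which(array(TRUE, dim = dims), arr.ind = TRUE)
  parc <- fcsurvey:::new_parcellation(
    assignment = c(1L, 1L, 2L, 2L),
    clusters = list(list(id = 1L, voxels = 1:2, center = 1L),
                    list(id = 2L, voxels = 3:4, center = 3L)),
    method_tag = "manual", coords = coords, dims = dims)
  ts <- extract_mean_timeseries(subj, parc)
  expect_equal(ts$series[1, ], rep(1, tt), tolerance = 1e-6)
  expect_equal(ts$series[2, ], sin(1:tt), tolerance = 1e-6)

  # overlapping clusters: a voxel contributes to every containing cluster
  parc_ov <- fcsurvey:::new_parcellation(
    assignment = c(1L, 1L, 2L, 2L),
    clusters = list(list(id = 1L, voxels = 1:3, center = 1L),
                    list(id = 2L, voxels = 3:4, center = 4L)),
    method_tag = "manual", coords = coords, dims = dims,
    overlapping = TRUE)
  ts_ov <- extract_mean_timeseries(subj, parc_ov)
  expect_equal(ts_ov$series[1, 1], mean(series[1:3, 1]), tolerance = 1e-6)

  st <- parcellation_summary(parc, subj)
  expect_identical(st$n_nodes, 2L)
  expect_equal(st$mean_voxels_per_node, 2)
  expect_true(st$mean_heterogeneity >= 1 && st$mean_heterogeneity <= 2)
})
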