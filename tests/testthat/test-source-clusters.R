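test_that("the activity index is the voxelwise power-to-noise ratio", {
  p <- source_volume(array(10, c(3, 3, 3)))
  n <- source_volume(array(2, c(3, 3, 3)))
  expect_true(all(compute_nai(p, n)$values == 5))
  expect_true(all(compute_nai(p, p)$values == 1))
  expect_equal(compute_nai(p, n)$values,
               compute_nai(source_volume(p$values * 7),
                           source_volume(n$values * 7))$values)
  bad <- source_volume(array(1, c(3, 3, 3)))
  bad$values[1] <- 0
  expect_error(compute_nai(p, bad), "non-positive")
  small <- source_volume(array(1, c(2, 2, 2)))
  expect_error(compute_nai(p, small), "same grid")
})

test_that("top-percentile thresholding counts and ties behave", {
  set.seed(30)
  v <- source_volume(array(sample(1:1000), c(10, 10, 10)))
  vox <- top_percent_threshold(v, percent = 1)
  expect_equal(nrow(vox), 10)
  expect_setequal(vox$value, 991:1000)

  flat <- source_volume(array(3, c(4, 4, 4)))
  expect_warning(all_vox <- top_percent_threshold(flat, percent = 1),
                 "one value")
  expect_equal(nrow(all_vox), 64)

  expect_equal(nrow(top_percent_threshold(v, percent = 100)), 1000)
  expect_error(top_percent_threshold(v, mask = array(FALSE, c(10, 10, 10))),
               "no voxels")
})

test_that("mask restricts the threshold population", {
  vals <- array(0, c(6, 6, 6))
  vals[1:3, , ] <- 100
  vals[4:6, , ] <- seq_len(108)
  v <- source_volume(vals)
  mask <- array(FALSE, c(6, 6, 6)); mask[4:6, , ] <- TRUE
  vox <- top_percent_threshold(v, percent = 10, mask = mask)
  expect_true(all(vox$i >= 4))
  expect_equal(nrow(vox), 11)   # ceiling at the interpolated threshold
})

test_that("dbscan geometry follows the eps = 1.5 x spacing rule", {
  line <- data.frame(x_mm = seq(0, 25, by = 5), y_mm = 0, z_mm = 0)
  cl <- dbscan_clusters(line, spacing = 5)
  expect_equal(cl$n_clusters, 1)
  expect_equal(cl$sizes, 6)

  blob4 <- expand.grid(x_mm = c(0, 5), y_mm = c(0, 5), z_mm = 0)
  cl4 <- dbscan_clusters(blob4, spacing = 5)
  expect_equal(cl4$n_clusters, 0)
  expect_equal(sum(cl4$voxels$cluster == 0), 4)

  # two 10-voxel blobs separated by 2 empty voxel planes
  b1 <- expand.grid(x_mm = c(0, 5), y_mm = c(0, 5, 10, 15, 20), z_mm = 0)
  b2 <- b1; b2$x_mm <- b2$x_mm + 20   # min inter-blob distance 10 mm > eps
  two <- dbscan_clusters(rbind(b1, b2), spacing = 5)
  expect_equal(two$n_clusters, 2)
  expect_equal(sort(two$sizes), c(10, 10))

  empty <- dbscan_clusters(data.frame(x_mm = numeric(0), y_mm = numeric(0),
                                      z_mm = numeric(0)), spacing = 5)
  expect_equal(empty$n_clusters, 0)
})

test_that("corner neighbors are not connected at the default eps", {
  diag2 <- data.frame(x_mm = c(0, 5), y_mm = c(0, 5), z_mm = c(0, 5))
  cl <- dbscan_clusters(diag2, spacing = 5, min_pts = 2)
  expect_equal(cl$n_clusters, 0)   # sqrt(3)*5 = 8.66 > 7.5
  edge2 <- data.frame(x_mm = c(0, 5), y_mm = c(0, 5), z_mm = c(0, 0))
  expect_equal(dbscan_clusters(edge2, spacing = 5, min_pts = 2)$n_clusters,
               1)                  # sqrt(2)*5 = 7.07 <= 7.5
})

test_that("dbscan equals the brute-force reference on random fixtures", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(50:400, 1)
    grid <- expand.grid(i = 1:12, j = 1:12, k = 1:12)
    pick <- grid[sample(nrow(grid), n), ]
    vox <- data.frame(x_mm = pick$i * 5, y_mm = pick$j * 5,
                      z_mm = pick$k * 5)
    got <- dbscan_clusters(vox, spacing = 5)
    ref <- brute_force_dbscan(as.matrix(vox), eps = 7.5, min_pts = 5)
    expect_true(same_partition(got$voxels$cluster, ref))
  }
})

test_that("cluster labels are invariant to voxel input order", {
  set.seed(31)
  grid <- expand.grid(i = 1:10, j = 1:10, k = 1:10)
  pick <- grid[sample(1000, 200), ]
  vox <- data.frame(x_mm = pick$i * 5, y_mm = pick$j * 5, z_mm = pick$k * 5)
  a <- dbscan_clusters(vox, spacing = 5)
  shuf <- sample(nrow(vox))
  b <- dbscan_clusters(vox[shuf, ], spacing = 5)
  restored <- integer(nrow(vox))
  restored[shuf] <- b$voxels$cluster
  expect_true(same_partition(a$voxels$cluster, restored))
})

test_that("threshold-then-cluster recovers two synthetic blobs", {
  hits <- 0
  for (seed in 1:20) {
    v <- generate_source_volume(c(24, 10, 10), spacing = 5, blobs = list(
      list(center = c(5, 5, 5), radius = 6, amplitude = 25),
      list(center = c(19, 5, 5), radius = 6, amplitude = 25)),
      baseline = 1, noise_sd = 25 / 5 * 0.2, seed = seed)
    cl <- extract_clusters(v, percent = 1)
    hits <- hits + (cl$n_clusters == 2)
  }
  expect_equal(hits, 20)
})
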