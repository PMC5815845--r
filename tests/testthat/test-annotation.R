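grid_coords <- function(dims) {
  as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                        z = seq_len(dims[3])))
}

test_that("cluster extraction handles degenerate shapes", {
  coords <- grid_coords(c(5, 5, 5))
  mask <- rep(FALSE, nrow(coords))
  expect_identical(extract_clusters(mask, coords), list())

  mask[1] <- TRUE
  expect_equal(extract_clusters(mask, coords), list(1L))

  # two face-adjacent voxels join under any connectivity
  mask2 <- rep(FALSE, nrow(coords))
  idx2 <- which(coords[, 1] %in% 1:2 & coords[, 2] == 1 & coords[, 3] == 1)
  mask2[idx2] <- TRUE
  for (conn in c(6, 18, 26)) {
    expect_equal(extract_clusters(mask2, coords, conn), list(sort(idx2)))
  }

  # corner-adjacent voxels: separate at 6/18, joined at 26
  mask3 <- rep(FALSE, nrow(coords))
  a <- which(coords[, 1] == 1 & coords[, 2] == 1 & coords[, 3] == 1)
  b <- which(coords[, 1] == 2 & coords[, 2] == 2 & coords[, 3] == 2)
  mask3[c(a, b)] <- TRUE
  expect_length(extract_clusters(mask3, coords, 6), 2)
  expect_length(extract_clusters(mask3, coords, 18), 2)
  expect_length(extract_clusters(mask3, coords, 26), 1)
})

test_that("cluster extraction matches the flood-fill oracle on random masks", {
  coords <- grid_coords(c(10, 10, 10))
  set.seed(42)
  for (i in 1:200) {
    mask <- runif(nrow(coords)) < runif(1, 0.02, 0.3)
    conn <- sample(c(6, 18, 26), 1)
    got <- extract_clusters(mask, coords, conn)
    want <- flood_fill_clusters(mask, coords, conn)
    expect_identical(partition_signature(got), partition_signature(want))
  }
})

test_that("atlas labeling applies the probability floor and size rule", {
  dims <- c(8, 8, 1)
  coords <- grid_coords(dims)
  n <- nrow(coords)
  # two regions: region 1 covers the left half strongly, region 2 the rest
  P <- matrix(0, 2, n)
  left <- coords[, 1] <= 4
  P[1, left] <- 0.8
  P[2, !left] <- 0.6
  # one low-probability voxel stays unlabeled
  low <- which(left)[1]
  P[1, low] <- 0.20

  loadings <- rnorm(n)
  cl <- list(which(left))  # one cluster = full left half (32 voxels)
  ann <- label_clusters(cl, P, loadings, coords)
  expect_true(is.na(ann$assignment[low]))
  expect_equal(ann$regions$region, "region_01")
  expect_equal(ann$regions$count, sum(left) - 1)
  expect_equal(ann$regions$percent, 100)   # cluster covers all labeled voxels

  # the >10 voxel reporting rule: 10 voxels not reported, 11 reported
  cl10 <- list(which(left)[2:11])
  expect_equal(nrow(label_clusters(cl10, P, loadings, coords)$regions), 0)
  cl11 <- list(which(left)[2:12])
  ann11 <- label_clusters(cl11, P, loadings, coords)
  expect_equal(nrow(ann11$regions), 1)
  expect_equal(ann11$regions$count, 11)

  # peak voxel is the maximal-|loading| member
  peak_idx <- cl[[1]][which.max(abs(loadings[cl[[1]]]))]
  expect_equal(ann$clusters$peak_loading, loadings[peak_idx])
})

test_that("labeling is independent of voxel enumeration order", {
  at <- generate_atlas(c(10, 10, 4), 6, seed = 3)
  coords <- at$voxel_coordinates
  set.seed(5)
  loadings <- rnorm(nrow(coords))
  mask <- loadings > 1
  cl <- extract_clusters(mask, coords)
  ann <- label_clusters(cl, at, loadings, coords, min_voxels = 0)
  # re-running gives the identical annotation (deterministic tie-breaks)
  ann2 <- label_clusters(cl, at, loadings, coords, min_voxels = 0)
  expect_identical(ann$regions, ann2$regions)
  expect_identical(ann$assignment, ann2$assignment)
})

test_that("overlap fractions partition the voxel set at every threshold", {
  ds <- tiny_noiseless_dataset(k = 3, m = 40, seed = 21)
  dec <- fastica_decompose(ds$contrast, 3, seed = 2)
  ov <- overlap_analysis(dec, 1, 2, thresholds = seq(0, 4, by = 0.5))
  expect_equal(ov$both + ov$only_a + ov$only_b + ov$neither,
               rep(1, nrow(ov)))

  # identical components never separate
  S2 <- rbind(dec$S[1, ], dec$S[1, ])
  ov2 <- overlap_analysis(S2, 1, 2)
  expect_true(all(ov2$only_a == 0 & ov2$only_b == 0))

  # disjoint supports never overlap above the noise floor
  S3 <- matrix(0, 2, 100)
  S3[1, 1:50] <- 3
  S3[2, 51:100] <- 3
  ov3 <- overlap_analysis(S3, 1, 2, thresholds = 1)
  expect_equal(ov3$both, 0)
  expect_error(overlap_analysis(dec, 2, 2), "distinct")
})

test_that("mask containment fractions count correctly", {
  map <- c(rep(TRUE, 10), rep(FALSE, 10))
  ref <- c(rep(TRUE, 7), rep(FALSE, 3), rep(TRUE, 10))
  expect_equal(mask_fraction(map, ref), 0.7)
  expect_equal(mask_fraction(map, map), 1.0)
  expect_equal(mask_fraction(map, !map), 0.0)
  expect_error(mask_fraction(rep(FALSE, 5), rep(TRUE, 5)), "empty")
})

test_that("component annotation stacks positive and negative clusters", {
  ds <- tiny_noiseless_dataset(k = 3, m = 50, seed = 30)
  dec <- fastica_decompose(ds$contrast, 3, seed = 1)
  th <- pooled_threshold(dec, 0.10)
  at <- generate_atlas(c(12, 12, 8), 8, seed = 2)
  ann <- annotate_components(dec, th, at, ds$contrast$coordinates,
                             min_voxels = 2)
  expect_true(nrow(ann) > 0)
  expect_true(all(ann$component %in% 1:3))
  expect_true(all(ann$sign %in% c("positive", "negative")))
  expect_true(all(ann$percent >= 0 & ann$percent <= 100))
})
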