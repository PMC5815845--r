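test_that("PCA scree reflects the rank and planted spectrum", {
  ds <- tiny_noiseless_dataset(k = 3, m = 30, seed = 5)
  sc <- pca_scree(ds$contrast)
  expect_lt(sc$eigenvalues[4] / sc$eigenvalues[1], 1e-8)
  expect_equal(sc$cumulative_variance[3], 1, tolerance = 1e-8)

  # independent standardized variables: eigenvalues concentrate near 1
  set.seed(8)
  iid <- matrix(rnorm(20 * 20000), 20, 20000)
  sc2 <- pca_scree(iid)
  expect_true(all(abs(sc2$eigenvalues - 1) < 0.2))
  expect_error(pca_scree(matrix(1:3, 1, 3)), "at least 2")
})

test_that("FastICA recovers planted sparse sources", {
  ds <- tiny_noiseless_dataset(k = 3, m = 50, seed = 7)
  dec <- fastica_decompose(ds$contrast, 3, seed = 1)
  expect_true(dec$converged)
  mt <- match_components(ds$truth$true_sources, dec, method = "one_to_one")
  expect_true(all(abs(mt$r) > 0.99))

  # single-component case
  ds1 <- tiny_noiseless_dataset(k = 1, m = 30, seed = 9)
  dec1 <- fastica_decompose(ds1$contrast, 1, seed = 1)
  expect_gt(abs(cor(dec1$S[1, ], ds1$truth$true_sources[1, ])), 0.999)

  # k above the numerical rank errors
  expect_error(fastica_decompose(ds$contrast, 10, seed = 1), "rank")
})

test_that("decomposition satisfies its structural invariants", {
  ds <- tiny_noiseless_dataset(k = 4, m = 60, seed = 3)
  dec <- fastica_decompose(ds$contrast, 4, seed = 6)

  expect_equal(rowMeans(dec$S), rep(0, 4), tolerance = 1e-6)
  expect_equal(apply(dec$S, 1, sd), rep(1, 4), tolerance = 1e-6)
  cc <- cor(t(dec$S))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-3)
  # peak-voxel loadings positive for every component
  peaks <- apply(dec$S, 1, function(s) s[which.max(abs(s))])
  expect_true(all(peaks > 0))
  # bit-reproducible under a fixed seed
  expect_identical(dec, fastica_decompose(ds$contrast, 4, seed = 6))
})

test_that("sign recoding flips negative-peak components and is idempotent", {
  ds <- tiny_noiseless_dataset(k = 3, m = 40, seed = 2)
  dec <- fastica_decompose(ds$contrast, 3, seed = 4)
  recon <- dec$A %*% dec$S

  flipped <- dec
  flipped$S[2, ] <- -flipped$S[2, ]
  flipped$A[, 2] <- -flipped$A[, 2]
  peak <- which.max(abs(flipped$S[2, ]))
  expect_lt(flipped$S[2, peak], 0)

  fixed <- enforce_sign_convention(flipped)
  expect_equal(fixed$S, dec$S)
  expect_equal(fixed$A, dec$A)
  expect_equal(fixed$A %*% fixed$S, recon)
  expect_identical(enforce_sign_convention(fixed), fixed)
})

test_that("pooled threshold hits the requested tail fraction", {
  set.seed(12)
  S <- matrix(rnorm(4 * 50000), 4, 50000)
  th <- pooled_threshold(S, 0.10)
  # oracle: 95th percentile of |z| for standard-normal loadings
  expect_lt(abs(th$threshold - qnorm(0.95)), 0.02)
  expect_lt(abs(th$fraction_retained - 0.10), 1 / length(S))
  retained <- sum(th$positive) + sum(th$negative)
  expect_equal(retained / length(S), th$fraction_retained)

  all_in <- pooled_threshold(S, 1)
  expect_equal(all_in$threshold, 0)
  expect_equal(sum(all_in$positive) + sum(all_in$negative), length(S))
})

test_that("score projection is exact for linear combinations", {
  ds <- tiny_noiseless_dataset(k = 3, m = 40, seed = 6)
  dec <- fastica_decompose(ds$contrast, 3, seed = 3)

  # exact combination a * S with no scaling: recovered scores equal a
  a <- matrix(c(1.5, -2, 0.5, 0, 3, -1), 2, 3)
  X_new <- a %*% dec$S
  expect_equal(project_scores(dec$S, X_new, scale_subjects = FALSE), a,
               tolerance = 1e-8, ignore_attr = TRUE)

  # projecting the training data reproduces the training mixing matrix
  expect_equal(project_scores(dec$S, ds$contrast), dec$A,
               tolerance = 1e-6, ignore_attr = TRUE)

  # orthonormalized sources: least squares equals the analytic shortcut
  qs <- qr.Q(qr(t(dec$S)))
  S_orth <- t(qs) * sqrt(nrow(qs))
  X2 <- matrix(rnorm(5 * ncol(S_orth)), 5) %*% diag(ncol(S_orth))
  ls <- project_scores(S_orth, X2, scale_subjects = FALSE)
  shortcut <- X2 %*% t(S_orth) / ncol(S_orth)
  expect_equal(ls, shortcut, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(project_scores(rbind(dec$S, dec$S[1, ]), ds$contrast),
               "rank-deficient")
})

test_that("separation error decreases with SNR", {
  base <- tiny_noiseless_dataset(k = 3, m = 100, seed = 15)
  signal <- base$truth$true_scores %*% base$truth$true_sources
  mean_abs_r <- vapply(c(2, 0.5, 0.1), function(noise_sd) {
    set.seed(77)
    X <- signal + matrix(rnorm(length(signal), 0, noise_sd), nrow(signal))
    dec <- fastica_decompose(X, 3, seed = 5)
    mean(abs(match_components(base$truth$true_sources, dec,
                              method = "one_to_one")$r))
  }, numeric(1))
  expect_true(all(diff(mean_abs_r) > 0))
})

test_that("Gaussian data yields unstable components across subsamples", {
  # ICA is unidentifiable for Gaussian sources: decompositions of two
  # disjoint halves of pure-noise data share no component structure
  set.seed(9)
  X <- matrix(rnorm(60 * 1500), 60, 1500)
  d1 <- suppressWarnings(fastica_decompose(X[1:30, ], 3, seed = 1,
                                           restarts = 1, max_iter = 200))
  d2 <- suppressWarnings(fastica_decompose(X[31:60, ], 3, seed = 1,
                                           restarts = 1, max_iter = 200))
  mt <- match_components(d1, d2)
  expect_true(all(abs(mt$r) < 0.9))
})
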