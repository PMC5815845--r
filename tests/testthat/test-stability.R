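test_that("component matching recovers permutations and sign flips", {
  set.seed(2)
  R <- matrix(rnorm(4 * 500), 4, 500)
  perm <- c(3, 1, 4, 2)
  E <- R[perm, ]
  E[c(1, 3), ] <- -E[c(1, 3), ]
  mt <- match_components(R, E)
  expect_equal(mt$reference, perm)
  expect_equal(abs(mt$r), rep(1, 4), tolerance = 1e-12)
  expect_equal(mt$sign, c(-1, 1, -1, 1))

  # identity case
  mt_id <- match_components(R, R)
  expect_equal(mt_id$reference, 1:4)
  expect_equal(mt_id$r, rep(1, 4))

  expect_error(match_components(R, rbind(E[1:3, ], 0)), "zero-variance")
})

test_that("greedy matching equals the exhaustive per-component argmax", {
  set.seed(6)
  for (i in 1:100) {
    k_ref <- sample(2:4, 1)
    k_est <- sample(2:4, 1)
    R <- matrix(rnorm(k_ref * 60), k_ref, 60)
    E <- matrix(rnorm(k_est * 60), k_est, 60)
    mt <- match_components(R, E)
    for (e in seq_len(k_est)) {
      cors <- vapply(seq_len(k_ref), function(r) cor(E[e, ], R[r, ]),
                     numeric(1))
      expect_equal(mt$reference[e], which.max(abs(cors)))
      expect_equal(mt$r[e], cors[which.max(abs(cors))])
    }
  }
})

test_that("one-to-one matching assigns each reference at most once", {
  set.seed(3)
  R <- matrix(rnorm(3 * 200), 3, 200)
  # both estimated components closest to reference 1
  E <- rbind(R[1, ] + rnorm(200, 0, 0.1), R[1, ] + rnorm(200, 0, 0.2),
             R[3, ] + rnorm(200, 0, 0.1))
  greedy <- match_components(R, E, "greedy")
  expect_equal(greedy$reference[1:2], c(1, 1))  # duplicates allowed
  strict <- match_components(R, E, "one_to_one")
  expect_equal(anyDuplicated(strict$reference), 0)
})

test_that("bootstrap subsamples are disjoint and stable at high SNR", {
  cfg <- synth_config(n_subjects = 220, grid_dims = c(12, 12, 8),
                      n_components_true = 3,
                      noise_sd = 0.2 * sqrt(3),     # noise at 20% of signal
                      batch_offset_sd = 0, behavioral_effects = list(),
                      fa_effect = NULL, n_atlas_regions = 5, seed = 51)
  ds <- generate_dataset(cfg)
  st <- bootstrap_stability(ds$contrast, 3, subsample_size = 100,
                            n_runs = 8, seed = 4)
  expect_true(all(st$summary$abs_r_split > 0.9))

  # the disjointness of the two subsamples is part of the resampling design
  m <- 220
  for (run in 1:8) {
    idx <- wmnica:::with_seed(4 + run, sample.int(m, 200))
    expect_equal(anyDuplicated(idx), 0)
  }

  # pure noise: matched split correlations collapse
  set.seed(9)
  noise <- matrix(rnorm(220 * 1152), 220, 1152)
  stn <- suppressWarnings(bootstrap_stability(noise, 3, subsample_size = 100,
                                              n_runs = 4, seed = 4,
                                              max_iter = 200, restarts = 1))
  expect_lt(mean(abs(stn$runs$r_split)), 0.5)
  expect_error(bootstrap_stability(ds$contrast, 3, subsample_size = 150,
                                   n_runs = 2), "2 \\* subsample_size")
})

test_that("cross-validation detects a planted association and aggregates betas", {
  cfg <- synth_config(n_subjects = 260, grid_dims = c(12, 12, 8),
                      n_components_true = 3, noise_sd = 0.5,
                      batch_offset_sd = 0,
                      behavioral_effects = list(
                        list(component = 1, variable = "d_prime_2back",
                             slope = 0.25)),
                      fa_effect = NULL, n_atlas_regions = 5, seed = 61)
  ds <- generate_dataset(cfg)
  ref <- fastica_decompose(ds$contrast, 3, seed = 1)
  planted_ref <- match_components(ref, ds$truth$true_sources)$reference[1]
  cv <- cross_validate(ds$contrast, ds$behavior, k = 3,
                       measures = c("d_prime_2back", "d_prime_0back"),
                       components = planted_ref, train_size = 160,
                       test_size = 100, n_runs = 25, seed = 7,
                       reference = ref)
  pct <- cv$percent
  hit <- pct$percent[pct$term == "d_prime_2back"]
  expect_gt(hit, 40)
  mb <- cv$mean_beta
  expect_gt(abs(mb$mean_beta[mb$term == "d_prime_2back"]), 0.15)
})

test_that("permutation empirical p has the documented edge behavior", {
  cfg <- synth_config(n_subjects = 120, grid_dims = c(8, 8, 4),
                      n_components_true = 2, noise_sd = 0.3,
                      batch_offset_sd = 0,
                      behavioral_effects = list(
                        list(component = 1, variable = "d_prime_2back",
                             slope = 0.6)),
                      fa_effect = NULL, n_atlas_regions = 4, seed = 71)
  ds <- generate_dataset(cfg)
  ref <- fastica_decompose(ds$contrast, 2, seed = 1)
  planted_ref <- match_components(ref, ds$truth$true_sources)$reference[1]
  cv <- cross_validate(ds$contrast, ds$behavior, k = 2,
                       measures = "d_prime_2back",
                       components = planted_ref, train_size = 70,
                       test_size = 50, n_runs = 10, seed = 3,
                       reference = ref)
  # a planted slope of 0.6 at n = 50 is detected in essentially every run,
  # so the observed percent exceeds every permutation-null value
  pp <- permutation_empirical_p(cv, ds$behavior, n_outer = 19, seed = 5)
  expect_equal(pp$empirical_p$empirical_p, 1 / 20)
  expect_true(all(pp$null >= 0 & pp$null <= 100))

  # the add-one estimator is recomputable from the reported null draws
  by_hand <- (1 + sum(pp$null[, 1] >= pp$observed$percent[1])) / 20
  expect_equal(pp$empirical_p$empirical_p[1], by_hand)
})
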