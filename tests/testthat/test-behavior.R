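test_that("default schedule satisfies the block, target, and lure structure", {
  sch <- build_schedule(seed = 42)
  expect_equal(nrow(sch), 168)
  expect_equal(length(unique(sch$block)), 12)

  two <- sch[sch$condition == "2back", ]
  expect_equal(nrow(two), 84)
  expect_equal(sum(two$is_target), 18)
  expect_equal(sum(two$is_lure), 15)
  expect_equal(round(100 * sum(two$is_lure) / nrow(two), 1), 17.9)

  # each block: exactly 3 targets, 11 nontargets
  per_block <- tapply(sch$is_target, sch$block, sum)
  expect_true(all(per_block == 3))

  # 0-back targets are exactly the occurrences of the letter x
  zero <- sch[sch$condition == "0back", ]
  expect_equal(zero$is_target, zero$letter == "x")

  # flags are self-consistent with the letter sequence within 2-back blocks
  for (b in unique(two$block)) {
    blk <- two[two$block == b, ]
    recomputed <- vapply(seq_len(nrow(blk)), function(i) {
      i > 2 && blk$letter[i] == blk$letter[i - 2]
    }, logical(1))
    expect_equal(blk$is_target, recomputed)
  }
})

test_that("schedule generation is deterministic and rejects infeasible lures", {
  expect_identical(build_schedule(seed = 5), build_schedule(seed = 5))
  expect_error(build_schedule(lure_count = 84, seed = 1), "infeasible")
})

test_that("d-prime scoring matches hand-computed signal-detection values", {
  sch <- build_schedule(seed = 1)

  # ceiling: perfect responder, extreme-proportion correction
  dp <- score_dprime(perfect_responses(sch), sch, "2back")
  expect_equal(dp, qnorm(17.5 / 18) - qnorm(0.5 / 66))
  expect_equal(round(dp, 2), 4.34)

  # interior case against independently evaluated inverse-normal values
  two_idx <- which(sch$condition == "2back")
  resp <- perfect_responses(sch)
  miss_targets <- two_idx[sch$is_target[two_idx]][1:2]
  resp$response[miss_targets] <- "nontarget"
  fa_non <- two_idx[!sch$is_target[two_idx]][1:6]
  resp$response[fa_non] <- "target"
  expect_equal(score_dprime(resp, sch, "2back"),
               qnorm(16 / 18) - qnorm(6 / 66), tolerance = 1e-12)
  expect_equal(round(qnorm(16 / 18) - qnorm(6 / 66), 3), 2.556)

  # H = F implies d' = 0: one hit rate equal to one false-alarm rate
  resp2 <- perfect_responses(sch)
  resp2$response[two_idx] <- "nontarget"
  hit_one <- two_idx[sch$is_target[two_idx]][1:6]     # H = 6/18 = 1/3
  fa_some <- two_idx[!sch$is_target[two_idx]][1:22]   # F = 22/66 = 1/3
  resp2$response[c(hit_one, fa_some)] <- "target"
  expect_equal(score_dprime(resp2, sch, "2back"), 0)
})

test_that("d-prime is invariant to trial order and errors on empty cells", {
  sch <- build_schedule(seed = 3)
  resp <- generate_trial_responses(sch, d_prime = 1.5, seed = 9)
  base <- score_dprime(resp, sch, "2back")
  perm <- sample(nrow(sch))
  expect_equal(score_dprime(resp[perm, , drop = FALSE],
                            sch[perm, , drop = FALSE], "2back"), base)
  expect_error(score_dprime(resp, sch, "5back"), "not present")

  all_missing <- resp
  all_missing$response[sch$condition == "2back" & sch$is_target] <- NA
  expect_error(score_dprime(all_missing, sch, "2back"), "undefined")
})

test_that("exclusion rules flag missingness, outliers, and incompleteness", {
  sch <- build_schedule(seed = 2)
  n <- 12
  tbl <- data.frame(d_prime_2back = rnorm(n, 2.5, 0.5),
                    d_prime_0back = rnorm(n, 3.6, 0.3),
                    rt_difference = rnorm(n, 126, 40),
                    episodic_memory = rnorm(n, 30, 5),
                    item_familiarity = rnorm(n, 3, 5))
  clean <- perfect_responses(sch)
  logs <- replicate(n, clean, simplify = FALSE)

  # (a) 70 of 168 missing responses = 41.7% > 30%
  bad_a <- clean
  bad_a$response[1:70] <- NA
  logs[[1]] <- bad_a

  # (b) at least one missing target in 3 blocks trips the per-block rule
  bad_b <- clean
  for (b in 1:3) {
    t_idx <- which(sch$block == b & sch$is_target)[1]
    bad_b$response[t_idx] <- NA
  }
  logs[[2]] <- bad_b

  # (d) episodic memory at mean + 5 SD (computed pre-exclusion)
  mu <- mean(tbl$episodic_memory)
  s <- sd(tbl$episodic_memory)
  tbl$episodic_memory[3] <- mu + 5 * s
  # recompute: the outlier shifts mean/SD; verify the flag from the final z
  z3 <- abs(tbl$episodic_memory[3] - mean(tbl$episodic_memory)) /
    sd(tbl$episodic_memory)

  # (e) incomplete data
  tbl$rt_difference[4] <- NA

  out <- apply_exclusions(tbl, logs, sch)
  expect_true(grepl("a", out$exclusion_reasons[1]))
  expect_true(grepl("b", out$exclusion_reasons[2]))
  expect_equal(grepl("d", out$exclusion_reasons[3]), z3 > 4)
  expect_true(grepl("e", out$exclusion_reasons[4]))
  expect_false(any(out$excluded[5:12]))

  # clean table passes unchanged
  tbl2 <- tbl
  tbl2$episodic_memory[3] <- mu
  tbl2$rt_difference[4] <- 0
  out2 <- apply_exclusions(tbl2, replicate(n, clean, simplify = FALSE), sch)
  expect_false(any(out2$excluded))
})

test_that("exclusion flags are monotone in added missingness", {
  sch <- build_schedule(seed = 8)
  tbl <- data.frame(d_prime_2back = rnorm(6), d_prime_0back = rnorm(6),
                    rt_difference = rnorm(6), episodic_memory = rnorm(6),
                    item_familiarity = rnorm(6))
  base_log <- perfect_responses(sch)
  set.seed(31)
  for (frac in c(0.2, 0.35, 0.5, 0.8)) {
    lighter <- base_log
    drop1 <- sample(nrow(sch), round(frac * nrow(sch) / 2))
    lighter$response[drop1] <- NA
    heavier <- lighter
    drop2 <- sample(setdiff(seq_len(nrow(sch)), drop1),
                    round(frac * nrow(sch) / 2))
    heavier$response[drop2] <- NA
    logs_light <- replicate(6, lighter, simplify = FALSE)
    logs_heavy <- replicate(6, heavier, simplify = FALSE)
    f_light <- apply_exclusions(tbl, logs_light, sch)$excluded
    f_heavy <- apply_exclusions(tbl, logs_heavy, sch)$excluded
    expect_true(all(f_heavy >= f_light))
  }
})

test_that("residualization removes batch offsets and standardizes", {
  # single-level factor reduces to z-scoring
  x <- c(3, 5, 9, 1, 2, 8)
  expect_equal(residualize(x, factor(rep("a", 6))), as.vector(scale(x)))

  # planted offsets with noise: per-batch residual means vanish
  set.seed(11)
  batch <- factor(rep(c("b1", "b2", "b3"), each = 20))
  vals <- c(2, 0, -2)[as.integer(batch)] + rnorm(60)
  res <- residualize(vals, batch)
  expect_true(all(abs(tapply(res, batch, mean)) < 1e-10))
  expect_equal(mean(res), 0, tolerance = 1e-12)
  expect_equal(sd(res), 1, tolerance = 1e-12)

  # exact offsets, zero noise: degenerate residual variance
  exact <- c(2, 0, -2)[as.integer(batch)]
  expect_warning(z <- residualize(exact, batch), "degenerate")
  expect_equal(z, rep(0, 60))

  # constant input is an error
  expect_error(residualize(rep(1, 10), batch[1:10]), "constant")
})

test_that("matrix residualization matches the vector operation per voxel", {
  set.seed(21)
  batch <- data.frame(hw = factor(rep(1:3, each = 10)))
  vals <- matrix(rnorm(30 * 5), 30, 5)
  vals[batch$hw == 2, ] <- vals[batch$hw == 2, ] + 1.5
  out <- residualize_matrix(vals, batch)
  for (j in 1:5) {
    expect_equal(out[, j], residualize(vals[, j], batch$hw))
  }
})
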