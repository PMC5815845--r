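#' Configuration for the synthetic working-memory dataset generator
#'
#' Bundles and validates every parameter of the generative model used for
#' ground-truth recovery tests. Contrast maps are simulated as
#' `X = A S + batch offsets + noise`: `k_true` sparse, Laplace-tailed
#' (super-Gaussian) spatial sources `S` mixed by standard-normal subject
#' scores `A`, plus additive per-voxel offsets for categorical acquisition
#' batches and i.i.d. Gaussian noise. Selected behavioral variables and FA
#' regions are tied linearly to chosen component scores with standardized
#' slopes.
#'
#' @param n_subjects Number of subjects m.
#' @param grid_dims Integer 3-vector of voxel grid dimensions.
#' @param n_components_true Number of planted spatial sources k_true.
#' @param source_sparsity Fraction of voxels carrying a nonzero Laplace
#'   loading per source, in (0, 1].
#' @param source_distribution Label of the super-Gaussian loading family;
#'   only `"laplace"` is implemented.
#' @param noise_sd Standard deviation of the additive Gaussian voxel noise.
#' @param batch_levels Named integer vector of level counts for the
#'   categorical batch factors (default: 3 hardware, 2 software,
#'   2 processing batches).
#' @param batch_offset_sd Standard deviation of the per-voxel offset field
#'   drawn once for each non-reference batch level; 0 disables batch effects.
#' @param behavioral_effects List of planted behavioral effects, each a list
#'   with `component`, `variable`, and standardized `slope` in \[-1, 1\].
#' @param fa_effect Planted FA effect: list with `component`, integer
#'   `regions`, and standardized `slope`; `NULL` for none.
#' @param n_fa_regions Number of white-matter FA regions (default 70, i.e.
#'   35 bilateral region pairs).
#' @param n_atlas_regions Number of gray-matter atlas regions.
#' @param seed Integer seed; generation is a pure function of
#'   (config, seed).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 300,
                         grid_dims = c(15, 15, 10),
                         n_components_true = 6,
                         source_sparsity = 0.2,
                         source_distribution = "laplace",
                         noise_sd = 1,
                         batch_levels = c(hardware = 3, software = 2,
                                          processing = 2),
                         batch_offset_sd = 0.5,
                         behavioral_effects = list(
                           list(component = 3, variable = "d_prime_2back",
                                slope = 0.24),
                           list(component = 4, variable = "d_prime_0back",
                                slope = 0.25)),
                         fa_effect = list(component = 3,
                                          regions = c(5L, 12L, 23L),
                                          slope = 0.15),
                         n_fa_regions = 70,
                         n_atlas_regions = 20,
                         seed = 1) {
  stopifnot(n_subjects >= 2,
            length(grid_dims) == 3, all(grid_dims >= 1),
            n_components_true >= 1,
            source_sparsity > 0, source_sparsity <= 1,
            noise_sd >= 0,
            batch_offset_sd >= 0,
            n_fa_regions >= 1, n_atlas_regions >= 1)
  if (!identical(source_distribution, "laplace")) {
    stop("only the 'laplace' source distribution is implemented",
         call. = FALSE)
  }
  n_voxels <- prod(grid_dims)
  if (n_components_true > min(n_subjects, n_voxels)) {
    stop("invalid config: n_components_true exceeds min(subjects, voxels)",
         call. = FALSE)
  }
  for (eff in behavioral_effects) {
    stopifnot(eff$component >= 1, eff$component <= n_components_true,
              abs(eff$slope) <= 1, is.character(eff$variable))
  }
  if (!is.null(fa_effect)) {
    stopifnot(fa_effect$component >= 1,
              fa_effect$component <= n_components_true,
              abs(fa_effect$slope) <= 1,
              all(fa_effect$regions >= 1),
              all(fa_effect$regions <= n_fa_regions))
  }
  structure(list(n_subjects = n_subjects, grid_dims = as.integer(grid_dims),
                 n_components_true = n_components_true,
                 source_sparsity = source_sparsity,
                 source_distribution = source_distribution,
                 noise_sd = noise_sd, batch_levels = batch_levels,
                 batch_offset_sd = batch_offset_sd,
                 behavioral_effects = behavioral_effects,
                 fa_effect = fa_effect, n_fa_regions = n_fa_regions,
                 n_atlas_regions = n_atlas_regions, seed = seed),
            class = "synth_config")
}

# Draw a standardized variable tied to a component score with a given
# standardized slope: slope * score + sqrt(1 - slope^2) * N(0,1), so the
# population variance is 1 and the population regression slope equals
# `slope` on the z scale.
planted_variable <- function(score, slope) {
  slope * score + sqrt(1 - slope^2) * stats::rnorm(length(score))
}

#' Generate a complete synthetic dataset with known ground truth
#'
#' Simulates, from a [synth_config()], every input the analysis pipeline
#' consumes: a subjects-by-voxels contrast matrix (`A S` plus batch offsets
#' plus Gaussian noise), a behavioral table with planted component-score
#' effects and realistic covariate marginals, a region-wise FA table with an
#' optional planted effect, a probabilistic gray-matter atlas, and the
#' planted ground truth itself. Identical (config, seed) pairs give
#' bit-identical outputs.
#'
#' @param config A [synth_config()].
#' @return A list of class `wmn_dataset` with elements `contrast`
#'   (a [contrast_matrix()]), `behavior`, `fa` (data.frames), `atlas`
#'   (a `wmn_atlas`), `batches` (data.frame of batch assignments), and
#'   `truth` (list with `true_sources`, `true_scores`, `batch_assignments`,
#'   `planted_effects`, `seed`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  m <- config$n_subjects
  dims <- config$grid_dims
  n <- prod(dims)
  k <- config$n_components_true

  with_seed(config$seed, {
    coords <- as.matrix(expand.grid(x = seq_len(dims[1]),
                                    y = seq_len(dims[2]),
                                    z = seq_len(dims[3])))

    # Sparse Laplace sources, z-scaled row-wise (mean 0, variance 1).
    n_active <- max(2L, round(config$source_sparsity * n))
    S <- matrix(0, k, n)
    for (j in seq_len(k)) {
      support <- sample.int(n, n_active)
      S[j, support] <- stats::rexp(n_active) * sample(c(-1, 1), n_active,
                                                      replace = TRUE)
      S[j, ] <- (S[j, ] - mean(S[j, ])) / stats::sd(S[j, ])
    }

    # Standard-normal subject scores, exactly standardized column-wise.
    A <- matrix(stats::rnorm(m * k), m, k)
    A <- apply(A, 2, function(a) (a - mean(a)) / stats::sd(a))
    A <- matrix(A, m, k)

    X <- A %*% S

    # Batch factors: additive per-voxel offset fields drawn once per
    # non-reference level.
    batches <- as.data.frame(lapply(config$batch_levels, function(L) {
      repeat {
        assign <- sample.int(L, m, replace = TRUE)
        if (all(tabulate(assign, L) >= 2)) break
      }
      factor(assign)
    }))
    if (config$batch_offset_sd > 0) {
      for (f in names(batches)) {
        L <- nlevels(batches[[f]])
        for (lev in 2:L) {
          offset <- stats::rnorm(n, 0, config$batch_offset_sd)
          rows <- which(as.integer(batches[[f]]) == lev)
          X[rows, ] <- X[rows, ] + rep(offset, each = length(rows))
        }
      }
    }

    if (config$noise_sd > 0) {
      X <- X + matrix(stats::rnorm(m * n, 0, config$noise_sd), m, n)
    }

    contrast <- contrast_matrix(X, coords,
                                subject_ids = sprintf("sub%04d", seq_len(m)),
                                grid_dims = dims)

    # Behavioral table: planted effects where configured, independent
    # standard normals elsewhere, covariates with realistic marginals.
    behavioral_vars <- c("d_prime_2back", "d_prime_0back", "rt_difference",
                         "episodic_memory", "item_familiarity")
    behavior <- data.frame(subject = contrast$subject_ids)
    planted <- vapply(config$behavioral_effects, function(e) e$variable,
                      character(1))
    for (v in behavioral_vars) {
      hit <- which(planted == v)
      behavior[[v]] <- if (length(hit) > 0) {
        eff <- config$behavioral_effects[[hit[1]]]
        planted_variable(A[, eff$component], eff$slope)
      } else {
        stats::rnorm(m)
      }
    }
    behavior$d_prime_difference <- behavior$d_prime_2back -
      behavior$d_prime_0back
    behavior$sex <- factor(sample(c("female", "male"), m, replace = TRUE,
                                  prob = c(0.61, 0.39)))
    behavior$age <- sample(18:35, m, replace = TRUE)
    behavior$hand <- factor(sample(c("right", "left"), m, replace = TRUE,
                                   prob = c(0.903, 0.097)))
    behavior$motivation <- sample(1:5, m, replace = TRUE,
                                  prob = c(0.001, 0.005, 0.066, 0.444, 0.484))
    behavior$difficulty <- sample(1:5, m, replace = TRUE,
                                  prob = c(0.092, 0.403, 0.381, 0.12, 0.004))
    behavior$smoking <- sample(1:5, m, replace = TRUE,
                               prob = c(0.65, 0.23, 0.052, 0.068, 0.007))
    behavior$sleep <- round(stats::rnorm(m, 7.96, 1), 2)
    behavior$chronotype <- factor(sample(c("evening", "morning"), m,
                                         replace = TRUE,
                                         prob = c(0.698, 0.302)))
    behavior$bmi <- round(stats::rnorm(m, 22.2, 2.5), 1)
    behavior$icv <- round(stats::rnorm(m, 1500, 120), 1)

    # FA table: 70 standard-normal region columns on the FA scale, with a
    # planted standardized effect only where configured.
    n_half <- ceiling(config$n_fa_regions / 2)
    fa_names <- paste0("wm_region_",
                       sprintf("%02d", rep(seq_len(n_half), each = 2)),
                       c("_left", "_right"))[seq_len(config$n_fa_regions)]
    fa_z <- matrix(stats::rnorm(m * config$n_fa_regions), m,
                   config$n_fa_regions)
    if (!is.null(config$fa_effect)) {
      eff <- config$fa_effect
      for (r in eff$regions) {
        fa_z[, r] <- planted_variable(A[, eff$component], eff$slope)
      }
    }
    fa_vals <- pmin(pmax(0.45 + 0.04 * fa_z, 0), 1)
    fa <- data.frame(subject = contrast$subject_ids)
    fa[fa_names] <- as.data.frame(fa_vals)

    atlas <- generate_atlas(dims, config$n_atlas_regions,
                            seed = config$seed + 1L)

    truth <- list(true_sources = S, true_scores = A,
                  batch_assignments = batches,
                  planted_effects = list(
                    behavioral = config$behavioral_effects,
                    fa = config$fa_effect),
                  seed = config$seed)

    structure(list(contrast = contrast, behavior = behavior, fa = fa,
                   atlas = atlas, batches = batches, truth = truth,
                   config = config),
              class = "wmn_dataset")
  })
}

#' Generate a probabilistic gray-matter atlas of smoothed blobs
#'
#' Places `n_regions` seed points on the voxel grid by farthest-point
#' sampling (the first seed random, each further seed maximizing its minimum
#' distance to the chosen set) and builds one Gaussian probability blob per
#' region. Per-voxel probability sums are normalized to be at most 1.
#'
#' @param grid_dims Integer 3-vector of grid dimensions.
#' @param n_regions Number of atlas regions.
#' @param seed Integer seed.
#' @param blob_sd Gaussian radius of each region blob, in voxels.
#' @return A list of class `wmn_atlas` with `region_names`,
#'   `probability_maps` (regions x voxels, each in \[0, 1\]), and
#'   `voxel_coordinates`.
#' @export
generate_atlas <- function(grid_dims, n_regions = 20, seed = 1,
                           blob_sd = 3) {
  n <- prod(grid_dims)
  if (n_regions > n) {
    stop("n_regions exceeds the number of voxels in the grid", call. = FALSE)
  }
  with_seed(seed, {
    coords <- as.matrix(expand.grid(x = seq_len(grid_dims[1]),
                                    y = seq_len(grid_dims[2]),
                                    z = seq_len(grid_dims[3])))
    seeds <- integer(n_regions)
    seeds[1] <- sample.int(n, 1)
    if (n_regions > 1) {
      d2min <- colSums((t(coords) - coords[seeds[1], ])^2)
      for (r in 2:n_regions) {
        seeds[r] <- which.max(d2min)
        d2min <- pmin(d2min, colSums((t(coords) - coords[seeds[r], ])^2))
      }
    }
    P <- matrix(0, n_regions, n)
    for (r in seq_len(n_regions)) {
      d2 <- colSums((t(coords) - coords[seeds[r], ])^2)
      p <- exp(-d2 / (2 * blob_sd^2))
      p[p < 0.01] <- 0
      P[r, ] <- p
    }
    tot <- colSums(P)
    over <- tot > 1
    if (any(over)) {
      P[, over] <- sweep(P[, over, drop = FALSE], 2, tot[over], "/")
    }
    structure(list(region_names = sprintf("region_%02d", seq_len(n_regions)),
                   probability_maps = P,
                   voxel_coordinates = coords,
                   grid_dims = as.integer(grid_dims),
                   seeds = seeds),
              class = "wmn_atlas")
  })
}

#' Simulate trial-level n-back responses from a signal-detection responder
#'
#' For each stimulus of a schedule, the response is missing with probability
#' `miss_rate`; otherwise it is drawn from the equal-variance signal-detection
#' model: targets are answered "target" with probability
#' `pnorm(d_prime/2 - criterion)` and nontargets with probability
#' `pnorm(-d_prime/2 - criterion)`.
#'
#' @param schedule A `wmn_schedule` (see [build_schedule()]).
#' @param d_prime Planted sensitivity d'.
#' @param criterion Response criterion c (0 = unbiased).
#' @param miss_rate Probability of a missing response per stimulus, in
#'   \[0, 1\].
#' @param seed Integer seed or `NULL`.
#' @return A data.frame with columns `response`
#'   (`"target"`/`"nontarget"`/`NA`) and `rt_ms`, one row per stimulus.
#' @export
generate_trial_responses <- function(schedule, d_prime, criterion = 0,
                                     miss_rate = 0, seed = NULL) {
  stopifnot(miss_rate >= 0, miss_rate <= 1)
  n <- nrow(schedule)
  with_seed(seed, {
    p_target_resp <- ifelse(schedule$is_target,
                            stats::pnorm(d_prime / 2 - criterion),
                            stats::pnorm(-d_prime / 2 - criterion))
    resp <- ifelse(stats::runif(n) < p_target_resp, "target", "nontarget")
    rt <- round(stats::rlnorm(n, log(500), 0.25), 1)
    missing <- stats::runif(n) < miss_rate
    resp[missing] <- NA
    rt[missing] <- NA
    data.frame(response = resp, rt_ms = rt, stringsAsFactors = FALSE)
  })
}

#' Deterministic perfect response log for a schedule
#'
#' Answers every stimulus correctly with no missing responses; used to probe
#' the attainable d-prime ceiling under the extreme-proportion correction.
#'
#' @param schedule A `wmn_schedule`.
#' @return A response data.frame as in [generate_trial_responses()].
#' @export
perfect_responses <- function(schedule) {
  data.frame(response = ifelse(schedule$is_target, "target", "nontarget"),
             rt_ms = 500, stringsAsFactors = FALSE)
}
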