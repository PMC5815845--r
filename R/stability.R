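# Decomposition stability (disjoint-split bootstrap) and predictive validity
# (projection cross-validation with permutation nulls).

#' Match estimated components to a reference decomposition
#'
#' Maps each estimated component to the reference component maximizing the
#' absolute Pearson correlation of voxel loadings, recording the signed
#' correlation. The default greedy matching is per estimated component
#' without a uniqueness constraint (two estimated components may match the
#' same reference component); `method = "one_to_one"` instead assigns pairs
#' by repeatedly taking the globally largest remaining |r|.
#'
#' @param reference_S Reference loadings: `wmn_ica` or k_ref x voxels
#'   matrix.
#' @param estimated_S Estimated loadings over the same voxel set.
#' @param method "greedy" (default) or "one_to_one".
#' @return Data.frame with columns `estimated`, `reference`, `r`, `sign`.
#' @export
match_components <- function(reference_S, estimated_S, method = "greedy") {
  method <- match.arg(method, c("greedy", "one_to_one"))
  R <- if (inherits(reference_S, "wmn_ica")) reference_S$S else
    as.matrix(reference_S)
  E <- if (inherits(estimated_S, "wmn_ica")) estimated_S$S else
    as.matrix(estimated_S)
  stopifnot(ncol(R) == ncol(E))
  if (any(apply(R, 1, stats::sd) == 0) || any(apply(E, 1, stats::sd) == 0)) {
    stop("zero-variance source row", call. = FALSE)
  }
  C <- stats::cor(t(E), t(R))  # k_est x k_ref
  if (method == "greedy") {
    ref <- apply(abs(C), 1, which.max)
    r <- C[cbind(seq_len(nrow(C)), ref)]
    out <- data.frame(estimated = seq_len(nrow(C)), reference = ref, r = r,
                      sign = sign(r))
  } else {
    Cw <- abs(C)
    out <- data.frame()
    for (step in seq_len(min(nrow(C), ncol(C)))) {
      ij <- arrayInd(which.max(Cw), dim(Cw))
      r <- C[ij[1], ij[2]]
      out <- rbind(out, data.frame(estimated = ij[1], reference = ij[2],
                                   r = r, sign = sign(r)))
      Cw[ij[1], ] <- -Inf
      Cw[, ij[2]] <- -Inf
    }
    out <- out[order(out$estimated), ]
    rownames(out) <- NULL
  }
  out
}

# For each reference component, the best-matching estimated component with
# its signed correlation (used to align per-run decompositions before
# aggregation).
align_to_reference <- function(reference_S, estimated_S) {
  R <- if (inherits(reference_S, "wmn_ica")) reference_S$S else reference_S
  E <- if (inherits(estimated_S, "wmn_ica")) estimated_S$S else estimated_S
  C <- stats::cor(t(E), t(R))
  est <- apply(abs(C), 2, which.max)
  r <- C[cbind(est, seq_len(ncol(C)))]
  data.frame(reference = seq_len(ncol(C)), estimated = est, r = r,
             sign = sign(r))
}

#' Disjoint-split bootstrap of decomposition stability
#'
#' Repeats `n_runs` times: draw two disjoint subject subsamples of size
#' `subsample_size` (sampling without replacement), decompose each, match
#' both decompositions to the full-sample reference, and correlate the voxel
#' loadings of the matched component pair across the two subsamples. When a
#' behavioral table and predictors are supplied, the standardized
#' association model ([associate_components()]) is additionally fitted in
#' each subsample on sign-aligned scores and the coefficients averaged
#' across runs.
#'
#' @param X A [contrast_matrix()] or subjects x voxels matrix.
#' @param k Number of components.
#' @param subsample_size Subjects per subsample (2 x size <= m).
#' @param n_runs Number of bootstrap runs (default 100).
#' @param seed Integer seed.
#' @param behavior Optional behavioral data.frame aligned with subjects.
#' @param predictors Optional character vector of predictor columns in
#'   `behavior`.
#' @param reference Optional precomputed full-sample `wmn_ica` reference.
#' @param ... Passed to [fastica_decompose()].
#' @return List of class `wmn_stability` with `runs` (per run and reference
#'   component: split correlation and per-subsample match correlations),
#'   `summary` (per component: mean |r| across runs), optional `betas`
#'   (averaged sign-aligned coefficients with mean standard errors), and
#'   `params`.
#' @export
bootstrap_stability <- function(X, k, subsample_size, n_runs = 100,
                                seed = 1, behavior = NULL,
                                predictors = NULL, reference = NULL, ...) {
  vals <- if (inherits(X, "contrast_matrix")) X$values else as.matrix(X)
  m <- nrow(vals)
  stopifnot(2 * subsample_size <= m)
  if (is.null(reference)) {
    reference <- fastica_decompose(X, k, seed = seed, ...)
  }
  runs <- list()
  beta_acc <- NULL
  se_acc <- NULL
  n_beta <- 0L
  for (run in seq_len(n_runs)) {
    run_seed <- seed + run
    idx <- with_seed(run_seed, sample.int(m, 2 * subsample_size))
    s1 <- idx[seq_len(subsample_size)]
    s2 <- idx[subsample_size + seq_len(subsample_size)]
    d1 <- fastica_decompose(vals[s1, , drop = FALSE], k, seed = run_seed, ...)
    d2 <- fastica_decompose(vals[s2, , drop = FALSE], k,
                            seed = run_seed + 1L, ...)
    a1 <- align_to_reference(reference, d1)
    a2 <- align_to_reference(reference, d2)
    r_split <- vapply(seq_len(k), function(c) {
      stats::cor(d1$S[a1$estimated[c], ], d2$S[a2$estimated[c], ])
    }, numeric(1))
    runs[[run]] <- data.frame(run = run, component = seq_len(k),
                              r_split = r_split, r_ref1 = a1$r,
                              r_ref2 = a2$r)
    if (!is.null(behavior) && !is.null(predictors)) {
      for (sub in list(list(s = s1, d = d1, a = a1),
                       list(s = s2, d = d2, a = a2))) {
        scores <- sub$d$A[, sub$a$estimated, drop = FALSE] %*%
          diag(sub$a$sign, k)
        res <- associate_components(scores, behavior[sub$s, , drop = FALSE],
                                    predictors)
        se <- abs(res$beta / res$t)
        if (is.null(beta_acc)) {
          beta_acc <- res$beta * 0
          se_acc <- beta_acc
          beta_key <- res[, c("component", "term")]
        }
        beta_acc <- beta_acc + res$beta
        se_acc <- se_acc + se
        n_beta <- n_beta + 1L
      }
    }
  }
  runs <- do.call(rbind, runs)
  summary <- stats::aggregate(cbind(abs_r_split = abs(runs$r_split)),
                              by = list(component = runs$component), mean)
  betas <- NULL
  if (n_beta > 0) {
    betas <- cbind(beta_key,
                   mean_beta = beta_acc / n_beta,
                   mean_se = se_acc / n_beta)
  }
  structure(list(runs = runs, summary = summary, betas = betas,
                 params = list(k = k, subsample_size = subsample_size,
                               n_runs = n_runs, seed = seed)),
            class = "wmn_stability")
}

#' Projection cross-validation of component-behavior associations
#'
#' Repeats `n_runs` times: split the subjects into disjoint training and
#' test subsamples, decompose the training subjects, align components to the
#' full-sample reference, project the training sources onto the test
#' subjects ([project_scores()]), and regress each reported component's
#' projected (sign-aligned) scores on the performance measures and
#' covariates. Reports, per (component, measure), the percentage of runs
#' with nominal p < 0.05 and the mean standardized coefficient.
#'
#' @param X A [contrast_matrix()] or subjects x voxels matrix.
#' @param behavior Behavioral data.frame aligned with subjects.
#' @param k Number of components.
#' @param measures Character vector of performance-measure columns.
#' @param covariates Character vector of covariate columns (default sex and
#'   age).
#' @param components Reference components to report (default all).
#' @param train_size Training subjects per run (default m - test_size).
#' @param test_size Test subjects per run (default 100).
#' @param n_runs Number of runs (default 100).
#' @param seed Integer seed.
#' @param reference Optional precomputed full-sample `wmn_ica`.
#' @param ... Passed to [fastica_decompose()].
#' @return Object of class `wmn_crossval` with `percent` (per component x
#'   measure: percent of runs significant), `mean_beta`, `results` (per-run
#'   coefficient table), cached `runs` (test indices and projected scores,
#'   reused by [permutation_empirical_p()]), and `params`.
#' @export
cross_validate <- function(X, behavior, k, measures,
                           covariates = c("sex", "age"),
                           components = NULL, train_size = NULL,
                           test_size = 100, n_runs = 100, seed = 1,
                           reference = NULL, ...) {
  vals <- if (inherits(X, "contrast_matrix")) X$values else as.matrix(X)
  m <- nrow(vals)
  if (is.null(train_size)) train_size <- m - test_size
  stopifnot(train_size + test_size <= m, nrow(behavior) == m)
  if (is.null(components)) components <- seq_len(k)
  if (is.null(reference)) {
    reference <- fastica_decompose(X, k, seed = seed, ...)
  }

  runs <- vector("list", n_runs)
  rows <- list()
  for (run in seq_len(n_runs)) {
    run_seed <- seed + run
    idx <- with_seed(run_seed, sample.int(m, train_size + test_size))
    train <- idx[seq_len(train_size)]
    test <- idx[train_size + seq_len(test_size)]
    d <- fastica_decompose(vals[train, , drop = FALSE], k, seed = run_seed,
                           ...)
    al <- align_to_reference(reference, d)
    proj <- project_scores(d$S, vals[test, , drop = FALSE])
    aligned <- proj[, al$estimated, drop = FALSE] %*% diag(al$sign, k)
    runs[[run]] <- list(test = test, scores = aligned[, components,
                                                      drop = FALSE])
    for (ci in seq_along(components)) {
      fit <- fit_ic_model(aligned[, components[ci]],
                          behavior[test, measures, drop = FALSE],
                          covariates = behavior[test, covariates,
                                                drop = FALSE])
      fit <- fit[fit$role == "predictor", c("term", "beta", "p")]
      fit$component <- components[ci]
      fit$run <- run
      rows[[length(rows) + 1]] <- fit
    }
  }
  results <- do.call(rbind, rows)
  percent <- stats::aggregate(cbind(percent = 100 * (results$p < 0.05)),
                              by = list(component = results$component,
                                        term = results$term), mean)
  mean_beta <- stats::aggregate(cbind(mean_beta = results$beta),
                                by = list(component = results$component,
                                          term = results$term), mean)
  structure(list(percent = percent, mean_beta = mean_beta,
                 results = results, runs = runs,
                 params = list(k = k, components = components,
                               measures = measures, covariates = covariates,
                               train_size = train_size,
                               test_size = test_size, n_runs = n_runs,
                               seed = seed)),
            class = "wmn_crossval")
}

#' Permutation null and empirical p for cross-validation rates
#'
#' Builds the null distribution of the percent-significant statistic by
#' permuting the performance-measure columns across subjects (covariates
#' stay attached to their subjects) and re-running the cross-validation
#' regressions. Because permuting the outcome side leaves the per-run
#' decompositions and projected scores unchanged, those are reused from the
#' fitted [cross_validate()] object and only the regressions are recomputed.
#' The empirical p value uses the add-one estimator
#' `(1 + #{null >= observed}) / (n_outer + 1)`.
#'
#' @param cv A `wmn_crossval` object.
#' @param behavior The behavioral data.frame used to fit `cv`.
#' @param n_outer Number of outer permutation repeats (default 1000).
#' @param seed Integer seed.
#' @return List with `observed` (per component x measure percent),
#'   `null` (n_outer x cells matrix of null percentages), and `empirical_p`
#'   data.frame.
#' @export
permutation_empirical_p <- function(cv, behavior, n_outer = 1000, seed = 1) {
  stopifnot(inherits(cv, "wmn_crossval"), n_outer >= 1)
  measures <- cv$params$measures
  covariates <- cv$params$covariates
  components <- cv$params$components
  m <- nrow(behavior)
  obs <- cv$percent

  cells <- obs[, c("component", "term")]
  null_mat <- matrix(NA_real_, n_outer, nrow(cells))

  for (b in seq_len(n_outer)) {
    perm <- with_seed(seed + b, sample.int(m))
    beh_perm <- behavior
    beh_perm[, measures] <- behavior[perm, measures, drop = FALSE]
    sig <- numeric(nrow(cells))
    counts <- numeric(nrow(cells))
    for (run in cv$runs) {
      for (ci in seq_along(components)) {
        fit <- fit_ic_model(run$scores[, ci],
                            beh_perm[run$test, measures, drop = FALSE],
                            covariates = beh_perm[run$test, covariates,
                                                  drop = FALSE])
        fit <- fit[fit$role == "predictor", ]
        for (ti in seq_len(nrow(fit))) {
          cell <- which(cells$component == components[ci] &
                          cells$term == fit$term[ti])
          counts[cell] <- counts[cell] + 1
          sig[cell] <- sig[cell] + (fit$p[ti] < 0.05)
        }
      }
    }
    null_mat[b, ] <- 100 * sig / counts
  }
  emp <- vapply(seq_len(nrow(cells)), function(cell) {
    (1 + sum(null_mat[, cell] >= obs$percent[cell])) / (n_outer + 1)
  }, numeric(1))
  list(observed = obs,
       null = null_mat,
       empirical_p = cbind(cells, observed_percent = obs$percent,
                           null_mean = colMeans(null_mat),
                           empirical_p = emp))
}
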