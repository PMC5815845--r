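# Region-wise white-matter (fractional anisotropy) association tests for
# component subject scores.

fa_region_columns <- function(fa_table) {
  num <- vapply(fa_table, is.numeric, logical(1))
  names(fa_table)[num & names(fa_table) != "subject"]
}

#' Region-wise regressions of component scores on FA
#'
#' For each white-matter region, fits a standardized linear model with the
#' component's subject scores as dependent variable and the region's mean FA
#' as independent variable, adjusting for the supplied covariates (sex, age,
#' handedness, intracranial volume, remaining components' scores). When
#' region columns come in `_left`/`_right` hemisphere pairs and
#' `hemisphere_scopes = TRUE`, an additional "both" scope averaging each
#' pair is fitted, and the BH-FDR correction spans all scopes x regions
#' jointly.
#'
#' @param scores Numeric vector of one component's subject scores.
#' @param fa_table Data.frame of per-subject region FA means (columns ending
#'   in `_left`/`_right` define hemisphere pairs).
#' @param covariates Data.frame of covariates aligned with `scores`.
#' @param regions Optional character vector restricting the region columns.
#' @param hemisphere_scopes Also fit averaged both-hemisphere models
#'   (default `FALSE`).
#' @param alpha FDR level.
#' @return Data.frame with one row per (scope, region): `region`, `scope`,
#'   `beta`, `t`, `df`, `p`, `q`, `significant`; attribute `family_size`.
#' @export
fit_fa_models <- function(scores, fa_table, covariates = NULL,
                          regions = NULL, hemisphere_scopes = FALSE,
                          alpha = 0.05) {
  regions <- regions %||% fa_region_columns(fa_table)
  stopifnot(length(regions) >= 1)
  n <- length(scores)
  stopifnot(nrow(fa_table) == n)
  if (n <= (NCOL(covariates) %||% 0) + 2) {
    stop("too few subjects for the FA design", call. = FALSE)
  }

  fit_one <- function(fa_col, region, scope) {
    if (stats::sd(fa_col) < .Machine$double.eps^0.5) {
      stop(sprintf("degenerate predictor: FA column '%s' is constant",
                   region), call. = FALSE)
    }
    fit <- fit_ic_model(scores, data.frame(fa = fa_col),
                        covariates = covariates)
    fit <- fit[fit$term == "fa", ]
    data.frame(region = region, scope = scope, beta = fit$beta, t = fit$t,
               df = fit$df, p = fit$p, stringsAsFactors = FALSE)
  }

  rows <- lapply(regions, function(r) {
    scope <- if (grepl("_left$", r)) "left" else
      if (grepl("_right$", r)) "right" else "all"
    fit_one(fa_table[[r]], r, scope)
  })

  if (hemisphere_scopes) {
    lefts <- grep("_left$", regions, value = TRUE)
    for (l in lefts) {
      r <- sub("_left$", "_right", l)
      if (r %in% regions) {
        base <- sub("_left$", "", l)
        both <- (fa_table[[l]] + fa_table[[r]]) / 2
        rows[[length(rows) + 1]] <- fit_one(both, base, "both")
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- fdr_across_tests(out, alpha)
  out
}

#' Kolmogorov-Smirnov test of p-value uniformity
#'
#' Two-sided one-sample KS test of a p-value vector against Uniform(0, 1);
#' asymptotic by default (exact small-sample p available). Applied per
#' component to the per-region FA p values, a global score-FA association
#' shows up as departure from uniformity.
#'
#' @param p_values Numeric vector in \[0, 1\], length >= 1.
#' @param exact Use the exact small-sample distribution (default `FALSE`).
#' @return List with `D` (statistic) and `p`.
#' @export
ks_uniformity <- function(p_values, exact = FALSE) {
  if (length(p_values) == 0) stop("empty p-value vector", call. = FALSE)
  stopifnot(all(p_values >= 0 & p_values <= 1))
  kt <- suppressWarnings(stats::ks.test(p_values, "punif", exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Permutation empirical p for the count of nominal FA associations
#'
#' The observed statistic is the number of regions with nominal p < 0.05 in
#' [fit_fa_models()]. The null distribution permutes the component's scores
#' across subjects `n_perm` times (covariates stay attached to their
#' subjects, leaving the covariate-FA linkage intact) and recounts; the
#' empirical p is the add-one estimator
#' `(1 + #{null count >= observed}) / (n_perm + 1)`. Refits are vectorized
#' over permutations through the fixed per-region QR decompositions.
#'
#' @param scores Component subject scores.
#' @param fa_table FA data.frame as in [fit_fa_models()].
#' @param covariates Covariate data.frame.
#' @param n_perm Number of permutations (>= 1; default 10000).
#' @param seed Integer seed.
#' @param regions Optional restriction of region columns.
#' @return List with `observed_count`, `null_counts`, `empirical_p`, and
#'   `n_regions`.
#' @export
empirical_fa_p <- function(scores, fa_table, covariates = NULL,
                           n_perm = 10000, seed = 1, regions = NULL) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  regions <- regions %||% fa_region_columns(fa_table)
  observed <- fit_fa_models(scores, fa_table, covariates, regions = regions)
  observed_count <- sum(observed$p < 0.05)

  n <- length(scores)
  y <- zscore(as.numeric(scores))
  Yp <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) y[sample.int(n)], numeric(n))
  })

  cov_mat <- if (!is.null(covariates) && NCOL(covariates) > 0) {
    zscore_frame(covariates)
  } else {
    NULL
  }
  null_sig <- matrix(FALSE, n_perm, length(regions))
  yp_sq <- colSums(Yp^2)
  for (ri in seq_along(regions)) {
    fa_col <- zscore(as_numeric_column(fa_table[[regions[ri]]]))
    D <- cbind(1, fa = fa_col)
    if (!is.null(cov_mat)) D <- cbind(D, cov_mat)
    df <- n - ncol(D)
    XtX_inv <- solve(crossprod(D))
    DtY <- crossprod(D, Yp)                      # ncol(D) x n_perm
    coefs <- XtX_inv %*% DtY
    rss <- yp_sq - colSums(DtY * coefs)
    sigma2 <- rss / df
    t_stat <- coefs[2, ] / sqrt(sigma2 * XtX_inv[2, 2])
    p_val <- 2 * stats::pt(-abs(t_stat), df)
    null_sig[, ri] <- p_val < 0.05
  }
  null_counts <- rowSums(null_sig)
  list(observed_count = observed_count,
       null_counts = null_counts,
       empirical_p = (1 + sum(null_counts >= observed_count)) / (n_perm + 1),
       n_regions = length(regions))
}

#' Global FA-association summary across all components
#'
#' For each component of a score matrix: the per-region FA regressions (with
#' the remaining components' scores appended to the covariates), the KS
#' uniformity test of the region p values, and the permutation empirical p,
#' with BH-FDR correction of the KS and empirical p values across
#' components.
#'
#' @param A Subjects x k score matrix (or `wmn_ica`).
#' @param fa_table FA data.frame.
#' @param covariates Covariate data.frame (sex, age, handedness, icv, ...).
#' @param n_perm Permutations for the empirical p (default 10000).
#' @param seed Integer seed.
#' @param alpha FDR level.
#' @return Data.frame with one row per component: `ks_D`, `ks_p`, `ks_q`,
#'   `observed_count`, `empirical_p`, `empirical_q`.
#' @export
fa_global_tests <- function(A, fa_table, covariates = NULL, n_perm = 10000,
                            seed = 1, alpha = 0.05) {
  A_mat <- if (inherits(A, "wmn_ica")) A$A else as.matrix(A)
  k <- ncol(A_mat)
  rows <- lapply(seq_len(k), function(j) {
    others <- A_mat[, -j, drop = FALSE]
    colnames(others) <- paste0("ic", setdiff(seq_len(k), j), "_score")
    covs <- if (!is.null(covariates)) {
      cbind(as.data.frame(covariates), as.data.frame(others))
    } else {
      as.data.frame(others)
    }
    fits <- fit_fa_models(A_mat[, j], fa_table, covs)
    ks <- ks_uniformity(fits$p)
    emp <- empirical_fa_p(A_mat[, j], fa_table, covs, n_perm = n_perm,
                          seed = seed + j)
    data.frame(component = j, ks_D = ks$D, ks_p = ks$p,
               observed_count = emp$observed_count,
               empirical_p = emp$empirical_p)
  })
  out <- do.call(rbind, rows)
  out$ks_q <- bh_fdr(out$ks_p, alpha)$q
  out$empirical_q <- bh_fdr(out$empirical_p, alpha)$q
  out
}
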