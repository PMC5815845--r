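# Standardized multiple-regression associations between component subject
# scores (or single voxels) and behavior, with family-wise BH-FDR control.

#' Iterative collinearity filter on candidate predictors
#'
#' Scans predictor pairs in the declared priority order (column order) and,
#' whenever a pair correlates beyond `threshold` in absolute value, drops
#' the later (lower-priority) member; repeats until no remaining pair
#' exceeds the bound.
#'
#' @param predictors Data.frame or matrix of candidate predictors; factors
#'   are coded numerically for the correlation screen.
#' @param threshold Absolute Pearson correlation bound (default 0.5).
#' @return The retained predictors (same type as the input), with attribute
#'   `dropped` listing removed column names.
#' @export
collinearity_filter <- function(predictors, threshold = 0.5) {
  df <- as.data.frame(predictors)
  stopifnot(ncol(df) >= 2)
  num <- vapply(df, as_numeric_column, numeric(nrow(df)))
  keep <- colnames(num)
  repeat {
    r <- stats::cor(num[, keep, drop = FALSE])
    hit <- NULL
    for (i in seq_along(keep)) {
      for (j in seq_along(keep)) {
        if (j > i && abs(r[i, j]) > threshold) { hit <- c(i, j); break }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    keep <- keep[-hit[2]]
  }
  out <- predictors[, keep, drop = FALSE]
  attr(out, "dropped") <- setdiff(colnames(num), keep)
  out
}

#' Standardized multiple regression of component scores on behavior
#'
#' Ordinary least squares with every variable z-transformed (factors coded
#' numerically first), so the coefficients are standardized betas. Two-sided
#' t tests with df = n - p - 1; variance explained per term is the squared
#' partial correlation t^2 / (t^2 + df). Underflowing p values are floored
#' at 1e-300.
#'
#' @param scores Numeric outcome vector (one component's subject scores).
#' @param predictors Data.frame/matrix of predictors of interest.
#' @param covariates Optional data.frame/matrix of covariates (e.g. the
#'   remaining components' scores); modeled jointly but flagged by role.
#' @return A data.frame of class `association_result` with one row per
#'   model term: `term`, `role` ("predictor"/"covariate"), `beta`, `t`,
#'   `df`, `p`, `r_squared`, plus attributes `n` and `terms`.
#' @export
fit_ic_model <- function(scores, predictors, covariates = NULL) {
  y <- zscore(as.numeric(scores))
  Xp <- zscore_frame(predictors)
  X <- if (!is.null(covariates) && NCOL(covariates) > 0) {
    cbind(Xp, zscore_frame(covariates))
  } else {
    Xp
  }
  role <- c(rep("predictor", ncol(Xp)),
            rep("covariate", ncol(X) - ncol(Xp)))
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("too few complete cases for the design", call. = FALSE)
  D <- cbind(`(Intercept)` = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    aliased <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
    stop(sprintf("singular design; aliased columns: %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm.fit(D, y)
  df <- n - p - 1
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtX_inv <- solve(crossprod(D))
  se <- sqrt(sigma2 * diag(XtX_inv))
  beta <- fit$coefficients
  t_stat <- beta / se
  p_val <- pmax(2 * stats::pt(-abs(t_stat), df), 1e-300)
  out <- data.frame(term = colnames(X),
                    role = role,
                    beta = unname(beta[-1]),
                    t = unname(t_stat[-1]),
                    df = df,
                    p = unname(p_val[-1]),
                    stringsAsFactors = FALSE)
  out$r_squared <- variance_explained(out$t, out$df)
  attr(out, "n") <- n
  class(out) <- c("association_result", "data.frame")
  out
}

#' Variance explained as squared partial correlation
#'
#' @param t t statistic(s).
#' @param df Residual degrees of freedom (> 0).
#' @return `t^2 / (t^2 + df)`.
#' @export
variance_explained <- function(t, df) {
  stopifnot(all(df > 0))
  t^2 / (t^2 + df)
}

#' BH-FDR adjustment across a declared family of association tests
#'
#' @param results Data.frame with a `p` column (e.g. stacked
#'   [fit_ic_model()] rows across components).
#' @param alpha FDR level (default 0.05).
#' @return `results` with added `q` and `significant` columns and attribute
#'   `family_size`.
#' @export
fdr_across_tests <- function(results, alpha = 0.05) {
  adj <- bh_fdr(results$p, alpha)
  results$q <- adj$q
  results$significant <- adj$reject
  attr(results, "family_size") <- nrow(results)
  results
}

#' Associate every component's scores with behavior in one family
#'
#' Fits one standardized multiple regression per component ([fit_ic_model()])
#' with the remaining components' scores appended to the covariates, then
#' BH-FDR-corrects the predictor tests over the full
#' `length(predictors) x k` family (e.g. 18 predictors x 6 components =
#' 108 tests).
#'
#' @param A Subjects x k score matrix (or `wmn_ica` decomposition).
#' @param data Behavioral data.frame, one row per subject.
#' @param predictors Character vector of predictor column names in `data`
#'   (performances and covariates entering the FDR family).
#' @param alpha FDR level.
#' @return Data.frame with one row per (component, predictor):
#'   `component`, `term`, `beta`, `t`, `df`, `p`, `q`, `significant`,
#'   `r_squared`; attribute `family_size`.
#' @export
associate_components <- function(A, data, predictors, alpha = 0.05) {
  A_mat <- if (inherits(A, "wmn_ica")) A$A else as.matrix(A)
  k <- ncol(A_mat)
  stopifnot(nrow(A_mat) == nrow(data))
  rows <- lapply(seq_len(k), function(j) {
    others <- A_mat[, -j, drop = FALSE]
    colnames(others) <- paste0("ic", setdiff(seq_len(k), j), "_score")
    fit <- fit_ic_model(A_mat[, j], data[, predictors, drop = FALSE],
                        covariates = as.data.frame(others))
    fit <- fit[fit$role == "predictor",
               c("term", "beta", "t", "df", "p", "r_squared")]
    fit$component <- j
    fit
  })
  res <- do.call(rbind, rows)
  res <- res[, c("component", "term", "beta", "t", "df", "p", "r_squared")]
  res <- fdr_across_tests(res, alpha)
  attr(res, "family_size") <- length(predictors) * k
  res
}

#' Voxel-wise standardized regression of contrast values on behavior
#'
#' Regresses every voxel's (z-scored) contrast values on the same z-scored
#' behavioral design, without component-score covariates, and BH-FDR-corrects
#' jointly over the predictors x voxels family.
#'
#' @param X A [contrast_matrix()] or subjects x voxels matrix (complete
#'   data).
#' @param predictors Data.frame of behavioral predictors, one row per
#'   subject.
#' @param alpha FDR level.
#' @return List with matrices `beta`, `t`, `p`, `q`, `significant`
#'   (predictors x voxels), scalar `df`, and `family_size`.
#' @export
voxelwise_model <- function(X, predictors, alpha = 0.05) {
  vals <- if (inherits(X, "contrast_matrix")) X$values else as.matrix(X)
  Xd <- zscore_frame(predictors)
  n <- nrow(vals)
  stopifnot(nrow(Xd) == n)
  p <- ncol(Xd)
  if (n <= p + 1) stop("too few subjects for the design", call. = FALSE)
  Y <- scale(vals)
  if (anyNA(Y)) stop("constant voxel in contrast matrix", call. = FALSE)
  D <- cbind(1, Xd)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) stop("singular behavioral design", call. = FALSE)
  coefs <- qr.coef(qrD, Y)              # (p+1) x voxels
  fitted <- qr.fitted(qrD, Y)
  df <- n - p - 1
  rss <- colSums((Y - fitted)^2)
  sigma2 <- rss / df
  XtX_inv_diag <- diag(solve(crossprod(D)))
  se <- sqrt(outer(XtX_inv_diag, sigma2))
  t_stat <- coefs / se
  beta <- coefs[-1, , drop = FALSE]
  t_stat <- t_stat[-1, , drop = FALSE]
  p_val <- pmax(2 * stats::pt(-abs(t_stat), df), 1e-300)
  adj <- bh_fdr(as.vector(p_val), alpha)
  q <- matrix(adj$q, nrow(p_val), ncol(p_val),
              dimnames = dimnames(p_val))
  sig <- matrix(adj$reject, nrow(p_val), ncol(p_val))
  rownames(beta) <- rownames(t_stat) <- rownames(p_val) <- colnames(Xd)
  list(beta = beta, t = t_stat, p = p_val, q = q, significant = sig,
       df = df, family_size = length(p_val))
}
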