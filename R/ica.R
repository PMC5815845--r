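# Spatial ICA of subject contrast maps.
#
# Orientation: voxels are the observations and subjects the variables, so the
# estimated sources are spatial maps (statistically independent across
# voxels) and the mixing coefficients are per-subject component scores with
# X ~= A %*% S in the retained k-dimensional subspace.

# Accept either a contrast_matrix or a plain subjects x voxels matrix and
# return the voxels x subjects matrix with each subject's map standardized
# (mean 0, unit variance across voxels).
voxels_by_subjects <- function(X, scale_subjects = TRUE) {
  vals <- if (inherits(X, "contrast_matrix")) X$values else as.matrix(X)
  if (anyNA(vals)) stop("contrast matrix contains missing values; run missing_data_filter() first",
                        call. = FALSE)
  Xv <- t(vals)
  if (scale_subjects) {
    Xv <- scale(Xv)
    if (anyNA(Xv)) stop("at least one subject map is constant", call. = FALSE)
    attributes(Xv)[c("scaled:center", "scaled:scale")] <- NULL
  }
  Xv
}

#' PCA eigenvalue spectrum (scree) of the masked contrast matrix
#'
#' Eigenvalues of the subject-by-subject correlation structure after
#' per-subject centering and scaling, in descending order, together with
#' cumulative variance fractions. Used to choose the number of independent
#' components to extract; the choice of k itself is left to the analyst.
#'
#' @param X A [contrast_matrix()] or subjects x voxels matrix.
#' @return List with `eigenvalues` and `cumulative_variance`.
#' @export
pca_scree <- function(X) {
  Xv <- voxels_by_subjects(X)
  if (nrow(Xv) < 2 || ncol(Xv) < 2) {
    stop("need at least 2 subjects and 2 voxels", call. = FALSE)
  }
  ev <- eigen(crossprod(Xv) / (nrow(Xv) - 1), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  list(eigenvalues = ev, cumulative_variance = cumsum(ev) / sum(ev))
}

symmetric_decorrelate <- function(W) {
  e <- eigen(crossprod(W), symmetric = TRUE)
  W %*% e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors)
}

#' Fixed-point FastICA decomposition of a contrast matrix
#'
#' Spatial ICA with the fixed-point FastICA algorithm: each subject's map is
#' centered and scaled, the data are PCA-whitened to `k` dimensions, and
#' symmetric (parallel) fixed-point updates with the log-cosh contrast are
#' iterated until the maximal change in the unmixing directions falls below
#' `tol`. Sources (voxel loadings) are z-scaled per component; subject scores
#' are the least-squares mixing coefficients so that `A %*% S` reconstructs
#' the standardized data in the retained subspace. The sign convention of
#' [enforce_sign_convention()] is applied and components are ordered by
#' decreasing score variance. On non-convergence the decomposition is
#' restarted from up to `restarts` fresh random initializations.
#'
#' @param X A [contrast_matrix()] or subjects x voxels matrix (complete
#'   data).
#' @param k Number of components to extract (chosen externally, e.g. from
#'   [pca_scree()]).
#' @param seed Integer seed for the random initial unmixing matrix.
#' @param tol Convergence tolerance (default 1e-6).
#' @param max_iter Maximum fixed-point iterations per restart (default 1000).
#' @param restarts Maximum number of random restarts on non-convergence.
#' @param alpha Slope parameter of the log-cosh contrast, in \[1, 2\].
#' @return An object of class `wmn_ica` with elements `S` (k x voxels
#'   z-scaled loadings), `A` (subjects x k scores), `k`, `eigenvalues`,
#'   `cumulative_variance`, `iterations`, `converged`, `seed`, `tolerance`,
#'   `max_iterations`, `nonlinearity`.
#' @export
fastica_decompose <- function(X, k, seed = 1, tol = 1e-6, max_iter = 1000,
                              restarts = 5, alpha = 1) {
  Xv <- voxels_by_subjects(X)
  n <- nrow(Xv)
  m <- ncol(Xv)
  if (k > min(n, m)) stop("k exceeds min(subjects, voxels)", call. = FALSE)

  ev <- eigen(crossprod(Xv) / (n - 1), symmetric = TRUE)
  rank <- sum(ev$values > max(ev$values) * 1e-10)
  if (k > rank) {
    stop(sprintf("k = %d exceeds the numerical rank %d of the data", k, rank),
         call. = FALSE)
  }
  K <- ev$vectors[, seq_len(k), drop = FALSE] %*%
    diag(1 / sqrt(ev$values[seq_len(k)]), k)
  Z <- Xv %*% K  # n x k, crossprod(Z)/(n-1) = I

  run_fastica <- function(W) {
    W <- symmetric_decorrelate(W)
    for (it in seq_len(max_iter)) {
      G <- tanh(alpha * (Z %*% W))
      W1 <- crossprod(Z, G) / n -
        sweep(W, 2, alpha * colMeans(1 - G^2), "*")
      W1 <- symmetric_decorrelate(W1)
      delta <- max(abs(abs(colSums(W1 * W)) - 1))
      W <- W1
      if (delta < tol) return(list(W = W, iterations = it, converged = TRUE))
    }
    list(W = W, iterations = max_iter, converged = FALSE)
  }

  fit <- NULL
  for (r in seq_len(max(1, restarts))) {
    W0 <- with_seed(seed + r - 1L, matrix(stats::rnorm(k * k), k, k))
    fit <- run_fastica(W0)
    if (fit$converged) break
  }
  if (!fit$converged) {
    warning(sprintf("FastICA did not converge in %d iterations (%d restarts)",
                    max_iter, max(1, restarts)), call. = FALSE)
  }

  S <- t(Z %*% fit$W)  # k x n voxel loadings
  S <- t(apply(S, 1, function(s) (s - mean(s)) / stats::sd(s)))
  S <- matrix(S, k, n)

  # Subject scores: least-squares mixing coefficients of each standardized
  # subject map on the sources (identical to project_scores on the training
  # data).
  A <- t(qr.coef(qr(t(S)), Xv))  # m x k

  decomp <- structure(list(S = S, A = A, k = k,
                           eigenvalues = pmax(ev$values, 0),
                           cumulative_variance =
                             cumsum(pmax(ev$values, 0)) / sum(pmax(ev$values, 0)),
                           iterations = fit$iterations,
                           converged = fit$converged,
                           seed = seed, tolerance = tol,
                           max_iterations = max_iter,
                           nonlinearity = "logcosh"),
                      class = "wmn_ica")
  decomp <- enforce_sign_convention(decomp)
  ord <- order(apply(decomp$A, 2, stats::var), decreasing = TRUE)
  decomp$S <- decomp$S[ord, , drop = FALSE]
  decomp$A <- decomp$A[, ord, drop = FALSE]
  decomp
}

#' @export
print.wmn_ica <- function(x, ...) {
  cat(sprintf("<wmn_ica> k = %d components, %d subjects x %d voxels; %s after %d iterations\n",
              x$k, nrow(x$A), ncol(x$S),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Recode component signs so peak loadings are positive
#'
#' The direction of an ICA estimate is arbitrary; every component whose
#' maximum-absolute-loading voxel carries a negative loading is negated
#' (source row and score column together), leaving the reconstruction
#' `A %*% S` unchanged. Idempotent.
#'
#' @param decomp A `wmn_ica` decomposition.
#' @return The decomposition with the sign convention enforced.
#' @export
enforce_sign_convention <- function(decomp) {
  for (j in seq_len(decomp$k)) {
    peak <- which.max(abs(decomp$S[j, ]))
    if (decomp$S[j, peak] < 0) {
      decomp$S[j, ] <- -decomp$S[j, ]
      decomp$A[, j] <- -decomp$A[, j]
    }
  }
  decomp
}

#' Pooled absolute-loading threshold across components
#'
#' Computes the empirical `1 - fraction` quantile of the absolute voxel
#' loadings pooled over all components (the default 0.10 retains the 10%
#' most extreme values) and returns per-component supra-threshold masks,
#' split by loading sign.
#'
#' @param S A `wmn_ica` decomposition or a k x voxels loading matrix.
#' @param fraction Fraction of pooled loadings to retain, in (0, 1].
#' @return List of class `wmn_threshold` with `threshold`, `fraction`
#'   (requested), `fraction_retained`, and logical matrices `positive`,
#'   `negative` (k x voxels).
#' @export
pooled_threshold <- function(S, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  S_mat <- if (inherits(S, "wmn_ica")) S$S else as.matrix(S)
  pooled <- abs(as.vector(S_mat))
  thr <- if (fraction == 1) 0 else
    unname(stats::quantile(pooled, 1 - fraction, type = 7))
  structure(list(threshold = thr, fraction = fraction,
                 fraction_retained = mean(pooled > thr),
                 positive = S_mat > thr, negative = S_mat < -thr),
            class = "wmn_threshold")
}

#' Project fixed spatial sources onto new subjects' contrast maps
#'
#' Dual-regression-style scoring of new subjects: after the same per-subject
#' centering and scaling as in training, each new subject's map is regressed
#' on the k source maps and the least-squares coefficients are returned as
#' that subject's component scores. Exact for correlated (non-orthogonal)
#' sources.
#'
#' @param S A `wmn_ica` decomposition or k x voxels loading matrix.
#' @param X_new A [contrast_matrix()] or subjects x voxels matrix over the
#'   same voxel set.
#' @param scale_subjects Standardize each new subject's map first (default
#'   `TRUE`, matching training preprocessing).
#' @return New-subjects x k score matrix.
#' @export
project_scores <- function(S, X_new, scale_subjects = TRUE) {
  S_mat <- if (inherits(S, "wmn_ica")) S$S else as.matrix(S)
  Xv <- voxels_by_subjects(X_new, scale_subjects = scale_subjects)
  if (nrow(Xv) != ncol(S_mat)) {
    stop("voxel sets of sources and new data are not aligned", call. = FALSE)
  }
  qrS <- qr(t(S_mat))
  if (qrS$rank < nrow(S_mat)) {
    stop("rank-deficient source matrix", call. = FALSE)
  }
  t(qr.coef(qrS, Xv))
}
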