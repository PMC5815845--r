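#' Construct a subjects-by-voxels contrast matrix
#'
#' Container for first-level 2-back minus 0-back contrast estimates: a
#' numeric subjects x voxels matrix together with the integer voxel
#' coordinates, an explicit missingness mask, and subject identifiers.
#'
#' @param values Subjects x voxels numeric matrix; `NA` entries are treated
#'   as missing.
#' @param coordinates Voxels x 3 integer matrix of voxel coordinates; rows
#'   must be unique.
#' @param missing Optional subjects x voxels logical matrix; merged with
#'   `is.na(values)`.
#' @param subject_ids Optional character vector of subject identifiers.
#' @param grid_dims Optional integer 3-vector recording the full voxel grid.
#' @return An object of class `contrast_matrix`.
#' @export
contrast_matrix <- function(values, coordinates, missing = NULL,
                            subject_ids = NULL, grid_dims = NULL) {
  values <- as.matrix(values)
  coordinates <- as.matrix(coordinates)
  stopifnot(ncol(values) == nrow(coordinates), ncol(coordinates) == 3)
  if (anyDuplicated(as.data.frame(coordinates))) {
    stop("voxel coordinates must be unique", call. = FALSE)
  }
  miss <- is.na(values)
  if (!is.null(missing)) {
    stopifnot(identical(dim(missing), dim(values)))
    miss <- miss | missing
  }
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("sub%04d", seq_len(nrow(values)))
  }
  stopifnot(length(subject_ids) == nrow(values))
  structure(list(values = values, coordinates = coordinates, missing = miss,
                 subject_ids = subject_ids, grid_dims = grid_dims),
            class = "contrast_matrix")
}

#' @export
print.contrast_matrix <- function(x, ...) {
  cat(sprintf("<contrast_matrix> %d subjects x %d voxels (%d missing entries)\n",
              nrow(x$values), ncol(x$values), sum(x$missing)))
  invisible(x)
}

#' Subset a contrast matrix by subject
#'
#' @param X A [contrast_matrix()].
#' @param subjects Integer or logical index over subjects.
#' @return A [contrast_matrix()] restricted to the selected subjects.
#' @export
subset_subjects <- function(X, subjects) {
  contrast_matrix(X$values[subjects, , drop = FALSE], X$coordinates,
                  missing = X$missing[subjects, , drop = FALSE],
                  subject_ids = X$subject_ids[subjects],
                  grid_dims = X$grid_dims)
}

#' Remove high-missingness subjects, then incomplete voxels
#'
#' First removes every subject whose missing-voxel count exceeds the sample
#' mean by more than `sd_limit` standard deviations (computed once, over all
#' subjects), then removes every voxel with any remaining missing value, so
#' that all downstream analyses run on complete data.
#'
#' @param X A [contrast_matrix()].
#' @param sd_limit Subject missingness threshold in SD units (default 4).
#' @return The filtered [contrast_matrix()], with attributes
#'   `removed_subjects` and `removed_voxels` recording the dropped indices.
#' @export
missing_data_filter <- function(X, sd_limit = 4) {
  stopifnot(inherits(X, "contrast_matrix"))
  counts <- rowSums(X$missing)
  s <- stats::sd(counts)
  keep_sub <- if (is.finite(s) && s > 0) {
    counts <= mean(counts) + sd_limit * s
  } else {
    rep(TRUE, length(counts))
  }
  vals <- X$values[keep_sub, , drop = FALSE]
  miss <- X$missing[keep_sub, , drop = FALSE]
  keep_vox <- colSums(miss) == 0
  if (!any(keep_vox)) {
    stop("all voxels removed by the missing-data filter", call. = FALSE)
  }
  out <- contrast_matrix(vals[, keep_vox, drop = FALSE],
                         X$coordinates[keep_vox, , drop = FALSE],
                         subject_ids = X$subject_ids[keep_sub],
                         grid_dims = X$grid_dims)
  attr(out, "removed_subjects") <- which(!keep_sub)
  attr(out, "removed_voxels") <- which(!keep_vox)
  out
}

#' Voxel-wise one-sample t tests against zero
#'
#' @param X A [contrast_matrix()] or subjects x voxels matrix (complete
#'   data).
#' @return A data.frame with per-voxel `mean`, `sd`, `t`, `df`, two-sided
#'   `p`, and a `zero_variance` flag (t and p are `NA` for flagged voxels).
#' @export
one_sample_t_map <- function(X) {
  vals <- if (inherits(X, "contrast_matrix")) X$values else as.matrix(X)
  m <- nrow(vals)
  if (m < 2) stop("at least 2 subjects required", call. = FALSE)
  mu <- colMeans(vals)
  sds <- sqrt(colSums(sweep(vals, 2, mu)^2) / (m - 1))
  zero_var <- sds < .Machine$double.eps^0.5
  t_stat <- ifelse(zero_var, NA_real_, mu / (sds / sqrt(m)))
  p <- 2 * stats::pt(-abs(t_stat), df = m - 1)
  data.frame(mean = mu, sd = sds, t = t_stat, df = m - 1, p = p,
             zero_variance = zero_var)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment of a vector of p values; a test is rejected when
#' its adjusted value is at most `alpha` (boundary inclusive).
#'
#' @param p_values Numeric vector of p values in \[0, 1\] (`NA` allowed).
#' @param alpha FDR level (default 0.05).
#' @return List with `q` (adjusted p values) and logical `reject`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) {
    return(list(q = numeric(0), reject = logical(0)))
  }
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Define the working-memory network mask
#'
#' The working-memory network (WMN) is the set of voxels significantly more
#' active under the 2-back than the 0-back condition: positive t statistic
#' and FDR-adjusted p value at most `alpha`.
#'
#' @param t_map Per-voxel t statistics (vector, or the data.frame returned
#'   by [one_sample_t_map()]).
#' @param q_map Per-voxel FDR-adjusted p values, aligned with `t_map`.
#' @param alpha FDR level (default 0.05).
#' @return A data.frame of class `wmn_mask` with columns `t`, `q`,
#'   `in_mask`.
#' @export
define_wmn_mask <- function(t_map, q_map, alpha = 0.05) {
  t_vec <- if (is.data.frame(t_map)) t_map$t else t_map
  stopifnot(length(t_vec) == length(q_map))
  in_mask <- !is.na(t_vec) & !is.na(q_map) & t_vec > 0 & q_map <= alpha
  out <- data.frame(t = t_vec, q = q_map, in_mask = in_mask)
  class(out) <- c("wmn_mask", "data.frame")
  out
}

#' Distributional diagnostics of a contrast matrix
#'
#' Sample skewness, non-excess kurtosis (normal = 3), and Shapiro-Wilk W and
#' p per subject (row) and per voxel (column). Shapiro-Wilk is computed only
#' for vector lengths between 3 and 5000; constant vectors are flagged and
#' their diagnostics set to `NA`.
#'
#' @param X A [contrast_matrix()] or subjects x voxels matrix.
#' @return List with data.frames `subjects` and `voxels`, each holding
#'   `skewness`, `kurtosis`, `shapiro_w`, `shapiro_p`, `constant`.
#' @export
gaussianity_diagnostics <- function(X) {
  vals <- if (inherits(X, "contrast_matrix")) X$values else as.matrix(X)
  diag_vec <- function(x) {
    if (length(x) < 3 || stats::sd(x) < .Machine$double.eps^0.5) {
      return(c(NA_real_, NA_real_, NA_real_, NA_real_, 1))
    }
    sw <- if (length(x) <= 5000) {
      s <- stats::shapiro.test(x)
      c(unname(s$statistic), s$p.value)
    } else {
      c(NA_real_, NA_real_)
    }
    c(sample_skewness(x), sample_kurtosis(x), sw, 0)
  }
  per_margin <- function(mat, margin) {
    out <- t(apply(mat, margin, diag_vec))
    out <- as.data.frame(out)
    names(out) <- c("skewness", "kurtosis", "shapiro_w", "shapiro_p",
                    "constant")
    out$constant <- out$constant == 1
    out
  }
  list(subjects = per_margin(vals, 1), voxels = per_margin(vals, 2))
}
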