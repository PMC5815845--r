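# Internal helpers shared across the pipeline.

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
# All stochastic operations in the package go through this so that identical
# (inputs, seed) pairs give bit-identical results without disturbing the
# global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# z-score a numeric vector; constant input yields an error unless allow_zero,
# in which case zeros are returned.
zscore <- function(x, allow_zero = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps^0.5) {
    if (allow_zero) return(rep(0, length(x)))
    stop("cannot z-score a (near-)constant vector", call. = FALSE)
  }
  (x - mean(x)) / s
}

# Coerce a column for use in a z-scored regression design: factors and
# character vectors become integer codes, logicals 0/1.
as_numeric_column <- function(x) {
  if (is.factor(x)) return(as.numeric(x))
  if (is.character(x)) return(as.numeric(factor(x)))
  if (is.logical(x)) return(as.numeric(x))
  as.numeric(x)
}

# Build a z-scored numeric design matrix from a data.frame/matrix.
zscore_frame <- function(df) {
  df <- as.data.frame(df)
  out <- vapply(df, function(col) zscore(as_numeric_column(col)),
                numeric(nrow(df)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(df))
  colnames(out) <- names(df)
  out
}

# Sample skewness m3 / m2^(3/2) and non-excess kurtosis m4 / m2^2
# (normal = 3), using biased central moments.
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < .Machine$double.eps) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

sample_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < .Machine$double.eps) return(NA_real_)
  mean((x - m)^4) / m2^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
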